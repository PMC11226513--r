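test_that("assimilation follows Monod kinetics with shutoff at zero substrate", {
  expect_equal(assimilation_flux(1.7396, 0, 1e-6), 0)
  expect_equal(assimilation_flux(1.7396, -1e-9, 1e-6), 0)
  expect_equal(assimilation_flux(1.7396, 1e-6, 1e-6), 1.7396 / 2)
  # at working concentrations S/(K+S) is essentially 1
  expect_equal(assimilation_flux(0.2405, 1.4e-3, 1e-6),
               0.2405 * 1.4e-3 / (1e-6 + 1.4e-3))
  expect_lt(abs(assimilation_flux(0.2405, 1.4e-3, 1e-6) - 0.2405) / 0.2405,
            1e-3)
  expect_equal(assimilation_flux(1.7396, 0.03, 1e-6, alive = FALSE), 0)
  expect_error(assimilation_flux(-1, 0.1, 1e-6),
               class = "debatch_validation_error")
  expect_error(assimilation_flux(1, 0.1, -1e-6),
               class = "debatch_validation_error")
})

test_that("mobilization is first order in reserve density and floored at zero", {
  expect_equal(mobilization_flux(0, 5.3, 0.5), 0)
  expect_equal(mobilization_flux(0.3282, 5.3, 5.3), 0)
  expect_equal(mobilization_flux(0.3282, 5.3, 0.5), 0.3282 * 4.8)
  expect_equal(mobilization_flux(0.3282, 5.3, 6), 0)   # r > kE guard
  expect_error(mobilization_flux(-0.1, 5.3, 0.5),
               class = "debatch_validation_error")
})

test_that("SU growth flux: hand values, complementarity, single-substrate limit", {
  # scaled inputs a = b = 1 give 1/(1 + 1 - 1/2) = 2/3
  expect_equal(growth_flux_su(1, 1), 2 / 3)
  expect_equal(growth_flux_su(0, 1), 0)
  expect_equal(growth_flux_su(1, 0), 0)
  # as one input grows the flux approaches the other input
  expect_equal(growth_flux_su(1, 1e9), 1, tolerance = 1e-6)
  expect_error(growth_flux_su(NaN, 1), class = "debatch_validation_error")
  expect_error(growth_flux_su(Inf, 1), class = "debatch_validation_error")
})

test_that("SU flux is strictly below the minimum of its scaled inputs", {
  set.seed(41)
  a <- 10^runif(300, -4, 3)
  b <- 10^runif(300, -4, 3)
  jg <- growth_flux_su(a, b)
  expect_true(all(jg < pmin(a, b)))
  expect_true(all(jg > 0))
})

test_that("the product-flux form reduces to the simplified SU form for large jP", {
  set.seed(42)
  a <- 10^runif(50, -3, 2)
  b <- 10^runif(50, -3, 2)
  fast <- growth_flux_su(a, b)
  full <- growth_flux_su(a, b, jP = 1e9 * max(a, b))
  expect_equal(full, fast, tolerance = 1e-6)
  # and a moderate jP strictly lowers the flux
  expect_true(all(growth_flux_su(a, b, jP = 1) < fast))
})

test_that("rejected flux is the SU leftover and is never negative", {
  expect_equal(rejected_flux(1.1, 1.1, 1.0), 0)
  expect_equal(rejected_flux(0, 0.23, 0), 0)
  # symmetric case a = b = 1 via the SU: jEcR = 1.1 * (1 - 2/3)
  jG <- growth_flux_su(1.1, 0.23, 1.1, 0.23)
  expect_equal(jG, 2 / 3)
  expect_equal(rejected_flux(1.1, 1.1, jG), 1.1 / 3, tolerance = 1e-12)
  expect_error(rejected_flux(1.0, 1.1, 1.0),
               class = "debatch_numerical_error")
})

test_that("switch-model maintenance charges structure only for the shortfall", {
  expect_equal(switch_maintenance(0.7, 0.6104, 1.1), 0)
  expect_equal(switch_maintenance(0.6104, 0.6104, 1.1), 0)
  expect_equal(switch_maintenance(0.1, 0.6104, 1.1), (0.6104 - 0.1) / 1.1)
})

test_that("the growth-rate fixed point satisfies r = jG(r)", {
  p <- table_params()
  set.seed(7)
  for (i in 1:20) {
    mEc <- 10^runif(1, -2, 0.5)
    mEn <- 10^runif(1, -2.5, 0)
    r <- deb_growth_rate(mEc, mEn, p)
    expect_lt(abs(debatch:::growth_at_rate(r, mEc, mEn, p) - r), 1e-9)
    expect_gte(r, 0)
    expect_lt(r, p$kE)
  }
})

test_that("flux set is self-consistent and signals the death condition", {
  p <- table_params()
  st <- midlog_state(p)
  fl <- deb_fluxes(st, p)
  expect_true(fl$maintenance_ok)
  expect_equal(fl$r, fl$jG)
  # reserve bookkeeping identities
  expect_equal(fl$jEcG, fl$jEcC - p$jEcM, tolerance = 1e-12)
  expect_equal(fl$jEcR, fl$jEcG - p$yEcV * fl$jG, tolerance = 1e-10)
  expect_equal(fl$jVM, 0)  # maintenance fully covered at mid-log
  # dead or empty culture: all fluxes zero
  dead <- culture_state(st$SC, st$SN, st$mEc, st$mEn, st$MV, alive = FALSE)
  expect_true(all(unlist(deb_fluxes(dead, p)[FLUX_NAMES]) == 0))
  empty <- culture_state(st$SC, st$SN, st$mEc, st$mEn, MV = 0)
  expect_true(all(unlist(deb_fluxes(empty, p)[FLUX_NAMES]) == 0))
  # starved reserves cannot pay maintenance
  starved <- culture_state(0, 0, mEc = 0.01, mEn = 0.001, MV = 1e-3)
  expect_false(deb_fluxes(starved, p)$maintenance_ok)
})

test_that("R reference derivatives agree with the compiled right-hand side", {
  p <- table_params()
  set.seed(11)
  for (i in 1:5) {
    # reserve ranges keep mobilization above maintenance (a live culture)
    st <- culture_state(SC = 10^runif(1, -4, -1), SN = 10^runif(1, -5, -2),
                        mEc = 10^runif(1, -0.6, 0.4), mEn = 10^runif(1, -2, -0.5),
                        MV = 10^runif(1, -5, -2))
    rhs <- deb_rhs(st, p)
    # one microscopic compiled step reproduces the same derivative
    tr <- deb_simulate(p, state0 = st, times = c(0, 1e-7, 2e-7),
                       rtol = 1e-10, atol = 1e-16)
    num <- (unlist(tr[2, c("SC_cmol_L", "SN_mol_L", "mEc", "mEn", "MV_cmol",
                           "dissC", "dissN")]) -
            unlist(tr[1, c("SC_cmol_L", "SN_mol_L", "mEc", "mEn", "MV_cmol",
                           "dissC", "dissN")])) / 1e-7
    expect_equal(unname(num), unname(rhs$dydt), tolerance = 1e-5)
    # and the reported instantaneous fluxes match the R flux set
    fl <- deb_fluxes(st, p)
    expect_equal(tr$jG[1], fl$jG, tolerance = 1e-9)
    expect_equal(tr$jEcR[1], fl$jEcR, tolerance = 1e-8)
    expect_equal(tr$JNH3[1], fl$JNH3, tolerance = 1e-8)
  }
})

test_that("full recycling removes the substrate-return term", {
  p <- update_params(table_params(), kappaEc = 1, kappaEn = 1)
  st <- midlog_state(p)
  rhs <- deb_rhs(st, p)
  fl <- rhs$fluxes
  expect_equal(rhs$dydt[["SC"]], -fl$jEcA * p$ySEc * st$MV / st$V)
  expect_equal(rhs$dydt[["SN"]],
               -fl$jEnA * p$ySEn * st$MV / st$V + fl$JNH3 / st$V)
})

test_that("balanced reserves solve the joint steady state", {
  p <- table_params()
  br <- balanced_reserves(p, SC = 1, SN = 1)
  st <- culture_state(SC = 1, SN = 1, mEc = br[["mEc"]], mEn = br[["mEn"]],
                      MV = 1e-3)
  # at S >> K the balanced state has dm/dt ~ 0 for both reserves
  rhs <- deb_rhs(st, p)
  expect_lt(abs(rhs$dydt[["mEc"]]), 1e-8)
  expect_lt(abs(rhs$dydt[["mEn"]]), 1e-8)
  expect_equal(br[["r"]], rhs$fluxes$r, tolerance = 1e-8)
})

test_that("a non-rejected reserve settles at the assimilation/turnover ratio", {
  # extreme nitrogen excess: the C reserve is the sole limitation and its
  # rejected flux vanishes, giving the closed form mEc* = jEcAm/kE
  p <- update_params(table_params(), jEnAm = 2405)
  br <- balanced_reserves(p)
  expect_equal(br[["mEc"]], p$jEcAm / p$kE, tolerance = 1e-6)
})
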