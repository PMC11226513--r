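test_that("carbon and nitrogen are conserved along every scenario trajectory", {
  p <- table_params()
  for (scn in limitation_scenarios()) {
    tr <- deb_simulate(p, scenario = scn)
    tot <- element_totals(tr, p)
    expect_lt(diff(range(tot$C)) / tot$C[1], 1e-6)
    expect_lt(diff(range(tot$N)) / tot$N[1], 1e-6)
  }
})

test_that("the metabolite ammonia flux is exactly what closes the N balance", {
  p <- table_params()
  st <- midlog_state(p)
  with_nh3 <- deb_rhs(st, p, include_nh3 = TRUE)
  without <- deb_rhs(st, p, include_nh3 = FALSE)
  # total-N rate: d(SN*V)/dt + d(mEn*MV)/dt + nNV*dMV/dt + d(dissN)/dt
  n_dot <- function(rhs)
    rhs$dydt[["SN"]] * st$V + rhs$dydt[["mEn"]] * st$MV +
      st$mEn * rhs$dydt[["MV"]] + p$nNV * rhs$dydt[["MV"]] + rhs$dydt[["dissN"]]
  expect_equal(n_dot(with_nh3), 0, tolerance = 1e-14)
  # dropping the closure flux breaks conservation by exactly its magnitude
  expect_equal(n_dot(without), -with_nh3$fluxes$JNH3, tolerance = 1e-12)
})

test_that("carbon limitation: glucose exhausts first, then the culture dies", {
  p <- table_params()
  tr <- deb_simulate(p, scenario = limitation_scenarios()$C1)
  dt <- attr(tr, "death_time")
  expect_false(is.na(dt))
  # glucose effectively exhausted at death, ammonium only slightly drawn down
  at_death <- tr[which.max(tr$time_h >= dt), ]
  expect_lt(at_death$SC_cmol_L, 1e-6)
  expect_gt(at_death$SN_mol_L, 0.5 * grams_to_cmol(0.75, "NH4Cl"))
  # biomass rose by orders of magnitude before arrest
  expect_gt(at_death$biomass_cmol_L / tr$biomass_cmol_L[1], 100)
})

test_that("after death the culture is frozen and flagged dead", {
  p <- table_params()
  tr <- deb_simulate(p, scenario = limitation_scenarios()$C1)
  dt <- attr(tr, "death_time")
  post <- tr[tr$time_h >= dt, ]
  expect_true(all(!post$alive[post$time_h > dt]))
  for (col in c("SC_cmol_L", "SN_mol_L", "mEc", "mEn", "MV_cmol",
                "biomass_cmol_L", "dissC", "dissN"))
    expect_equal(diff(range(post[[col]])), 0)
  expect_true(all(post$r_h == 0))
  expect_true(all(post$jEcA == 0))
})

test_that("no state variable dips below the solver's absolute tolerance", {
  p <- table_params()
  for (scn in limitation_scenarios()[c("C1", "N1")]) {
    tr <- deb_simulate(p, scenario = scn)
    for (col in c("SC_cmol_L", "SN_mol_L", "mEc", "mEn", "MV_cmol"))
      expect_gt(min(tr[[col]]), -1e-9)
  }
})

test_that("substrate excess yields steady exponential growth (weak homeostasis)", {
  p <- table_params()
  scn <- scenario("excess", glucose = 40, nh4cl = 5, inoculum = 4e-5,
                  horizon = 7, interval = 0.25)
  tr <- deb_simulate(p, scenario = scn)
  r_late <- tr$r_h[tr$time_h >= 5]
  expect_lt(max(abs(diff(r_late))), 1e-6)
  # growth is exponential: log-biomass is linear in time
  lb <- log(tr$biomass_cmol_L[tr$time_h >= 5])
  dt <- diff(tr$time_h[tr$time_h >= 5])
  expect_equal(diff(lb) / dt, r_late[-1], tolerance = 1e-6)
})

test_that("the limiting-reserve steady density matches jEAm/kE by simulation", {
  # nitrogen made effectively unlimiting: C reserve is never rejected
  p <- update_params(table_params(), jEnAm = 2405)
  scn <- scenario("single", glucose = 40, nh4cl = 50, inoculum = 4e-5,
                  horizon = 6, interval = 0.5,
                  reserves = c(mEc = 0.2, mEn = 10))
  tr <- deb_simulate(p, scenario = scn)
  expect_equal(tail(tr$mEc, 1), p$jEcAm / p$kE, tolerance = 5e-5)
})

test_that("an empty or dead inoculum gives a flat trajectory", {
  p <- table_params()
  st <- culture_state(SC = 0.03, SN = 1e-3, mEc = 0.3, mEn = 0.05, MV = 0)
  tr <- deb_simulate(p, state0 = st, times = 0:5)
  expect_true(all(tr$MV_cmol == 0))
  expect_true(all(tr$SC_cmol_L == 0.03))
  dead <- culture_state(SC = 0.03, SN = 1e-3, mEc = 0.3, mEn = 0.05,
                        MV = 1e-4, alive = FALSE)
  trd <- deb_simulate(p, state0 = dead, times = 0:5)
  expect_true(all(!trd$alive))
  expect_true(all(trd$MV_cmol == 1e-4))
})

test_that("a culture without substrates dies within half an hour from mid-log reserves", {
  p <- table_params()
  st <- midlog_state(p)
  bare <- culture_state(SC = 0, SN = 0, mEc = st$mEc, mEn = st$mEn,
                        MV = st$MV)
  tr <- deb_simulate(p, state0 = bare, times = seq(0, 2, by = 0.05))
  dt <- attr(tr, "death_time")
  expect_false(is.na(dt))
  expect_lt(dt, 0.5)
})

test_that("integration is reproducible and reports trajectories on the sampling grid", {
  p <- table_params()
  scn <- limitation_scenarios()$C2
  tr1 <- deb_simulate(p, scenario = scn)
  tr2 <- deb_simulate(p, scenario = scn)
  expect_identical(tr1, tr2)
  expect_true(all(scenario_times(scn) %in% tr1$time_h))
})
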