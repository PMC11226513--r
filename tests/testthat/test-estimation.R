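make_obs <- function(values_by_time, scenario_id = "s1", variable = "X") {
  # values_by_time: list mapping time -> replicate values
  do.call(rbind, lapply(seq_along(values_by_time), function(i) {
    v <- values_by_time[[i]]
    data.frame(scenario_id = scenario_id, variable = variable,
               time_h = i - 1, replicate = seq_along(v), value = v)
  }))
}

test_that("weights are reciprocal mean replicate variances", {
  # homoscedastic: W = 1/s^2
  obs <- make_obs(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  w <- compute_weights(obs)
  expect_equal(w$weight, 1)
  # s2 = {1, 2, 3} across times -> W = 1/mean = 0.5
  obs2 <- do.call(rbind, lapply(1:3, function(i) {
    # two replicates (0, sqrt(2 i)) have sample variance i
    data.frame(scenario_id = "s1", variable = "X", time_h = i - 1,
               replicate = 1:2, value = c(0, sqrt(2 * i)))
  }))
  expect_equal(compute_weights(obs2)$weight, 0.5)
  # single replicate anywhere: variance undefined
  duo <- make_obs(list(c(1, 2), c(2, 3)))
  expect_error(compute_weights(duo[-1, ]), class = "debatch_validation_error")
  # all-zero variance is degenerate
  flat <- make_obs(list(c(1, 1), c(2, 2)))
  expect_error(compute_weights(flat), class = "debatch_validation_error")
})

test_that("the loss reproduces hand-computed weighted squares", {
  # one variable, one scenario, residuals {1, -1}, W = 2 -> 4
  tab <- data.frame(obs = c(1, 3), fit = c(2, 2), weight = 2)
  expect_equal(sum(tab$weight * (tab$fit - tab$obs)^2), 4)
  # invariance of the full pipeline loss under row reordering
  p <- table_params()
  scns <- growth_scenarios()[c("C1", "N1")]
  obs <- synthesize_observations(scns, p, "deb", noise_model(), seed = 12)
  w <- compute_weights(obs)
  v1 <- deb_wsse(p, obs, scns, "deb", weights = w)
  shuffled <- obs[sample(nrow(obs)), ]
  expect_equal(deb_wsse(p, shuffled, scns, "deb", weights = w), v1)
  # rescaling one variable and its weight leaves the loss unchanged
  c_scale <- 1000
  obs_sc <- obs
  obs_sc$value[obs_sc$variable == "SN"] <- obs_sc$value[obs_sc$variable == "SN"]
  w_sc <- w
  w_sc$weight[w_sc$variable == "SN"] <- w_sc$weight[w_sc$variable == "SN"] / c_scale^2
  tab <- debatch:::residual_table(p, obs, scns, "deb", w, TRUE, 1e-8, 1e-12)
  contrib <- function(tt, v) sum(tt$weight[tt$variable == v] *
                                 (tt$fit - tt$obs)[tt$variable == v]^2)
  tab_sc <- tab
  tab_sc$obs[tab_sc$variable == "SN"] <- tab_sc$obs[tab_sc$variable == "SN"] * c_scale
  tab_sc$fit[tab_sc$variable == "SN"] <- tab_sc$fit[tab_sc$variable == "SN"] * c_scale
  tab_sc$weight[tab_sc$variable == "SN"] <-
    tab_sc$weight[tab_sc$variable == "SN"] / c_scale^2
  expect_equal(contrib(tab_sc, "SN"), contrib(tab, "SN"))
})

test_that("reduced chi-square is near one when weights equal the true variances", {
  p <- table_params()
  scns <- growth_scenarios()
  nm <- noise_model(cv = c(X = 0.05, SC = 0.05, SN = 0.05),
                    floor = c(X = 0, SC = 0, SN = 0))
  obs <- synthesize_observations(scns, p, "deb", nm, seed = 21)
  # with W ~ 1/sigma^2, each weighted squared mean-of-3 residual has
  # expectation ~ 1/3, so the sum over n points is ~ n/3
  w <- compute_weights(obs)
  tab <- debatch:::residual_table(p, obs, scns, "deb", w, TRUE, 1e-8, 1e-12)
  # each weighted squared mean-residual has expectation ~ 1/n_rep
  chi2 <- sum(tab$weight * (tab$fit - tab$obs)^2) / (nrow(tab) / 3)
  expect_gt(chi2, 0.5)
  expect_lt(chi2, 2)
})

test_that("goodness of fit follows the adjusted-R2 and RMSE definitions", {
  g <- goodness_of_fit(c(1, 2, 3, 4), c(1, 2, 3, 4), n_free = 1)
  expect_equal(g$r2adj, 1)
  expect_equal(g$rmse, 0)
  # fitted = mean: R2 = 0, adjusted below zero
  y <- c(1, 2, 3, 4, 5)
  g0 <- goodness_of_fit(y, rep(mean(y), 5), n_free = 1)
  expect_equal(g0$r2, 0)
  expect_lt(g0$r2adj, 0)
  expect_error(goodness_of_fit(1:2, 1:2, n_free = 1),
               class = "debatch_validation_error")
  expect_error(goodness_of_fit(rep(1, 5), rep(1, 5), n_free = 1),
               class = "debatch_validation_error")
})

test_that("fitting is deterministic and exact on noiseless Monod data", {
  mp <- monod_params()
  scns <- growth_scenarios()
  obs <- synthesize_observations(scns, mp, "monod", zero_noise())
  start <- update_params(mp, mu_max = 2 * mp$mu_max, YXSC = 2 * mp$YXSC,
                         YXSN = 2 * mp$YXSN)
  fit1 <- deb_fit(obs, scns, "monod", start = start, weights = "unit")
  fit2 <- deb_fit(obs, scns, "monod", start = start, weights = "unit")
  expect_identical(coef(fit1), coef(fit2))
  rel <- abs(coef(fit1) / unlist(unclass(mp)[fit1$free]) - 1)
  expect_true(all(rel < 1e-3))
  expect_true(fit1$convergence)
  expect_lt(fit1$wsse, 1e-10)
  expect_equal(fit1$gof$r2adj, 1, tolerance = 1e-6)
})

test_that("the Levenberg-Marquardt engine matches on the identifiable parameters", {
  p <- table_params()
  scns <- growth_scenarios()
  obs <- synthesize_observations(scns, p, "deb", zero_noise())
  start <- update_params(p, jEcAm = 1.5 * p$jEcAm, jEnAm = 1.5 * p$jEnAm,
                         jEcM = 1.5 * p$jEcM)
  fit <- deb_fit(obs, scns, "deb", method = "lm", start = start,
                 free = c("jEcAm", "jEnAm", "jEcM"), weights = "unit")
  rel <- abs(coef(fit) / unlist(unclass(p)[fit$free]) - 1)
  expect_true(all(rel < 1e-2))
})

test_that("two-stage turnover estimation recovers the generating kE", {
  p <- table_params()
  scns <- growth_scenarios()
  obs <- synthesize_observations(scns, p, "deb", zero_noise())
  fit <- deb_fit(obs, scns, "deb", start = update_params(p, kE = 4),
                 free = c("jEcAm"), weights = "unit",
                 kE_mode = "two_stage",
                 control = list(maxit = 200, restarts = 0))
  expect_equal(length(fit$kE_stage), 2)
  expect_equal(unname(fit$params$kE), p$kE, tolerance = 0.02)
})

test_that("prediction intervals collapse at zero residual variance and cover new data", {
  mp <- monod_params()
  scns <- growth_scenarios()[c("C1", "N1")]
  # near-degenerate: tiny noise -> near-collapsed band
  tiny <- noise_model(cv = c(X = 1e-8, SC = 1e-8, SN = 1e-8),
                      floor = c(X = 0, SC = 0, SN = 0))
  obs <- synthesize_observations(scns, mp, "monod", tiny, seed = 2)
  fit <- deb_fit(obs, scns, "monod", method = "lm", start = mp)
  pi <- prediction_interval(fit)
  expect_lt(max(pi$upr - pi$lwr), 1e-5)
  # large-n normal limit: half-width -> 1.96 * sigma
  set.seed(8)
  n <- 2000
  yobs <- rnorm(n, 10, 0.5)
  g <- goodness_of_fit(yobs, rep(10, n), n_free = 0)
  halfwidth <- qt(0.975, n) * sqrt(sum((yobs - 10)^2) / n)
  expect_equal(halfwidth, 1.96 * 0.5, tolerance = 0.05)
})

test_that("95% prediction bands cover about 95% of new replicate observations", {
  mp <- monod_params()
  scns <- growth_scenarios()[c("C1", "N2")]
  # additive (homoscedastic) noise matches the pooled-residual-SD
  # construction of the band; proportional noise would not (see the
  # methods vignette)
  nm <- noise_model(cv = c(X = 0, SC = 0, SN = 0),
                    floor = c(X = 3e-4, SC = 2e-3, SN = 2e-4))
  covered <- 0; total <- 0
  for (sd in 1:25) {
    obs <- synthesize_observations(scns, mp, "monod", nm, seed = 1000 + sd)
    fit <- deb_fit(obs, scns, "monod", method = "lm", start = mp,
                   control = list(restarts = 0))
    pi <- prediction_interval(fit, level = 0.95)
    fresh <- synthesize_observations(scns, mp, "monod", nm, seed = 5000 + sd)
    fresh1 <- fresh[fresh$replicate == 1, ]
    key <- paste(fresh1$scenario_id, fresh1$variable, fresh1$time_h)
    pk <- paste(pi$scenario_id, pi$variable, pi$time_h)
    idx <- match(key, pk)
    ok <- fresh1$value >= pi$lwr[idx] & fresh1$value <= pi$upr[idx]
    covered <- covered + sum(ok); total <- total + length(ok)
  }
  coverage <- covered / total
  expect_gt(coverage, 0.90)
  expect_lte(coverage, 0.99)
})
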