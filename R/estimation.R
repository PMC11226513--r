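# Observation tables are long-format data frames with columns
# scenario_id, variable ("X", "SC", "SN"), time_h, replicate, value;
# biomass X in C-mol/L, SC in C-mol/L, SN in mol/L.

OBS_VARIABLES <- c("X", "SC", "SN")

check_observations <- function(observations) {
  need <- c("scenario_id", "variable", "time_h", "replicate", "value")
  if (!all(need %in% names(observations)))
    stop_validation("observations need columns ",
                    paste(need, collapse = ", "))
  if (!all(observations$variable %in% OBS_VARIABLES))
    stop_validation("observation variables must be among ",
                    paste(OBS_VARIABLES, collapse = ", "))
  if (any(observations$time_h < 0))
    stop_validation("observation times must be non-negative")
  observations
}

# per (scenario, variable, time): replicate mean, sample variance, count
obs_moments <- function(observations) {
  key <- interaction(observations$scenario_id, observations$variable,
                     observations$time_h, drop = TRUE)
  mom <- do.call(rbind, lapply(split(observations, key), function(d) {
    data.frame(scenario_id = d$scenario_id[1], variable = d$variable[1],
               time_h = d$time_h[1], mean = mean(d$value),
               s2 = if (nrow(d) >= 2) var(d$value) else NA_real_,
               n_rep = nrow(d))
  }))
  rownames(mom) <- NULL
  mom[order(mom$scenario_id, mom$variable, mom$time_h), ]
}

#' Reciprocal-mean-variance weights
#'
#' One weight per variable per scenario: the reciprocal of the mean (over
#' sampling times) of the replicate sample variances.  Requires at least
#' two replicates wherever a variance is claimed; an all-zero variance is
#' degenerate and rejected.
#'
#' @param observations an observation table (see [synthesize_observations()]).
#' @return data frame with columns \code{scenario_id}, \code{variable},
#'   \code{weight}.
#' @export
compute_weights <- function(observations) {
  observations <- check_observations(observations)
  mom <- obs_moments(observations)
  if (any(mom$n_rep < 2))
    stop_validation("weights need >= 2 replicates at every sampling time")
  key <- interaction(mom$scenario_id, mom$variable, drop = TRUE)
  out <- do.call(rbind, lapply(split(mom, key), function(d) {
    mv <- mean(d$s2)
    if (!is.finite(mv) || mv <= 0)
      stop_validation("degenerate (zero) replicate variance for variable '",
                      d$variable[1], "' in scenario '", d$scenario_id[1], "'")
    data.frame(scenario_id = d$scenario_id[1], variable = d$variable[1],
               weight = 1 / mv)
  }))
  rownames(out) <- NULL
  out
}

# model curves at requested times for one scenario
model_curve <- function(params, scn, times, model, rtol, atol) {
  times_full <- sort(unique(c(0, times)))
  if (model == "deb") {
    tr <- deb_simulate(params, scenario = scn, times = times_full,
                       rtol = rtol, atol = atol)
    idx <- match(times, tr$time_h)
    data.frame(time_h = times, X = tr$biomass_cmol_L[idx],
               SC = tr$SC_cmol_L[idx], SN = tr$SN_mol_L[idx])
  } else {
    tr <- monod_simulate(params, scenario = scn, times = times_full,
                         rtol = rtol, atol = atol)
    idx <- match(times, tr$time_h)
    data.frame(time_h = times, X = tr$X_cmol_L[idx],
               SC = tr$SC_cmol_L[idx], SN = tr$SN_mol_L[idx])
  }
}

# fitting target: one row per compared point, with weights attached
obs_target <- function(observations, weights, fit_means) {
  obs <- if (fit_means) {
    mom <- obs_moments(observations)
    data.frame(scenario_id = as.character(mom$scenario_id),
               variable = as.character(mom$variable),
               time_h = mom$time_h, obs = mom$mean,
               stringsAsFactors = FALSE)
  } else {
    data.frame(scenario_id = as.character(observations$scenario_id),
               variable = as.character(observations$variable),
               time_h = observations$time_h, obs = observations$value,
               stringsAsFactors = FALSE)
  }
  key <- paste(obs$scenario_id, obs$variable)
  wkey <- paste(weights$scenario_id, weights$variable)
  obs$weight <- weights$weight[match(key, wkey)]
  if (any(is.na(obs$weight)))
    stop_validation("missing weight for some scenario/variable pair")
  obs[order(obs$scenario_id, obs$variable, obs$time_h), ]
}

# model values at the target points (vectorized per scenario)
target_fit <- function(params, target, scenarios, model, rtol, atol) {
  fit <- numeric(nrow(target))
  for (sid in unique(target$scenario_id)) {
    scn <- scenarios[[sid]]
    if (is.null(scn))
      stop_validation("no scenario definition for id '", sid, "'")
    rows <- which(target$scenario_id == sid)
    tt <- sort(unique(target$time_h[rows]))
    cur <- model_curve(params, scn, tt, model, rtol, atol)
    ti <- match(target$time_h[rows], cur$time_h)
    fit[rows] <- vapply(seq_along(rows), function(k)
      cur[[target$variable[rows[k]]]][ti[k]], numeric(1))
  }
  fit
}

# residual table: observed (means or replicates) vs model, with weights
residual_table <- function(params, observations, scenarios, model,
                           weights, fit_means, rtol, atol) {
  target <- obs_target(observations, weights, fit_means)
  target$fit <- target_fit(params, target, scenarios, model, rtol, atol)
  rownames(target) <- NULL
  target[c("scenario_id", "variable", "time_h", "obs", "fit", "weight")]
}

#' Weighted sum of squared errors of a model against observations
#'
#' The estimation loss: for every limitation scenario, each variable's
#' squared deviations between the simulated curve (evaluated at the
#' observation times) and the observations are summed and multiplied by
#' that variable's scenario weight, then summed over variables and
#' scenarios.  A parameter set at which a simulation fails maps to
#' \code{+Inf} rather than raising, which keeps a simplex search alive
#' near death-event discontinuities.
#'
#' @param params a [deb_params()] or [monod_params()] object.
#' @param observations an observation table.
#' @param scenarios named list of [scenario()] objects covering the
#'   \code{scenario_id}s present.
#' @param model \code{"deb"} or \code{"monod"}.
#' @param weights weight table from [compute_weights()]; \code{NULL}
#'   computes it; \code{"unit"} uses unit weights.
#' @param fit_means compare the model against replicate means (the
#'   default estimation mode) or against every replicate.
#' @param rtol,atol solver tolerances used during loss evaluation.
#' @return the scalar loss (non-negative, possibly \code{Inf}).
#' @export
deb_wsse <- function(params, observations, scenarios,
                     model = c("deb", "monod"), weights = NULL,
                     fit_means = TRUE, rtol = 1e-8, atol = 1e-12) {
  model <- match.arg(model)
  observations <- check_observations(observations)
  weights <- resolve_weights(weights, observations)
  tab <- tryCatch(
    residual_table(params, observations, scenarios, model, weights,
                   fit_means, rtol, atol),
    debatch_numerical_error = function(e) NULL)
  if (is.null(tab)) return(Inf)
  s <- sum(tab$weight * (tab$fit - tab$obs)^2)
  if (!is.finite(s)) Inf else s
}

resolve_weights <- function(weights, observations) {
  if (is.null(weights)) return(compute_weights(observations))
  if (identical(weights, "unit")) {
    u <- unique(observations[c("scenario_id", "variable")])
    u$weight <- 1
    return(u)
  }
  if (!all(c("scenario_id", "variable", "weight") %in% names(weights)))
    stop_validation("'weights' must have scenario_id, variable, weight")
  if (any(weights$weight <= 0)) stop_validation("weights must be positive")
  weights
}

default_free <- function(model) {
  if (model == "deb") c("jEcAm", "jEnAm", "jEcM", "jEnM")
  else c("mu_max", "YXSC", "YXSN")
}

#' Fit the DEB or Monod model to limitation-scenario observations
#'
#' Simultaneous weighted nonlinear least squares across all scenarios:
#' the loss is the scenario- and variable-weighted sum of squared errors
#' ([deb_wsse()]), minimized over the free parameters by the Nelder-Mead
#' simplex.  Parameters are optimized in log space, which enforces
#' positivity without hard bounds; the search is restarted once at its
#' own optimum to guard against premature simplex collapse.  Fitting is
#' deterministic for fixed data and starting point.
#'
#' By default the DEB free parameters are the two maximum assimilation
#' rates and the two maintenance coefficients, with the reserve turnover
#' rate held fixed; \code{kE_mode = "two_stage"} first estimates the
#' turnover rate separately on the carbon- and the nitrogen-limitation
#' scenario groups (other parameters at their starting values) and fixes
#' it at the mean of the two before the main fit.  The Monod free
#' parameters are the maximum growth rate and the two yields; the
#' half-saturation constants stay fixed in both models.
#'
#' @param observations observation table (long format; see
#'   [synthesize_observations()] and [read_observations()]).
#' @param scenarios named list of [scenario()] objects.
#' @param model \code{"deb"} or \code{"monod"}.
#' @param method \code{"nelder-mead"} (the reference procedure) or
#'   \code{"lm"}, Levenberg-Marquardt on the square-root-weighted
#'   residual vector — faster on well-behaved problems and often better
#'   in the sloppy, strongly correlated directions of ODE fits; both
#'   operate on log parameters.
#' @param start starting parameter object; defaults to [deb_params()] or
#'   [monod_params()].
#' @param free character vector of parameter names to estimate.
#' @param weights \code{NULL} (reciprocal mean replicate variance),
#'   \code{"unit"}, or a weight table.
#' @param fit_means fit replicate means (default) or individual
#'   replicates.
#' @param kE_mode \code{"fixed"} or \code{"two_stage"} (DEB only).
#' @param control list: \code{maxit} (default 2000), \code{reltol}
#'   (1e-10), \code{restarts} (1), \code{rtol}, \code{atol} (solver
#'   tolerances during fitting).
#' @return an object of class \code{"deb_fit"} with components
#'   \code{params} (fitted parameter object), \code{free}, \code{wsse},
#'   \code{gof} (pooled weighted R2, adjusted R2, RMSE, per-variable R2),
#'   \code{residuals} (residual table), \code{convergence} (TRUE if the
#'   simplex converged), \code{counts}, and the inputs needed by the
#'   methods.  Non-convergence is flagged, not raised.
#' @seealso [predict.deb_fit()], [prediction_interval()],
#'   [simulate.deb_fit()]
#' @export
deb_fit <- function(observations, scenarios, model = c("deb", "monod"),
                    method = c("nelder-mead", "lm"),
                    start = NULL, free = NULL, weights = NULL,
                    fit_means = TRUE, kE_mode = c("fixed", "two_stage"),
                    control = list()) {
  model <- match.arg(model)
  method <- match.arg(method)
  kE_mode <- match.arg(kE_mode)
  observations <- check_observations(observations)
  ctl <- modifyList(list(maxit = 2000, reltol = 1e-10, restarts = 1,
                         rtol = 1e-8, atol = 1e-12, trace = 0,
                         epsfcn = 1e-6), control)
  start <- start %||% if (model == "deb") deb_params() else monod_params()
  free <- free %||% default_free(model)
  bad <- setdiff(free, names(unclass(start)))
  if (length(bad))
    stop_validation("unknown free parameter(s): ", paste(bad, collapse = ", "))
  weights <- resolve_weights(weights, observations)

  kE_stage <- NULL
  if (model == "deb" && kE_mode == "two_stage") {
    groups <- split(names(scenarios),
                    vapply(scenarios, `[[`, "", "limitation"))
    groups <- groups[names(groups) %in% c("C", "N")]
    kE_stage <- vapply(groups, function(ids) {
      obs_g <- observations[observations$scenario_id %in% ids, , drop = FALSE]
      w_g <- weights[weights$scenario_id %in% ids, , drop = FALSE]
      opt <- optimize(function(lk) {
        deb_wsse(update_params(start, kE = exp(lk)), obs_g,
                 scenarios[ids], model, w_g, fit_means, ctl$rtol, ctl$atol)
      }, interval = log(start$kE) + c(-log(10), log(10)), tol = 1e-6)
      exp(opt$minimum)
    }, numeric(1))
    start <- update_params(start, kE = mean(kE_stage))
  }

  target <- obs_target(observations, weights, fit_means)
  p0 <- unlist(unclass(start)[free])
  objective <- function(logp) {
    p <- tryCatch(do.call(update_params, c(list(start),
                                           as.list(setNames(exp(logp), free)))),
                  debatch_validation_error = function(e) NULL)
    if (is.null(p)) return(Inf)
    fit <- tryCatch(
      target_fit(p, target, scenarios, model, ctl$rtol, ctl$atol),
      debatch_numerical_error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    s <- sum(target$weight * (fit - target$obs)^2)
    if (is.finite(s)) s else Inf
  }

  par <- log(p0)
  counts <- c(0, 0)
  conv <- 1L
  if (method == "nelder-mead") {
    for (i in seq_len(1 + ctl$restarts)) {
      opt <- if (length(par) == 1L) {
        # the simplex is unreliable in one dimension; bracketed search
        optim(par, objective, method = "Brent",
              lower = par - log(100), upper = par + log(100),
              control = list(maxit = ctl$maxit))
      } else {
        optim(par, objective, method = "Nelder-Mead",
              control = list(maxit = ctl$maxit, reltol = ctl$reltol,
                             trace = ctl$trace))
      }
      par <- opt$par
      counts <- counts + opt$counts[1]
      conv <- opt$convergence
    }
  } else {
    resid_fn <- function(logp) {
      p <- tryCatch(do.call(update_params,
                            c(list(start), as.list(setNames(exp(logp), free)))),
                    debatch_validation_error = function(e) NULL)
      if (is.null(p)) return(rep(1e6, nrow(target)))
      fit <- tryCatch(
        target_fit(p, target, scenarios, model, ctl$rtol, ctl$atol),
        debatch_numerical_error = function(e) NULL)
      if (is.null(fit) || any(!is.finite(fit))) return(rep(1e6, nrow(target)))
      sqrt(target$weight) * (fit - target$obs)
    }
    dev_prev <- Inf
    for (i in seq_len(1 + ctl$restarts)) {
      opt <- minpack.lm::nls.lm(
        par, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = min(ctl$maxit, 1024), ftol = 1e-15, ptol = 1e-12,
          epsfcn = ctl$epsfcn))
      counts <- counts + opt$niter
      conv <- if (opt$info %in% c(1, 2, 3, 4)) 0L else 1L
      if (opt$deviance < dev_prev) {
        par <- opt$par
        dev_prev <- opt$deviance
      } else break
    }
  }

  fitted_params <- do.call(update_params,
                           c(list(start), as.list(setNames(exp(par), free))))
  tab <- residual_table(fitted_params, observations, scenarios, model,
                        weights, fit_means, ctl$rtol, ctl$atol)
  gof <- goodness_of_fit(tab$obs, tab$fit, tab$weight,
                         n_free = length(free),
                         groups = tab$variable)
  structure(list(model = model, params = fitted_params, free = free,
                 start = start, kE_stage = kE_stage,
                 wsse = sum(tab$weight * (tab$fit - tab$obs)^2),
                 gof = gof, residuals = tab,
                 convergence = conv == 0L, counts = counts,
                 observations = observations, scenarios = scenarios,
                 weights = weights, fit_means = fit_means, control = ctl),
            class = "deb_fit")
}

#' Goodness of fit on the weighted scale
#'
#' Pooled over all variables and scenarios after scaling observations and
#' fitted values by the square root of their weights (so that each
#' variable contributes on a comparable footing): the coefficient of
#' determination, its adjusted version
#' \code{R2adj = 1 - (1 - R2) (n - 1)/(n - k - 1)}, and the root mean
#' squared (weighted) error.  Per-group R2 values are reported for
#' diagnostics when a grouping is supplied.
#'
#' @param observed,fitted observation and model-value vectors.
#' @param weights weights (recycled).
#' @param n_free number of estimated parameters k.
#' @param groups optional grouping factor (e.g. the variable) for
#'   per-group diagnostics.
#' @return list with \code{r2}, \code{r2adj}, \code{rmse}, \code{n},
#'   \code{n_free}, and \code{per_group}.
#' @export
goodness_of_fit <- function(observed, fitted, weights = 1, n_free = 0,
                            groups = NULL) {
  n <- length(observed)
  if (length(fitted) != n) stop_validation("length mismatch")
  if (n <= n_free + 1)
    stop_validation("need more points than parameters + 1")
  w <- sqrt(rep_len(weights, n))
  zo <- w * observed
  zf <- w * fitted
  ss_res <- sum((zo - zf)^2)
  ss_tot <- sum((zo - mean(zo))^2)
  if (ss_tot <= 0) stop_validation("degenerate observations: zero variance")
  r2 <- 1 - ss_res / ss_tot
  per_group <- NULL
  if (!is.null(groups)) {
    per_group <- vapply(split(seq_len(n), groups), function(i) {
      st <- sum((zo[i] - mean(zo[i]))^2)
      if (st <= 0) return(NA_real_)
      1 - sum((zo[i] - zf[i])^2) / st
    }, numeric(1))
  }
  list(r2 = r2,
       r2adj = 1 - (1 - r2) * (n - 1) / (n - n_free - 1),
       rmse = sqrt(ss_res / n),
       n = n, n_free = n_free, per_group = per_group)
}

#' Nonsimultaneous prediction intervals for fitted curves
#'
#' Pointwise t-intervals for the next observation: fitted curve plus or
#' minus \code{t(1 - alpha/2, dof) * s_pred}, where \code{s_pred} is the
#' per-variable residual standard deviation pooled over scenarios on the
#' original measurement scale and \code{dof = n - k} within that
#' variable.  When the fit compared replicate means (the default), the
#' mean residuals estimate the measurement variance divided by the
#' replicate count, so \code{s_pred} is scaled back up by the square
#' root of the mean replicate number to refer to one new observation.
#' Parameter uncertainty is not propagated, and the band assumes
#' homoscedastic noise within a variable.
#'
#' @param fit a [deb_fit()] result (must have estimable residual
#'   variance).
#' @param scenario_ids scenarios to predict (default: all fitted).
#' @param times prediction time grid (default: the observation times).
#' @param level coverage level for a single new observation.
#' @return data frame with \code{scenario_id}, \code{variable},
#'   \code{time_h}, \code{fit}, \code{lwr}, \code{upr}.
#' @export
prediction_interval <- function(fit, scenario_ids = NULL, times = NULL,
                                level = 0.95) {
  stopifnot(inherits(fit, "deb_fit"))
  tab <- fit$residuals
  scenario_ids <- scenario_ids %||% unique(as.character(tab$scenario_id))
  k <- length(fit$free)
  rep_factor <- if (fit$fit_means) {
    counts <- table(paste(fit$observations$scenario_id,
                          fit$observations$variable,
                          fit$observations$time_h))
    sqrt(mean(counts))
  } else 1
  s_pred <- vapply(split(tab, tab$variable), function(d) {
    dof <- nrow(d) - k
    if (dof <= 0) stop_validation("non-positive residual degrees of freedom")
    rep_factor * sqrt(sum((d$obs - d$fit)^2) / dof)
  }, numeric(1))
  dof <- vapply(split(tab, tab$variable), nrow, 0L) - k
  out <- lapply(scenario_ids, function(sid) {
    tt <- times %||% sort(unique(tab$time_h[tab$scenario_id == sid]))
    cur <- model_curve(fit$params, fit$scenarios[[sid]], tt, fit$model,
                       fit$control$rtol, fit$control$atol)
    do.call(rbind, lapply(OBS_VARIABLES, function(v) {
      half <- qt(1 - (1 - level) / 2, dof[[v]]) * s_pred[[v]]
      data.frame(scenario_id = sid, variable = v, time_h = tt,
                 fit = cur[[v]], lwr = cur[[v]] - half, upr = cur[[v]] + half)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.deb_fit <- function(x, ...) {
  cat(sprintf("%s model fit (%s)\n",
              if (x$model == "deb") "DEB" else "Monod",
              if (x$convergence) "converged" else "NOT converged"))
  est <- unlist(unclass(x$params)[x$free])
  cat("Estimated parameters:\n")
  print(signif(est, 6))
  cat(sprintf("WSSE %.6g | R2adj %.4f | RMSE %.4g | n %d\n",
              x$wsse, x$gof$r2adj, x$gof$rmse, x$gof$n))
  invisible(x)
}

#' @export
summary.deb_fit <- function(object, ...) {
  x <- object
  print(x)
  cat("\nPer-variable R2 (weighted scale):\n")
  print(round(x$gof$per_group, 4))
  if (!is.null(x$kE_stage)) {
    cat("\nTwo-stage turnover estimates (per limitation group):\n")
    print(signif(x$kE_stage, 4))
    cat(sprintf("kE fixed at mean: %.4g 1/h\n", x$params$kE))
  }
  cat(sprintf("\nFunction evaluations: %d\n", x$counts[1]))
  invisible(x)
}

#' @export
coef.deb_fit <- function(object, all = FALSE, ...) {
  p <- unlist(unclass(object$params))
  if (all) p else p[object$free]
}

#' @export
fitted.deb_fit <- function(object, ...) object$residuals$fit

#' @export
residuals.deb_fit <- function(object, weighted = FALSE, ...) {
  r <- object$residuals$obs - object$residuals$fit
  if (weighted) r * sqrt(object$residuals$weight) else r
}

#' Model curves at the fitted parameters
#'
#' @param object a [deb_fit()].
#' @param scenario_ids scenarios to predict (default all).
#' @param times prediction grid (default: the observation times).
#' @param interval \code{"none"} or \code{"prediction"}.
#' @param level prediction level.
#' @param ... unused.
#' @return data frame of curves (long format), with interval bounds when
#'   requested.
#' @export
predict.deb_fit <- function(object, scenario_ids = NULL, times = NULL,
                            interval = c("none", "prediction"),
                            level = 0.95, ...) {
  interval <- match.arg(interval)
  if (interval == "prediction")
    return(prediction_interval(object, scenario_ids, times, level))
  scenario_ids <- scenario_ids %||%
    unique(as.character(object$residuals$scenario_id))
  out <- lapply(scenario_ids, function(sid) {
    tt <- times %||%
      sort(unique(object$residuals$time_h[object$residuals$scenario_id == sid]))
    cur <- model_curve(object$params, object$scenarios[[sid]], tt,
                       object$model, object$control$rtol, object$control$atol)
    do.call(rbind, lapply(OBS_VARIABLES, function(v)
      data.frame(scenario_id = sid, variable = v, time_h = tt,
                 fit = cur[[v]])))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Draw synthetic replicate observation sets from a fitted model
#'
#' New observation tables at the fitted parameters, with additive
#' Gaussian noise (truncated at zero) whose per-variable standard
#' deviation equals the fit's pooled residual standard deviation — the
#' parametric-bootstrap companion of [prediction_interval()].
#'
#' @param object a [deb_fit()].
#' @param nsim number of observation sets.
#' @param seed optional seed.
#' @param ... unused.
#' @return a list of observation tables.
#' @export
simulate.deb_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  tab <- object$residuals
  k <- length(object$free)
  rep_factor <- if (object$fit_means) {
    counts <- table(paste(object$observations$scenario_id,
                          object$observations$variable,
                          object$observations$time_h))
    sqrt(mean(counts))
  } else 1
  s_pred <- vapply(split(tab, tab$variable), function(d)
    rep_factor * sqrt(sum((d$obs - d$fit)^2) / max(nrow(d) - k, 1)),
    numeric(1))
  lapply(seq_len(nsim), function(i) {
    reps <- lapply(seq_len(3), function(rep) {
      v <- as.character(tab$variable)
      data.frame(scenario_id = tab$scenario_id, variable = v,
                 time_h = tab$time_h, replicate = rep,
                 value = rtruncnorm_pos(tab$fit, s_pred[v]))
    })
    out <- do.call(rbind, reps)
    rownames(out) <- NULL
    out
  })
}

#' @export
plot.deb_fit <- function(x, scenario_ids = NULL, ...) {
  scenario_ids <- scenario_ids %||%
    unique(as.character(x$residuals$scenario_id))
  op <- graphics::par(mfrow = c(length(scenario_ids), 3),
                      mar = c(3.5, 3.5, 1.5, 0.5), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(op))
  for (sid in scenario_ids) {
    d <- x$residuals[x$residuals$scenario_id == sid, ]
    tt <- seq(0, max(d$time_h), length.out = 60)
    cur <- model_curve(x$params, x$scenarios[[sid]], tt, x$model,
                       x$control$rtol, x$control$atol)
    for (v in OBS_VARIABLES) {
      dv <- d[d$variable == v, ]
      graphics::plot(dv$time_h, dv$obs, xlab = "time (h)", ylab = v,
                     main = paste(sid, v), pch = 16, cex = 0.7,
                     ylim = range(c(dv$obs, cur[[v]])))
      graphics::lines(tt, cur[[v]], col = 2)
    }
  }
  invisible(x)
}
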