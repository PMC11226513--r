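FLUX_COLUMNS <- c("r", "jEcA", "jEnA", "jEcC", "jEnC", "jEcG", "jEnG",
                  "jG", "jEcR", "jEnR", "jVMc", "jVMn", "jVM", "JNH3")

#' Simulate the DEB batch culture
#'
#' Integrates the mass balances with the compiled right-hand side
#' (adaptive stiff-capable \code{lsodar}) while monitoring the death
#' condition: integration stops at the first time either reserve's
#' mobilization falls below its maintenance demand, after which the
#' culture is frozen — all fluxes zero, state constant.  Substrate
#' exhaustion needs no event of its own: assimilation falls smoothly to
#' zero with the Monod factor and is clamped at non-positive
#' concentrations.
#'
#' @param params a [deb_params()] object.
#' @param scenario a [scenario()]; alternatively give \code{state0}.
#' @param state0 a [culture_state()] overriding the scenario's initial
#'   state.
#' @param times output time grid (h); defaults to the scenario's
#'   sampling grid.
#' @param feed_JNH3 external ammonia feed (mol/h); zero in batch culture.
#' @param rtol,atol relative and absolute integration tolerances.  The
#'   defaults resolve the stiff substrate-exhaustion corners and keep the
#'   elemental balances conserved to better than 1e-6 relative.
#' @param maxsteps maximum internal steps per output interval.
#' @return a data frame of class \code{"deb_trajectory"} with columns
#'   \code{time_h}, the state (\code{SC_cmol_L}, \code{SN_mol_L},
#'   \code{mEc}, \code{mEn}, \code{MV_cmol}, \code{dissC}, \code{dissN}),
#'   \code{biomass_cmol_L} (structure plus C reserve per liter),
#'   \code{r_h}, \code{alive}, and the specific-flux columns.  Attributes:
#'   \code{death_time} (h, \code{NA} if the culture outlives the horizon),
#'   \code{params}, \code{scenario}.
#' @export
deb_simulate <- function(params, scenario = NULL, state0 = NULL,
                         times = NULL, feed_JNH3 = 0,
                         rtol = 1e-8, atol = 1e-12, maxsteps = 50000) {
  if (is.null(state0)) {
    if (is.null(scenario))
      stop_validation("either 'scenario' or 'state0' is required")
    state0 <- scenario_state(scenario, params)
  }
  if (is.null(times)) {
    if (is.null(scenario))
      stop_validation("'times' is required when no scenario is given")
    times <- scenario_times(scenario)
  }
  times <- sort(unique(times))
  if (times[1] < 0) stop_validation("times must be non-negative")
  if (length(times) < 2) stop_validation("need at least two output times")

  y0 <- state_vector(state0)
  pv <- deb_parms_vector(params, V = state0$V, feed_JNH3 = feed_JNH3)

  fl0 <- deb_fluxes(state0, params)
  dead_from_start <- !state0$alive || state0$MV <= 0 || !fl0$maintenance_ok

  if (dead_from_start) {
    n <- length(times)
    out <- data.frame(time_h = times,
                      matrix(rep(y0, each = n), nrow = n,
                             dimnames = list(NULL, names(y0))),
                      matrix(0, n, length(FLUX_COLUMNS),
                             dimnames = list(NULL, FLUX_COLUMNS)))
    death_time <- if (!state0$alive || !fl0$maintenance_ok) times[1] else NA_real_
    alive <- rep(FALSE, n)
    if (state0$MV <= 0 && state0$alive && fl0$maintenance_ok) {
      # an empty but viable culture is flat, not dead
      alive <- rep(TRUE, n)
      death_time <- NA_real_
    }
    return(finish_deb_trajectory(out, alive, death_time, params, scenario,
                                 state0$V))
  }

  raw <- tryCatch(
    deSolve::lsodar(y = y0, times = times, func = "deb_derivs", parms = pv,
                    dllname = "debatch", initfunc = "deb_initmod",
                    rootfunc = "deb_root", nroot = 2L,
                    nout = length(FLUX_COLUMNS), outnames = FLUX_COLUMNS,
                    rtol = rtol, atol = atol, maxsteps = maxsteps),
    error = function(e)
      stop_numerical("DEB integration failed: ", conditionMessage(e)))

  troot <- attr(raw, "troot")
  death_time <- if (length(troot)) troot[1] else NA_real_
  df <- as.data.frame(raw)
  names(df)[1] <- "time_h"
  alive <- rep(TRUE, nrow(df))

  if (!is.na(death_time)) {
    # final solver row is the root time; freeze the remaining grid there
    frozen <- df[nrow(df), , drop = FALSE]
    frozen[FLUX_COLUMNS] <- 0
    later <- times[times > death_time]
    if (length(later)) {
      add <- frozen[rep(1, length(later)), , drop = FALSE]
      add$time_h <- later
      df <- rbind(df, add)
    }
    alive <- df$time_h < death_time
    # at the root itself the culture is at the point of death
    df[df$time_h >= death_time, FLUX_COLUMNS] <- 0
  }
  finish_deb_trajectory(df, alive, death_time, params, scenario, state0$V)
}

finish_deb_trajectory <- function(df, alive, death_time, params, scenario, V) {
  rownames(df) <- NULL
  out <- data.frame(time_h = df$time_h,
                    SC_cmol_L = df$SC, SN_mol_L = df$SN,
                    mEc = df$mEc, mEn = df$mEn,
                    MV_cmol = df$MV,
                    biomass_cmol_L = (1 + df$mEc) * df$MV / V,
                    r_h = df$r,
                    alive = alive,
                    dissC = df$dissC, dissN = df$dissN,
                    df[FLUX_COLUMNS[FLUX_COLUMNS != "r"]])
  attr(out, "death_time") <- death_time
  attr(out, "params") <- params
  attr(out, "scenario") <- scenario
  attr(out, "volume") <- V
  class(out) <- c("deb_trajectory", "data.frame")
  out
}

#' @export
print.deb_trajectory <- function(x, ...) {
  dt <- attr(x, "death_time")
  cat(sprintf("DEB trajectory: %d time points over %g h%s\n", nrow(x),
              max(x$time_h),
              if (!is.na(dt)) sprintf(", death at %.3f h", dt) else ""))
  print.data.frame(utils::head(as.data.frame(
    x[c("time_h", "SC_cmol_L", "SN_mol_L", "mEc", "mEn",
        "biomass_cmol_L", "r_h", "alive")]), 10), digits = 4)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' @export
plot.deb_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time_h, x$biomass_cmol_L, type = "l", xlab = "time (h)",
                 ylab = "biomass (C-mol/L)", main = "biomass", ...)
  graphics::matplot(x$time_h, cbind(x$SC_cmol_L, x$SN_mol_L), type = "l",
                    lty = 1, xlab = "time (h)", ylab = "concentration",
                    main = "substrates (C-mol/L, mol/L)")
  graphics::legend("topright", c("SC", "SN"), lty = 1, col = 1:2, bty = "n")
  graphics::matplot(x$time_h, cbind(x$mEc, x$mEn), type = "l", lty = 1,
                    xlab = "time (h)", ylab = "reserve density",
                    main = "reserves")
  graphics::legend("topright", c("mEc", "mEn"), lty = 1, col = 1:2, bty = "n")
  graphics::plot(x$time_h, x$r_h, type = "l", xlab = "time (h)",
                 ylab = "r (1/h)", main = "specific growth rate")
  invisible(x)
}

#' Monod-model specific growth rate
#'
#' Product of two Monod factors, one per limiting substrate; zero if
#' either substrate is exhausted.
#' @param SC,SN substrate concentrations (vectors recycle).
#' @param params a [monod_params()] object.
#' @return specific growth rate(s), 1/h.
#' @export
monod_mu <- function(SC, SN, params) {
  fc <- ifelse(SC > 0, SC / (params$KC + SC), 0)
  fn <- ifelse(SN > 0, SN / (params$KN + SN), 0)
  params$mu_max * fc * fn
}

#' Monod-model derivatives
#'
#' @param state named vector or list with \code{X}, \code{SC}, \code{SN}.
#' @param params a [monod_params()] object.
#' @return named derivative vector.
#' @export
monod_rhs <- function(state, params) {
  mu <- monod_mu(state[["SC"]], state[["SN"]], params)
  c(X = mu * state[["X"]],
    SC = -mu * state[["X"]] / params$YXSC,
    SN = -mu * state[["X"]] / params$YXSN)
}

#' Simulate the two-substrate Monod model
#'
#' Growth simply slows to a halt as a substrate runs out (the Monod
#' factor vanishes smoothly); there is no death event and no reserve
#' dynamics.
#'
#' @param params a [monod_params()] object.
#' @param scenario a [scenario()]; alternatively \code{state0}.
#' @param state0 named vector \code{c(X=, SC=, SN=)} (C-mol/L, C-mol/L,
#'   mol/L).
#' @param times output grid (h).
#' @param rtol,atol integration tolerances; tight enough that the yield
#'   identities hold to 1e-8 relative.
#' @return a data frame of class \code{"monod_trajectory"} with columns
#'   \code{time_h, X_cmol_L, SC_cmol_L, SN_mol_L, mu_h}.
#' @export
monod_simulate <- function(params, scenario = NULL, state0 = NULL,
                           times = NULL, rtol = 1e-10, atol = 1e-14) {
  if (is.null(state0)) {
    if (is.null(scenario))
      stop_validation("either 'scenario' or 'state0' is required")
    state0 <- c(X = scenario$inoculum,
                SC = grams_to_cmol(scenario$glucose, "glucose"),
                SN = grams_to_cmol(scenario$nh4cl, "NH4Cl"))
  }
  if (is.null(times)) {
    if (is.null(scenario))
      stop_validation("'times' is required when no scenario is given")
    times <- scenario_times(scenario)
  }
  times <- sort(unique(times))
  raw <- tryCatch(
    deSolve::lsoda(y = state0[c("X", "SC", "SN")], times = times,
                   func = "monod_derivs", parms = monod_parms_vector(params),
                   dllname = "debatch", initfunc = "monod_initmod",
                   nout = 1L, outnames = "mu",
                   rtol = rtol, atol = atol, maxsteps = 50000),
    error = function(e)
      stop_numerical("Monod integration failed: ", conditionMessage(e)))
  out <- data.frame(time_h = raw[, "time"], X_cmol_L = raw[, "X"],
                    SC_cmol_L = raw[, "SC"], SN_mol_L = raw[, "SN"],
                    mu_h = raw[, "mu"])
  attr(out, "params") <- params
  attr(out, "scenario") <- scenario
  class(out) <- c("monod_trajectory", "data.frame")
  out
}

#' @export
print.monod_trajectory <- function(x, ...) {
  cat(sprintf("Monod trajectory: %d time points over %g h\n", nrow(x),
              max(x$time_h)))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Run the shock-limitation transfer experiment
#'
#' Simulates the basic-medium pre-culture, transfers the cells to a fresh
#' medium lacking one substrate ([transfer_event()]), and follows the
#' culture after the transfer with 30-minute sampling.  The post-transfer
#' clock starts at the transfer.
#'
#' @param params a [deb_params()] object.
#' @param remove substrate absent from the fresh medium, \code{"C"} or
#'   \code{"N"}.
#' @param pre_scenario the pre-culture scenario (basic medium, 4 h).
#' @param post_horizon,post_interval post-transfer sampling design, h.
#' @param ... passed to [deb_simulate()].
#' @return list with elements \code{pre} and \code{post} (trajectories),
#'   \code{transfer_state}, and \code{death_after_transfer} (h since the
#'   transfer at which the missing reserve can no longer pay maintenance).
#' @export
shock_experiment <- function(params, remove = c("C", "N"),
                             pre_scenario = limitation_scenarios()$shock_pre,
                             post_horizon = 6.5, post_interval = 0.5, ...) {
  remove <- match.arg(remove)
  pre <- deb_simulate(params, scenario = pre_scenario, ...)
  end <- pre[nrow(pre), ]
  pre_state <- culture_state(SC = end$SC_cmol_L, SN = end$SN_mol_L,
                             mEc = end$mEc, mEn = end$mEn,
                             MV = end$MV_cmol, V = attr(pre, "volume"),
                             alive = end$alive)
  fresh <- transfer_event(pre_state, remove = remove,
                          glucose = pre_scenario$glucose,
                          nh4cl = pre_scenario$nh4cl)
  post <- deb_simulate(params, state0 = fresh,
                       times = seq(0, post_horizon, by = post_interval), ...)
  list(pre = pre, post = post, transfer_state = fresh,
       death_after_transfer = attr(post, "death_time"))
}

#' Write a trajectory to CSV
#'
#' Plain CSV with '.' decimal separator and deterministic column order;
#' optional \code{# key: value} header comment lines (seed, configuration
#' hash, package version) precede the table.
#'
#' @param trajectory a trajectory data frame.
#' @param path output file.
#' @param header named character vector written as comment lines.
#' @export
write_trajectory <- function(trajectory, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header))
    writeLines(paste0("# ", names(header), ": ", header), con)
  utils::write.csv(as.data.frame(trajectory), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
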