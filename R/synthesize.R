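#' Measurement-noise model for synthetic observations
#'
#' Proportional (constant-CV) Gaussian noise with a small additive floor
#' near each assay's detection limit, truncated at zero.  Defaults are
#' plausible assay CVs for optical-density-derived biomass (5 %), an
#' enzymatic glucose assay (3 %) and a colorimetric ammonium assay
#' (5 %); the floors are ~0.6 mg/L biomass, ~0.01 g/L glucose and
#' ~0.5 mg/L ammonium chloride expressed in molar units.
#'
#' @param cv named vector of coefficients of variation for \code{X},
#'   \code{SC}, \code{SN}.
#' @param floor named vector of additive noise standard deviations on
#'   the measurement scales (C-mol/L, C-mol/L, mol/L).
#' @return an object of class \code{"noise_model"}.
#' @export
noise_model <- function(cv = c(X = 0.05, SC = 0.03, SN = 0.05),
                        floor = c(X = 2e-5, SC = 3e-4, SN = 1e-5)) {
  cv <- cv[OBS_VARIABLES]; floor <- floor[OBS_VARIABLES]
  if (any(is.na(cv)) || any(cv < 0))
    stop_validation("'cv' needs non-negative entries for X, SC, SN")
  if (any(is.na(floor)) || any(floor < 0))
    stop_validation("'floor' needs non-negative entries for X, SC, SN")
  structure(list(cv = cv, floor = floor), class = "noise_model")
}

# Gaussian truncated at zero by resampling: concentrations cannot be
# negative.  Vectorized over mean and sd.
rtruncnorm_pos <- function(mean, sd) {
  out <- rnorm(length(mean), mean, sd)
  for (i in 1:100) {
    bad <- out < 0
    if (!any(bad)) break
    out[bad] <- rnorm(sum(bad), mean[bad], sd[bad])
  }
  pmax(out, 0)
}

#' Generate synthetic replicate observations for limitation scenarios
#'
#' Simulates the chosen model for each scenario, samples the scenario's
#' grid, and draws replicate measurements under the noise model.  Output
#' is deterministic for a fixed seed.  Stands in for wet-lab triplicate
#' time courses of biomass, glucose and ammonium.
#'
#' @param scenarios a [scenario()] or (named) list of scenarios.
#' @param params [deb_params()] or [monod_params()] matching \code{model}.
#' @param model \code{"deb"} or \code{"monod"}.
#' @param noise a [noise_model()]; zero CVs and floors reproduce the
#'   model curve exactly.
#' @param seed optional integer seed.
#' @param ... passed to the simulator.
#' @return an observation table: \code{scenario_id}, \code{variable}
#'   (\code{X}/\code{SC}/\code{SN}), \code{time_h}, \code{replicate},
#'   \code{value}.
#' @export
synthesize_observations <- function(scenarios, params,
                                    model = c("deb", "monod"),
                                    noise = noise_model(), seed = NULL, ...) {
  model <- match.arg(model)
  if (inherits(scenarios, "deb_scenario")) {
    scenarios <- list(scenarios)
    names(scenarios) <- scenarios[[1]]$id
  }
  if (!is.null(seed)) set.seed(seed)
  parts <- lapply(scenarios, function(scn) {
    tt <- scenario_times(scn)
    cur <- model_curve(params, scn, tt, model, rtol = 1e-8, atol = 1e-12)
    do.call(rbind, lapply(OBS_VARIABLES, function(v) {
      mu <- cur[[v]]
      sdv <- sqrt((noise$cv[[v]] * mu)^2 + noise$floor[[v]]^2)
      do.call(rbind, lapply(seq_len(scn$replicates), function(rep) {
        val <- if (all(sdv == 0)) mu else rtruncnorm_pos(mu, sdv)
        data.frame(scenario_id = scn$id, variable = v, time_h = tt,
                   replicate = rep, value = val)
      }))
    }))
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$scenario_id, out$variable, out$time_h,
                   out$replicate), ]
  rownames(out) <- NULL
  out
}

#' Linear optical-density emulation
#'
#' Observations are generated directly in C-mol/L; for interfaces that
#' expect optical-density readings, a linear calibration layer converts
#' both ways.  The default slope assumes ~0.4 g dry biomass per OD550
#' unit per liter, i.e. one OD unit is 0.4/30 C-mol/L.
#'
#' @param biomass biomass concentration(s), C-mol/L.
#' @param od optical density reading(s).
#' @param cmol_per_od calibration slope, C-mol/L per OD unit.
#' @return the converted vector.
#' @export
biomass_to_od <- function(biomass, cmol_per_od = 0.4 / 30) {
  check_positive(cmol_per_od, "cmol_per_od")
  biomass / cmol_per_od
}

#' @rdname biomass_to_od
#' @export
od_to_biomass <- function(od, cmol_per_od = 0.4 / 30) {
  check_positive(cmol_per_od, "cmol_per_od")
  od * cmol_per_od
}

#' Read and write observation tables
#'
#' Long-format CSV with columns \code{scenario_id, variable, time_h,
#' replicate, value}; values are written with 17 significant digits so a
#' round trip through disk is lossless.  Optional \code{# key: value}
#' comment header lines carry provenance (seed, configuration hash).
#'
#' @param path CSV file path.
#' @return \code{read_observations}: the observation table.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: ", path)
  out <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  out$time_h <- as.numeric(out$time_h)
  out$value <- as.numeric(out$value)
  check_observations(out)
}

#' @rdname read_observations
#' @param observations observation table.
#' @param header named character vector of comment lines.
#' @export
write_observations <- function(observations, path, header = character()) {
  observations <- check_observations(observations)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header))
    writeLines(paste0("# ", names(header), ": ", header), con)
  fmt <- observations
  fmt$time_h <- sprintf("%.17g", fmt$time_h)
  fmt$value <- sprintf("%.17g", fmt$value)
  write.csv(fmt, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
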