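#' Read and validate a run configuration
#'
#' YAML configuration driving the canned experiments.  Common fields:
#' \code{command} (\code{simulate} or \code{recover}), \code{model}
#' (\code{deb}, \code{monod} or \code{both}), \code{seed},
#' \code{outdir}, \code{scenarios} (ids from [limitation_scenarios()]),
#' \code{parameters} / \code{monod_parameters} (named overrides),
#' \code{solver} (\code{rtol}, \code{atol}).  \code{recover} adds
#' \code{seeds}, \code{noise} (\code{cv}, \code{floor}),
#' \code{start_factor} and \code{free}.
#'
#' @param path YAML file.
#' @return the validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_validation("no such config file: ", path)
  config <- yaml::read_yaml(path)
  if (is.null(config$command) ||
      !config$command %in% c("simulate", "recover"))
    stop_validation("config 'command' must be 'simulate' or 'recover'")
  config$model <- config$model %||% "deb"
  if (!config$model %in% c("deb", "monod", "both"))
    stop_validation("config 'model' must be deb, monod or both")
  config$seed <- config$seed %||% 1L
  config$outdir <- config$outdir %||% "."
  config
}

config_params <- function(config) {
  do.call(deb_params, as.list(config$parameters %||% list()))
}

config_monod_params <- function(config) {
  do.call(monod_params, as.list(config$monod_parameters %||% list()))
}

config_scenarios <- function(config) {
  lib <- limitation_scenarios(inoculum = config$inoculum %||% 4e-5)
  ids <- if (is.null(config$scenarios)) setdiff(names(lib), "shock_pre")
         else as.character(unlist(config$scenarios))
  bad <- setdiff(ids, names(lib))
  if (length(bad))
    stop_validation("unknown scenario id(s): ", paste(bad, collapse = ", "))
  lib[ids]
}

output_header <- function(config, extra = character()) {
  c(package_version = as.character(utils::packageVersion("debatch")),
    seed = as.character(config$seed),
    config_hash = config_hash(config),
    extra)
}

#' Run scripted scenario simulations
#'
#' Simulates the configured scenarios with the DEB model, the Monod
#' model, or both, and writes one trajectory CSV per scenario and model
#' plus a biomass-composition time series per DEB trajectory.  Output
#' files embed the seed, the configuration hash and the package version
#' in comment headers, so reruns with an identical configuration are
#' byte-identical.
#'
#' @param config a configuration list ([read_run_config()]) or path to
#'   a YAML file.
#' @return invisibly, the vector of files written.
#' @export
run_simulate <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  scns <- config_scenarios(config)
  if (length(scns) == 0) {
    warning("no scenarios configured; nothing to do")
    return(invisible(character()))
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  solver <- config$solver %||% list()
  rtol <- solver$rtol %||% 1e-8
  atol <- solver$atol %||% 1e-12
  models <- if (config$model == "both") c("deb", "monod") else config$model
  files <- character()
  for (scn in scns) {
    hdr <- output_header(config, c(scenario = scn$id))
    if ("deb" %in% models) {
      tr <- deb_simulate(config_params(config), scenario = scn,
                         rtol = rtol, atol = atol)
      f <- file.path(config$outdir, paste0("deb_", scn$id, ".csv"))
      write_trajectory(tr, f, hdr)
      files <- c(files, f)
      if (isTRUE(config$compose %||% TRUE)) {
        comp <- composition_trajectory(tr)
        fc <- file.path(config$outdir, paste0("composition_", scn$id, ".csv"))
        write_trajectory(comp, fc, hdr)
        files <- c(files, fc)
      }
    }
    if ("monod" %in% models) {
      tr <- monod_simulate(config_monod_params(config), scenario = scn,
                           rtol = max(rtol, 1e-10), atol = atol)
      f <- file.path(config$outdir, paste0("monod_", scn$id, ".csv"))
      write_trajectory(tr, f, hdr)
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Parameter-recovery experiment over seeds
#'
#' For each seed: generate synthetic observations at the true (default)
#' parameters under the configured noise model, fit the model starting
#' from the truth scaled by \code{start_factor}, and tabulate relative
#' errors of the free parameters.  Summary quantiles and convergence
#' flags are written as a JSON report plus a CSV table.  An empty seed
#' list yields an empty (but valid) report.
#'
#' @param config configuration list or YAML path; uses fields
#'   \code{seeds}, \code{noise}, \code{start_factor}, \code{free},
#'   \code{model}, \code{scenarios}, \code{outdir}.
#' @return invisibly, the per-seed results data frame.
#' @export
run_recover <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  model <- if (config$model == "both") "deb" else config$model
  truth <- if (model == "deb") config_params(config)
           else config_monod_params(config)
  free <- config$free %||% default_free(model)
  start_factor <- config$start_factor %||% 2
  seeds <- unlist(config$seeds %||% list())
  scns <- config_scenarios(config)
  noise_cfg <- config$noise %||% list()
  nm <- noise_model(
    cv = unlist(noise_cfg$cv %||% c(X = 0.05, SC = 0.03, SN = 0.05)),
    floor = unlist(noise_cfg$floor %||% c(X = 2e-5, SC = 3e-4, SN = 1e-5)))
  noiseless <- all(nm$cv == 0) && all(nm$floor == 0)

  rows <- lapply(seeds, function(sd) {
    obs <- synthesize_observations(scns, truth, model, nm, seed = sd)
    fit <- deb_fit(obs, scns, model,
                   method = config$method %||% "nelder-mead",
                   start = do.call(update_params, c(list(truth),
                     as.list(setNames(unlist(unclass(truth)[free]) *
                                        start_factor, free)))),
                   free = free,
                   weights = if (noiseless) "unit" else NULL,
                   control = config$fit_control %||% list())
    est <- coef(fit)
    tru <- unlist(unclass(truth)[free])
    data.frame(seed = sd, parameter = free, truth = tru, estimate = est,
               rel_error = (est - tru) / tru, converged = fit$convergence,
               wsse = fit$wsse, row.names = NULL)
  })
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seed = integer(), parameter = character(), truth = numeric(),
               estimate = numeric(), rel_error = numeric(),
               converged = logical(), wsse = numeric())

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- output_header(config)
  csv <- file.path(config$outdir, "recovery.csv")
  con <- file(csv, "w"); writeLines(paste0("# ", names(hdr), ": ", hdr), con)
  write.csv(res, con, row.names = FALSE, quote = FALSE); close(con)

  summ <- if (nrow(res)) lapply(split(res, res$parameter), function(d) list(
    truth = d$truth[1],
    median_abs_rel_error = median(abs(d$rel_error)),
    q90_abs_rel_error = unname(quantile(abs(d$rel_error), 0.9)),
    n_converged = sum(d$converged), n = nrow(d))) else list()
  report <- list(package_version = hdr[["package_version"]],
                 config_hash = hdr[["config_hash"]],
                 model = model, n_seeds = length(seeds),
                 start_factor = start_factor, parameters = summ)
  jsonlite::write_json(report, file.path(config$outdir, "recovery.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
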