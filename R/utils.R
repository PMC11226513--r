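`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("debatch_validation_error", "error")))
}

#' @keywords internal
stop_numerical <- function(...) {
  stop(errorCondition(paste0(...), class = c("debatch_numerical_error", "error")))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_validation("'", name, "' must be a single finite positive number")
  x
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop_validation("'", name, "' must be a single non-negative number")
  x
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop_validation("'", name, "' must lie in [0, 1]")
  x
}

#' MD5 hash of an R configuration object
#'
#' Hashes the canonical YAML rendering of a list, used to stamp output
#' files so that reruns with an identical configuration are identifiable.
#' @param config a list
#' @return a length-one character string
#' @keywords internal
config_hash <- function(config) {
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(config), f)
  unname(tools::md5sum(f))
}
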