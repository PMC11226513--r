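#' Parameters of the two-reserve DEB batch-culture model
#'
#' Constructs and validates the parameter set of the Dynamic Energy Budget
#' model with one structure and two complementary reserves (carbon and
#' nitrogen).  Defaults are the calibrated values for \emph{E. coli} growing
#' on glucose and ammonium in aerobic batch culture.
#'
#' All specific fluxes are expressed per C-mol of structure and per hour.
#' Carbon quantities are C-mol, nitrogen quantities mol.
#'
#' @param jEcAm maximum specific assimilation rate of the C substrate
#'   (C-mol_EC C-mol_MV^-1 h^-1).
#' @param jEnAm maximum specific assimilation rate of the N substrate
#'   (mol_EN C-mol_MV^-1 h^-1).
#' @param KC,KN half-saturation concentrations for the C and N substrates
#'   (C-mol/L resp. mol/L).  At working concentrations both are far below
#'   the substrate levels, so assimilation runs at its maximum until a
#'   substrate is nearly exhausted.
#' @param kE reserve turnover rate (1/h), common to both reserves.
#' @param jEcM,jEnM specific maintenance demand paid from the C and N
#'   reserve respectively.
#' @param yEcV,yEnV yield of reserve on structure: C-mol (mol) of reserve
#'   consumed per C-mol of structure built.  Must be at least the
#'   corresponding elemental index of structure (1 for C, \code{nNV} for N)
#'   so that synthesis overheads are non-negative.
#' @param ySEc,ySEn yield of substrate on reserve: substrate consumed per
#'   unit of reserve assimilated.
#' @param kappaEc,kappaEn fraction of the rejected growth flux returned to
#'   the respective reserve.
#' @param kappaSc,kappaSn fraction of the excreted rejected flux that
#'   reappears in the medium as substrate.
#' @param jP specific product-formation capacity of the synthesizing unit.
#'   The default \code{Inf} selects the simplified SU expression obtained
#'   when product formation is much faster than the reserve fluxes.
#' @param nNV nitrogen chemical index of structure (mol N per C-mol).
#' @return an object of class \code{"deb_params"} (a validated named list).
#' @seealso [monod_params()], [deb_simulate()], [deb_fluxes()]
#' @export
deb_params <- function(jEcAm = 1.7396, jEnAm = 0.2405,
                       KC = 1e-6, KN = 1e-6,
                       kE = 5.3,
                       jEcM = 0.6104, jEnM = 0.0010,
                       yEcV = 1.1, yEnV = 0.23,
                       ySEc = 1.1, ySEn = 1.05,
                       kappaEc = 0.9, kappaEn = 0.9,
                       kappaSc = 1, kappaSn = 1,
                       jP = Inf, nNV = 0.22) {
  for (nm in c("jEcAm", "jEnAm", "KC", "KN", "kE", "jEcM", "jEnM",
               "yEcV", "yEnV", "ySEc", "ySEn", "nNV"))
    check_positive(get(nm), nm)
  for (nm in c("kappaEc", "kappaEn", "kappaSc", "kappaSn"))
    check_fraction(get(nm), nm)
  if (!is.numeric(jP) || length(jP) != 1L || is.na(jP) || jP <= 0)
    stop_validation("'jP' must be positive (possibly Inf)")
  if (yEcV < 1)
    stop_validation("'yEcV' must be >= 1, the carbon index of structure")
  if (yEnV < nNV)
    stop_validation("'yEnV' must be >= 'nNV', the nitrogen index of structure")
  structure(list(jEcAm = jEcAm, jEnAm = jEnAm, KC = KC, KN = KN, kE = kE,
                 jEcM = jEcM, jEnM = jEnM, yEcV = yEcV, yEnV = yEnV,
                 ySEc = ySEc, ySEn = ySEn,
                 kappaEc = kappaEc, kappaEn = kappaEn,
                 kappaSc = kappaSc, kappaSn = kappaSn,
                 jP = jP, nNV = nNV),
            class = "deb_params")
}

#' @export
print.deb_params <- function(x, ...) {
  cat("Two-reserve DEB model parameters\n")
  v <- unlist(x)
  print(signif(v, 6))
  invisible(x)
}

#' Update a parameter set
#'
#' Replaces named components of a \code{deb_params} or \code{monod_params}
#' object and revalidates.
#' @param params parameter object.
#' @param ... named replacements.
#' @return a parameter object of the same class.
#' @export
update_params <- function(params, ...) {
  repl <- list(...)
  if (length(repl) == 0) return(params)
  bad <- setdiff(names(repl), names(unclass(params)))
  if (length(bad))
    stop_validation("unknown parameter(s): ", paste(bad, collapse = ", "))
  args <- utils::modifyList(unclass(params), repl)
  if (inherits(params, "deb_params")) do.call(deb_params, args)
  else do.call(monod_params, args)
}

#' Parameters of the two-substrate Monod model
#'
#' The baseline unstructured model: biomass grows at a rate given by the
#' product of two Monod factors, consuming each substrate with a constant
#' yield.  Defaults are the values calibrated simultaneously with the DEB
#' model on the same limitation scenarios.
#'
#' @param mu_max maximum specific growth rate (1/h).
#' @param YXSC yield of biomass on C substrate (C-mol_X per C-mol_SC).
#' @param YXSN yield of biomass on N substrate (C-mol_X per mol_SN).
#' @param KC,KN half-saturation concentrations.
#' @return an object of class \code{"monod_params"}.
#' @export
monod_params <- function(mu_max = 0.51, YXSC = 0.45, YXSN = 4.74,
                         KC = 1e-6, KN = 1e-6) {
  for (nm in c("mu_max", "YXSC", "YXSN", "KC", "KN"))
    check_positive(get(nm), nm)
  structure(list(mu_max = mu_max, YXSC = YXSC, YXSN = YXSN, KC = KC, KN = KN),
            class = "monod_params")
}

#' @export
print.monod_params <- function(x, ...) {
  cat("Two-substrate Monod model parameters\n")
  print(unlist(x))
  invisible(x)
}

# parameter vector in the layout the compiled derivatives expect
deb_parms_vector <- function(params, V = 1, feed_JNH3 = 0) {
  c(params$jEcAm, params$jEnAm, params$KC, params$KN, params$kE,
    params$jEcM, params$jEnM, params$yEcV, params$yEnV,
    params$ySEc, params$ySEn,
    params$kappaEc, params$kappaEn, params$kappaSc, params$kappaSn,
    if (is.finite(params$jP)) 1 / params$jP else 0,
    V, params$nNV, feed_JNH3)
}

monod_parms_vector <- function(params) {
  c(params$mu_max, params$YXSC, params$YXSN, params$KC, params$KN)
}

#' State of a DEB batch culture
#'
#' Bundles the instantaneous state of the culture: dissolved substrate
#' concentrations, reserve densities, structural mass, medium volume, the
#' cumulative dissipation pools used by the elemental conservation checks,
#' and the viability flag.
#'
#' @param SC C substrate concentration (C-mol/L).
#' @param SN N substrate concentration (mol/L).
#' @param mEc C reserve density (C-mol per C-mol structure).
#' @param mEn N reserve density (mol per C-mol structure).
#' @param MV structural mass (C-mol).
#' @param V medium volume (L).
#' @param dissC,dissN cumulative dissipated carbon (C-mol) and nitrogen
#'   (mol); these close the element balances.
#' @param alive viability flag; a dead culture has all fluxes zero and
#'   never revives.
#' @return an object of class \code{"culture_state"}.
#' @export
culture_state <- function(SC, SN, mEc, mEn, MV, V = 1,
                          dissC = 0, dissN = 0, alive = TRUE) {
  check_nonneg(SC, "SC"); check_nonneg(SN, "SN")
  check_nonneg(mEc, "mEc"); check_nonneg(mEn, "mEn")
  check_nonneg(MV, "MV"); check_positive(V, "V")
  if (!is.logical(alive) || length(alive) != 1L || is.na(alive))
    stop_validation("'alive' must be TRUE or FALSE")
  structure(list(SC = SC, SN = SN, mEc = mEc, mEn = mEn, MV = MV, V = V,
                 dissC = dissC, dissN = dissN, alive = alive),
            class = "culture_state")
}

#' @export
print.culture_state <- function(x, ...) {
  cat(sprintf(paste0("Culture state (%s): SC=%.4g C-mol/L, SN=%.4g mol/L, ",
                     "mEc=%.4g, mEn=%.4g, MV=%.4g C-mol, V=%g L\n"),
              if (x$alive) "alive" else "dead",
              x$SC, x$SN, x$mEc, x$mEn, x$MV, x$V))
  invisible(x)
}

state_vector <- function(state) {
  c(SC = state$SC, SN = state$SN, mEc = state$mEc, mEn = state$mEn,
    MV = state$MV, dissC = state$dissC, dissN = state$dissN)
}
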