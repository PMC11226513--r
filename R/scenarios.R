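#' Define a batch-culture scenario
#'
#' A scenario is an initial medium composition (mass units, converted to
#' molar units at the boundary), an inoculum, and a sampling design.
#'
#' @param id scenario identifier.
#' @param glucose initial glucose concentration, g/L.
#' @param nh4cl initial ammonium chloride concentration, g/L.
#' @param inoculum inoculum biomass (structure plus reserves), C-mol/L.
#' @param horizon simulation/incubation horizon, h.
#' @param interval sampling interval, h.
#' @param replicates number of replicate measurements per sampling time.
#' @param volume medium volume, L.
#' @param reserves optional named vector \code{c(mEc=, mEn=)} overriding
#'   the default balanced-growth initial reserve densities.
#' @param limitation which substrate the design intends to exhaust first
#'   (\code{"C"}, \code{"N"}, or \code{"basic"} for the unrestricted
#'   pre-culture medium); used to group scenarios in two-stage turnover
#'   estimation.
#' @return an object of class \code{"deb_scenario"}.
#' @export
scenario <- function(id, glucose, nh4cl, inoculum = 4e-5,
                     horizon = 12, interval = 1, replicates = 3,
                     volume = 1, reserves = NULL,
                     limitation = c("C", "N", "basic")) {
  limitation <- match.arg(limitation)
  check_nonneg(glucose, "glucose"); check_nonneg(nh4cl, "nh4cl")
  check_nonneg(inoculum, "inoculum")
  check_positive(horizon, "horizon"); check_positive(interval, "interval")
  check_positive(volume, "volume")
  if (replicates < 1) stop_validation("'replicates' must be >= 1")
  if (!is.null(reserves)) {
    if (!all(c("mEc", "mEn") %in% names(reserves)))
      stop_validation("'reserves' needs named entries mEc and mEn")
    check_nonneg(reserves[["mEc"]], "mEc"); check_nonneg(reserves[["mEn"]], "mEn")
  }
  structure(list(id = id, glucose = glucose, nh4cl = nh4cl,
                 inoculum = inoculum, horizon = horizon, interval = interval,
                 replicates = replicates, volume = volume,
                 reserves = reserves, limitation = limitation),
            class = "deb_scenario")
}

#' @export
print.deb_scenario <- function(x, ...) {
  cat(sprintf(paste0("Scenario %s (%s limitation): glucose %g g/L, ",
                     "NH4Cl %g g/L, inoculum %.3g C-mol/L, %g h every %g h",
                     " x%d replicates\n"),
              x$id, x$limitation, x$glucose, x$nh4cl, x$inoculum,
              x$horizon, x$interval, x$replicates))
  invisible(x)
}

#' The six limitation scenarios and the shock pre-culture
#'
#' The experimental design this package emulates: three carbon-limitation
#' media (glucose at 25/50/75 % of the basic 4 g/L; ammonium chloride at
#' 150 % of the basic 0.5 g/L, i.e. 0.75 g/L, guaranteeing nitrogen
#' excess) and three nitrogen-limitation media (glucose raised 50 % to
#' 6 g/L; ammonium chloride at 15/25/50 % of basic), all sampled hourly
#' in triplicate; plus the basic-medium pre-culture for the
#' shock-limitation transfer, sampled every 30 minutes.
#'
#' @param inoculum inoculum biomass, C-mol/L; the default is calibrated
#'   so the carbon-limited cultures arrest in the observed 8-10 h window.
#' @return a named list of [scenario()] objects: \code{C1, C2, C3, N1,
#'   N2, N3, shock_pre}.
#' @export
limitation_scenarios <- function(inoculum = 4e-5) {
  list(
    C1 = scenario("C1", glucose = 1, nh4cl = 0.75, inoculum = inoculum,
                  limitation = "C"),
    C2 = scenario("C2", glucose = 2, nh4cl = 0.75, inoculum = inoculum,
                  limitation = "C"),
    C3 = scenario("C3", glucose = 3, nh4cl = 0.75, inoculum = inoculum,
                  limitation = "C"),
    N1 = scenario("N1", glucose = 6, nh4cl = 0.075, inoculum = inoculum,
                  limitation = "N"),
    N2 = scenario("N2", glucose = 6, nh4cl = 0.125, inoculum = inoculum,
                  limitation = "N"),
    N3 = scenario("N3", glucose = 6, nh4cl = 0.25, inoculum = inoculum,
                  limitation = "N"),
    shock_pre = scenario("shock_pre", glucose = 4, nh4cl = 0.5,
                         inoculum = inoculum, horizon = 4, interval = 0.5,
                         limitation = "basic")
  )
}

#' Initial culture state of a scenario
#'
#' Converts the medium recipe to molar units and initializes the reserve
#' densities at their balanced-growth values (inocula come from
#' exponential pre-cultures) unless the scenario overrides them.  The
#' inoculum is total biomass; structural mass is obtained by dividing by
#' (1 + mEc), the carbon content per C-mol of structure.
#'
#' @param scn a [scenario()].
#' @param params a [deb_params()] object.
#' @return a [culture_state()].
#' @export
scenario_state <- function(scn, params) {
  SC0 <- grams_to_cmol(scn$glucose, "glucose")
  SN0 <- grams_to_cmol(scn$nh4cl, "NH4Cl")
  res <- scn$reserves %||% balanced_reserves(params, SC = SC0, SN = SN0)
  MV0 <- scn$inoculum / (1 + res[["mEc"]]) * scn$volume
  culture_state(SC = SC0, SN = SN0, mEc = res[["mEc"]], mEn = res[["mEn"]],
                MV = MV0, V = scn$volume)
}

#' Sampling grid of a scenario
#' @param scn a [scenario()].
#' @return time vector from 0 to the horizon at the sampling interval (h).
#' @export
scenario_times <- function(scn) seq(0, scn$horizon, by = scn$interval)

#' Transfer a culture to a fresh medium lacking one substrate
#'
#' The shock-limitation protocol: cells from a mid-exponential pre-culture
#' are spun down and resuspended in fresh basic medium from which either
#' the carbon or the nitrogen source has been omitted.  Structure and both
#' reserve densities are carried over; the dissolved phase is reset.
#'
#' @param pre_state the [culture_state()] at the end of the pre-culture.
#' @param remove which substrate the fresh medium lacks, \code{"C"} or
#'   \code{"N"}.
#' @param glucose,nh4cl composition of the basic medium, g/L.
#' @param volume fresh medium volume, L.
#' @param dead_time handling time of the transfer procedure, h; recorded
#'   as an attribute so post-transfer sampling times can be offset.  The
#'   absent substrate cannot be assimilated during (or after) it in any
#'   case, its concentration being zero.
#' @return a [culture_state()] in the fresh medium, with attribute
#'   \code{dead_time}.
#' @export
transfer_event <- function(pre_state, remove = c("C", "N"),
                           glucose = 4, nh4cl = 0.5, volume = pre_state$V,
                           dead_time = 0.5) {
  remove <- match.arg(remove)
  SC <- if (remove == "C") 0 else grams_to_cmol(glucose, "glucose")
  SN <- if (remove == "N") 0 else grams_to_cmol(nh4cl, "NH4Cl")
  out <- culture_state(SC = SC, SN = SN,
                       mEc = pre_state$mEc, mEn = pre_state$mEn,
                       MV = pre_state$MV, V = volume,
                       alive = pre_state$alive)
  attr(out, "dead_time") <- dead_time
  out
}
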