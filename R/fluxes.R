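#' Specific assimilation flux
#'
#' Monod-type uptake of a dissolved substrate into the corresponding
#' reserve.  Assimilation is shut off when the substrate concentration is
#' zero (or numerically below zero) and in a dead culture.
#'
#' @param jEAm maximum specific assimilation rate (> 0).
#' @param S substrate concentration; may be a vector.
#' @param K half-saturation concentration (> 0).
#' @param alive viability flag.
#' @return specific assimilation flux in \code{[0, jEAm)}.
#' @export
assimilation_flux <- function(jEAm, S, K, alive = TRUE) {
  check_positive(jEAm, "jEAm"); check_positive(K, "K")
  if (!alive) return(rep_len(0, length(S)))
  ifelse(S > 0, jEAm * S / (K + S), 0)
}

#' Specific mobilization flux
#'
#' First-order release of reserve for metabolic use, proportional to the
#' reserve density: \code{mE * (kE - r)}.  The flux is floored at zero —
#' a specific growth rate above the turnover rate cannot occur at the
#' model's fixed point, and negative mobilization is unphysical.
#'
#' @param mE reserve density (>= 0); may be a vector.
#' @param kE reserve turnover rate (> 0).
#' @param r specific growth rate.
#' @return specific mobilization flux (>= 0).
#' @export
mobilization_flux <- function(mE, kE, r) {
  check_positive(kE, "kE")
  if (any(mE < 0)) stop_validation("reserve density must be non-negative")
  pmax(mE * (kE - r), 0)
}

#' Synthesizing-unit growth flux
#'
#' Merges the two parallel, complementary per-reserve growth fluxes into
#' a single structure-synthesis flux.  With scaled inputs
#' \code{a = jEcG/yEcV} and \code{b = jEnG/yEnV}, the flux is
#' \code{1 / (1/jP + 1/a + 1/b - 1/(a+b))}; the \code{1/jP} term drops
#' out when product formation is much faster than the reserve fluxes
#' (the default, \code{jP = Inf}).  The result is strictly below
#' \code{min(a, b)} whenever both inputs are positive, and zero when
#' either is zero: both reserves are required to build structure.
#'
#' @param jEcG,jEnG per-reserve growth fluxes (>= 0); vectors recycle.
#' @param yEcV,yEnV reserve-to-structure yields (> 0).
#' @param jP specific product-formation capacity; \code{Inf} selects the
#'   simplified form.
#' @return the specific growth flux of structure.
#' @export
growth_flux_su <- function(jEcG, jEnG, yEcV = 1, yEnV = 1, jP = Inf) {
  check_positive(yEcV, "yEcV"); check_positive(yEnV, "yEnV")
  if (any(!is.finite(jEcG)) || any(!is.finite(jEnG)))
    stop_validation("SU input fluxes must be finite")
  if (any(jEcG < 0) || any(jEnG < 0))
    stop_validation("SU input fluxes must be non-negative")
  jPinv <- if (is.finite(jP)) 1 / jP else 0
  a <- jEcG / yEcV
  b <- jEnG / yEnV
  ifelse(a > 0 & b > 0, 1 / (jPinv + 1 / a + 1 / b - 1 / (a + b)), 0)
}

#' Rejected growth flux
#'
#' The part of a per-reserve growth flux the synthesizing unit cannot
#' incorporate because the complementary reserve limits synthesis:
#' \code{jEG - yEV * jG}.  Non-negative by the SU contract.
#'
#' @param jEG per-reserve growth flux.
#' @param yEV reserve-to-structure yield.
#' @param jG SU growth flux.
#' @return rejected specific flux (>= 0).
#' @export
rejected_flux <- function(jEG, yEV, jG) {
  out <- jEG - yEV * jG
  if (any(out < -1e-9 * pmax(jEG, 1)))
    stop_numerical("rejected flux came out negative; SU contract violated")
  pmax(out, 0)
}

#' Switch-model maintenance paid from structure
#'
#' Maintenance not covered by mobilized reserve is charged to structure:
#' \code{(jEM - min(jEC, jEM)) / yEV}.  In this model the flux is
#' reported diagnostically but never fed into the dynamics — a culture
#' whose mobilization cannot cover maintenance dies instead.
#'
#' @param jEC mobilization flux (>= 0).
#' @param jEM maintenance demand (>= 0).
#' @param yEV reserve-to-structure yield (> 0).
#' @return structure-paid maintenance flux (>= 0).
#' @export
switch_maintenance <- function(jEC, jEM, yEV) {
  check_positive(yEV, "yEV")
  if (any(jEC < 0) || any(jEM < 0))
    stop_validation("fluxes must be non-negative")
  (jEM - pmin(jEC, jEM)) / yEV
}

# SU growth flux at a trial growth rate r, given reserve densities
growth_at_rate <- function(r, mEc, mEn, params) {
  jEcC <- max(mEc * (params$kE - r), 0)
  jEnC <- max(mEn * (params$kE - r), 0)
  growth_flux_su(max(jEcC - params$jEcM, 0), max(jEnC - params$jEnM, 0),
                 params$yEcV, params$yEnV, params$jP)
}

#' Specific growth rate at given reserve densities
#'
#' The growth rate is implicit: mobilization depends on \code{r} while
#' \code{r} equals the SU growth flux fed by mobilization (structure-paid
#' maintenance being disabled).  \code{g(r) - r} is strictly decreasing
#' on \code{[0, kE]} with \code{g(kE) = 0}, so the fixed point is unique;
#' it is found by bracketed root finding.
#'
#' @param mEc,mEn reserve densities.
#' @param params a [deb_params()] object.
#' @param tol root tolerance on r (1/h).
#' @return the specific growth rate (1/h), in \code{[0, kE)}.
#' @export
deb_growth_rate <- function(mEc, mEn, params, tol = 1e-12) {
  if (growth_at_rate(0, mEc, mEn, params) <= 0) return(0)
  root <- tryCatch(
    stats::uniroot(function(r) growth_at_rate(r, mEc, mEn, params) - r,
                   interval = c(0, params$kE), tol = tol),
    error = function(e)
      stop_numerical("growth-rate fixed point failed at mEc=", mEc,
                     ", mEn=", mEn, ": ", conditionMessage(e)))
  root$root
}

#' Evaluate all specific fluxes at a culture state
#'
#' Composes assimilation, mobilization, the synthesizing unit, rejection,
#' the (diagnostic) switch-model maintenance and the nitrogen-closure
#' ammonia flux into one self-consistent flux set at the implicit growth
#' rate.  A dead culture, or one without structure, has all fluxes zero.
#'
#' @param state a [culture_state()].
#' @param params a [deb_params()] object.
#' @return a list of class \code{"deb_fluxes"}: \code{jEcA, jEnA} the
#'   assimilation fluxes, \code{jEcC, jEnC} mobilization, \code{jEcG,
#'   jEnG} per-reserve growth fluxes, \code{jG} the SU flux, \code{r} the
#'   specific growth rate, \code{jEcR, jEnR} rejected fluxes,
#'   \code{jVMc, jVMn, jVM} structure-paid maintenance (diagnostic),
#'   \code{JNH3} the total metabolite ammonia flux (mol/h), and
#'   \code{maintenance_ok} — \code{FALSE} signals the death condition
#'   (some reserve's mobilization below its maintenance demand).
#' @export
deb_fluxes <- function(state, params) {
  zero <- list(jEcA = 0, jEnA = 0, jEcC = 0, jEnC = 0, jEcG = 0, jEnG = 0,
               jG = 0, r = 0, jEcR = 0, jEnR = 0,
               jVMc = params$jEcM / params$yEcV,
               jVMn = params$jEnM / params$yEnV,
               jVM = params$jEcM / params$yEcV + params$jEnM / params$yEnV,
               JNH3 = 0, maintenance_ok = FALSE)
  if (!state$alive || state$MV <= 0) {
    zero$jVMc <- zero$jVMn <- zero$jVM <- 0
    return(structure(zero, class = "deb_fluxes"))
  }

  jEcA <- assimilation_flux(params$jEcAm, state$SC, params$KC)
  jEnA <- assimilation_flux(params$jEnAm, state$SN, params$KN)
  r <- deb_growth_rate(state$mEc, state$mEn, params)
  jEcC <- mobilization_flux(state$mEc, params$kE, r)
  jEnC <- mobilization_flux(state$mEn, params$kE, r)
  jEcG <- max(jEcC - params$jEcM, 0)
  jEnG <- max(jEnC - params$jEnM, 0)
  jEcR <- rejected_flux(jEcG, params$yEcV, r)
  jEnR <- rejected_flux(jEnG, params$yEnV, r)
  jVMc <- switch_maintenance(jEcC, params$jEcM, params$yEcV)
  jVMn <- switch_maintenance(jEnC, params$jEnM, params$yEnV)

  fl <- list(jEcA = jEcA, jEnA = jEnA, jEcC = jEcC, jEnC = jEnC,
             jEcG = jEcG, jEnG = jEnG, jG = r, r = r,
             jEcR = jEcR, jEnR = jEnR,
             jVMc = jVMc, jVMn = jVMn, jVM = jVMc + jVMn,
             JNH3 = 0,
             maintenance_ok = jEcC >= params$jEcM && jEnC >= params$jEnM)
  fl$JNH3 <- nh3_closure_flux(fl, params, state$MV)
  structure(fl, class = "deb_fluxes")
}

#' Time derivatives of the DEB culture state
#'
#' Reference implementation of the mass balances for dissolved
#' substrates, reserve densities, structure, and the dissipation pools.
#' The compiled right-hand side used by [deb_simulate()] evaluates the
#' same expressions; agreement between the two is enforced by the test
#' suite.
#'
#' The substrate balances lose assimilated substrate and regain the
#' excreted part of the rejected flux (converted back at the
#' substrate-to-reserve yield); dissolved nitrogen additionally receives
#' the metabolite ammonia flux.  The dissipation pools accumulate every
#' element flow not captured by substrate, reserve or structure, so total
#' C and total N are conserved exactly.
#'
#' @param state a [culture_state()].
#' @param params a [deb_params()] object.
#' @param feed_JNH3 external ammonia feed (mol/h), zero in batch.
#' @param include_nh3 if \code{FALSE} the metabolite ammonia flux is left
#'   out of the dissolved-N balance; used by the conservation tests to
#'   demonstrate that it is exactly the flux that closes the N balance.
#' @return a list with the derivative vector \code{dydt} (named: SC, SN,
#'   mEc, mEn, MV, dissC, dissN) and the flux set used.
#' @export
deb_rhs <- function(state, params, feed_JNH3 = 0, include_nh3 = TRUE) {
  fl <- deb_fluxes(state, params)
  MV <- state$MV; V <- state$V
  jEcMp <- min(fl$jEcC, params$jEcM)
  jEnMp <- min(fl$jEnC, params$jEnM)

  dSC <- (-fl$jEcA + params$kappaSc * (1 - params$kappaEc) * fl$jEcR) *
    params$ySEc * MV / V
  dSN <- (-fl$jEnA + params$kappaSn * (1 - params$kappaEn) * fl$jEnR) *
    params$ySEn * MV / V +
    (if (include_nh3) fl$JNH3 else 0) / V + feed_JNH3 / V
  dmEc <- fl$jEcA - fl$jEcC + params$kappaEc * fl$jEcR - fl$r * state$mEc
  dmEn <- fl$jEnA - fl$jEnC + params$kappaEn * fl$jEnR - fl$r * state$mEn
  dMV <- fl$r * MV
  ddissC <- MV * ((params$ySEc - 1) * fl$jEcA +
                  (1 - params$kappaEc) * (1 - params$ySEc * params$kappaSc) * fl$jEcR +
                  (params$yEcV - 1) * fl$r +
                  jEcMp)
  ddissN <- MV * (1 - params$kappaEn) * (1 - params$ySEn * params$kappaSn) * fl$jEnR

  list(dydt = c(SC = dSC, SN = dSN, mEc = dmEc, mEn = dmEn, MV = dMV,
                dissC = ddissC, dissN = ddissN),
       fluxes = fl)
}

#' Balanced-growth reserve densities
#'
#' Steady reserve densities under constant substrate concentrations,
#' solving \code{dmE/dt = 0} for both reserves jointly, including
#' rejected-flux recycling.  For a reserve whose rejected flux vanishes
#' (extreme single limitation) the solution reduces to the closed form
#' \code{jEAm/kE}.  Used as the default inoculum reserve state: inocula
#' are taken from exponential pre-cultures.
#'
#' @param params a [deb_params()] object.
#' @param SC,SN substrate concentrations at which assimilation runs
#'   (default: excess, i.e. the maximum rates).
#' @param tol root tolerance on the growth rate.
#' @return named vector \code{c(mEc=, mEn=, r=)}.
#' @export
balanced_reserves <- function(params, SC = Inf, SN = Inf, tol = 1e-12) {
  jEcA <- if (is.finite(SC)) assimilation_flux(params$jEcAm, SC, params$KC)
          else params$jEcAm
  jEnA <- if (is.finite(SN)) assimilation_flux(params$jEnAm, SN, params$KN)
          else params$jEnAm
  kE <- params$kE

  # steady density of one reserve at growth rate r: dm/dt = 0 is linear
  # in m once the rejected flux is known to be active or not
  steady_density <- function(jA, jM, yV, kap, r) {
    m_rej <- (jA - kap * (jM + yV * r)) / (kE - kap * (kE - r))
    jR <- m_rej * (kE - r) - jM - yV * r
    if (is.finite(m_rej) && m_rej >= 0 && jR >= 0) m_rej else jA / kE
  }
  densities <- function(r) c(
    mEc = steady_density(jEcA, params$jEcM, params$yEcV, params$kappaEc, r),
    mEn = steady_density(jEnA, params$jEnM, params$yEnV, params$kappaEn, r))

  # consistency: the SU growth flux at the steady densities must equal r
  f <- function(r) {
    m <- densities(r)
    growth_at_rate(r, m[["mEc"]], m[["mEn"]], params) - r
  }
  if (f(0) <= 0) {
    # no balanced growth is possible; densities fall back to the
    # assimilation/turnover ratio of a non-growing reserve
    m <- densities(0)
    return(c(m, r = 0))
  }
  root <- tryCatch(
    stats::uniroot(f, interval = c(0, kE), tol = tol),
    error = function(e)
      stop_numerical("balanced-reserve solve failed: ", conditionMessage(e)))
  r <- root$root
  c(densities(r), r = r)
}
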