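# Atomic masses (g/mol) used throughout the C-mol bookkeeping.
ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007)

# Molar masses at the unit boundary: glucose per C-mol, ammonium chloride
# per mol, and the measured C-mol masses of structure and whole biomass
# (the measured values include residual S/ash and therefore exceed the
# CHON-computed masses).
MOLAR_MASS <- c(
  glucose   = 180.156 / 6,  # 30.026 g per C-mol
  NH4Cl     = 53.491,
  structure = 29.76,
  biomass   = 30.00
)

#' Convert mass concentrations to molar concentrations
#'
#' Converts g/L to C-mol/L (carbon-bearing compounds) or mol/L (NH4Cl)
#' for the compounds handled at the package's I/O boundary.  Internally
#' all state is kept in C-mol (mol) and hours; grams appear only in
#' scenario definitions and reports.
#'
#' @param mass_conc mass concentration(s), g/L; non-negative.
#' @param compound one of \code{"glucose"}, \code{"NH4Cl"},
#'   \code{"structure"}, \code{"biomass"}.
#' @return molar concentration(s): C-mol/L except for NH4Cl (mol/L).
#' @examples
#' grams_to_cmol(1, "glucose")    # 0.033305 C-mol/L
#' grams_to_cmol(30, "biomass")   # 1 C-mol/L
#' @export
grams_to_cmol <- function(mass_conc, compound = c("glucose", "NH4Cl",
                                                  "structure", "biomass")) {
  compound <- match.arg(compound)
  if (any(!is.finite(mass_conc)) || any(mass_conc < 0))
    stop_validation("mass concentrations must be finite and non-negative")
  mass_conc / MOLAR_MASS[[compound]]
}

#' @rdname grams_to_cmol
#' @param molar_conc molar concentration(s), C-mol/L or mol/L.
#' @export
cmol_to_grams <- function(molar_conc, compound = c("glucose", "NH4Cl",
                                                   "structure", "biomass")) {
  compound <- match.arg(compound)
  molar_conc * MOLAR_MASS[[compound]]
}

#' Elemental formula of a biomass component
#'
#' A CHON formula normalized per C-mol (or per mol of N for carbon-free
#' compounds), optionally with a measured molar mass overriding the mass
#' computed from the indices.  A measured mass may only exceed the CHON
#' mass: the difference is the residual sulfur/ash allowance of the
#' elemental analysis.
#'
#' @param C,H,O,N chemical indices (non-negative; \code{C} is 1 for
#'   carbon-bearing compounds and 0 for e.g. an ammonia-like N reserve).
#' @param molar_mass optional measured molar mass (g per C-mol or per mol).
#' @return an object of class \code{"elemental_formula"}.
#' @export
elemental_formula <- function(C = 1, H = 0, O = 0, N = 0, molar_mass = NULL) {
  idx <- c(C = C, H = H, O = O, N = N)
  if (any(!is.finite(idx)) || any(idx < 0))
    stop_validation("chemical indices must be finite and non-negative")
  chon <- sum(idx * ATOMIC_MASS[names(idx)])
  if (is.null(molar_mass)) {
    molar_mass <- chon
  } else {
    check_positive(molar_mass, "molar_mass")
    if (molar_mass < chon)
      stop_validation("measured molar mass (", molar_mass,
                      ") below the CHON-computed mass (", round(chon, 3),
                      "); only a residual S/ash excess is allowed")
  }
  structure(list(C = C, H = H, O = O, N = N,
                 chon_mass = chon, molar_mass = molar_mass),
            class = "elemental_formula")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat(sprintf("C%g H%g O%g N%g  (%.3f g/mol%s)\n", x$C, x$H, x$O, x$N,
              x$molar_mass,
              if (x$molar_mass > x$chon_mass + 1e-9)
                sprintf(", CHON %.3f", x$chon_mass) else ""))
  invisible(x)
}

#' Default component formulas
#'
#' \code{structure_formula()} is the measured composition of structural
#' biomass, CH1.96O0.45N0.22, with the measured C-mol mass 29.76 g/mol
#' (which exceeds the CHON mass because of residual S and ash).
#' \code{c_reserve_formula()} is a carbohydrate-like glucose-derived
#' reserve, CH2O.  \code{n_reserve_formula()} is an ammonia-like
#' ammonium-derived reserve, NH3, carrying one N and no C per mol.
#' @return an [elemental_formula()].
#' @export
structure_formula <- function() {
  elemental_formula(C = 1, H = 1.96, O = 0.45, N = 0.22, molar_mass = 29.76)
}

#' @rdname structure_formula
#' @export
c_reserve_formula <- function() elemental_formula(C = 1, H = 2, O = 1)

#' @rdname structure_formula
#' @export
n_reserve_formula <- function() elemental_formula(C = 0, H = 3, N = 1)

#' Elemental composition of total biomass from reserve densities
#'
#' Under strong homeostasis the structure and both reserves each have a
#' fixed composition, so the composition of total biomass (structure plus
#' reserves) changes only through the reserve densities.  Per C-mol of
#' structure, the amount of element e is the structure index plus
#' \code{mEc} times the C-reserve index plus \code{mEn} times the
#' N-reserve index, and mass fractions follow from the component molar
#' masses (measured masses, where available, take precedence over the
#' CHON-computed ones).
#'
#' @param mEc,mEn reserve densities (vectors of equal length are recycled).
#' @param structure,c_reserve,n_reserve component formulas.
#' @return a data frame with mass-percent columns \code{C_pct},
#'   \code{H_pct}, \code{O_pct}, \code{N_pct}, the structural fraction of
#'   biomass (C-mol structure per C-mol biomass), and the densities used.
#' @examples
#' biomass_composition(0, 0)$N_pct  # composition of pure structure, 10.35 %
#' @export
biomass_composition <- function(mEc, mEn,
                                structure = structure_formula(),
                                c_reserve = c_reserve_formula(),
                                n_reserve = n_reserve_formula()) {
  if (any(mEc < 0) || any(mEn < 0))
    stop_validation("reserve densities must be non-negative")
  n <- max(length(mEc), length(mEn))
  mEc <- rep_len(mEc, n); mEn <- rep_len(mEn, n)

  amount <- function(el)
    structure[[el]] + mEc * c_reserve[[el]] + mEn * n_reserve[[el]]
  total_mass <- structure$molar_mass + mEc * c_reserve$molar_mass +
    mEn * n_reserve$molar_mass

  out <- data.frame(
    C_pct = 100 * amount("C") * ATOMIC_MASS[["C"]] / total_mass,
    H_pct = 100 * amount("H") * ATOMIC_MASS[["H"]] / total_mass,
    O_pct = 100 * amount("O") * ATOMIC_MASS[["O"]] / total_mass,
    N_pct = 100 * amount("N") * ATOMIC_MASS[["N"]] / total_mass,
    structural_fraction = 1 / (1 + mEc * c_reserve$C + mEn * n_reserve$C),
    mEc = mEc, mEn = mEn
  )
  class(out) <- c("composition_report", "data.frame")
  out
}

#' @export
print.composition_report <- function(x, ...) {
  cat("Biomass elemental composition (mass %):\n")
  print.data.frame(head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Composition time series along a simulated trajectory
#'
#' @param trajectory a \code{deb_trajectory} from [deb_simulate()].
#' @param ... passed to [biomass_composition()].
#' @return the composition report with a leading \code{time_h} column.
#' @export
composition_trajectory <- function(trajectory, ...) {
  comp <- biomass_composition(trajectory$mEc, trajectory$mEn, ...)
  cbind(time_h = trajectory$time_h, comp)
}

#' Metabolite ammonia flux closing the nitrogen balance
#'
#' Ammonia is produced as a metabolite by the overheads of assimilation
#' (\code{ySEn - 1} per unit assimilated), of growth (\code{yEnV - nNV}
#' per unit structure built) and by maintenance dissipation of the N
#' reserve, and is excreted back into the medium.  Adding this flux to
#' the dissolved-N balance closes total-nitrogen conservation exactly.
#'
#' @param fluxes a flux set from [deb_fluxes()].
#' @param params a [deb_params()] object.
#' @param MV structural mass (C-mol).
#' @return total NH3 flux (mol/h).
#' @export
nh3_closure_flux <- function(fluxes, params, MV) {
  check_nonneg(MV, "MV")
  jEnMp <- min(fluxes$jEnC, params$jEnM)
  terms <- c(assimilation = (params$ySEn - 1) * fluxes$jEnA,
             growth = (params$yEnV - params$nNV) * fluxes$jG,
             maintenance = jEnMp)
  if (any(terms < -1e-12))
    stop_numerical("negative nitrogen-overhead term in NH3 closure: ",
                   paste(names(terms)[terms < -1e-12], collapse = ", "))
  MV * sum(pmax(terms, 0))
}
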