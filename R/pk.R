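# Exposure arithmetic linking in vitro potency to in vivo dosing:
# mass <-> molar conversion, unbound (free) concentrations, CSF:plasma
# scaling to an unbound-brain estimate, Kp,uu, and the apparent
# therapeutic index. All pure functions: same inputs, bit-identical
# outputs.

#' Convert a mass concentration to molar
#'
#' `nM = ng/mL / MW * 1000` for molecular weight in g/mol.
#'
#' @param conc_ngml concentration in ng/mL (>= 0).
#' @param mol_weight molecular weight, g/mol (> 0).
#' @return concentration in nM.
#' @seealso [molar_to_mass()] for the exact inverse.
#' @export
mass_to_molar <- function(conc_ngml, mol_weight) {
  if (any(conc_ngml < 0)) pf_input_error("concentration must be non-negative")
  if (any(mol_weight <= 0)) pf_input_error("molecular weight must be positive")
  conc_ngml / mol_weight * 1000
}

#' Convert a molar concentration to mass units
#' @param conc_nM concentration in nM (>= 0).
#' @param mol_weight molecular weight, g/mol (> 0).
#' @return concentration in ng/mL.
#' @export
molar_to_mass <- function(conc_nM, mol_weight) {
  if (any(conc_nM < 0)) pf_input_error("concentration must be non-negative")
  if (any(mol_weight <= 0)) pf_input_error("molecular weight must be positive")
  conc_nM * mol_weight / 1000
}

#' Unbound (free) concentration from total and fraction unbound
#'
#' `Cu = Ctotal * fu`. The plasma fraction unbound must lie in (0, 1.5]
#' (values slightly above 1 tolerate assay variability).
#'
#' @param total_nM total concentration (any unit; returned in the same).
#' @param fu fraction unbound.
#' @return unbound concentration.
#' @export
unbound_concentration <- function(total_nM, fu) {
  if (any(total_nM < 0)) pf_input_error("total concentration must be non-negative")
  if (any(fu <= 0 | fu > 1.5)) pf_input_error("fu must be in (0, 1.5]")
  total_nM * fu
}

#' Unbound brain exposure range from plasma Cmax and CSF:plasma ratios
#'
#' Converts the plasma Cmax to nM and scales by the smallest and largest
#' CSF:plasma ratio, treating CSF as a surrogate for unbound brain
#' concentration. Endpoints are rounded to the nearest nM for reporting;
#' the exact values are retained in the `exact` field.
#'
#' @param cmax_plasma_ngml plasma Cmax, ng/mL.
#' @param mol_weight molecular weight, g/mol.
#' @param ratios non-empty numeric vector of CSF:plasma ratios.
#' @return list with `low`, `high` (rounded nM) and `exact` (length-2
#'   unrounded).
#' @export
brain_exposure_range <- function(cmax_plasma_ngml, mol_weight, ratios) {
  if (length(ratios) == 0L) pf_input_error("ratio list must be non-empty")
  if (any(ratios <= 0 | ratios > 1.5)) pf_input_error("ratios must be in (0, 1.5]")
  plasma_nM <- mass_to_molar(cmax_plasma_ngml, mol_weight)
  exact <- plasma_nM * range(ratios)
  list(low = round(exact[1]), high = round(exact[2]), exact = exact)
}

#' Unbound brain-to-plasma partition coefficient (Kp,uu)
#'
#' Ratio of unbound brain to unbound plasma concentration; dimensionless
#' and invariant to the concentration unit as long as both share it.
#'
#' @param cu_brain,cu_plasma unbound concentrations in matching units.
#' @return Kp,uu (fraction).
#' @export
kpuu <- function(cu_brain, cu_plasma) {
  if (any(cu_plasma <= 0)) pf_input_error("unbound plasma concentration must be positive")
  if (any(cu_brain < 0)) pf_input_error("unbound brain concentration must be non-negative")
  cu_brain / cu_plasma
}

#' Apparent therapeutic index
#'
#' Fold-margin between an adverse-effect exposure and an efficacious
#' exposure, computed on matching units (the conventional basis is total
#' plasma exposure; pass unbound values for an unbound-basis margin).
#'
#' @param adverse_exposure exposure at which adverse effects appear.
#' @param efficacy_exposure exposure at the efficacious dose (> 0).
#' @param units declared unit labels for the two exposures; they must
#'   match.
#' @return the unrounded fold-margin.
#' @export
therapeutic_index <- function(adverse_exposure, efficacy_exposure,
                              units = c("ng/mL", "ng/mL")) {
  if (length(units) == 2L && !identical(units[1], units[2]))
    pf_input_error(sprintf("exposure unit mismatch: '%s' vs '%s'", units[1], units[2]))
  if (any(efficacy_exposure <= 0)) pf_input_error("efficacy exposure must be positive")
  adverse_exposure / efficacy_exposure
}

#' Species exposure record with derived unbound and brain quantities
#'
#' Bundles a species/dose exposure observation and runs the full conversion
#' chain: plasma molar concentration, unbound plasma concentration, the
#' CSF-scaled unbound-brain range, and Kp,uu if an unbound brain estimate is
#' available. Construction asserts internal dimensional consistency
#' (unbound <= total when fu <= 1; brain range within the plasma molar
#' value when all ratios <= 1).
#'
#' @param species species label.
#' @param dose_mgkg dose, mg/kg.
#' @param route dosing route label.
#' @param cmax_plasma_ngml plasma Cmax, ng/mL.
#' @param fu_plasma plasma fraction unbound, in (0, 1.5].
#' @param mol_weight molecular weight, g/mol.
#' @param csf_plasma_ratios optional named numeric vector of CSF:plasma
#'   ratios (names are time labels).
#' @param cu_brain_nM optional measured/estimated unbound brain
#'   concentration for Kp,uu.
#' @param notes free-text notes.
#' @return An object of class `"exposure_record"` with the input fields and
#'   derived `plasma_nM`, `cu_plasma_nM`, `cu_brain_range_nM`, `kpuu`.
#' @export
exposure_record <- function(species, dose_mgkg, route = "po",
                            cmax_plasma_ngml, fu_plasma, mol_weight,
                            csf_plasma_ratios = NULL, cu_brain_nM = NULL,
                            notes = "") {
  plasma_nM <- mass_to_molar(cmax_plasma_ngml, mol_weight)
  cu_plasma <- unbound_concentration(plasma_nM, fu_plasma)
  rng <- if (!is.null(csf_plasma_ratios) && length(csf_plasma_ratios))
    brain_exposure_range(cmax_plasma_ngml, mol_weight, csf_plasma_ratios)
  else NULL
  kp <- if (!is.null(cu_brain_nM)) kpuu(cu_brain_nM, cu_plasma) else NA_real_
  # dimensional-analysis audit
  if (fu_plasma <= 1 && cu_plasma > plasma_nM + 1e-9)
    pf_input_error("internal inconsistency: unbound exceeds total at fu <= 1")
  if (!is.null(rng) && all(csf_plasma_ratios <= 1) &&
      rng$exact[2] > plasma_nM + 1e-9)
    pf_input_error("internal inconsistency: brain range exceeds plasma molar value")
  structure(list(species = species, dose_mgkg = dose_mgkg, route = route,
                 cmax_plasma_ngml = cmax_plasma_ngml, fu_plasma = fu_plasma,
                 mol_weight = mol_weight,
                 csf_plasma_ratios = csf_plasma_ratios,
                 plasma_nM = plasma_nM, cu_plasma_nM = cu_plasma,
                 cu_brain_range_nM = rng, kpuu = kp, notes = notes),
            class = "exposure_record")
}

#' @export
print.exposure_record <- function(x, ...) {
  cat(sprintf("Exposure record: %s, %.3g mg/kg (%s)\n", x$species,
              x$dose_mgkg, x$route))
  cat(sprintf("  Cmax %.4g ng/mL = %.4g nM total; Cu,pl %.4g nM (fu %.3g)\n",
              x$cmax_plasma_ngml, x$plasma_nM, x$cu_plasma_nM, x$fu_plasma))
  if (!is.null(x$cu_brain_range_nM))
    cat(sprintf("  estimated unbound brain range: %d to %d nM\n",
                x$cu_brain_range_nM$low, x$cu_brain_range_nM$high))
  if (is.finite(x$kpuu)) cat(sprintf("  Kp,uu = %.3g\n", x$kpuu))
  invisible(x)
}
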