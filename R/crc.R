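#' Concentration-response curve
#'
#' Container for a single ligand x pathway concentration-response dataset.
#' Concentrations are stored internally in molar regardless of the unit they
#' were supplied in, so downstream potencies (pEC50) are always -log10 molar.
#'
#' @param conc numeric vector of agonist concentrations (strictly positive,
#'   finite), in the unit given by `conc_unit`. With `conc_unit = "log10M"`
#'   the values are log10 molar concentrations and are exponentiated.
#' @param response numeric vector of responses, same length as `conc`.
#' @param ligand,pathway identifiers for the ligand and the assay/pathway
#'   (e.g. `"pERK"`, `"IP1"`, `"GTPgS"`, `"DMR"`).
#' @param replicate optional replicate identifiers (recycled if length 1).
#' @param units response units: `"raw"` assay units or `"percent_reference"`.
#' @param conc_unit concentration unit of the supplied values.
#' @return An object of class `"crc"`: a list with fields `ligand_id`,
#'   `pathway_id`, `conc` (molar), `response`, `replicate_ids`,
#'   `response_units`.
#' @examples
#' crc(10^seq(-10, -5, 1), c(1, 4, 22, 60, 90, 98), ligand = "ACh",
#'     pathway = "IP1")
#' @export
crc <- function(conc, response, ligand = "ligand", pathway = "pathway",
                replicate = NULL, units = c("raw", "percent_reference"),
                conc_unit = c("M", "mM", "uM", "nM", "pM", "log10M")) {
  units <- match.arg(units)
  conc_unit <- match.arg(conc_unit)
  conc <- as.numeric(conc)
  response <- as.numeric(response)
  if (length(conc) != length(response) || length(conc) < 1L)
    pf_input_error("`conc` and `response` must have equal length >= 1")
  conc <- switch(conc_unit,
    M = conc, mM = conc * 1e-3, uM = conc * 1e-6,
    nM = conc * 1e-9, pM = conc * 1e-12, log10M = 10^conc)
  if (any(!is.finite(conc)) || any(conc <= 0))
    pf_input_error("all concentrations must be finite and strictly positive")
  if (any(!is.finite(response)))
    pf_input_error("all responses must be finite")
  replicate <- replicate %||% rep(1L, length(conc))
  if (length(replicate) == 1L) replicate <- rep(replicate, length(conc))
  if (length(replicate) != length(conc))
    pf_input_error("`replicate` must match the number of measurements")
  structure(
    list(ligand_id = as.character(ligand), pathway_id = as.character(pathway),
         conc = conc, response = response,
         replicate_ids = as.character(replicate), response_units = units),
    class = "crc")
}

#' @export
print.crc <- function(x, ...) {
  cat(sprintf(
    "Concentration-response curve: %s / %s\n  %d points, %d distinct concentrations (%.3g to %.3g M), units: %s\n",
    x$ligand_id, x$pathway_id, length(x$conc),
    length(unique(x$conc)), min(x$conc), max(x$conc), x$response_units))
  invisible(x)
}

#' @export
as.data.frame.crc <- function(x, ...) {
  data.frame(ligand = x$ligand_id, pathway = x$pathway_id,
             conc_M = x$conc, response = x$response,
             replicate = x$replicate_ids, units = x$response_units,
             stringsAsFactors = FALSE)
}

# Coerce data.frame rows (ligand, pathway, conc_M, response, replicate) to crc
as_crc <- function(df, ligand = NULL, pathway = NULL,
                   units = c("raw", "percent_reference")) {
  if (inherits(df, "crc")) return(df)
  ligand <- ligand %||% as.character(df$ligand[1] %||% "ligand")
  pathway <- pathway %||% as.character(df$pathway[1] %||% "pathway")
  crc(df$conc_M, df$response, ligand = ligand, pathway = pathway,
      replicate = df$replicate %||% NULL, units = match.arg(units))
}

# Guard shared by the curve fitters
check_fittable <- function(curve) {
  if (length(unique(curve$conc)) < 4L)
    pf_input_error("a curve submitted for fitting must span >= 4 distinct concentrations")
  span <- diff(range(curve$response))
  if (span <= 1e-6 * max(abs(curve$response), 1))
    pf_no_fit_error("responses are flat: no concentration-response relationship to fit")
  invisible(TRUE)
}
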