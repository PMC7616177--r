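# Surmountable (competitive) antagonism: dose ratios and Schild regression.
# Under simple competition the Gaddum shift is EC50' = EC50 * (1 + [B]/KB),
# so log10(DR - 1) regressed on log10[B] has slope 1 and x-intercept -pKB.

#' Dose ratio from paired control/treated 4PL fits
#'
#' `DR = EC50(treated) / EC50(control)` on the molar scale: the fold
#' rightward shift of the agonist curve caused by an antagonist.
#'
#' @param control_fit,treated_fit converged [fit_4pl()] fits of the same
#'   agonist/pathway without and with antagonist.
#' @return numeric dose ratio (>= 0).
#' @export
dose_ratio <- function(control_fit, treated_fit) {
  if (!isTRUE(control_fit$converged) || !isTRUE(treated_fit$converged))
    pf_input_error("dose ratios require converged control and treated fits")
  treated_fit$ec50 / control_fit$ec50
}

#' Schild regression: slope, pA2 and slope-constrained pKB
#'
#' Ordinary least squares of `log10(DR - 1)` on `log10[B]`. Points with
#' `DR <= 1` carry no antagonism information on this scale and are excluded
#' with a warning (noise at low antagonist concentrations commonly yields
#' DR around 1). The free-slope x-intercept gives pA2; refitting with the
#' slope fixed at unity gives the constrained pKB. A Schild slope near 1
#' supports simple competitive antagonism, in which case pA2 estimates
#' -log10 KB.
#'
#' @param B numeric vector of antagonist concentrations (molar).
#' @param DR numeric vector of dose ratios, same length.
#' @return An object of class `"schild"`: `slope`, `se_slope`, `pA2`,
#'   `pKB_constrained`, `r_squared`, `n_points`, `excluded`
#'   (concentrations dropped for DR <= 1).
#' @export
schild_regression <- function(B, DR) {
  B <- as.numeric(B); DR <- as.numeric(DR)
  if (length(B) != length(DR) || any(B <= 0))
    pf_input_error("B and DR must match in length and B must be positive molar")
  usable <- DR > 1
  if (!any(usable))
    pf_no_fit_error("no antagonism detected: all dose ratios <= 1")
  if (any(!usable))
    warning(sprintf("excluding %d point(s) with DR <= 1 from Schild regression",
                    sum(!usable)))
  if (sum(usable) < 2L)
    pf_input_error("need >= 2 antagonist concentrations with DR > 1")
  x <- log10(B[usable]); y <- log10(DR[usable] - 1)
  ols <- lm(y ~ x)
  cf <- coef(ols)
  slope <- unname(cf["x"]); intercept <- unname(cf["(Intercept)"])
  # summary.lm warns on zero-residual input; exact Gaddum data are valid here
  s <- suppressWarnings(summary(ols))
  se_slope <- tryCatch(s$coefficients["x", "Std. Error"],
                       error = function(e) NA_real_)
  structure(list(
    slope = slope, se_slope = se_slope,
    pA2 = intercept / slope,              # -(x-intercept)
    pKB_constrained = mean(y - x),        # slope fixed at 1
    r_squared = s$r.squared,
    n_points = sum(usable),
    excluded = B[!usable],
    antagonist_conc = B[usable], dose_ratios = DR[usable]),
    class = "schild")
}

#' @export
print.schild <- function(x, ...) {
  cat(sprintf("Schild analysis (%d usable dose ratios)\n", x$n_points))
  cat(sprintf("  slope %.3f +/- %.3f, pA2 %.3f, constrained pKB %.3f, R2 %.4f\n",
              x$slope, x$se_slope, x$pA2, x$pKB_constrained, x$r_squared))
  if (length(x$excluded))
    cat(sprintf("  excluded %d concentration(s) with DR <= 1\n",
                length(x$excluded)))
  invisible(x)
}

#' Full Schild analysis from a family of agonist curves
#'
#' Fits a 4PL curve for each antagonist concentration (0 = control),
#' computes dose ratios against the control, and runs the Schild
#' regression. The interacting ligand's own partial agonism, if any, is
#' ignored at this stage (it is treated purely as a competitive
#' antagonist).
#'
#' @param data data.frame with columns `conc_M` (agonist), `response`, and
#'   `antagonist_conc_M` (0 for the control family).
#' @return the [schild_regression()] result, with the per-concentration
#'   fits attached as attribute `"fits"`.
#' @export
schild_analysis <- function(data) {
  if (!all(c("conc_M", "response", "antagonist_conc_M") %in% names(data)))
    pf_input_error("data must have conc_M, response, antagonist_conc_M columns")
  if (!any(data$antagonist_conc_M == 0))
    pf_input_error("control curves (antagonist_conc_M = 0) are required")
  fits <- lapply(split(data, data$antagonist_conc_M), function(d)
    fit_4pl(crc(d$conc_M, d$response)))
  Bs <- as.numeric(names(fits))
  ctrl <- fits[[which(Bs == 0)]]
  idx <- which(Bs > 0)
  DR <- vapply(idx, function(i) dose_ratio(ctrl, fits[[i]]), numeric(1))
  res <- schild_regression(Bs[idx], DR)
  attr(res, "fits") <- fits
  res
}
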