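#' Fit a four-parameter logistic (4PL / Hill) concentration-response curve
#'
#' Fits `E = bottom + (top - bottom) / (1 + 10^(hill * (-pEC50 - log10 A)))`
#' by Levenberg-Marquardt least squares in log10-concentration space, with
#' pEC50 (-log10 molar EC50) as a free parameter for numerical conditioning
#' on multi-decade designs.
#'
#' Default bounds keep fits sane on truncated curves: `hill` in \[0.3, 5\],
#' `pEC50` within the data's log-concentration range widened by 2 log units;
#' `bottom`/`top` are unbounded unless constrained. Initialization is
#' deterministic: bottom = min response, top = max response, pEC50 at the
#' half-range crossing, hill = 1.
#'
#' @param curve a [crc()] object (or data.frame with `conc_M`, `response`).
#' @param constraints optional named list of `lower`/`upper` numeric vectors
#'   over `c(bottom, top, pEC50, hill)` overriding the defaults elementwise
#'   (use `NA` to keep a default).
#' @param bootstrap logical; if `TRUE`, parameter standard errors are
#'   recomputed by seeded residual-bootstrap resampling.
#' @param n_boot number of bootstrap resamples.
#' @param seed seed for the bootstrap stream.
#' @return An object of class `"pl4_fit"`: coefficients (`bottom`, `top`,
#'   `pEC50`, `hill`), standard errors, `ec50` (molar), `emax` (= top),
#'   `converged`, `residual_sd`, `n_points`, and a `top_extrapolated` flag
#'   set when the fitted EC50 exceeds one third of the highest concentration
#'   tested (the plateau is not approached).
#' @examples
#' cv <- crc(10^seq(-10, -6.5, 0.5), 100 / (1 + 10^(-7 - seq(-10, -6.5, 0.5))))
#' fit_4pl(cv)
#' @export
fit_4pl <- function(curve, constraints = NULL, bootstrap = FALSE,
                    n_boot = 1000L, seed = 1L) {
  curve <- as_crc(curve)
  check_fittable(curve)
  x <- log10(curve$conc)
  y <- curve$response

  lower <- c(bottom = -Inf, top = -Inf, pEC50 = -max(x) - 2, hill = 0.3)
  upper <- c(bottom = Inf, top = Inf, pEC50 = -min(x) + 2, hill = 5)
  if (!is.null(constraints)) {
    for (side in c("lower", "upper")) {
      v <- constraints[[side]]
      if (!is.null(v)) {
        tgt <- if (side == "lower") lower else upper
        tgt[names(v)[!is.na(v)]] <- v[!is.na(v)]
        if (side == "lower") lower <- tgt else upper <- tgt
      }
    }
  }

  start <- pl4_start(x, y, lower, upper)
  resid_fn <- function(p)
    p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
      (1 + 10^(p[["hill"]] * (-p[["pEC50"]] - x))) - y
  fit <- pf_fit(start, resid_fn, lower, upper)

  if (!fit$converged) {
    return(structure(list(
      coefficients = start, se = setNames(rep(NA_real_, 4), names(start)),
      converged = FALSE, message = fit$message, residual_sd = NA_real_,
      n_points = length(y), ec50 = NA_real_, emax = NA_real_,
      top_extrapolated = NA, ligand = curve$ligand_id,
      pathway = curve$pathway_id, fitted = NULL, residuals = NULL),
      class = "pl4_fit"))
  }

  cf <- fit$par[c("bottom", "top", "pEC50", "hill")]
  se <- fit$se[names(cf)]
  res <- resid_fn(cf)
  if (isTRUE(bootstrap)) {
    se <- pl4_boot_se(x, y + res, res, cf, lower, upper, n_boot, seed)
  }
  rsd <- sqrt(sum(res^2) / max(1, length(y) - 4))
  ec50 <- 10^(-cf[["pEC50"]])
  structure(list(
    coefficients = cf, se = setNames(pmax(se, 0), names(cf)),
    converged = TRUE, message = "converged",
    residual_sd = rsd, n_points = length(y), ec50 = ec50,
    emax = cf[["top"]],
    top_extrapolated = ec50 > max(curve$conc) / 3,
    ligand = curve$ligand_id, pathway = curve$pathway_id,
    fitted = y + res, residuals = res),
    class = "pl4_fit")
}

# Deterministic starting values: half-range crossing for pEC50.
pl4_start <- function(x, y, lower, upper) {
  mid <- (min(y) + max(y)) / 2
  m <- aggregate(y, list(x = x), mean)
  m <- m[order(m$x), ]
  ybar <- m[[2]]
  idx <- which(diff(sign(ybar - mid)) != 0)
  x50 <- if (length(idx)) {
    i <- idx[1]
    m$x[i] + (mid - ybar[i]) * (m$x[i + 1] - m$x[i]) / (ybar[i + 1] - ybar[i])
  } else median(x)
  st <- c(bottom = min(y), top = max(y),
          pEC50 = min(max(-x50, lower[["pEC50"]] + 1e-6), upper[["pEC50"]] - 1e-6),
          hill = 1)
  st
}

pl4_boot_se <- function(x, fv, res, cf, lower, upper, n_boot, seed) {
  out <- matrix(NA_real_, n_boot, 4)
  for (b in seq_len(n_boot)) {
    set.seed((seed * 1000L + b) %% .Machine$integer.max)
    yb <- fv + sample(res, replace = TRUE)
    fb <- pf_fit(cf, function(p)
      p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
        (1 + 10^(p[["hill"]] * (-p[["pEC50"]] - x))) - yb,
      lower, upper, maxiter = 200)
    if (fb$converged) out[b, ] <- fb$par[c("bottom", "top", "pEC50", "hill")]
  }
  apply(out, 2, sd, na.rm = TRUE)
}

#' @export
print.pl4_fit <- function(x, ...) {
  cat(sprintf("4PL fit: %s / %s (%s)\n", x$ligand, x$pathway,
              if (x$converged) "converged" else paste("NOT converged:", x$message)))
  if (x$converged) {
    cf <- x$coefficients
    cat(sprintf("  pEC50 %.3f (EC50 %.3g M), hill %.2f, bottom %.2f, top %.2f\n",
                cf[["pEC50"]], x$ec50, cf[["hill"]], cf[["bottom"]], cf[["top"]]))
    if (isTRUE(x$top_extrapolated))
      cat("  warning: top plateau extrapolated (EC50 > max conc / 3)\n")
  }
  invisible(x)
}

#' @export
coef.pl4_fit <- function(object, ...) object$coefficients

#' Rescale a curve to percent of a reference agonist
#'
#' Rescales responses so that the reference fit's bottom maps to 0% and its
#' top to 100%, the convention used when partial-agonist responses are
#' expressed as percent of a full agonist's maximum.
#'
#' @param curve a [crc()] object.
#' @param reference_fit a converged [fit_4pl()] fit of the reference agonist
#'   (must have `top > bottom`).
#' @return A new `crc` with `response_units = "percent_reference"`.
#' @export
normalize_to_reference <- function(curve, reference_fit) {
  curve <- as_crc(curve)
  cf <- reference_fit$coefficients
  if (!isTRUE(reference_fit$converged))
    pf_input_error("reference fit did not converge")
  if (!(cf[["top"]] > cf[["bottom"]]))
    pf_input_error("degenerate reference: top must exceed bottom")
  resp <- (curve$response - cf[["bottom"]]) / (cf[["top"]] - cf[["bottom"]]) * 100
  out <- curve
  out$response <- resp
  out$response_units <- "percent_reference"
  out
}

#' Summarize potency and efficacy across independent experiments
#'
#' Averages on the log scale (mean and SEM of pEC50, i.e. geometric-mean
#' EC50) and arithmetic mean/SEM of Emax, the standard "mean +/- SEM of N
#' experiments" reporting convention.
#'
#' @param fits list of converged [fit_4pl()] fits for the same ligand and
#'   pathway.
#' @return A list with `mean_pEC50`, `sem_pEC50`, `mean_Emax`, `sem_Emax`,
#'   `n_experiments`, and `single_experiment` flag (SEM reported as 0 when
#'   n = 1).
#' @export
potency_summary <- function(fits) {
  if (length(fits) == 0L) pf_input_error("empty fit list")
  if (!all(vapply(fits, function(f) isTRUE(f$converged), logical(1))))
    pf_input_error("all fits must have converged")
  lig <- unique(vapply(fits, `[[`, character(1), "ligand"))
  pw <- unique(vapply(fits, `[[`, character(1), "pathway"))
  if (length(lig) > 1L || length(pw) > 1L)
    pf_input_error("fits must share one ligand and one pathway")
  p <- vapply(fits, function(f) f$coefficients[["pEC50"]], numeric(1))
  e <- vapply(fits, function(f) f$emax, numeric(1))
  n <- length(p)
  sem <- function(v) if (n > 1L) sd(v) / sqrt(n) else 0
  list(ligand = lig, pathway = pw, mean_pEC50 = mean(p), sem_pEC50 = sem(p),
       mean_Emax = mean(e), sem_Emax = sem(e), n_experiments = n,
       single_experiment = n == 1L)
}

#' Fit a thermal melt curve and estimate Tm
#'
#' Fits a descending logistic in temperature to fraction-of-ligand-bound
#' data and reports Tm, the temperature at which 50% of the low-temperature
#' ligand binding is retained (found on the fitted curve, not by linear
#' interpolation between points).
#'
#' @param temperature numeric vector of temperatures (degrees C), >= 4 values
#'   spanning the transition.
#' @param fraction_bound numeric vector of retained-binding fractions
#'   (typically pre-normalized so the lowest temperature is 1.0).
#' @return A list with `Tm` (degrees C), `midpoint` (logistic inflection),
#'   `scale`, `top`, `bottom`, `converged`.
#' @export
fit_thermal_melt <- function(temperature, fraction_bound) {
  t <- as.numeric(temperature); f <- as.numeric(fraction_bound)
  if (length(t) != length(f) || length(unique(t)) < 4L)
    pf_input_error("need >= 4 distinct temperatures spanning the transition")
  # monotonicity check: binding should fall with temperature
  ord <- order(t)
  inc <- diff(f[ord])
  tol <- 3 * sd(inc) / sqrt(2)
  if (any(inc > max(tol, 0.05)))
    warning("fraction bound increases with temperature beyond noise tolerance")
  st <- c(top = max(f), bottom = min(f),
          Tmid = t[ord][which.min(abs(f[ord] - (max(f) + min(f)) / 2))],
          scale = diff(range(t)) / 10)
  fit <- pf_fit(st, function(p)
    p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
      (1 + exp((t - p[["Tmid"]]) / p[["scale"]])) - f,
    lower = c(top = -Inf, bottom = -Inf, Tmid = min(t) - 20, scale = 1e-3),
    upper = c(top = Inf, bottom = Inf, Tmid = max(t) + 20, scale = diff(range(t))))
  if (!fit$converged)
    return(list(Tm = NA_real_, converged = FALSE))
  cf <- fit$par
  pred <- function(tt) cf[["bottom"]] +
    (cf[["top"]] - cf[["bottom"]]) / (1 + exp((tt - cf[["Tmid"]]) / cf[["scale"]]))
  target <- 0.5 * cf[["top"]]  # 50% of full (low-temperature) binding
  lo <- min(t) - 10; hi <- max(t) + 10
  if ((pred(lo) - target) * (pred(hi) - target) > 0)
    pf_no_fit_error("no 50% binding transition within the measured temperature range")
  Tm <- uniroot(function(tt) pred(tt) - target, c(lo, hi), tol = 1e-9)$root
  list(Tm = Tm, midpoint = cf[["Tmid"]], scale = cf[["scale"]],
       top = cf[["top"]], bottom = cf[["bottom"]], converged = TRUE)
}
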