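# Radioligand-binding analyses: one-site saturation, one-site competition
# with Cheng-Prusoff conversion, mono-exponential dissociation kinetics,
# and the dpm -> fmol/mg unit conversion (1 Ci = 2.22e12 dpm).

#' One-site saturation binding: KD and Bmax
#'
#' Specific binding is obtained by point-wise subtraction of the matched
#' non-specific (NSB) wells and fitted to the one-site isotherm
#' `B(L) = Bmax * L / (KD + L)`; the NSB channel is modeled as linear
#' through the origin (`nsb = ns_slope * L`).
#'
#' @param L radioligand concentrations (molar), >= 5 values spanning KD.
#' @param total_dpm total-binding counts (or any consistent unit such as
#'   fmol/mg after [dpm_to_fmol_per_mg()]).
#' @param nsb_dpm matched non-specific-binding counts.
#' @return An object of class `"saturation_fit"`: `KD` (molar), `Bmax`
#'   (input units), `ns_slope`, standard errors, `converged`, and
#'   `extrapolated` flag set when the fitted KD exceeds the highest
#'   concentration tested (no approach to saturation).
#' @export
fit_saturation <- function(L, total_dpm, nsb_dpm) {
  L <- as.numeric(L)
  if (length(L) < 5L || length(unique(L)) < 5L)
    pf_input_error("need >= 5 radioligand concentrations spanning KD")
  if (length(total_dpm) != length(L) || length(nsb_dpm) != length(L))
    pf_input_error("total_dpm and nsb_dpm must match L in length")
  if (any(L <= 0)) pf_input_error("concentrations must be positive molar")
  specific <- total_dpm - nsb_dpm
  ns <- lm(nsb_dpm ~ 0 + L)
  st <- c(Bmax = max(specific) * 1.2,
          KD = L[which.min(abs(specific - max(specific) / 2))])
  fit <- pf_fit(st, function(p) p[["Bmax"]] * L / (p[["KD"]] + L) - specific,
                lower = c(Bmax = 0, KD = min(L) / 1e4),
                upper = c(Bmax = Inf, KD = max(L) * 1e4))
  if (!fit$converged)
    return(structure(list(converged = FALSE, KD = NA_real_, Bmax = NA_real_),
                     class = "saturation_fit"))
  cf <- fit$par; se <- fit$se
  structure(list(
    KD = unname(cf["KD"]), Bmax = unname(cf["Bmax"]),
    se_KD = unname(se["KD"]), se_Bmax = unname(se["Bmax"]),
    ns_slope = unname(coef(ns)["L"]),
    converged = TRUE, extrapolated = unname(cf["KD"]) > max(L),
    residual_sd = sqrt(fit$deviance / max(1, length(L) - 2))),
    class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) { cat("Saturation fit: NOT converged\n"); return(invisible(x)) }
  cat(sprintf("One-site saturation fit: KD = %.4g M, Bmax = %.4g (ns slope %.3g)\n",
              x$KD, x$Bmax, x$ns_slope))
  if (isTRUE(x$extrapolated))
    cat("  warning: fitted KD above highest concentration tested (extrapolated)\n")
  invisible(x)
}

#' One-site competition binding: pIC50
#'
#' Fits the descending one-site logistic with the Hill slope fixed at -1,
#' `B(I) = bottom + (top - bottom) / (1 + 10^(log10 I + pIC50))`. When the
#' response span is below three times the estimated measurement noise the
#' result is returned as a "no binding" call (e.g. a compound with no
#' detectable affinity at a receptor subtype), which is distinct from a
#' solver failure.
#'
#' @param log_I log10 molar inhibitor concentrations (>= 5 values with both
#'   plateaus represented).
#' @param bound bound radioligand (counts or normalized).
#' @return An object of class `"competition_fit"`: `pIC50`, `se_pIC50`,
#'   `IC50` (molar), `top`, `bottom`, `no_binding`, `converged`.
#' @export
fit_competition <- function(log_I, bound) {
  log_I <- as.numeric(log_I); bound <- as.numeric(bound)
  if (length(log_I) < 5L || length(unique(log_I)) < 5L)
    pf_input_error("need >= 5 inhibitor concentrations")
  if (length(bound) != length(log_I))
    pf_input_error("bound must match log_I in length")
  ord <- order(log_I)
  m <- aggregate(bound, list(x = log_I), mean)
  noise <- mad(diff(bound[ord])) / sqrt(2)
  span <- diff(range(m[[2]]))
  if (span < 3 * max(noise, .Machine$double.eps)) {
    return(structure(list(pIC50 = NA_real_, no_binding = TRUE,
                          converged = TRUE, span = span, noise = noise),
                     class = "competition_fit"))
  }
  mid <- (max(m[[2]]) + min(m[[2]])) / 2
  st <- c(top = max(bound), bottom = min(bound),
          pIC50 = -m$x[which.min(abs(m[[2]] - mid))])
  fit <- pf_fit(st, function(p)
    p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
      (1 + 10^(log_I + p[["pIC50"]])) - bound,
    lower = c(top = -Inf, bottom = -Inf, pIC50 = -max(log_I) - 3),
    upper = c(top = Inf, bottom = Inf, pIC50 = -min(log_I) + 3))
  if (!fit$converged)
    return(structure(list(pIC50 = NA_real_, no_binding = FALSE,
                          converged = FALSE), class = "competition_fit"))
  cf <- fit$par
  se <- unname(fit$se["pIC50"])
  structure(list(pIC50 = unname(cf["pIC50"]), se_pIC50 = se,
                 IC50 = 10^(-unname(cf["pIC50"])),
                 top = unname(cf["top"]), bottom = unname(cf["bottom"]),
                 no_binding = FALSE, converged = TRUE),
            class = "competition_fit")
}

#' @export
print.competition_fit <- function(x, ...) {
  if (isTRUE(x$no_binding)) {
    cat("Competition fit: no detectable binding (span below 3x noise)\n")
  } else if (!isTRUE(x$converged)) {
    cat("Competition fit: NOT converged\n")
  } else {
    cat(sprintf("One-site competition fit: pIC50 = %.3f (IC50 %.4g M)\n",
                x$pIC50, x$IC50))
  }
  invisible(x)
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' `Ki = IC50 / (1 + L/KD)` for a competition experiment run with the
#' radioligand at concentration `L` and affinity `KD`. When the radioligand
#' is present at its KD, `Ki = IC50 / 2`, i.e. `pKi = pIC50 + log10(2)`.
#'
#' @param IC50 half-maximal inhibitory concentration (molar).
#' @param L radioligand concentration (molar).
#' @param KD radioligand equilibrium dissociation constant (molar).
#' @return list with `Ki` (molar) and `pKi` (-log10 molar).
#' @export
cheng_prusoff <- function(IC50, L, KD) {
  if (any(c(IC50, L, KD) <= 0) || any(!is.finite(c(IC50, L, KD))))
    pf_input_error("IC50, L and KD must all be positive and finite")
  Ki <- IC50 / (1 + L / KD)
  list(Ki = Ki, pKi = -log10(Ki))
}

#' Mono-exponential radioligand dissociation kinetics
#'
#' Fits `B(t) = B0 * exp(-koff * t)` (optionally plus a plateau) to a
#' reverse-time-course dissociation experiment, e.g. dissociation initiated
#' by excess unlabeled antagonist with or without a test ligand that may
#' alter the off-rate allosterically.
#'
#' @param time minutes (>= 5 points; t = 0 included or extrapolable).
#' @param bound bound radioligand.
#' @param condition label for the experimental condition.
#' @param plateau logical; add a non-dissociating plateau term.
#' @return An object of class `"dissociation_fit"`: `B0`, `koff` (per
#'   minute), `half_life` (= ln 2 / koff, minutes), SEs, `condition`,
#'   `converged`.
#' @export
fit_dissociation <- function(time, bound, condition = "control",
                             plateau = FALSE) {
  time <- as.numeric(time); bound <- as.numeric(bound)
  if (length(time) < 5L || length(unique(time)) < 5L)
    pf_input_error("need >= 5 time points")
  if (length(bound) != length(time))
    pf_input_error("bound must match time in length")
  tr <- lm(bound ~ time)
  sl <- suppressWarnings(summary(tr))$coefficients["time", ]
  if (sl["Estimate"] > 0 && sl["Pr(>|t|)"] < 0.01)
    pf_input_error("bound increases with time beyond noise: not a dissociation time course")
  k0 <- max(-sl[["Estimate"]] / max(mean(bound), 1e-12), 1e-4)
  st <- if (plateau) c(B0 = max(bound), koff = k0, plat = min(bound))
        else c(B0 = max(bound), koff = k0)
  decay_fn <- function(p) {
    plat_v <- if (plateau) p[["plat"]] else 0
    plat_v + (p[["B0"]] - plat_v) * exp(-p[["koff"]] * time) - bound
  }
  lower <- if (plateau) c(B0 = 0, koff = 1e-8, plat = 0) else c(B0 = 0, koff = 1e-8)
  fit <- pf_fit(st, decay_fn, lower = lower)
  if (!fit$converged)
    return(structure(list(converged = FALSE, koff = NA_real_,
                          condition = condition), class = "dissociation_fit"))
  cf <- fit$par; se <- fit$se
  res <- decay_fn(cf)
  structure(list(B0 = unname(cf["B0"]), koff = unname(cf["koff"]),
                 half_life = log(2) / unname(cf["koff"]),
                 se_B0 = unname(se["B0"]), se_koff = unname(se["koff"]),
                 plateau = if (plateau) unname(cf["plat"]) else 0,
                 condition = condition, converged = TRUE,
                 time = time, bound = bound,
                 fitted = bound + res, residuals = res),
            class = "dissociation_fit")
}

#' @export
print.dissociation_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) { cat("Dissociation fit: NOT converged\n"); return(invisible(x)) }
  cat(sprintf("Dissociation kinetics [%s]: koff = %.4g /min, t1/2 = %.3g min\n",
              x$condition, x$koff, x$half_life))
  invisible(x)
}

#' Compare dissociation rates between two conditions
#'
#' Ratio test on the fitted off-rates with a seeded residual-bootstrap
#' confidence interval; the kinetics are flagged as altered when the CI of
#' `koff(test)/koff(control)` excludes 1 (the signature of an allosteric
#' effect on the dissociation rate).
#'
#' @param control_fit,test_fit [fit_dissociation()] results.
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @param level CI coverage (default 0.95).
#' @return list with `ratio`, `ci` (length 2), `kinetics_altered`.
#' @export
compare_dissociation <- function(control_fit, test_fit, n_boot = 500L,
                                 seed = 1L, level = 0.95) {
  if (!isTRUE(control_fit$converged) || !isTRUE(test_fit$converged))
    pf_input_error("both dissociation fits must have converged")
  boot_koff <- function(f, offset) {
    vapply(seq_len(n_boot), function(b) {
      set.seed((seed * 10000L + offset + b) %% .Machine$integer.max)
      yb <- f$fitted + sample(f$residuals, replace = TRUE)
      fb <- pf_fit(c(B0 = f$B0, koff = f$koff), function(p)
        p[["B0"]] * exp(-p[["koff"]] * f$time) - yb,
        lower = c(B0 = 0, koff = 1e-8), maxiter = 200)
      if (fb$converged) fb$par[["koff"]] else NA_real_
    }, numeric(1))
  }
  kc <- boot_koff(control_fit, 0L)
  kt <- boot_koff(test_fit, n_boot)
  ratio <- test_fit$koff / control_fit$koff
  ci <- quantile(kt / kc, c((1 - level) / 2, 1 - (1 - level) / 2),
                 na.rm = TRUE, names = FALSE)
  list(ratio = ratio, ci = ci,
       kinetics_altered = ci[1] > 1 || ci[2] < 1)
}

#' Convert scintillation counts to receptor density
#'
#' `fmol/mg = dpm / (specific_activity * 2.22) / protein_mg`, using
#' 1 Ci = 2.22e12 dpm so that `specific_activity * 2.22` is in dpm per
#' fmol when the specific activity is given in Ci/mmol.
#'
#' @param dpm disintegrations per minute (>= 0).
#' @param specific_activity radioligand specific activity, Ci/mmol.
#' @param protein_mg protein per well, mg (> 0).
#' @return receptor density, fmol per mg protein.
#' @export
dpm_to_fmol_per_mg <- function(dpm, specific_activity, protein_mg) {
  if (any(dpm < 0)) pf_input_error("dpm must be non-negative")
  if (specific_activity <= 0) pf_input_error("specific activity must be positive")
  if (protein_mg <= 0) pf_input_error("protein amount must be positive")
  dpm / (specific_activity * 2.22) / protein_mg
}
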