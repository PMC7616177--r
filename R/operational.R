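# Black-Leff operational model of agonism:
#   E(A) = Basal + (Em - Basal) * (tau*A)^n / ((A + KA)^n + (tau*A)^n)
# The quantity interpreted for bias is the transduction coefficient
# log(tau/KA) = log_R, fitted directly (with log_KA) per ligand while
# Em, Basal and the transducer slope n are shared across ligands.

op_model <- function(A, Em, Basal, n, log_R, log_KA) {
  KA <- 10^log_KA
  tau <- 10^(log_R + log_KA)
  num <- (tau * A)^n
  Basal + (Em - Basal) * num / ((A + KA)^n + num)
}

#' Global operational-model fit across ligands sharing system parameters
#'
#' Fits the Black-Leff operational model to all ligands' curves in one
#' pathway simultaneously. The system parameters Em (maximal system
#' response), Basal and transducer slope n are shared; each ligand gets a
#' free transduction coefficient `log_R = log10(tau/KA)` and `log_KA`
#' (log10 molar functional dissociation constant), with
#' `log_tau = log_R + log_KA` derived. For full agonists whose plateau
#' reaches within 2% of Em, KA is intrinsically unidentifiable and the
#' entry is flagged; only `log_R` should be interpreted.
#'
#' @param curves list of [crc()] objects for a single pathway, at least two
#'   ligands including the reference.
#' @param reference_ligand ligand id of the reference agonist (e.g. `"ACh"`).
#' @param fix_basal optional numeric: fix Basal (e.g. 0 for
#'   reference-normalized data) instead of fitting it.
#' @param n_shared logical; fit one transducer slope n for the pathway
#'   (default) rather than fixing it at 1.
#' @return An object of class `"operational_fit"`: `$ligands` data.frame
#'   (`ligand`, `log_R`, `se_log_R`, `log_KA`, `se_log_KA`, `log_tau`,
#'   `tau`, `plateau`, `ka_unidentifiable`), `$system` (Em, Basal, n with
#'   SEs), `$converged`, `$pathway`, `$reference`.
#' @export
fit_operational_global <- function(curves, reference_ligand,
                                   fix_basal = NULL, n_shared = TRUE) {
  curves <- lapply(curves, as_crc)
  ligs <- vapply(curves, `[[`, character(1), "ligand_id")
  pws <- unique(vapply(curves, `[[`, character(1), "pathway_id"))
  if (length(pws) > 1L)
    pf_input_error("all curves must come from a single pathway")
  if (length(unique(ligs)) < 2L)
    pf_input_error("need >= 2 ligands: system parameters (Em, n) are unidentifiable from one ligand")
  if (!reference_ligand %in% ligs)
    pf_input_error(sprintf("reference ligand '%s' not among the curves", reference_ligand))
  lapply(curves, check_fittable)

  # collapse to one curve per ligand (pool replicates/experiments)
  ulig <- unique(ligs)
  by_lig <- lapply(ulig, function(l) {
    idx <- which(ligs == l)
    list(A = unlist(lapply(curves[idx], `[[`, "conc")),
         y = unlist(lapply(curves[idx], `[[`, "response")))
  })
  names(by_lig) <- ulig
  allA <- unlist(lapply(by_lig, `[[`, "A"))
  ally <- unlist(lapply(by_lig, `[[`, "y"))

  # starting values via per-ligand 4PL fits
  ymax <- max(ally); ymin <- min(ally)
  Em0 <- ymax * 1.02 + 1e-9
  Basal0 <- fix_basal %||% ymin
  starts <- lapply(ulig, function(l) {
    f <- tryCatch(fit_4pl(crc(by_lig[[l]]$A, by_lig[[l]]$y, ligand = l, pathway = pws)),
                  error = function(e) NULL)
    if (!is.null(f) && isTRUE(f$converged)) {
      plat <- f$coefficients[["top"]]
      tau0 <- max((plat - Basal0) / max(Em0 - plat, 0.02 * (Em0 - Basal0)), 1e-3)
      ka0 <- f$ec50 * (1 + tau0)
    } else {
      tau0 <- 1; ka0 <- exp(mean(log(by_lig[[l]]$A)))
    }
    c(log_R = log10(tau0 / ka0), log_KA = log10(ka0))
  })
  names(starts) <- ulig

  lKA_lo <- log10(min(allA)) - 3; lKA_hi <- log10(max(allA)) + 3
  par <- c(Em = Em0,
           if (is.null(fix_basal)) c(Basal = Basal0),
           if (n_shared) c(n = 1),
           unlist(lapply(ulig, function(l)
             setNames(starts[[l]], paste0(c("logR.", "logKA."), l)))))
  lower <- setNames(rep(-Inf, length(par)), names(par))
  upper <- setNames(rep(Inf, length(par)), names(par))
  # Em is the system maximal response: anchored near the observed maximum
  # (a full-agonist reference is assumed present); an unbounded Em is not
  # identifiable from agonist curves and lets the model degenerate to 4PL.
  span <- ymax - ymin
  lower["Em"] <- ymax - 0.25 * span
  upper["Em"] <- ymax + 0.5 * span
  if (n_shared) { lower["n"] <- 0.1; upper["n"] <- 10 }
  for (l in ulig) {
    lower[paste0("logKA.", l)] <- lKA_lo
    upper[paste0("logKA.", l)] <- lKA_hi
  }

  resid_fn <- function(p) {
    Em <- p[["Em"]]
    Basal <- if (is.null(fix_basal)) p[["Basal"]] else fix_basal
    n <- if (n_shared) p[["n"]] else 1
    unlist(lapply(ulig, function(l) {
      d <- by_lig[[l]]
      op_model(d$A, Em, Basal, n, p[[paste0("logR.", l)]],
               p[[paste0("logKA.", l)]]) - d$y
    }))
  }

  fit <- pf_fit(par, resid_fn, lower, upper)
  if (!fit$converged) {
    return(structure(list(converged = FALSE, message = fit$message,
                          pathway = pws, reference = reference_ligand),
                     class = "operational_fit"))
  }
  p <- fit$par
  se <- fit$se
  Em <- p[["Em"]]
  Basal <- if (is.null(fix_basal)) p[["Basal"]] else fix_basal
  n <- if (n_shared) p[["n"]] else 1

  lig_df <- do.call(rbind, lapply(ulig, function(l) {
    lR <- p[[paste0("logR.", l)]]; lK <- p[[paste0("logKA.", l)]]
    tau <- 10^(lR + lK)
    plat <- Basal + (Em - Basal) * tau^n / (1 + tau^n)
    data.frame(ligand = l, log_R = lR,
               se_log_R = unname(se[paste0("logR.", l)]),
               log_KA = lK, se_log_KA = unname(se[paste0("logKA.", l)]),
               log_tau = lR + lK, tau = tau, plateau = plat,
               ka_unidentifiable = plat >= Basal + 0.98 * (Em - Basal),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    ligands = lig_df,
    system = list(Em = Em, se_Em = unname(se["Em"]),
                  Basal = Basal,
                  se_Basal = if (is.null(fix_basal)) unname(se["Basal"]) else 0,
                  n = n, se_n = if (n_shared) unname(se["n"]) else 0),
    converged = TRUE, message = "converged", deviance = fit$deviance,
    pathway = pws, reference = reference_ligand),
    class = "operational_fit")
}

#' @export
print.operational_fit <- function(x, ...) {
  cat(sprintf("Operational-model global fit: pathway %s (reference %s)\n",
              x$pathway, x$reference))
  if (!isTRUE(x$converged)) {
    cat("  NOT converged:", x$message, "\n"); return(invisible(x))
  }
  cat(sprintf("  Em = %.3f, Basal = %.3f, n = %.3f\n",
              x$system$Em, x$system$Basal, x$system$n))
  print(x$ligands[, c("ligand", "log_R", "se_log_R", "log_KA",
                      "ka_unidentifiable")], row.names = FALSE)
  invisible(x)
}

# extract the one-row ligand entry from an operational fit
ligand_entry <- function(fit, ligand) {
  row <- fit$ligands[fit$ligands$ligand == ligand, , drop = FALSE]
  if (nrow(row) != 1L)
    pf_input_error(sprintf("ligand '%s' not found in fit", ligand))
  row$pathway <- fit$pathway
  row
}

#' Delta log(tau/KA) of a test ligand versus the reference, one pathway
#'
#' `delta = log_R(test) - log_R(reference)`; SEM combined in quadrature.
#' Positive values mean the test ligand activates the pathway more
#' efficiently than the reference.
#'
#' @param test,reference one-row ligand entries (rows of
#'   `operational_fit$ligands`, carrying a `pathway` column) from the same
#'   pathway fit.
#' @return list with `pathway`, `ligand`, `delta`, `sem`.
#' @export
delta_log_r <- function(test, reference) {
  if (!identical(as.character(test$pathway), as.character(reference$pathway)))
    pf_input_error("test and reference entries must come from the same pathway fit")
  list(pathway = as.character(test$pathway),
       ligand = as.character(test$ligand),
       delta = test$log_R - reference$log_R,
       sem = sqrt(test$se_log_R^2 + reference$se_log_R^2))
}

#' Delta-delta log(tau/KA) across pathway pairs
#'
#' For every ordered pathway pair (i, j), `dd = delta_i - delta_j`, the log
#' bias factor; SEM by quadrature; `bias_factor = 10^dd`. The table is
#' exactly antisymmetric in (i, j). Pathways with a missing delta are
#' omitted with a message.
#'
#' @param deltas data.frame with columns `pathway`, `delta`, `sem` (one row
#'   per pathway, e.g. assembled from [delta_log_r()]).
#' @return data.frame with `pathway_i`, `pathway_j`, `dd_log_r`, `sem`,
#'   `bias_factor`.
#' @export
delta_delta_log_r <- function(deltas) {
  deltas <- as.data.frame(deltas)
  keep <- is.finite(deltas$delta)
  if (any(!keep))
    message("omitting pathways with missing delta: ",
            paste(deltas$pathway[!keep], collapse = ", "))
  deltas <- deltas[keep, , drop = FALSE]
  if (nrow(deltas) < 2L)
    pf_input_error("need deltas for >= 2 pathways")
  pairs <- expand.grid(i = seq_len(nrow(deltas)), j = seq_len(nrow(deltas)))
  pairs <- pairs[pairs$i != pairs$j, ]
  dd <- deltas$delta[pairs$i] - deltas$delta[pairs$j]
  sem <- sqrt(deltas$sem[pairs$i]^2 + deltas$sem[pairs$j]^2)
  data.frame(pathway_i = as.character(deltas$pathway[pairs$i]),
             pathway_j = as.character(deltas$pathway[pairs$j]),
             dd_log_r = dd, sem = sem, bias_factor = 10^dd,
             stringsAsFactors = FALSE)
}

#' Flag biased pathway pairs
#'
#' An entry is unbiased iff `|dd_log_r| <= threshold` (default 1 log unit,
#' i.e. a ten-fold bias factor window); the ligand is called unbiased
#' overall iff every pair is.
#'
#' @param table data.frame from [delta_delta_log_r()].
#' @param threshold log-unit window for the unbiased call.
#' @return the table with an added logical `unbiased` column plus attribute
#'   `overall_unbiased`.
#' @export
assess_bias <- function(table, threshold = 1.0) {
  table$unbiased <- abs(table$dd_log_r) <= threshold
  attr(table, "overall_unbiased") <- all(table$unbiased)
  table
}

#' End-to-end bias analysis from tidy concentration-response data
#'
#' Fits the operational model per pathway (shared system parameters,
#' per-ligand transduction coefficients), computes delta log(tau/KA) for
#' each test ligand versus the reference, then delta-delta across all
#' ordered pathway pairs, and flags bias.
#'
#' @param data data.frame with columns `ligand`, `pathway`, `conc_M`,
#'   `response` (and optionally `replicate`).
#' @param reference reference ligand id present in every pathway.
#' @param threshold unbiased window in log units (default 1.0).
#' @param fix_basal optional fixed Basal passed to the pathway fits.
#' @return list of class `"bias_table"`: `$delta` (ligand x pathway),
#'   `$delta_delta` per test ligand (with `unbiased` flags), `$fits` (the
#'   per-pathway operational fits).
#' @export
compute_bias <- function(data, reference, threshold = 1.0, fix_basal = NULL) {
  pws <- unique(as.character(data$pathway))
  fits <- lapply(pws, function(pw) {
    d <- data[data$pathway == pw, ]
    curves <- lapply(split(d, d$ligand), as_crc)
    fit_operational_global(curves, reference_ligand = reference,
                           fix_basal = fix_basal)
  })
  names(fits) <- pws
  tests <- setdiff(unique(as.character(data$ligand)), reference)
  delta <- do.call(rbind, lapply(pws, function(pw) {
    f <- fits[[pw]]
    if (!isTRUE(f$converged))
      return(data.frame(pathway = pw, ligand = tests, delta = NA_real_,
                        sem = NA_real_))
    ref <- ligand_entry(f, reference)
    do.call(rbind, lapply(tests, function(l) {
      d <- delta_log_r(ligand_entry(f, l), ref)
      data.frame(pathway = pw, ligand = l, delta = d$delta, sem = d$sem)
    }))
  }))
  dd <- lapply(tests, function(l) {
    dl <- delta[delta$ligand == l, c("pathway", "delta", "sem")]
    assess_bias(delta_delta_log_r(dl), threshold = threshold)
  })
  names(dd) <- tests
  structure(list(delta = delta, delta_delta = dd, fits = fits,
                 reference = reference, threshold = threshold),
            class = "bias_table")
}

#' @export
print.bias_table <- function(x, ...) {
  cat(sprintf("Ligand-bias analysis (reference %s, threshold %.2f log units)\n",
              x$reference, x$threshold))
  cat("\nDelta log(tau/KA) vs reference:\n")
  print(x$delta, row.names = FALSE)
  for (l in names(x$delta_delta)) {
    dd <- x$delta_delta[[l]]
    up <- dd[match(dd$pathway_i, unique(dd$pathway_i)) <
               match(dd$pathway_j, unique(dd$pathway_i)), ]
    cat(sprintf("\nDeltaDelta log(tau/KA), %s (upper triangle): overall %s\n",
                l, if (attr(dd, "overall_unbiased")) "unbiased" else "BIASED"))
    print(up, row.names = FALSE)
  }
  invisible(x)
}
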