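# Intrinsic efficacy by irreversible receptor inactivation (Furchgott
# analysis). Alkylating a fraction of the receptor pool leaves KA unchanged
# and scales the operational efficacy tau by the surviving fraction q, so a
# joint operational fit of control and depleted curves with shared KA (and
# system Em, Basal, n) identifies q = tau_post / tau_pre. Partial agonists
# (small tau) lose maximal response faster than full agonists under the
# same depletion, which is the diagnostic signature of low intrinsic
# efficacy.

#' Paired operational fit of control vs receptor-depleted curves
#'
#' Jointly fits the operational model to one ligand's curves before and
#' after irreversible receptor inactivation, sharing KA, Em, Basal and n
#' across conditions with a free tau per condition. Depletion is modeled
#' purely as tau-scaling (the Furchgott assumption).
#'
#' @param control,depleted [crc()] objects for the same ligand/pathway.
#' @param system optional named list fixing system parameters, any of `Em`,
#'   `Basal`, `n` (e.g. Em anchored by a pre-depletion full-agonist
#'   reference). Parameters not supplied are co-fitted; a co-fitted Em is
#'   flagged in the result.
#' @return An object of class `"depletion_fit"`: `tau_pre`, `tau_post`,
#'   `q` (= tau_post/tau_pre, surviving receptor fraction), `se_log_q`,
#'   `log_KA`, `se_log_KA`, system parameters, `partial_agonist` flag
#'   (pre-depletion plateau below 95% of Em), `q_flagged` (q > 1.1),
#'   `em_cofitted`, `converged`.
#' @export
fit_depletion_pair <- function(control, depleted, system = NULL) {
  control <- as_crc(control); depleted <- as_crc(depleted)
  if (control$ligand_id != depleted$ligand_id ||
      control$pathway_id != depleted$pathway_id)
    pf_input_error("control and depleted curves must share ligand and pathway")
  check_fittable(control)
  ally <- c(control$response, depleted$response)
  allA <- c(control$conc, depleted$conc)
  if (diff(range(depleted$response)) <=
      0.02 * max(diff(range(control$response)), 1e-12)) {
    # depleted response entirely at basal: q only bounded from above
    return(structure(list(converged = FALSE, q = NA_real_,
                          q_upper_bound = TRUE,
                          message = "depleted responses at basal; q reported as upper bound only"),
                     class = "depletion_fit"))
  }

  fixEm <- system$Em; fixBasal <- system$Basal; fixN <- system$n
  par <- c(if (is.null(fixEm)) c(Em = max(ally) * 1.05 + 1e-9),
           if (is.null(fixBasal)) c(Basal = min(ally)),
           if (is.null(fixN)) c(n = 1),
           lKA = log10(exp(mean(log(allA)))), ltau_pre = 0.5, ltau_post = 0)
  lower <- setNames(rep(-Inf, length(par)), names(par))
  upper <- setNames(rep(Inf, length(par)), names(par))
  if (is.null(fixEm)) {
    lower["Em"] <- max(ally)
    upper["Em"] <- max(ally) + diff(range(ally))
  }
  if (is.null(fixN)) { lower["n"] <- 0.1; upper["n"] <- 10 }
  lower["lKA"] <- log10(min(allA)) - 4; upper["lKA"] <- log10(max(allA)) + 4
  lower[c("ltau_pre", "ltau_post")] <- -8
  upper[c("ltau_pre", "ltau_post")] <- 8

  resid_fn <- function(p) {
    Em <- fixEm %||% p[["Em"]]
    Basal <- fixBasal %||% p[["Basal"]]
    n <- fixN %||% p[["n"]]
    f <- function(A, ltau) {
      tau <- 10^ltau; KA <- 10^p[["lKA"]]
      num <- (tau * A)^n
      Basal + (Em - Basal) * num / ((A + KA)^n + num)
    }
    c(f(control$conc, p[["ltau_pre"]]) - control$response,
      f(depleted$conc, p[["ltau_post"]]) - depleted$response)
  }
  fit <- pf_fit(par, resid_fn, lower, upper)
  if (!fit$converged)
    return(structure(list(converged = FALSE, message = fit$message),
                     class = "depletion_fit"))
  p <- fit$par
  V <- fit$vcov
  se_of <- function(nm) if (!is.null(V) && nm %in% rownames(V))
    sqrt(max(V[nm, nm], 0)) else NA_real_
  lq <- p[["ltau_post"]] - p[["ltau_pre"]]
  se_lq <- if (!is.null(V) && all(c("ltau_pre", "ltau_post") %in% rownames(V))) {
    sqrt(max(V["ltau_pre", "ltau_pre"] + V["ltau_post", "ltau_post"] -
               2 * V["ltau_pre", "ltau_post"], 0))
  } else NA_real_
  Em <- fixEm %||% p[["Em"]]
  Basal <- fixBasal %||% p[["Basal"]]
  n <- fixN %||% p[["n"]]
  tau_pre <- 10^p[["ltau_pre"]]
  plat_pre <- Basal + (Em - Basal) * tau_pre^n / (1 + tau_pre^n)
  structure(list(
    ligand = control$ligand_id, pathway = control$pathway_id,
    tau_pre = tau_pre, tau_post = 10^p[["ltau_post"]],
    se_log_tau_pre = se_of("ltau_pre"), se_log_tau_post = se_of("ltau_post"),
    q = 10^lq, se_log_q = se_lq, q_flagged = 10^lq > 1.1,
    log_KA = p[["lKA"]], se_log_KA = se_of("lKA"),
    Em = Em, Basal = Basal, n = n,
    em_cofitted = is.null(fixEm),
    partial_agonist = plat_pre < Basal + 0.95 * (Em - Basal),
    converged = TRUE, message = "converged"),
    class = "depletion_fit")
}

#' @export
print.depletion_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("Depletion fit:", x$message %||% "not converged", "\n")
    return(invisible(x))
  }
  cat(sprintf("Receptor-depletion fit: %s / %s\n", x$ligand, x$pathway))
  cat(sprintf("  tau_pre = %.4g, tau_post = %.4g, q = %.4g (log KA = %.3f)\n",
              x$tau_pre, x$tau_post, x$q, x$log_KA))
  if (isTRUE(x$partial_agonist)) cat("  ligand is a partial agonist pre-depletion\n")
  if (isTRUE(x$q_flagged)) cat("  warning: q > 1.1\n")
  invisible(x)
}

# covariance of an nls.lm fit from its summary SEs and deviance
vcov_nlslm <- function(fit) {
  s <- summary(fit)
  se <- s$coefficients[, "Std. Error"]
  # nls.lm exposes the Gauss-Newton hessian (J'J); covariance = (J'J)^-1 s^2
  h <- fit$hessian
  dof <- max(1, length(fit$fvec) - length(fit$par))
  sigma2 <- fit$deviance / dof
  V <- tryCatch(solve(h) * sigma2, error = function(e) NULL)
  if (is.null(V)) {
    V <- diag(se^2, nrow = length(se))
    rownames(V) <- colnames(V) <- names(fit$par)
  } else {
    rownames(V) <- colnames(V) <- names(fit$par)
  }
  V
}

#' Joint common-q depletion fit across ligands in one treatment batch
#'
#' Irreversible alkylation removes a fraction of the receptor pool, not of
#' any one ligand's efficacy, so ligands treated in the same batch share the
#' surviving fraction q. This joint fit shares Em, Basal, n and q across
#' ligands, with free per-ligand tau and KA.
#'
#' @param data data.frame with columns `ligand`, `conc_M`, `response`, and
#'   `depletion` (`"control"`/`"depleted"`).
#' @param system optional fixed system parameters as in
#'   [fit_depletion_pair()].
#' @return list with `q`, `se_log_q`, per-ligand data.frame (`ligand`,
#'   `tau_pre`, `tau_post`, `log_KA`), system parameters, `converged`.
#' @export
fit_depletion_batch <- function(data, system = NULL) {
  if (!all(c("ligand", "conc_M", "response", "depletion") %in% names(data)))
    pf_input_error("data must have ligand, conc_M, response, depletion columns")
  if (!all(data$depletion %in% c("control", "depleted")))
    pf_input_error("depletion column must be 'control' or 'depleted'")
  ulig <- unique(as.character(data$ligand))
  fixEm <- system$Em; fixBasal <- system$Basal; fixN <- system$n
  ally <- data$response; allA <- data$conc_M
  par <- c(if (is.null(fixEm)) c(Em = max(ally) * 1.05 + 1e-9),
           if (is.null(fixBasal)) c(Basal = min(ally)),
           if (is.null(fixN)) c(n = 1),
           lq = -0.3,
           unlist(lapply(ulig, function(l)
             setNames(c(0.5, log10(exp(mean(log(allA))))),
                      paste0(c("ltau.", "lKA."), l)))))
  lower <- setNames(rep(-Inf, length(par)), names(par))
  upper <- setNames(rep(Inf, length(par)), names(par))
  if (is.null(fixEm)) {
    lower["Em"] <- max(ally)
    upper["Em"] <- max(ally) + diff(range(ally))
  }
  if (is.null(fixN)) { lower["n"] <- 0.1; upper["n"] <- 10 }
  lower["lq"] <- -8; upper["lq"] <- 1
  for (l in ulig) {
    lower[paste0("lKA.", l)] <- log10(min(allA)) - 4
    upper[paste0("lKA.", l)] <- log10(max(allA)) + 4
    lower[paste0("ltau.", l)] <- -8; upper[paste0("ltau.", l)] <- 8
  }
  resid_fn <- function(p) {
    Em <- fixEm %||% p[["Em"]]
    Basal <- fixBasal %||% p[["Basal"]]
    n <- fixN %||% p[["n"]]
    unlist(lapply(ulig, function(l) {
      d <- data[data$ligand == l, ]
      ltau <- p[[paste0("ltau.", l)]] +
        ifelse(d$depletion == "depleted", p[["lq"]], 0)
      KA <- 10^p[[paste0("lKA.", l)]]
      tau <- 10^ltau
      num <- (tau * d$conc_M)^n
      Basal + (Em - Basal) * num / ((d$conc_M + KA)^n + num) - d$response
    }))
  }
  fit <- pf_fit(par, resid_fn, lower, upper)
  if (!fit$converged)
    return(list(converged = FALSE, message = fit$message))
  p <- fit$par
  V <- fit$vcov
  Em <- fixEm %||% p[["Em"]]; Basal <- fixBasal %||% p[["Basal"]]
  n <- fixN %||% p[["n"]]
  lig <- do.call(rbind, lapply(ulig, function(l)
    data.frame(ligand = l, tau_pre = 10^p[[paste0("ltau.", l)]],
               tau_post = 10^(p[[paste0("ltau.", l)]] + p[["lq"]]),
               log_KA = p[[paste0("lKA.", l)]], stringsAsFactors = FALSE)))
  list(q = 10^p[["lq"]],
       se_log_q = if (!is.null(V)) sqrt(max(V["lq", "lq"], 0)) else NA_real_,
       ligands = lig, Em = Em, Basal = Basal, n = n,
       converged = TRUE)
}

#' Relative intrinsic efficacy of a test agonist versus a reference
#'
#' `tau_test / tau_ref` (pre-depletion) with a log-scale quadrature
#' standard error.
#'
#' @param test,reference either numeric tau values, [fit_depletion_pair()]
#'   results (their `tau_pre` is used), or lists with `tau` and optional
#'   `se_log_tau`.
#' @return list with `ratio` and `se` (delta-method SE of the ratio).
#' @export
relative_efficacy <- function(test, reference) {
  get_tau <- function(x) {
    if (is.numeric(x)) return(list(tau = x, se_log = 0))
    if (inherits(x, "depletion_fit"))
      return(list(tau = x$tau_pre, se_log = x$se_log_tau_pre %||% 0))
    list(tau = x$tau, se_log = x$se_log_tau %||% 0)
  }
  a <- get_tau(test); b <- get_tau(reference)
  if (!is.finite(b$tau) || b$tau <= 0)
    pf_input_error("reference tau must be positive")
  ratio <- a$tau / b$tau
  se_log <- sqrt((a$se_log %||% 0)^2 + (b$se_log %||% 0)^2)
  list(ratio = ratio, se = ratio * log(10) * se_log, se_log10 = se_log)
}
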