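# Seeded synthetic-assay generators. All randomness flows from one explicit
# integer seed through named per-replicate substreams, so the noiseless
# model values never depend on the seed and adding replicates never
# perturbs existing ones. Noise is additive Gaussian with sd expressed as a
# fraction of the curve's noiseless response span.

# derived substream seed, kept below 2^31 (exact in double arithmetic)
sub_seed <- function(seed, stream) {
  as.integer((abs(as.numeric(seed)) * 1009 + as.numeric(stream) * 7919) %%
               2147483647)
}

with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  expr
}

span_of <- function(mu) {
  s <- diff(range(mu))
  if (s <= 0) max(abs(mu), 1) else s
}

pl4_mu <- function(A, truth) {
  truth$bottom + (truth$top - truth$bottom) /
    (1 + 10^(truth$hill * (-truth$pEC50 - log10(A))))
}

op_mu <- function(A, truth) {
  op_model(A, truth$Em, truth$Basal %||% 0, truth$n %||% 1,
           truth$log_R, truth$log_KA)
}

#' Default half-log concentration grid
#'
#' @param from,to range endpoints in molar.
#' @param n number of log-equispaced points (default covers the range in
#'   half-log steps).
#' @return molar concentration vector.
#' @export
conc_grid <- function(from = 1e-10, to = 1e-4, n = NULL) {
  lo <- log10(from); hi <- log10(to)
  n <- n %||% (round((hi - lo) * 2) + 1)
  10^seq(lo, hi, length.out = n)
}

#' Simulate an agonist concentration-response curve
#'
#' Generates replicate responses from a 4PL or operational-model truth with
#' additive Gaussian noise. `noise_sd = 0` returns the model values
#' exactly; the same `(design, seed)` pair is byte-identical on re-run.
#'
#' @param truth named list of true parameters. For `model = "logistic4"`:
#'   `bottom`, `top`, `pEC50`, `hill`. For `model = "operational"`: `Em`,
#'   `Basal` (default 0), `n` (default 1), and either (`log_R`, `log_KA`)
#'   or (`tau`, `KA` in molar).
#' @param model curve model generating the truth.
#' @param conc molar concentration grid (default 8 points, 0.1 nM-100 uM).
#' @param replicates number of replicate response streams.
#' @param noise_sd Gaussian noise sd as a fraction of the noiseless
#'   response span over the grid.
#' @param seed integer seed.
#' @param ligand,pathway identifiers attached to the curve.
#' @return a [crc()] object with `replicates * length(conc)` points.
#' @export
gen_dose_response <- function(truth, model = c("logistic4", "operational"),
                              conc = conc_grid(1e-10, 1e-4, 8),
                              replicates = 3L, noise_sd = 0.05, seed = 1L,
                              ligand = "ligand", pathway = "pathway") {
  model <- match.arg(model)
  if (noise_sd < 0) pf_input_error("noise_sd must be >= 0")
  if (replicates < 1L) pf_input_error("replicates must be >= 1")
  if (model == "operational" && is.null(truth$log_R)) {
    if (is.null(truth$tau) || is.null(truth$KA))
      pf_input_error("operational truth needs (log_R, log_KA) or (tau, KA)")
    truth$log_R <- log10(truth$tau / truth$KA)
    truth$log_KA <- log10(truth$KA)
  }
  mu <- switch(model, logistic4 = pl4_mu(conc, truth),
               operational = op_mu(conc, truth))
  sdv <- noise_sd * span_of(mu)
  resp <- with_preserved_rng({
    unlist(lapply(seq_len(replicates), function(r) {
      set.seed(sub_seed(seed, r))
      mu + if (sdv > 0) rnorm(length(mu), 0, sdv) else 0
    }))
  })
  crc(rep(conc, replicates), resp, ligand = ligand, pathway = pathway,
      replicate = rep(seq_len(replicates), each = length(conc)))
}

#' Simulate a Gaddum-shifted antagonism curve family
#'
#' Generates agonist curves at each antagonist concentration. In
#' `"pure_competitive"` mode curves share top/bottom/hill and the EC50 is
#' shifted by the Gaddum factor `1 + B/KB`. In `"partial_agonist"` mode
#' the interacting ligand additionally exerts its own operational effect
#' (two-ligand competitive operational model, n = 1), raising the baseline
#' at high antagonist concentrations.
#'
#' @param agonist_truth for pure mode, a 4PL truth (`bottom`, `top`,
#'   `pEC50`, `hill`); for partial mode, an operational truth (`Em`,
#'   `Basal`, `tau`, `KA` molar).
#' @param pKB true antagonist affinity, -log10 molar.
#' @param B antagonist concentrations (molar); must include 0 as control.
#' @param mode interaction mode.
#' @param tau_B antagonist's own operational efficacy (partial mode).
#' @param conc,replicates,noise_sd,seed as in [gen_dose_response()].
#' @return data.frame with columns `conc_M`, `response`, `replicate`,
#'   `antagonist_conc_M`.
#' @export
gen_antagonism_family <- function(agonist_truth, pKB, B,
                                  mode = c("pure_competitive", "partial_agonist"),
                                  tau_B = 0,
                                  conc = conc_grid(1e-9, 1e-3, 9),
                                  replicates = 2L, noise_sd = 0.05,
                                  seed = 1L) {
  mode <- match.arg(mode)
  if (!any(B == 0)) pf_input_error("B must include 0 (the control family)")
  KB <- 10^(-pKB)
  fam <- lapply(seq_along(B), function(i) {
    b <- B[i]
    mu <- if (mode == "pure_competitive") {
      tr <- agonist_truth
      tr$pEC50 <- agonist_truth$pEC50 - log10(1 + b / KB)
      pl4_mu(conc, tr)
    } else {
      Em <- agonist_truth$Em; Basal <- agonist_truth$Basal %||% 0
      tauA <- agonist_truth$tau; KA <- agonist_truth$KA
      rhoA <- (conc / KA) / (1 + conc / KA + b / KB)
      rhoB <- (b / KB) / (1 + conc / KA + b / KB)
      act <- tauA * rhoA + tau_B * rhoB
      Basal + (Em - Basal) * act / (1 + act)
    }
    sdv <- noise_sd * span_of(mu)
    resp <- with_preserved_rng({
      unlist(lapply(seq_len(replicates), function(r) {
        set.seed(sub_seed(seed, (i - 1L) * 100L + r))
        mu + if (sdv > 0) rnorm(length(mu), 0, sdv) else 0
      }))
    })
    data.frame(conc_M = rep(conc, replicates), response = resp,
               replicate = rep(seq_len(replicates), each = length(conc)),
               antagonist_conc_M = b)
  })
  do.call(rbind, fam)
}

#' Simulate a radioligand-binding dataset
#'
#' Forward-simulates the three supported binding designs.
#' `"saturation"` emits total and matched non-specific channels
#' (`total = Bmax*L/(KD+L) + ns*L`, `nsb = ns*L`); `"competition"` emits a
#' descending one-site curve whose IC50 follows the Cheng-Prusoff relation
#' `IC50 = Ki * (1 + L/KD)`; `"dissociation"` emits mono-exponential decay.
#'
#' @param kind assay kind.
#' @param truth named list. Saturation: `KD` (molar), `Bmax`, optional
#'   `ns_slope` (default makes NSB 10% of Bmax at the top concentration).
#'   Competition: `Ki` (molar), `L`, `KD` (molar), optional `top`
#'   (default 100), `bottom` (default 0). Dissociation: `koff` (/min),
#'   `B0`, optional `plateau`.
#' @param grid concentration (molar) or time (minutes) grid.
#' @param noise_sd Gaussian sd as a fraction of the signal span.
#' @param seed integer seed.
#' @param condition label for dissociation output.
#' @return data.frame in the matching analysis schema: saturation
#'   (`conc_M`, `total_dpm`, `nsb_dpm`), competition
#'   (`inhibitor_conc_M`, `bound`), dissociation (`time_min`, `bound`,
#'   `condition`).
#' @export
gen_binding_assay <- function(kind = c("saturation", "competition", "dissociation"),
                              truth, grid, noise_sd = 0.05, seed = 1L,
                              condition = "control") {
  kind <- match.arg(kind)
  if (kind == "saturation") {
    ns <- truth$ns_slope %||% (0.1 * truth$Bmax / max(grid))
    spec <- truth$Bmax * grid / (truth$KD + grid)
    nsb <- ns * grid
    sdv <- noise_sd * span_of(spec)
    out <- with_preserved_rng({
      set.seed(sub_seed(seed, 1L))
      e1 <- if (sdv > 0) rnorm(length(grid), 0, sdv) else 0
      set.seed(sub_seed(seed, 2L))
      e2 <- if (sdv > 0) rnorm(length(grid), 0, sdv) else 0
      data.frame(conc_M = grid, total_dpm = spec + nsb + e1,
                 nsb_dpm = nsb + e2)
    })
    return(out)
  }
  if (kind == "competition") {
    top <- truth$top %||% 100; bottom <- truth$bottom %||% 0
    IC50 <- truth$Ki * (1 + truth$L / truth$KD)
    mu <- bottom + (top - bottom) / (1 + grid / IC50)
    sdv <- noise_sd * span_of(mu)
    out <- with_preserved_rng({
      set.seed(sub_seed(seed, 1L))
      data.frame(inhibitor_conc_M = grid,
                 bound = mu + if (sdv > 0) rnorm(length(mu), 0, sdv) else 0)
    })
    return(out)
  }
  plat <- truth$plateau %||% 0
  mu <- plat + (truth$B0 - plat) * exp(-truth$koff * grid)
  sdv <- noise_sd * span_of(mu)
  with_preserved_rng({
    set.seed(sub_seed(seed, 1L))
    data.frame(time_min = grid,
               bound = mu + if (sdv > 0) rnorm(length(mu), 0, sdv) else 0,
               condition = condition)
  })
}

#' Simulate a paired receptor-depletion experiment
#'
#' Generates control and depleted operational-model curves for one or more
#' ligands; depletion scales every ligand's tau by the common surviving
#' fraction `q` while KA, Em, Basal, n are untouched.
#'
#' @param ligand_truths named list (by ligand) of lists with `tau` and `KA`
#'   (molar).
#' @param q surviving receptor fraction in (0, 1].
#' @param Em,Basal,n shared system parameters.
#' @param conc,replicates,noise_sd,seed as in [gen_dose_response()].
#' @return data.frame with columns `ligand`, `depletion`
#'   (`"control"`/`"depleted"`), `conc_M`, `response`, `replicate`.
#' @export
gen_depletion_experiment <- function(ligand_truths, q, Em = 100, Basal = 0,
                                     n = 1, conc = conc_grid(1e-10, 1e-4, 9),
                                     replicates = 2L, noise_sd = 0.05,
                                     seed = 1L) {
  if (q <= 0) pf_input_error("q must be positive")
  out <- lapply(seq_along(ligand_truths), function(i) {
    lt <- ligand_truths[[i]]
    nm <- names(ligand_truths)[i] %||% paste0("ligand", i)
    rows <- lapply(c("control", "depleted"), function(cond) {
      tau <- lt$tau * if (cond == "depleted") q else 1
      mu <- op_model(conc, Em, Basal, n, log10(tau / lt$KA), log10(lt$KA))
      sdv <- noise_sd * span_of(mu)
      resp <- with_preserved_rng({
        unlist(lapply(seq_len(replicates), function(r) {
          set.seed(sub_seed(seed, i * 101L + (cond == "depleted") * 50L + r))
          mu + if (sdv > 0) rnorm(length(mu), 0, sdv) else 0
        }))
      })
      data.frame(ligand = nm, depletion = cond,
                 conc_M = rep(conc, replicates), response = resp,
                 replicate = rep(seq_len(replicates), each = length(conc)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}
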