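# I/O and pipeline orchestration. All tabular I/O is plain CSV with a
# header row; concentrations are normalized to molar on read.

pf_schemas <- list(
  dose_response = c("ligand", "pathway", "conc_M", "response"),
  antagonism = c("conc_M", "response", "antagonist_conc_M"),
  saturation = c("conc_M", "total_dpm", "nsb_dpm"),
  competition = c("inhibitor_conc_M", "bound"),
  kinetics = c("time_min", "bound", "condition"),
  exposure = c("species", "dose_mgkg", "route", "cmax_ngml", "fu", "mw")
)

#' Read and validate an assay CSV
#'
#' Reads a CSV in one of the package's schemas, validates required columns
#' and row-level constraints (positive finite concentrations, finite
#' responses), and normalizes units: a `units` column of `"log10M"` marks
#' concentration columns supplied as log10 molar and is converted to molar.
#' Validation errors name the offending rows.
#'
#' @param path CSV file path.
#' @param schema one of `"dose_response"`, `"antagonism"`, `"saturation"`,
#'   `"competition"`, `"kinetics"`, `"exposure"`.
#' @return validated data.frame in molar/minutes units.
#' @export
read_dataset <- function(path, schema = names(pf_schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) pf_input_error(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- pf_schemas[[schema]]
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    pf_input_error(sprintf("%s: missing required column(s): %s",
                           path, paste(missing_cols, collapse = ", ")))
  conc_cols <- intersect(names(df),
                         c("conc_M", "antagonist_conc_M", "inhibitor_conc_M"))
  if ("units" %in% names(df)) {
    u <- unique(df$units[df$units != ""])
    if (length(u) > 1L)
      pf_input_error(sprintf("%s: mixed concentration units: %s",
                             path, paste(u, collapse = ", ")))
    if (length(u) == 1L && u == "log10M") {
      for (cc in conc_cols) df[[cc]] <- 10^df[[cc]]
      df$units <- "M"
    } else if (length(u) == 1L && !u %in% c("M", "raw", "percent_reference")) {
      pf_input_error(sprintf("%s: unknown units value '%s'", path, u))
    }
  }
  for (cc in setdiff(conc_cols, "antagonist_conc_M")) {
    bad <- which(!is.finite(df[[cc]]) | df[[cc]] <= 0)
    if (length(bad))
      pf_input_error(sprintf("%s: non-positive or non-finite %s in row(s) %s",
                             path, cc, paste(bad, collapse = ", ")))
  }
  if ("antagonist_conc_M" %in% names(df)) {
    bad <- which(!is.finite(df$antagonist_conc_M) | df$antagonist_conc_M < 0)
    if (length(bad))
      pf_input_error(sprintf("%s: negative or non-finite antagonist_conc_M in row(s) %s",
                             path, paste(bad, collapse = ", ")))
  }
  num_cols <- intersect(names(df), c("response", "total_dpm", "nsb_dpm",
                                     "bound", "time_min", "cmax_ngml", "fu", "mw"))
  for (cc in num_cols) {
    bad <- which(!is.finite(as.numeric(df[[cc]])))
    if (length(bad))
      pf_input_error(sprintf("%s: non-numeric %s in row(s) %s",
                             path, cc, paste(bad, collapse = ", ")))
  }
  df
}

#' Assemble an analysis configuration
#'
#' @param reference_ligand reference agonist id for normalization/bias.
#' @param pathways optional pathway whitelist.
#' @param bias_threshold unbiased window in log units.
#' @param seed seed recorded in every output and used for any bootstrap.
#' @param radioligand_KD,radioligand_conc molar binding constants for
#'   Cheng-Prusoff conversion.
#' @param specific_activity Ci/mmol, for dpm conversion.
#' @param protein_mg protein per well.
#' @param mol_weight,fu compound MW (g/mol) and plasma fraction unbound for
#'   the exposure table.
#' @param output_dir directory for report tables.
#' @return list of class `"analysis_config"`.
#' @export
analysis_config <- function(reference_ligand = "ACh", pathways = NULL,
                            bias_threshold = 1.0, seed = 1L,
                            radioligand_KD = NULL, radioligand_conc = NULL,
                            specific_activity = NULL, protein_mg = NULL,
                            mol_weight = 365.5, fu = NULL,
                            output_dir = tempfile("pharmfit_run_")) {
  structure(list(reference_ligand = reference_ligand, pathways = pathways,
                 bias_threshold = bias_threshold, seed = as.integer(seed),
                 radioligand_KD = radioligand_KD,
                 radioligand_conc = radioligand_conc,
                 specific_activity = specific_activity,
                 protein_mg = protein_mg, mol_weight = mol_weight, fu = fu,
                 output_dir = output_dir),
            class = "analysis_config")
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates whichever analyses the supplied data paths support:
#' per-ligand 4PL fit tables, the operational-model bias table, a Schild
#' table, binding tables, a depletion table and the PK-derived exposure
#' table, writing each as CSV into `config$output_dir` together with
#' `run_info.json` (seed, package version, full config echo) and a
#' plain-text summary. Re-running with the same config and data yields
#' byte-identical numeric outputs. Any stage failure is captured in an
#' error manifest (`errors.csv`) without discarding completed stages.
#'
#' @param config an [analysis_config()].
#' @param paths named list of CSV paths, any of `dose_response`,
#'   `antagonism`, `saturation`, `competition`, `kinetics`, `exposure`.
#' @return invisibly, a list of the computed tables; the `errors` element
#'   is non-empty if a stage failed.
#' @export
run_pipeline <- function(config, paths) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(); errs <- list(); summ <- character()

  if (!is.null(paths$dose_response)) {
    dr <- read_dataset(paths$dose_response, "dose_response")
    if (!is.null(config$pathways))
      dr <- dr[dr$pathway %in% config$pathways, ]
    if (!config$reference_ligand %in% dr$ligand)
      pf_input_error(sprintf("configured reference ligand '%s' absent from dose-response data",
                             config$reference_ligand))
    fit_tab <- do.call(rbind, lapply(
      split(dr, list(dr$ligand, dr$pathway), drop = TRUE), function(d) {
        f <- tryCatch(fit_4pl(as_crc(d)), error = function(e) e)
        if (inherits(f, "error")) {
          errs[[length(errs) + 1]] <<- data.frame(
            stage = "fit_4pl", unit = paste(d$ligand[1], d$pathway[1]),
            message = conditionMessage(f))
          return(NULL)
        }
        data.frame(ligand = d$ligand[1], pathway = d$pathway[1],
                   bottom = f$coefficients[["bottom"]],
                   top = f$coefficients[["top"]],
                   pEC50 = f$coefficients[["pEC50"]],
                   hill = f$coefficients[["hill"]],
                   se_pEC50 = f$se[["pEC50"]], ec50_M = f$ec50,
                   converged = f$converged,
                   top_extrapolated = f$top_extrapolated,
                   n_points = f$n_points, source = paths$dose_response)
      }))
    out$fits <- fit_tab
    write.csv(fit_tab, file.path(config$output_dir, "fits.csv"),
              row.names = FALSE)
    summ <- c(summ, sprintf("4PL fits: %d ligand x pathway groups", nrow(fit_tab)))

    if (length(unique(dr$ligand)) >= 2) {
      bias <- tryCatch(compute_bias(dr, reference = config$reference_ligand,
                                    threshold = config$bias_threshold),
                       error = function(e) e)
      if (inherits(bias, "error")) {
        errs[[length(errs) + 1]] <- data.frame(stage = "bias", unit = "all",
                                               message = conditionMessage(bias))
      } else {
        dd <- do.call(rbind, lapply(names(bias$delta_delta), function(l)
          cbind(ligand = l, bias$delta_delta[[l]])))
        out$bias <- dd
        write.csv(dd, file.path(config$output_dir, "bias_table.csv"),
                  row.names = FALSE)
        summ <- c(summ, sprintf("bias table: %d pathway pairs; overall unbiased: %s",
                                nrow(dd), all(dd$unbiased)))
      }
    }
  }

  if (!is.null(paths$antagonism)) {
    an <- read_dataset(paths$antagonism, "antagonism")
    sch <- tryCatch(withCallingHandlers(
      schild_analysis(an),
      warning = function(w) {
        summ <<- c(summ, paste("schild warning:", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }), error = function(e) e)
    if (inherits(sch, "error")) {
      errs[[length(errs) + 1]] <- data.frame(stage = "schild", unit = "all",
                                             message = conditionMessage(sch))
    } else {
      sch_tab <- data.frame(antagonist_conc_M = sch$antagonist_conc,
                            dose_ratio = sch$dose_ratios,
                            slope = sch$slope, se_slope = sch$se_slope,
                            pA2 = sch$pA2, pKB_constrained = sch$pKB_constrained,
                            r_squared = sch$r_squared, source = paths$antagonism)
      out$schild <- sch_tab
      write.csv(sch_tab, file.path(config$output_dir, "schild.csv"),
                row.names = FALSE)
      summ <- c(summ, sprintf("Schild: slope %.3f, pA2 %.3f (%d usable DRs)",
                              sch$slope, sch$pA2, sch$n_points))
    }
  }

  if (!is.null(paths$saturation)) {
    sat <- read_dataset(paths$saturation, "saturation")
    f <- fit_saturation(sat$conc_M, sat$total_dpm, sat$nsb_dpm)
    tab <- data.frame(KD_M = f$KD, Bmax = f$Bmax, se_KD = f$se_KD,
                      ns_slope = f$ns_slope, converged = f$converged,
                      extrapolated = f$extrapolated, source = paths$saturation)
    out$saturation <- tab
    write.csv(tab, file.path(config$output_dir, "saturation.csv"),
              row.names = FALSE)
    summ <- c(summ, sprintf("saturation: KD %.4g M, Bmax %.4g", f$KD, f$Bmax))
  }

  if (!is.null(paths$competition)) {
    comp <- read_dataset(paths$competition, "competition")
    f <- fit_competition(log10(comp$inhibitor_conc_M), comp$bound)
    ki <- if (!isTRUE(f$no_binding) && isTRUE(f$converged) &&
              !is.null(config$radioligand_KD) && !is.null(config$radioligand_conc))
      cheng_prusoff(f$IC50, config$radioligand_conc, config$radioligand_KD)
    else list(Ki = NA_real_, pKi = NA_real_)
    tab <- data.frame(pIC50 = f$pIC50, se_pIC50 = f$se_pIC50 %||% NA_real_,
                      pKi = ki$pKi, Ki_M = ki$Ki,
                      no_binding = f$no_binding, converged = f$converged,
                      source = paths$competition)
    out$competition <- tab
    write.csv(tab, file.path(config$output_dir, "competition.csv"),
              row.names = FALSE)
    summ <- c(summ, if (isTRUE(f$no_binding)) "competition: no detectable binding"
              else sprintf("competition: pIC50 %.3f, pKi %.3f", f$pIC50, ki$pKi))
  }

  if (!is.null(paths$kinetics)) {
    kin <- read_dataset(paths$kinetics, "kinetics")
    fits <- lapply(split(kin, kin$condition), function(d)
      fit_dissociation(d$time_min, d$bound, condition = d$condition[1]))
    tab <- do.call(rbind, lapply(fits, function(f)
      data.frame(condition = f$condition, koff_per_min = f$koff,
                 half_life_min = f$half_life, converged = f$converged,
                 source = paths$kinetics)))
    if (length(fits) == 2L && all(vapply(fits, `[[`, logical(1), "converged"))) {
      cmp <- compare_dissociation(fits[[1]], fits[[2]], seed = config$seed)
      tab$koff_ratio <- cmp$ratio
      tab$kinetics_altered <- cmp$kinetics_altered
      summ <- c(summ, sprintf("dissociation: koff ratio %.3f, altered: %s",
                              cmp$ratio, cmp$kinetics_altered))
    }
    out$kinetics <- tab
    write.csv(tab, file.path(config$output_dir, "kinetics.csv"),
              row.names = FALSE)
  }

  if (!is.null(paths$exposure)) {
    ex <- read_dataset(paths$exposure, "exposure")
    tab <- do.call(rbind, lapply(seq_len(nrow(ex)), function(i) {
      r <- ex[i, ]
      rec <- exposure_record(r$species, r$dose_mgkg, r$route, r$cmax_ngml,
                             r$fu, r$mw)
      data.frame(species = r$species, dose_mgkg = r$dose_mgkg,
                 cmax_ngml = r$cmax_ngml, plasma_nM = rec$plasma_nM,
                 cu_plasma_nM = rec$cu_plasma_nM, source = paths$exposure)
    }))
    out$exposure <- tab
    write.csv(tab, file.path(config$output_dir, "exposure.csv"),
              row.names = FALSE)
    summ <- c(summ, sprintf("exposure: %d records", nrow(tab)))
  }

  errs_df <- if (length(errs)) do.call(rbind, errs) else
    data.frame(stage = character(), unit = character(), message = character())
  out$errors <- errs_df
  if (nrow(errs_df))
    write.csv(errs_df, file.path(config$output_dir, "errors.csv"),
              row.names = FALSE)

  info <- list(package = "pharmfit",
               version = as.character(packageVersion("pharmfit")),
               seed = config$seed,
               config = unclass(config))
  jsonlite::write_json(info, file.path(config$output_dir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  writeLines(c("pharmfit pipeline summary", paste0("  ", summ)),
             file.path(config$output_dir, "summary.txt"))
  invisible(out)
}
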