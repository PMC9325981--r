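#' Pipeline run configuration
#'
#' Collects every knob of an end-to-end run: output directory, root seed
#' (split deterministically per stage so stage skipping never changes
#' upstream numbers), study design, stage toggles and the per-module
#' settings.
#'
#' @param outdir output directory (created if absent).
#' @param seed root RNG seed; per-stage seeds are derived by fixed offsets.
#' @param design a [study_design()].
#' @param stages character subset of
#'   `c("dom", "metabolism", "lmm", "assoc")`; the synthetic input bundle is
#'   always generated (it is the pipeline's data source), stages lacking
#'   their inputs are skipped with a logged message.
#' @param assign an [assignment_config()].
#' @param dom_scale optional named list overriding [make_formula_universe()]
#'   arguments (e.g. `list(lake_formula_range = c(300, 500))` for a
#'   reduced-size run).
#' @param asv named list of [make_asv_table()] overrides (default plants a
#'   log2 slope of 1.5 on 10% of 300 ASVs).
#' @param rq,stability_sd,leucine_to_carbon metabolism settings, see
#'   [incubation_rates()].
#' @param min_reads ASV total-read filter threshold.
#' @param write_outputs write CSV/JSON outputs under `outdir`.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(outdir = tempfile("plasticdom_run_"), seed = 1,
                            design = study_design(),
                            stages = c("dom", "metabolism", "lmm", "assoc"),
                            assign = assignment_config(),
                            dom_scale = list(),
                            asv = list(planted_fraction = 0.1),
                            rq = 1, stability_sd = 0.1,
                            leucine_to_carbon = 1.55, min_reads = 100,
                            write_outputs = TRUE) {
  stopifnot(all(stages %in% c("dom", "metabolism", "lmm", "assoc")))
  structure(list(outdir = outdir, seed = seed, design = design,
                 stages = stages, assign = assign, dom_scale = dom_scale,
                 asv = asv, rq = rq, stability_sd = stability_sd,
                 leucine_to_carbon = leucine_to_carbon,
                 min_reads = min_reads, write_outputs = write_outputs),
            class = "pipeline_config")
}

.log_msg <- function(...) message("[plasticdom] ", ...)

#' Run the full analysis pipeline on a synthetic study
#'
#' Generates the synthetic input bundle from the configured design and seed,
#' then executes the enabled stages in dependency order:
#' formula assignment and blank correction of all peak lists followed by DOM
#' composition statistics (`dom`); conversion of raw incubation records to
#' BPP, respiration and BGE (`metabolism`); log-scale mixed-model inference
#' of the treatment effect with AIC backward elimination and marginal fold
#' changes (`lmm`, requires `metabolism`); and negative-binomial association
#' of ASV counts with the per-lake metabolic fold changes (`assoc`, requires
#' `metabolism`). Outputs are written as tidy CSVs plus a JSON summary under
#' `config$outdir`, and the same report is returned invisibly.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with elements `dom` (per-sample summaries,
#'   unique-formula analysis, additive matches), `metabolism` (rates table),
#'   `lmm` (per-response model reports), `assoc` (association tables),
#'   and `truth` (generator ground truth for validation).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- config$design
  report <- list(truth = list())
  if (config$write_outputs) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  }

  # --- generate: the input bundle (always; it is the data source) ---------
  .log_msg("generating synthetic study (seed ", config$seed, ")")
  cov <- make_lake_covariates(design, seed = config$seed + 11L)
  bpp_truth <- make_response_data(design, "bpp", covariates = cov,
                                  seed = config$seed + 12L)
  bge_truth <- make_response_data(design, "bge", covariates = cov,
                                  seed = config$seed + 13L)
  report$truth$bpp <- attr(bpp_truth, "truth")
  report$truth$bge <- attr(bge_truth, "truth")

  # --- dom ----------------------------------------------------------------
  if ("dom" %in% config$stages) {
    .log_msg("dom: generating formula universe and assigning peak lists")
    uni <- do.call(make_formula_universe,
                   c(list(design = design, seed = config$seed + 14L),
                     config$dom_scale))
    asg <- assign_formulas(uni$peaks, config$assign)
    tables <- lapply(split(asg, asg$sample_id), formula_table_from_assignments)
    blank_tab <- tables[["blank"]]
    corrected <- lapply(tables[setdiff(names(tables), "blank")],
                        blank_correct, blank = blank_tab)
    summaries <- do.call(rbind, lapply(corrected, dom_summary))
    rownames(summaries) <- NULL
    lake_tabs <- corrected[grep("^lake", names(corrected))]
    uniq <- unique_formulas(corrected[["leachate"]], lake_tabs)
    matches <- crossref_additives(uniq$table, corrected[["leachate"]])
    report$dom <- list(summaries = summaries,
                       unique = uniq[c("n_target", "n_unique", "pct_unique")],
                       additive_matches = matches)
    report$truth$dom <- uni$truth[c("pct_unique", "lability_count_frac")]
    if (config$write_outputs) {
      utils::write.csv(summaries, file.path(config$outdir, "dom_summary.csv"),
                       row.names = FALSE)
      utils::write.csv(matches,
                       file.path(config$outdir, "additive_matches.csv"),
                       row.names = FALSE)
    }
  } else .log_msg("dom: skipped")

  # --- metabolism ---------------------------------------------------------
  rates <- NULL
  if ("metabolism" %in% config$stages) {
    .log_msg("metabolism: generating and inverting incubation records")
    truth_rates <- bpp_truth[, c("lake_id", "treatment", "replicate", "bpp")]
    bge_key <- paste(bge_truth$lake_id, bge_truth$treatment)
    bpp_mean <- stats::aggregate(bpp ~ lake_id + treatment, bpp_truth, mean)
    i <- match(paste(truth_rates$lake_id, truth_rates$treatment), bge_key)
    bge_val <- bge_truth$bge[i]
    mean_bpp <- bpp_mean$bpp[match(paste(truth_rates$lake_id,
                                         truth_rates$treatment),
                                   paste(bpp_mean$lake_id,
                                         bpp_mean$treatment))]
    truth_rates$respiration <- ifelse(is.na(bge_val), NA,
                                      mean_bpp * (1 - bge_val) / bge_val)
    incub <- make_incubation_data(design, truth_rates,
                                  temperature_C =
                                    stats::setNames(cov$temperature,
                                                    cov$lake_id),
                                  seed = config$seed + 15L)
    rates <- incubation_rates(incub$scint, incub$oxygen, duration_h = 72,
                              rq = config$rq,
                              stability_sd = config$stability_sd,
                              leucine_to_carbon = config$leucine_to_carbon)
    report$metabolism <- rates
    if (config$write_outputs) {
      utils::write.csv(rates, file.path(config$outdir, "rates.csv"),
                       row.names = FALSE)
    }
  } else .log_msg("metabolism: skipped")

  # --- lmm ----------------------------------------------------------------
  if ("lmm" %in% config$stages) {
    if (is.null(rates)) {
      .log_msg("lmm: skipped (no metabolism rates available)")
    } else {
      .log_msg("lmm: fitting treatment models")
      bottles <- attr(rates, "bottles")
      report$lmm <- list()
      for (resp in c("bpp", "bge")) {
        d <- if (resp == "bpp") {
          merge(bottles, cov, by = "lake_id")
        } else {
          merge(rates[!is.na(rates$bge), c("lake_id", "treatment", "bge")],
                cov, by = "lake_id")
        }
        covars <- c("fd", "doc", "tn", "temperature", "ph", "latitude",
                    "shannon")
        dc <- d[stats::complete.cases(d[, c(resp, covars)]), , drop = FALSE]
        scr <- collinearity_screen(dc, covars)
        fit <- fit_lmm(dc, resp, scr$retained, interactions = TRUE,
                       REML = FALSE)
        sel <- backward_eliminate(fit)
        eff <- marginal_effects(sel)
        probe <- if ("treatment:fd" %in% sel$terms) {
          marginal_effects(sel, moderator = "fd")
        } else NULL
        report$lmm[[resp]] <- list(screen = scr, terms = sel$terms,
                                   aic_trace = sel$aic_trace,
                                   effects = eff, fd_probe = probe,
                                   n_lakes = length(unique(dc$lake_id)))
        if (config$write_outputs) {
          utils::write.csv(eff$fold,
                           file.path(config$outdir,
                                     paste0("lmm_", resp, "_fold.csv")),
                           row.names = FALSE)
          utils::write.csv(sel$aic_trace,
                           file.path(config$outdir,
                                     paste0("lmm_", resp, "_aic_trace.csv")),
                           row.names = FALSE)
        }
      }
    }
  } else .log_msg("lmm: skipped")

  # --- assoc --------------------------------------------------------------
  if ("assoc" %in% config$stages) {
    if (is.null(rates)) {
      .log_msg("assoc: skipped (no metabolism rates available)")
    } else {
      .log_msg("assoc: ASV diversity and NB association")
      samples <- .lake_ids(design)[seq_len(design$lakes_with_16s)]
      wide <- stats::reshape(rates[, c("lake_id", "treatment", "bpp")],
                             idvar = "lake_id", timevar = "treatment",
                             direction = "wide")
      fold_cov <- log2(wide$bpp.plastic / wide$bpp.control)[
        match(samples, wide$lake_id)]
      tab <- do.call(make_asv_table,
                     c(list(design = design, covariate = fold_cov,
                            seed = config$seed + 16L), config$asv))
      filt <- filter_low_abundance(tab$counts, config$min_reads)
      assoc <- nb_association(filt, tab$covariate)
      assoc <- merge(assoc, tab$taxonomy, by = "asv", sort = FALSE)
      assoc <- assoc[order(assoc$padj, assoc$p), ]
      shannon <- shannon_index(tab$counts)
      report$assoc <- list(results = assoc, shannon = shannon,
                           n_filtered = nrow(filt),
                           n_significant = sum(assoc$padj < 0.05,
                                               na.rm = TRUE))
      report$truth$assoc <- tab$truth
      if (config$write_outputs) {
        utils::write.csv(assoc, file.path(config$outdir, "asv_association.csv"),
                         row.names = FALSE)
      }
    }
  } else .log_msg("assoc: skipped")

  if (config$write_outputs) {
    summary <- .pipeline_summary(report)
    jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(utils::capture.output(utils::str(summary, give.head = FALSE)),
               file.path(config$outdir, "summary.txt"))
  }
  invisible(report)
}

# headline quantities of a pipeline report, as a flat named list
.pipeline_summary <- function(report) {
  out <- list()
  if (!is.null(report$dom)) {
    s <- report$dom$summaries
    leach <- s[s$sample_id == "leachate", ]
    lakes <- s[grepl("^lake", s$sample_id), ]
    out$leachate_n_formulas <- leach$n_formulas
    out$leachate_fd <- leach$fd
    out$lake_fd_range <- range(lakes$fd)
    out$leachate_lability_count_pct <- 100 * leach$frac_high_lability_count
    out$leachate_lability_intensity_pct <-
      100 * leach$frac_high_lability_intensity
    out$leachate_unique_pct <- report$dom$unique$pct_unique
    out$n_additive_matches <- nrow(report$dom$additive_matches)
  }
  if (!is.null(report$lmm)) {
    for (resp in names(report$lmm)) {
      f <- report$lmm[[resp]]$effects$fold
      out[[paste0(resp, "_fold_change")]] <- f$fold_change[1]
      out[[paste0(resp, "_fold_lcl")]] <- f$lcl[1]
      out[[paste0(resp, "_fold_ucl")]] <- f$ucl[1]
    }
    if (!is.null(out$bpp_fold_change) && !is.null(report$lmm$bge)) {
      m <- report$lmm$bge$effects$means
      bge_plastic <- m$response_mean[m$treatment == "plastic"][1]
      mm <- report$lmm$bpp$effects$means
      delta_total <- (mm$response_mean[mm$treatment == "plastic"][1] -
                        mm$response_mean[mm$treatment == "control"][1]) * 72
      out$carbon_processed_ugC_L <- carbon_processed(delta_total, bge_plastic)
    }
  }
  if (!is.null(report$assoc)) {
    out$shannon_range <- range(report$assoc$shannon, na.rm = TRUE)
    out$n_asv_significant <- report$assoc$n_significant
  }
  out
}
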