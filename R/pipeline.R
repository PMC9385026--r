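# End-to-end driver: expression (real or simulated) -> response profiles ->
# stability ranking -> panel selection -> nested-set correlation -> volcano
# tables -> subtype calls -> over-representation, with every report written
# as a TSV stamped with the configuration and seed.

#' Run a stage with error context
#' @noRd
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort("stage '", stage, "': ", conditionMessage(e))
  })
}

#' Nested set-size ladder for the correlation and mean-CV tables
#'
#' The full ranked list plus the descending ladder 174/150/120/90/60/30,
#' truncated to sizes the ranking can support.
#' @noRd
default_nested_sizes <- function(n_ranked, top_k) {
  ladder <- c(n_ranked, 174L, 150L, 120L, 90L, 60L, 30L, as.integer(top_k))
  sizes <- sort(unique(ladder[ladder >= 2L & ladder <= n_ranked]),
                decreasing = TRUE)
  sizes
}

#' Run the full panel-selection and evaluation pipeline
#'
#' Orchestrates every analysis stage and writes the report bundle to
#' \code{outdir}. Inputs are either a prepared experiment or a simulation
#' configuration (exactly one must be given); peak evidence and gene sets
#' are optional and switch on the subtype-classification and enrichment
#' stages. All randomness is governed by \code{config$seed} /
#' \code{sim$seed}, and re-running with identical inputs produces
#' byte-identical files.
#'
#' @param config An [erg_config()] (or plain list validated against it).
#' @param experiment An [erg_experiment()], or \code{NULL} to simulate.
#' @param sim An [sim_config()] used when \code{experiment} is \code{NULL}.
#' @param evidence Optional peak-evidence data frame for ER-subtype calls.
#' @param gene_sets Optional named list of gene sets for enrichment.
#' @param outdir Output directory (created if missing).
#' @param nested_sizes Optional integer vector of nested set sizes for the
#'   correlation and mean-CV tables; a descending ladder is chosen by
#'   default.
#' @return Invisibly, a list with the in-memory results: \code{response},
#'   \code{stability}, \code{ranking}, \code{panel}, \code{correlations},
#'   \code{mean_cv}, \code{volcano_pvalue}, \code{volcano_cv},
#'   \code{subtypes}, \code{enrichment_up}, \code{enrichment_down},
#'   \code{truth}, \code{files}.
#' @export
run_full_pipeline <- function(config, experiment = NULL, sim = NULL,
                              evidence = NULL, gene_sets = NULL,
                              outdir, nested_sizes = NULL) {
  config <- run_stage("config", validate_erg_config(config))
  if (is.null(experiment) == is.null(sim)) {
    abort("provide exactly one of 'experiment' or 'sim'")
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  stamp <- paste0(config_stamp(config), "; package=ergpanel")
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    write_stamped_tsv(df, path, stamp)
    files[[name]] <<- path
  }

  truth <- NULL
  if (is.null(experiment)) {
    simres <- run_stage("simulate", simulate_experiment(sim))
    experiment <- simres$experiment
    truth <- simres$truth
    emit(truth, "ground_truth.tsv")
    run_stage("simulate", {
      write_expression_matrix(experiment$treated,
                              file.path(outdir, "treated_fpkm.tsv"))
      write_expression_matrix(experiment$control,
                              file.path(outdir, "control_fpkm.tsv"))
      files[["treated_fpkm.tsv"]] <- file.path(outdir, "treated_fpkm.tsv")
      files[["control_fpkm.tsv"]] <- file.path(outdir, "control_fpkm.tsv")
    })
  }

  response <- run_stage("response", response_profile(experiment, config$pseudocount))
  stability <- run_stage("stability", stability_table(response, config$epsilon))
  ranking <- run_stage("stability", rank_by_stability(stability))
  panel <- run_stage("selection", select_panel(response, stability, config))

  sizes <- nested_sizes
  if (is.null(sizes)) sizes <- default_nested_sizes(nrow(ranking), config$top_k)
  mean_cv <- run_stage("stability", mean_cv_by_set(ranking, sizes))

  correlations <- NULL
  if (length(experiment$replicate_labels) >= 2L) {
    profiles <- arm_profiles(experiment, "treated", config$pseudocount)
    correlations <- run_stage("correlation", nested_set_correlation(
      profiles[[1L]], profiles[-1L], ranking$gene, sizes))
  }

  cv_vec <- stats::setNames(stability$cv, stability$gene)
  volcano_p <- run_stage("volcano",
                         volcano_table(response, "pvalue", config$alpha))
  volcano_cv <- run_stage("volcano",
                          volcano_table(response, "cv", config$alpha, cv_vec))

  subtypes <- NULL
  if (!is.null(evidence)) {
    subtypes <- run_stage("subtype", classify_panel(evidence))
    run_stage("subtype", write_subtype_calls(
      subtypes,
      calls_path = file.path(outdir, "subtype_calls.tsv"),
      counts_path = file.path(outdir, "subtype_counts.tsv"),
      stamp = stamp))
    files[["subtype_calls.tsv"]] <- file.path(outdir, "subtype_calls.tsv")
    files[["subtype_counts.tsv"]] <- file.path(outdir, "subtype_counts.tsv")
  }

  enrichment_up <- enrichment_down <- NULL
  if (!is.null(gene_sets)) {
    universe <- response$summary$gene[
      response$summary$mean_control_fpkm >= config$expression_floor]
    enrichment_up <- run_stage("enrichment", {
      if (length(panel$up) > 0L)
        enrich_panel(intersect(panel$up, universe), gene_sets, universe)
    })
    enrichment_down <- run_stage("enrichment", {
      if (length(panel$down) > 0L)
        enrich_panel(intersect(panel$down, universe), gene_sets, universe)
    })
    if (!is.null(enrichment_up)) {
      emit(enrichment_up, "enrichment_up.tsv")
      emit(top_categories(enrichment_up, config$fdr_threshold,
                          config$top_n_categories), "top_categories_up.tsv")
    }
    if (!is.null(enrichment_down)) {
      emit(enrichment_down, "enrichment_down.tsv")
      emit(top_categories(enrichment_down, config$fdr_threshold,
                          config$top_n_categories), "top_categories_down.tsv")
    }
  }

  emit(panel$records, "panel_records.tsv")
  emit(ranking, "stability_ranking.tsv")
  emit(mean_cv, "mean_cv_by_set.tsv")
  if (!is.null(correlations)) emit(correlations, "correlation_nested.tsv")
  emit(volcano_p, "volcano_pvalue.tsv")
  emit(volcano_cv, "volcano_cv.tsv")
  for (nm in c("up", "down", "top_k")) {
    path <- file.path(outdir, paste0("panel_", nm, ".txt"))
    con <- file(path, open = "wb")
    writeLines(panel[[nm]], con, sep = "\n")
    close(con)
    files[[paste0("panel_", nm, ".txt")]] <- path
  }

  invisible(list(response = response, stability = stability,
                 ranking = ranking, panel = panel,
                 correlations = correlations, mean_cv = mean_cv,
                 volcano_pvalue = volcano_p, volcano_cv = volcano_cv,
                 subtypes = subtypes, enrichment_up = enrichment_up,
                 enrichment_down = enrichment_down, truth = truth,
                 files = files))
}
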