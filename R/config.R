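#' Analysis configuration for panel selection and reporting
#'
#' Bundles every tunable threshold of the pipeline with validation, so each
#' report can be stamped with the exact settings that produced it.
#'
#' The defaults mirror the published study design: panels of 150 up- and 150
#' down-regulated genes drawn from the stability ranking, a 30-gene
#' high-stability subset, significance at \code{alpha = 0.05}, and
#' over-representation reporting of the top ten categories at FDR < 0.05.
#' The fold-change floor of 0.585 on the mean log2 ratio corresponds to a
#' 1.5-fold response; the expression floor of 1 FPKM removes genes too weakly
#' expressed for a ratio to be meaningful.
#'
#' @param pseudocount Positive value added to FPKM before log2 transformation
#'   (guards against zeros; FPKM data contain exact zeros for silent genes).
#' @param n_up,n_down Target sizes of the up- and down-regulated panels.
#' @param top_k Size of the high-stability subset taken from the union of the
#'   two panels.
#' @param fc_threshold Minimum absolute mean log2 ratio for a candidate gene.
#' @param expression_floor Minimum mean control-arm FPKM for a candidate gene.
#' @param alpha Per-gene significance level for the treated-vs-control test.
#' @param fdr_threshold Benjamini-Hochberg FDR cutoff for reported categories.
#' @param top_n_categories Number of enriched categories reported per panel.
#' @param epsilon Genes with \code{|Av|} below this are flagged as having an
#'   undefined coefficient of variation and excluded from ranking.
#' @param seed Integer seed recorded in every output and used for any
#'   stochastic step.
#'
#' @return An object of class \code{"erg_config"}: a validated named list.
#' @examples
#' cfg <- erg_config(n_up = 10, n_down = 10, top_k = 5, seed = 1)
#' cfg$fc_threshold
#' @export
erg_config <- function(pseudocount = 1,
                       n_up = 150L,
                       n_down = 150L,
                       top_k = 30L,
                       fc_threshold = 0.585,
                       expression_floor = 1,
                       alpha = 0.05,
                       fdr_threshold = 0.05,
                       top_n_categories = 10L,
                       epsilon = 1e-8,
                       seed = 1L) {
  cfg <- list(pseudocount = pseudocount, n_up = n_up, n_down = n_down,
              top_k = top_k, fc_threshold = fc_threshold,
              expression_floor = expression_floor, alpha = alpha,
              fdr_threshold = fdr_threshold,
              top_n_categories = top_n_categories, epsilon = epsilon,
              seed = seed)
  validate_erg_config(cfg)
}

#' Validate a configuration list
#'
#' Accepts a plain named list (e.g. parsed from a file) and checks every
#' field; the error names the first offending or missing field.
#'
#' @param cfg Named list with the fields of [erg_config()].
#' @return The list, classed as \code{"erg_config"}.
#' @export
validate_erg_config <- function(cfg) {
  required <- c("pseudocount", "n_up", "n_down", "top_k", "fc_threshold",
                "expression_floor", "alpha", "fdr_threshold",
                "top_n_categories", "epsilon", "seed")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0L) {
    abort("configuration is missing required field(s): ",
          paste(missing, collapse = ", "))
  }
  for (nm in required) {
    if (!is_scalar_number(cfg[[nm]])) {
      abort("configuration field '", nm, "' must be a single finite number")
    }
  }
  if (cfg$pseudocount < 0) abort("'pseudocount' must be >= 0")
  if (cfg$n_up < 1 || cfg$n_down < 1) abort("panel sizes 'n_up'/'n_down' must be >= 1")
  if (cfg$top_k < 1) abort("'top_k' must be >= 1")
  if (cfg$fc_threshold < 0) abort("'fc_threshold' must be >= 0")
  if (cfg$expression_floor < 0) abort("'expression_floor' must be >= 0")
  if (cfg$alpha <= 0 || cfg$alpha > 1) abort("'alpha' must be in (0, 1]")
  if (cfg$fdr_threshold <= 0 || cfg$fdr_threshold > 1) abort("'fdr_threshold' must be in (0, 1]")
  if (cfg$top_n_categories < 1) abort("'top_n_categories' must be >= 1")
  if (cfg$epsilon <= 0) abort("'epsilon' must be > 0")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "erg_config")
}

#' @export
print.erg_config <- function(x, ...) {
  cat("ERG pipeline configuration\n")
  for (nm in setdiff(names(x), NULL)) {
    cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}
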