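# Differential response: log2 transformation, per-replicate response ratios,
# per-gene significance, and volcano summary tables.

#' Log2 transform with a pseudocount
#'
#' @param fpkm Non-negative expression values.
#' @param pseudocount Value added before taking log2 (> 0 unless all inputs
#'   are strictly positive). FPKM matrices contain exact zeros for silent
#'   genes, so a pseudocount keeps the transform finite.
#' @return \code{log2(fpkm + pseudocount)}.
#' @examples
#' log2_with_pseudocount(7, 1)  # 3
#' @export
log2_with_pseudocount <- function(fpkm, pseudocount = 1) {
  if (any(fpkm < 0)) abort("FPKM values must be >= 0")
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  if (pseudocount == 0 && any(fpkm == 0)) {
    abort("pseudocount 0 requires strictly positive FPKM values")
  }
  log2(fpkm + pseudocount)
}

#' Welch two-sample test on log2 expression values
#'
#' Two-sided Welch t-test, the unequal-variance form appropriate when
#' nothing justifies assuming equal spread in the two arms. Degenerate
#' inputs where both arms are exactly constant (the test statistic is
#' undefined) are resolved by convention: p = 1 when the two constants are
#' equal, p = 0 when they differ.
#'
#' @param treated,control Numeric vectors of log2 expression values, at
#'   least 2 values per arm.
#' @return Two-sided p-value.
#' @export
per_gene_test <- function(treated, control) {
  if (length(treated) < 2L || length(control) < 2L) {
    abort("each arm needs at least 2 values for a two-sample test")
  }
  if (stats::sd(treated) == 0 && stats::sd(control) == 0) {
    return(if (treated[1L] == control[1L]) 1 else 0)
  }
  res <- tryCatch(
    stats::t.test(treated, control, var.equal = FALSE,
                  alternative = "two.sided"),
    error = function(e) NULL)
  if (is.null(res)) {
    # t.test refuses near-constant data; fall back to the same convention
    return(if (isTRUE(all.equal(mean(treated), mean(control)))) 1 else 0)
  }
  unname(res$p.value)
}

#' Per-gene response profiles from a paired experiment
#'
#' For each gene and replicate pair i the response ratio is
#' \code{log2(treated_i + pc) - log2(control_i + pc)}; the per-gene summary
#' holds the mean ratio (the log2 fold change), its standard deviation, the
#' Welch p-value of treated vs control log2 values, and the mean raw FPKM of
#' each arm (used downstream by the expression filter).
#'
#' @param experiment An [erg_experiment()].
#' @param pseudocount Pseudocount for the log2 transform.
#' @return Object of class \code{"erg_response"}:
#'   \describe{
#'     \item{ratios}{genes x replicates matrix of per-replicate log2 ratios}
#'     \item{summary}{data frame \code{gene}, \code{log2fc}, \code{sd_ratio},
#'       \code{p_value}, \code{mean_treated_fpkm}, \code{mean_control_fpkm}}
#'     \item{log2_treated, log2_control}{transformed arm matrices}
#'     \item{pseudocount}{the value used}
#'   }
#' @export
response_profile <- function(experiment, pseudocount = 1) {
  if (!inherits(experiment, "erg_experiment")) {
    abort("'experiment' must be an erg_experiment")
  }
  if (ncol(experiment$treated) < 2L) {
    abort("at least 2 replicate pairs are required to test and rank responses")
  }
  lt <- log2_with_pseudocount(experiment$treated, pseudocount)
  lc <- log2_with_pseudocount(experiment$control, pseudocount)
  ratios <- lt - lc
  p <- vapply(seq_len(nrow(ratios)),
              function(i) per_gene_test(lt[i, ], lc[i, ]), numeric(1))
  summary <- data.frame(
    gene = experiment$gene_ids,
    log2fc = rowMeans(ratios),
    sd_ratio = apply(ratios, 1L, stats::sd),
    p_value = p,
    mean_treated_fpkm = rowMeans(experiment$treated),
    mean_control_fpkm = rowMeans(experiment$control),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(ratios = ratios, summary = summary,
                 log2_treated = lt, log2_control = lc,
                 pseudocount = pseudocount),
            class = "erg_response")
}

#' @export
print.erg_response <- function(x, ...) {
  cat(sprintf("erg_response: %d genes x %d replicate pairs (pseudocount %g)\n",
              nrow(x$ratios), ncol(x$ratios), x$pseudocount))
  invisible(x)
}

#' Volcano summary table
#'
#' One row per gene with the mean log2 ratio on the x-axis and either
#' \code{-log10(p)} (variant \code{"pvalue"}) or the stability statistic CV
#' (variant \code{"cv"}) on the y-axis. Genes are classed \code{"up"} when
#' significant with positive fold change, \code{"down"} when significant
#' with negative fold change, \code{"not_significant"} otherwise.
#'
#' @param response An [response_profile()] result.
#' @param variant \code{"pvalue"} or \code{"cv"}.
#' @param alpha Significance level for the class assignment.
#' @param cv Named numeric vector of CV values (required for variant
#'   \code{"cv"}; typically the \code{cv} column of [stability_table()]).
#' @return Data frame \code{gene}, \code{log2fc}, \code{y_value},
#'   \code{y_kind}, \code{class}, sorted by gene.
#' @export
volcano_table <- function(response, variant = c("pvalue", "cv"), alpha = 0.05,
                          cv = NULL) {
  variant <- match.arg(variant)
  s <- response$summary
  if (variant == "pvalue") {
    y <- -log10(s$p_value)
    kind <- "neg_log10_p"
  } else {
    if (is.null(cv)) abort("variant 'cv' requires a named 'cv' vector")
    if (is.null(names(cv))) abort("'cv' must be named by gene")
    y <- unname(cv[s$gene])
    kind <- "cv"
  }
  cls <- ifelse(s$p_value < alpha & s$log2fc > 0, "up",
                ifelse(s$p_value < alpha & s$log2fc < 0, "down",
                       "not_significant"))
  out <- data.frame(gene = s$gene, log2fc = s$log2fc, y_value = y,
                    y_kind = kind, class = cls, stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
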