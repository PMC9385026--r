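# Over-representation analysis: one-sided hypergeometric test of the
# overlap between a query gene panel and annotated gene sets, with
# Benjamini-Hochberg FDR across sets and a top-N reporting rule.

#' Hypergeometric over-representation test
#'
#' With a universe of N genes of which K belong to the set, and a query of
#' n genes of which k fall in the set, the p-value is the upper tail
#' P(X >= k) for X ~ hypergeometric(N, K, n): the chance of at least this
#' much overlap when the query is drawn at random from the universe.
#'
#' @param query Character vector of query genes (must lie in the universe).
#' @param gene_set Character vector of set members (intersected with the
#'   universe before testing).
#' @param universe Character vector of background genes.
#' @return List with \code{k} (overlap), \code{K}, \code{n}, \code{N},
#'   \code{p}.
#' @examples
#' ora_test(letters[1:5], letters[1:5], letters[1:10])  # p = 1/252
#' @export
ora_test <- function(query, gene_set, universe) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (length(query) == 0L) abort("query gene list is empty")
  if (length(universe) == 0L) abort("universe gene list is empty")
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    abort("query gene(s) absent from universe: ",
          paste(outside[seq_len(min(5L, length(outside)))], collapse = ", "))
  }
  set_in_universe <- intersect(unique(as.character(gene_set)), universe)
  k <- length(intersect(query, set_in_universe))
  K <- length(set_in_universe)
  n <- length(query)
  N <- length(universe)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR control: with the m p-values sorted ascending,
#' q_(i) = min over j >= i of m * p_(j) / j, capped at 1, reported in the
#' original order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Numeric vector of adjusted values (same length and order).
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p, method = "BH")
}

#' Run over-representation analysis across a gene-set collection
#'
#' @param query Character vector of query genes.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector of background genes.
#' @return Data frame of class \code{"erg_enrichment"}: one row per set with
#'   \code{set}, \code{N}, \code{K}, \code{n}, \code{k},
#'   \code{enrichment_ratio} = (k/n)/(K/N), \code{p}, \code{q}, ordered by
#'   ascending q then p.
#' @export
enrich_panel <- function(query, gene_sets, universe) {
  if (length(gene_sets) == 0L) abort("gene-set collection is empty")
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets)))) {
    abort("gene sets must be named")
  }
  res <- lapply(gene_sets, function(gs) ora_test(query, gs, universe))
  out <- data.frame(
    set = names(gene_sets),
    N = vapply(res, `[[`, numeric(1), "N"),
    K = vapply(res, `[[`, numeric(1), "K"),
    n = vapply(res, `[[`, numeric(1), "n"),
    k = vapply(res, `[[`, numeric(1), "k"),
    stringsAsFactors = FALSE)
  out$enrichment_ratio <- ifelse(out$K > 0,
                                 (out$k / out$n) / (out$K / out$N),
                                 NA_real_)
  out$p <- vapply(res, `[[`, numeric(1), "p")
  out$q <- bh_adjust(out$p)
  out <- out[order(out$q, out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("erg_enrichment", "data.frame")
  out
}

#' Report the top enriched categories
#'
#' Filters to categories passing the FDR threshold, sorts by ascending q
#' (ties broken by larger enrichment ratio, then set name), and truncates
#' to the reporting size.
#'
#' @param results An [enrich_panel()] data frame.
#' @param fdr_threshold FDR (q-value) cutoff; strictly below passes.
#' @param top_n Maximum number of categories reported.
#' @return The filtered, ordered, truncated data frame.
#' @export
top_categories <- function(results, fdr_threshold = 0.05, top_n = 10L) {
  keep <- results[results$q < fdr_threshold, , drop = FALSE]
  ratio <- keep$enrichment_ratio
  ratio[is.na(ratio)] <- -Inf
  keep <- keep[order(keep$q, -ratio, keep$set), , drop = FALSE]
  out <- keep[seq_len(min(top_n, nrow(keep))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
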