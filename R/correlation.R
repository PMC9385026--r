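# Reproducibility evaluation: Pearson correlation between replicate
# expression profiles restricted to a gene panel, and the nested-set
# correlation table that shows how restricting to the most stable genes
# tightens inter-replicate agreement.

#' Pearson correlation between two expression profiles over a gene set
#'
#' Profiles are named vectors of log2 expression values (one per gene); the
#' correlation is computed over exactly the genes in \code{gene_set}. The
#' p-value is the standard two-sided test of zero correlation via the
#' t-distribution with n - 2 degrees of freedom (identical to the R of a
#' simple linear regression between the two profiles).
#'
#' @param profile_a,profile_b Named numeric vectors of log2 expression.
#' @param gene_set Character vector of genes to correlate over (>= 2; >= 3
#'   for the p-value to be defined).
#' @return List with \code{r}, \code{p} (\code{NA} when fewer than 3 genes
#'   or when either profile is constant over the set), \code{n}.
#' @export
profile_correlation <- function(profile_a, profile_b, gene_set) {
  gene_set <- as.character(gene_set)
  if (length(gene_set) < 2L) abort("gene set must contain at least 2 genes")
  for (nm in list(a = profile_a, b = profile_b)) {
    if (is.null(names(nm))) abort("profiles must be named by gene")
  }
  miss_a <- setdiff(gene_set, names(profile_a))
  miss_b <- setdiff(gene_set, names(profile_b))
  if (length(miss_a) > 0L || length(miss_b) > 0L) {
    abort("gene(s) missing from profile: ",
          paste(unique(c(miss_a, miss_b)), collapse = ", "))
  }
  x <- unname(profile_a[gene_set])
  y <- unname(profile_b[gene_set])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(gene_set)))
  }
  if (length(gene_set) >= 3L) {
    ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
    list(r = unname(ct$estimate), p = unname(ct$p.value), n = length(gene_set))
  } else {
    list(r = stats::cor(x, y), p = NA_real_, n = length(gene_set))
  }
}

#' Nested-set correlation table
#'
#' Correlates one reference replicate profile against each of the others
#' over nested prefixes of a stability ranking: for each set size s, the s
#' top-ranked genes. With a CV-ascending ranking, small s restricts to the
#' most stably responding genes, and the correlations show how reproducible
#' the profiles are on progressively stricter panels.
#'
#' @param reference Named numeric vector (log2 expression, reference
#'   replicate).
#' @param others Named list of named numeric vectors (the remaining
#'   replicate profiles).
#' @param ranked_genes Character vector of genes in ranking order.
#' @param sizes Integer vector of nested set sizes (each <= number of
#'   ranked genes).
#' @return Data frame \code{pair}, \code{set_size}, \code{r}, \code{p},
#'   ordered by size descending then pair label.
#' @export
nested_set_correlation <- function(reference, others, ranked_genes, sizes) {
  if (length(others) < 1L) abort("at least one comparison profile is required")
  if (is.null(names(others))) names(others) <- paste0("profile", seq_along(others))
  sizes <- as.integer(sizes)
  too_big <- sizes[sizes > length(ranked_genes)]
  if (length(too_big) > 0L) {
    abort("set size ", too_big[1L], " exceeds the ranked gene list (",
          length(ranked_genes), ")")
  }
  grid <- expand.grid(pair = names(others), set_size = sizes,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    genes <- ranked_genes[seq_len(grid$set_size[i])]
    profile_correlation(reference, others[[grid$pair[i]]], genes)
  })
  out <- data.frame(pair = grid$pair, set_size = grid$set_size,
                    r = vapply(res, `[[`, numeric(1), "r"),
                    p = vapply(res, `[[`, numeric(1), "p"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$set_size, out$pair), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replicate profiles of an experiment arm as named vectors
#'
#' Convenience accessor for the correlation functions: each replicate column
#' of the chosen arm, log2-transformed, as a named vector.
#'
#' @param experiment An [erg_experiment()].
#' @param arm \code{"treated"} or \code{"control"}.
#' @param pseudocount Pseudocount for the log2 transform.
#' @return Named list of named numeric vectors, one per replicate.
#' @export
arm_profiles <- function(experiment, arm = c("treated", "control"),
                         pseudocount = 1) {
  arm <- match.arg(arm)
  mat <- log2_with_pseudocount(experiment[[arm]], pseudocount)
  stats::setNames(
    lapply(seq_len(ncol(mat)), function(j) mat[, j]),
    colnames(mat))
}
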