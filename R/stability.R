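# Stability statistic and panel selection. The core statistic is the
# coefficient of variation CV = |SD/Av| of a gene's per-replicate log2
# response ratios: a small CV means the gene responds with the same
# magnitude in every replicate, which is what qualifies it as a stable
# expression marker.

#' Coefficient of variation of a ratio vector
#'
#' Av is the arithmetic mean, SD the sample standard deviation (n - 1
#' denominator), and CV = |SD/Av|. When |Av| falls below \code{epsilon} the
#' ratio of the two is numerically meaningless, so the CV is flagged
#' undefined instead of exploding; such genes are excluded from ranking.
#'
#' @param x Numeric vector of per-replicate log2 ratios, length >= 2.
#' @param epsilon Threshold below which |Av| counts as zero.
#' @return List with \code{av}, \code{sd}, \code{cv} (\code{NA} when
#'   undefined), \code{defined}.
#' @examples
#' cv_statistic(c(2, 4))  # av 3, sd sqrt(2), cv ~0.471
#' @export
cv_statistic <- function(x, epsilon = 1e-8) {
  if (length(x) < 2L) abort("CV needs at least 2 values")
  if (anyNA(x)) abort("ratio vector must not contain missing values")
  av <- mean(x)
  s <- stats::sd(x)
  if (abs(av) < epsilon) {
    list(av = av, sd = s, cv = NA_real_, defined = FALSE)
  } else {
    list(av = av, sd = s, cv = abs(s / av), defined = TRUE)
  }
}

#' Per-gene stability table
#'
#' Applies [cv_statistic()] gene-wise. By default the statistic is computed
#' on the per-replicate log2 response ratios, the reading under which a low
#' CV means a stable response to treatment. The alternative
#' \code{cv_on = "log2_expression"} computes it on the treated-arm log2
#' expression levels instead (response-independent expression stability).
#'
#' @param response An [response_profile()] result.
#' @param epsilon Zero-mean guard passed to [cv_statistic()].
#' @param cv_on Quantity the statistic is computed on: \code{"ratios"}
#'   (default) or \code{"log2_expression"}.
#' @return Data frame \code{gene}, \code{av}, \code{sd}, \code{cv},
#'   \code{cv_defined}, in input gene order.
#' @export
stability_table <- function(response, epsilon = 1e-8,
                            cv_on = c("ratios", "log2_expression")) {
  cv_on <- match.arg(cv_on)
  mat <- if (cv_on == "ratios") response$ratios else response$log2_treated
  recs <- lapply(seq_len(nrow(mat)), function(i) cv_statistic(mat[i, ], epsilon))
  out <- data.frame(
    gene = rownames(mat),
    av = vapply(recs, `[[`, numeric(1), "av"),
    sd = vapply(recs, `[[`, numeric(1), "sd"),
    cv = vapply(recs, `[[`, numeric(1), "cv"),
    cv_defined = vapply(recs, `[[`, logical(1), "defined"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Rank genes by ascending CV
#'
#' Genes with an undefined CV are excluded (their count is logged, not an
#' error). Ties on CV are broken by larger |Av|, then by gene symbol, so
#' the ranking is fully deterministic.
#'
#' @param records Data frame with columns \code{gene}, \code{cv}; optional
#'   \code{av} (used for tie-breaks; treated as 0 when absent) and
#'   \code{cv_defined}.
#' @return The ranked data frame with a 1-based \code{rank} column.
#' @export
rank_by_stability <- function(records) {
  if (!all(c("gene", "cv") %in% names(records))) {
    abort("records must have 'gene' and 'cv' columns")
  }
  if (!"av" %in% names(records)) records$av <- 0
  defined <- if ("cv_defined" %in% names(records)) records$cv_defined else !is.na(records$cv)
  n_excluded <- sum(!defined)
  if (n_excluded > 0L) {
    log_msg(n_excluded, " gene(s) with undefined CV excluded from ranking")
  }
  kept <- records[defined, , drop = FALSE]
  ord <- order(kept$cv, -abs(kept$av), kept$gene)
  kept <- kept[ord, , drop = FALSE]
  kept$rank <- seq_len(nrow(kept))
  rownames(kept) <- NULL
  kept
}

#' Select stable up- and down-regulated marker panels
#'
#' Candidate genes must respond significantly (p < alpha), strongly
#' (|mean log2 ratio| >= \code{fc_threshold}), from a measurable expression
#' level (mean control FPKM >= \code{expression_floor}), and have a defined
#' CV. Among candidates the \code{n_up} lowest-CV genes with positive mean
#' ratio form the up-panel, symmetrically for the down-panel; the
#' \code{top_k} lowest-CV genes of the union form the high-stability subset.
#'
#' @param response An [response_profile()] result.
#' @param stability A [stability_table()] on the same genes.
#' @param config An [erg_config()].
#' @return Object of class \code{"erg_panel"}: list with \code{up},
#'   \code{down}, \code{top_k} (character vectors in ascending-CV order),
#'   \code{records} (per-gene table with selection flags), \code{config},
#'   and \code{shortfall} (named logical: whether either direction ran out
#'   of qualifying genes).
#' @export
select_panel <- function(response, stability, config) {
  config <- validate_erg_config(config)
  s <- response$summary
  if (!identical(s$gene, stability$gene)) {
    abort("response and stability tables must cover the same genes in the same order")
  }
  rec <- data.frame(gene = s$gene, av = stability$av, sd = stability$sd,
                    cv = stability$cv, cv_defined = stability$cv_defined,
                    p_value = s$p_value,
                    mean_control_fpkm = s$mean_control_fpkm,
                    stringsAsFactors = FALSE)
  rec$candidate <- rec$cv_defined &
    rec$p_value < config$alpha &
    abs(rec$av) >= config$fc_threshold &
    rec$mean_control_fpkm >= config$expression_floor
  pick <- function(direction) {
    pool <- rec[rec$candidate & if (direction == "up") rec$av > 0 else rec$av < 0, ,
                drop = FALSE]
    pool <- pool[order(pool$cv, -abs(pool$av), pool$gene), , drop = FALSE]
    n_want <- if (direction == "up") config$n_up else config$n_down
    short <- nrow(pool) < n_want
    if (short) {
      log_msg("only ", nrow(pool), " qualifying ", direction,
              "-regulated gene(s) for a panel of ", n_want, level = "WARN")
    }
    list(genes = pool$gene[seq_len(min(n_want, nrow(pool)))], short = short)
  }
  up <- pick("up")
  down <- pick("down")
  union_rec <- rec[rec$gene %in% c(up$genes, down$genes), , drop = FALSE]
  union_rec <- union_rec[order(union_rec$cv, -abs(union_rec$av), union_rec$gene), ,
                         drop = FALSE]
  top_k <- union_rec$gene[seq_len(min(config$top_k, nrow(union_rec)))]
  rec$direction <- ifelse(rec$gene %in% up$genes, "up",
                          ifelse(rec$gene %in% down$genes, "down", "none"))
  rec$in_top_k <- rec$gene %in% top_k
  structure(list(up = up$genes, down = down$genes, top_k = top_k,
                 records = rec, config = config,
                 shortfall = c(up = up$short, down = down$short)),
            class = "erg_panel")
}

#' @export
print.erg_panel <- function(x, ...) {
  cat(sprintf("erg_panel: %d up / %d down regulated genes; top-%d subset\n",
              length(x$up), length(x$down), length(x$top_k)))
  if (any(x$shortfall)) cat("  note: shortfall in direction(s): ",
                            paste(names(x$shortfall)[x$shortfall], collapse = ", "), "\n")
  invisible(x)
}

#' Mean CV over nested top-ranked gene sets
#'
#' For each requested set size s, the mean and SD of the CV of the s
#' top-ranked genes. Because the ranking is CV-ascending, the mean is
#' non-decreasing in s.
#'
#' @param ranked Data frame from [rank_by_stability()] (CV-ascending).
#' @param sizes Integer vector of nested set sizes.
#' @return Data frame \code{set_size}, \code{mean_cv}, \code{sd_cv}, in the
#'   order the sizes were given.
#' @examples
#' ranked <- rank_by_stability(erg_panel30())
#' mean_cv_by_set(ranked, c(30, 10, 1))
#' @export
mean_cv_by_set <- function(ranked, sizes) {
  sizes <- as.integer(sizes)
  if (any(sizes < 1L)) abort("set sizes must be >= 1")
  too_big <- sizes[sizes > nrow(ranked)]
  if (length(too_big) > 0L) {
    abort("set size ", too_big[1L], " exceeds the ranked list length (",
          nrow(ranked), ")")
  }
  data.frame(
    set_size = sizes,
    mean_cv = vapply(sizes, function(s) mean(ranked$cv[seq_len(s)]), numeric(1)),
    sd_cv = vapply(sizes, function(s) {
      if (s == 1L) 0 else stats::sd(ranked$cv[seq_len(s)])
    }, numeric(1)))
}
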