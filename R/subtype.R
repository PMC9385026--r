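# Rule-based ER-subtype classification from tabulated ChIP peak evidence.
#
# Evidence per gene: two ERalpha peak-significance scores (with and without
# estradiol stimulation; larger = more significant peak within +/- 10 kb of
# the TSS) and one ERbeta signal-to-noise ratio (mean of two ChIP replicate
# signals over the input-control signal, same window). Two strict-threshold
# rules convert the evidence into binding flags, whose combination yields one
# of four subtype classes.

SUBTYPE_LEVELS <- c("ERalpha", "ERbeta", "ERalpha/beta", "other")

#' Call ER-alpha binding from paired peak-significance scores
#'
#' Binding is positive when the peak score under estradiol strictly exceeds
#' the score without estradiol. The strictness matters at the boundary: a
#' gene scoring 0 in both conditions is negative.
#'
#' @param q_minus,q_plus Non-negative peak-significance scores without and
#'   with estradiol treatment. Vectorised.
#' @return Logical vector: \code{TRUE} where binding is called.
#' @export
alpha_binding_call <- function(q_minus, q_plus) {
  if (any(q_minus < 0) || any(q_plus < 0)) abort("peak-significance scores must be >= 0")
  if (anyNA(q_minus) || anyNA(q_plus)) abort("peak-significance scores must not be missing")
  q_plus > q_minus
}

#' Signal-to-noise ratio for ER-beta ChIP evidence
#'
#' The signal is the mean of the two ChIP replicate values and the noise the
#' input-control value, all taken within the same window around the TSS.
#'
#' @param rep1_signal,rep2_signal Non-negative ChIP replicate signals.
#' @param input_signal Non-negative input-control signal.
#' @return Numeric vector of ratios; \code{NA} where the input signal is zero
#'   (undefined ratio, reported rather than dropped).
#' @examples
#' sn_ratio(2, 4, 3)  # 1.0
#' @export
sn_ratio <- function(rep1_signal, rep2_signal, input_signal) {
  if (any(c(rep1_signal, rep2_signal, input_signal) < 0)) {
    abort("ChIP signals must be >= 0")
  }
  out <- ((rep1_signal + rep2_signal) / 2) / input_signal
  out[input_signal == 0] <- NA_real_
  out
}

#' Call ER-beta binding from a signal-to-noise ratio
#'
#' Binding is positive when the ratio strictly exceeds 1.0; a ratio of
#' exactly 1.0 is negative. An undefined ratio (\code{NA}, zero input signal)
#' yields a negative call so that the gene stays classifiable; callers can
#' track the undefined flag separately.
#'
#' @param sn Numeric vector of signal-to-noise ratios (may contain \code{NA}).
#' @return Logical vector: \code{TRUE} where binding is called.
#' @export
beta_binding_call <- function(sn) {
  if (any(sn < 0, na.rm = TRUE)) abort("S/N ratio must be >= 0")
  !is.na(sn) & sn > 1.0
}

#' Combine binding flags into an ER-subtype label
#'
#' @param alpha_flag,beta_flag Logical vectors of binding calls.
#' @return Character vector over \code{"ERalpha"}, \code{"ERbeta"},
#'   \code{"ERalpha/beta"}, \code{"other"}.
#' @export
classify_subtype <- function(alpha_flag, beta_flag) {
  if (anyNA(alpha_flag) || anyNA(beta_flag)) abort("binding flags must be resolved (no NA)")
  ifelse(alpha_flag & beta_flag, "ERalpha/beta",
         ifelse(alpha_flag, "ERalpha",
                ifelse(beta_flag, "ERbeta", "other")))
}

#' Classify a table of peak evidence into ER subtypes
#'
#' Applies both binding rules to every row and tabulates the four classes.
#'
#' @param evidence Data frame with columns \code{gene}, \code{q_minus},
#'   \code{q_plus}, \code{sn_ratio} (as returned by [read_peak_evidence()] or
#'   [simulate_peak_evidence()]).
#' @return List of class \code{"erg_subtype_calls"}:
#'   \describe{
#'     \item{calls}{data frame \code{gene}, \code{alpha_bound},
#'       \code{beta_bound}, \code{subtype}, sorted by gene}
#'     \item{counts}{named integer vector over the four classes}
#'   }
#' @examples
#' ev <- erg_chip_evidence()
#' classify_panel(ev)$counts
#' @export
classify_panel <- function(evidence) {
  evidence <- validate_peak_evidence(evidence)
  if (nrow(evidence) == 0L) {
    calls <- data.frame(gene = character(0), alpha_bound = logical(0),
                        beta_bound = logical(0), subtype = character(0),
                        stringsAsFactors = FALSE)
    counts <- stats::setNames(integer(length(SUBTYPE_LEVELS)), SUBTYPE_LEVELS)
    return(structure(list(calls = calls, counts = counts),
                     class = "erg_subtype_calls"))
  }
  alpha <- alpha_binding_call(evidence$q_minus, evidence$q_plus)
  beta <- beta_binding_call(evidence$sn_ratio)
  calls <- data.frame(gene = evidence$gene, alpha_bound = alpha,
                      beta_bound = beta,
                      subtype = classify_subtype(alpha, beta),
                      stringsAsFactors = FALSE)
  calls <- calls[order(calls$gene), , drop = FALSE]
  rownames(calls) <- NULL
  counts <- vapply(SUBTYPE_LEVELS, function(s) sum(calls$subtype == s), integer(1))
  structure(list(calls = calls, counts = counts), class = "erg_subtype_calls")
}

#' @export
print.erg_subtype_calls <- function(x, ...) {
  cat("ER-subtype calls for", nrow(x$calls), "genes\n")
  print(x$counts)
  invisible(x)
}

#' Validate (and normalise) a peak-evidence data frame
#' @noRd
validate_peak_evidence <- function(evidence) {
  needed <- c("gene", "q_minus", "q_plus", "sn_ratio")
  missing <- setdiff(needed, names(evidence))
  if (length(missing) > 0L) {
    abort("peak evidence is missing column(s): ", paste(missing, collapse = ", "))
  }
  dup <- evidence$gene[duplicated(evidence$gene)]
  if (length(dup) > 0L) {
    abort("duplicate gene(s) in peak evidence: ", paste(unique(dup), collapse = ", "))
  }
  num <- c("q_minus", "q_plus", "sn_ratio")
  for (nm in num) {
    v <- evidence[[nm]]
    if (!is.numeric(v)) abort("peak evidence column '", nm, "' must be numeric")
    if (any(v[!is.na(v)] < 0) || any(is.infinite(v))) {
      abort("peak evidence column '", nm, "' must be finite and >= 0")
    }
  }
  evidence
}

#' Read a peak-evidence table from TSV
#'
#' Two layouts are accepted: pre-computed ratios (columns \code{gene},
#' \code{q_minus}, \code{q_plus}, \code{sn_ratio}) or raw ChIP signals
#' (columns \code{gene}, \code{q_minus}, \code{q_plus}, \code{rep1},
#' \code{rep2}, \code{input}), in which case the signal-to-noise ratio is
#' computed with [sn_ratio()]. Supplying both layouts at once is ambiguous
#' and rejected. Columns with other names are carried through untouched.
#'
#' @param path Path to the TSV file.
#' @return Data frame with at least \code{gene}, \code{q_minus},
#'   \code{q_plus}, \code{sn_ratio}.
#' @export
read_peak_evidence <- function(path) {
  df <- read_plain_tsv(path)
  if (!"gene" %in% names(df)) abort("peak-evidence file must have a 'gene' column")
  has_sn <- "sn_ratio" %in% names(df)
  raw_cols <- c("rep1", "rep2", "input")
  has_raw <- all(raw_cols %in% names(df))
  if (has_sn && any(raw_cols %in% names(df))) {
    abort("peak-evidence file supplies both 'sn_ratio' and raw signal columns; ambiguous")
  }
  if (!has_sn && !has_raw) {
    abort("peak-evidence file must supply either 'sn_ratio' or raw columns rep1/rep2/input")
  }
  if (has_raw) {
    df$sn_ratio <- sn_ratio(df$rep1, df$rep2, df$input)
  }
  validate_peak_evidence(df)
}

#' Write ER-subtype calls and class counts as TSV
#'
#' @param calls An \code{"erg_subtype_calls"} object from [classify_panel()].
#' @param calls_path,counts_path Output paths; either may be \code{NULL} to
#'   skip that file.
#' @param stamp Optional comment-line stamp recording configuration and seed.
#' @return \code{calls}, invisibly.
#' @export
write_subtype_calls <- function(calls, calls_path = NULL, counts_path = NULL,
                                stamp = NULL) {
  if (!is.null(calls_path)) write_stamped_tsv(calls$calls, calls_path, stamp)
  if (!is.null(counts_path)) {
    counts_df <- data.frame(subtype = names(calls$counts),
                            n_genes = as.integer(calls$counts),
                            stringsAsFactors = FALSE)
    write_stamped_tsv(counts_df, counts_path, stamp)
  }
  invisible(calls)
}
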