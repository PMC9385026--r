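# Packaged reference tables: the published 30-gene stability panel and the
# 29-gene ChIP peak-evidence table used to classify ER-subtype dependence.

#' Published 30-gene stability panel
#'
#' The 30 estrogen-responsive genes selected by ranking the coefficient of
#' variation |SD/Av| of replicated log2 response ratios, with their printed
#' CV values. The long non-coding RNA LINC02593 heads the ranking with
#' CV 0.058.
#'
#' @return Data frame with columns \code{rank}, \code{gene}, \code{cv}
#'   (30 rows).
#' @examples
#' head(erg_panel30())
#' @export
erg_panel30 <- function() {
  path <- system.file("extdata", "table1_stability.tsv", package = "ergpanel",
                      mustWork = TRUE)
  df <- read_plain_tsv(path)
  df$rank <- as.integer(df$rank)
  df
}

#' Packaged ChIP peak-evidence table for 29 panel genes
#'
#' ER-alpha peak-significance scores without/with estradiol and the ER-beta
#' signal-to-noise ratio for 29 of the 30 panel genes (LINC02593, a long
#' non-coding RNA, carries no usable evidence and is excluded). Peaks were
#' scored within +/- 10 kb of each gene's transcription start site; see
#' [classify_panel()] for the binding rules. The \code{subtype} column holds
#' the published classification for cross-checking.
#'
#' @return Data frame with columns \code{gene}, \code{q_minus},
#'   \code{q_plus}, \code{sn_ratio}, \code{subtype} (29 rows).
#' @examples
#' ev <- erg_chip_evidence()
#' table(ev$subtype)
#' @export
erg_chip_evidence <- function() {
  path <- system.file("extdata", "table2_peak_evidence.tsv",
                      package = "ergpanel", mustWork = TRUE)
  read_peak_evidence(path)
}
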