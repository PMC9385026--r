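#' @keywords internal
"_PACKAGE"

# Internal helpers shared across the package. Nothing here is exported.

#' Check that a value is a single finite number
#' @noRd
is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' Abort with a consistent message prefix
#' @noRd
abort <- function(..., call. = FALSE) {
  stop(..., call. = call.)
}

#' Write a data.frame as TSV with optional stamped comment header
#'
#' All pipeline reports go through this writer so that identical inputs give
#' byte-identical files. Numbers are serialised with full precision via
#' as.character(); the stamp records the configuration and seed.
#' @noRd
write_stamped_tsv <- function(df, path, stamp = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(stamp)) {
    writeLines(paste0("# ", stamp), con, sep = "\n")
  }
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format(out[[j]], digits = 15L, trim = TRUE, scientific = FALSE)
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a TSV written by write_stamped_tsv (comment lines skipped)
#' @noRd
read_plain_tsv <- function(path, colClasses = NA) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = colClasses)
}

#' Serialise a configuration list into a one-line stamp
#' @noRd
config_stamp <- function(config) {
  flat <- vapply(names(config), function(nm) {
    paste0(nm, "=", paste(format(config[[nm]], digits = 15L), collapse = ","))
  }, character(1))
  paste(flat, collapse = "; ")
}

#' Log to standard error with a level prefix
#' @noRd
log_msg <- function(..., level = "INFO") {
  message(sprintf("[%s] %s", level, paste0(...)))
}
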