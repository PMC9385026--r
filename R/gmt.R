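#' Read a gene-set collection in GMT format
#'
#' GMT is the tab-separated gene-set exchange format: one set per line, with
#' the set name in the first field, a free-text description in the second,
#' and the member genes in the remaining fields. Members are de-duplicated
#' within each set; set names must be unique.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (members per set), with the
#'   descriptions attached as the \code{"descriptions"} attribute.
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines("setA\tdesc\tTP53\tBRCA1", tf)
#' read_gmt(tf)
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      abort("GMT line ", i, " has fewer than 3 fields (name, description, members)")
    }
    nm <- fields[1L]
    if (nm %in% names(sets)) abort("duplicate gene-set name: ", nm)
    members <- unique(fields[-c(1L, 2L)])
    members <- members[nzchar(members)]
    sets[[nm]] <- members
    descs[nm] <- fields[2L]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write a gene-set collection in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions; sets
#'   without one get \code{"na"}.
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions)) descriptions[[nm]] else "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
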