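#' Paired treated/control expression experiment
#'
#' Container for a replicated two-arm FPKM experiment: one matrix per arm,
#' genes in rows, replicates in columns. Replicates are paired by column
#' position (treated replicate i against control replicate i), the convention
#' under which per-replicate response ratios are defined.
#'
#' @param gene_ids Character vector of unique gene symbols (row order).
#' @param treated,control Numeric matrices of non-negative FPKM values with
#'   \code{length(gene_ids)} rows and one column per replicate; both arms must
#'   have the same number of columns.
#' @param replicate_labels Optional labels for the replicate pairs; defaults
#'   to \code{"rep1".."repN"}.
#'
#' @return An object of class \code{"erg_experiment"} with elements
#'   \code{gene_ids}, \code{treated}, \code{control}, \code{replicate_labels}.
#' @examples
#' exp <- erg_experiment(c("A", "B"),
#'                       treated = matrix(c(2, 4, 8, 16), 2),
#'                       control = matrix(c(1, 1, 2, 2), 2))
#' dim(exp$treated)
#' @export
erg_experiment <- function(gene_ids, treated, control, replicate_labels = NULL) {
  gene_ids <- as.character(gene_ids)
  treated <- as.matrix(treated)
  control <- as.matrix(control)
  storage.mode(treated) <- "double"
  storage.mode(control) <- "double"
  if (length(gene_ids) == 0L) abort("experiment must contain at least one gene")
  if (anyNA(gene_ids) || any(gene_ids == "")) abort("gene identifiers must be non-missing and non-empty")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0L) {
    abort("duplicate gene identifier(s): ", paste(unique(dup), collapse = ", "))
  }
  if (nrow(treated) != length(gene_ids) || nrow(control) != length(gene_ids)) {
    abort("arm matrices must have one row per gene identifier")
  }
  if (ncol(treated) != ncol(control)) {
    abort("treated arm has ", ncol(treated), " replicates but control arm has ",
          ncol(control), "; arms must pair replicate-by-replicate")
  }
  if (anyNA(treated) || anyNA(control)) abort("FPKM matrices must not contain missing values")
  if (any(treated < 0) || any(control < 0)) abort("FPKM values must be non-negative")
  if (is.null(replicate_labels)) {
    replicate_labels <- paste0("rep", seq_len(ncol(treated)))
  }
  if (length(replicate_labels) != ncol(treated)) {
    abort("replicate_labels length must equal the replicate count")
  }
  rownames(treated) <- gene_ids
  rownames(control) <- gene_ids
  colnames(treated) <- replicate_labels
  colnames(control) <- replicate_labels
  structure(list(gene_ids = gene_ids, treated = treated, control = control,
                 replicate_labels = as.character(replicate_labels)),
            class = "erg_experiment")
}

#' @export
print.erg_experiment <- function(x, ...) {
  cat(sprintf("erg_experiment: %d genes x %d paired replicates\n",
              length(x$gene_ids), length(x$replicate_labels)))
  invisible(x)
}

#' Read one arm of an expression experiment from TSV
#'
#' The expected format is tab-separated text with a header row: the first
#' column holds gene identifiers, the remaining columns one replicate each.
#' Gene symbols are case-preserved and compared case-sensitively.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix (genes x replicates) with gene identifiers as row
#'   names, in file order.
#' @seealso [erg_experiment()] to pair two arms; [write_expression_matrix()].
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", comment.char = "#")
  if (ncol(df) < 2L) abort("expression file must have a gene column plus at least one replicate column")
  genes <- df[[1L]]
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0L) {
    abort("duplicate gene identifier(s) in ", path, ": ",
          paste(unique(dup), collapse = ", "))
  }
  body <- df[-1L]
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(body),
                dimnames = list(genes, names(body)))
  for (j in seq_along(body)) {
    vals <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(vals) & !is.na(body[[j]]))
    if (anyNA(vals)) {
      row <- if (length(bad) > 0L) bad[1L] else which(is.na(vals))[1L]
      abort("non-numeric value in ", path, " at row ", row,
            " (gene ", genes[row], "), column '", names(body)[j], "'")
    }
    mat[, j] <- vals
  }
  if (any(mat < 0)) abort("negative FPKM value in ", path)
  mat
}

#' Write one arm of an expression experiment as TSV
#'
#' @param mat Numeric matrix with gene identifiers as row names.
#' @param path Output path.
#' @param gene_column Name of the identifier column in the header.
#' @return The path, invisibly.
#' @export
write_expression_matrix <- function(mat, path, gene_column = "gene") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(gene_column, colnames(mat))
  write_stamped_tsv(df, path)
}

#' Assemble an experiment from two arm files
#'
#' @param treated_path,control_path Paths to the treated-arm and control-arm
#'   TSV files. The files must list the same genes in the same order and hold
#'   the same number of replicate columns.
#' @return An [erg_experiment()].
#' @export
read_experiment <- function(treated_path, control_path) {
  treated <- read_expression_matrix(treated_path)
  control <- read_expression_matrix(control_path)
  if (!identical(rownames(treated), rownames(control))) {
    abort("treated and control files must list identical genes in identical order")
  }
  erg_experiment(rownames(treated), treated, control,
                 replicate_labels = colnames(treated))
}
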