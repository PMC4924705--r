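#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix (genes in rows, ordered
#' samples in columns) carrying an `axis_kind` attribute that records what the
#' columns are: developmental time points, patients, or cell lines. All
#' pipeline stages consume this representation.
#'
#' @param values Numeric matrix with unique row and column names.
#' @param axis_kind One of `"timepoints"`, `"patients"`, `"cell_lines"`.
#'   When `"timepoints"`, column order is taken to be the developmental order.
#' @return A numeric matrix of class `"expression_matrix"`.
#' @export
expression_matrix <- function(values,
                              axis_kind = c("timepoints", "patients", "cell_lines")) {
  axis_kind <- match.arg(axis_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  rn <- rownames(values)
  cn <- colnames(values)
  if (is.null(rn) || is.null(cn))
    stop("expression matrix requires row (gene) and column (sample) names",
         call. = FALSE)
  if (anyDuplicated(rn))
    stop("duplicate gene identifiers: ",
         paste(unique(rn[duplicated(rn)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(cn))
    stop("duplicate sample identifiers: ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "), call. = FALSE)
  if (any(!nzchar(cn)) || anyNA(cn))
    stop("missing column labels", call. = FALSE)
  all_na <- rowSums(is.finite(values)) == 0L
  if (any(all_na))
    stop("rows without any finite value: ",
         paste(rn[all_na], collapse = ", "), call. = FALSE)
  structure(values, axis_kind = axis_kind,
            class = c("expression_matrix", class(values)))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%s)\n",
              nrow(x), ncol(x), attr(x, "axis_kind")))
  invisible(x)
}

#' Read an expression matrix from a TSV file
#'
#' The file must be tab-separated with sample identifiers in the first row and
#' gene identifiers in the first column. Column order is preserved. `NA` cells
#' are rejected unless every row keeps at least one finite value (downstream
#' operations that allow pairwise-complete handling state so explicitly).
#'
#' @inheritParams expression_matrix
#' @param path Path to a TSV file.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path,
                                   axis_kind = c("timepoints", "patients", "cell_lines")) {
  axis_kind <- match.arg(axis_kind)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", row.names = NULL)
  if (ncol(raw) < 2L)
    stop("expression file needs a gene-id column plus >=1 sample column",
         call. = FALSE)
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate gene identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) & !(cells %in% c("NA", "")) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                 ids[bad[1L, 1L]], colnames(cells)[bad[1L, 2L]],
                 cells[bad[1L, , drop = FALSE]]), call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(cells))
  expression_matrix(num, axis_kind = axis_kind)
}

#' Write an expression matrix to a TSV file
#'
#' Inverse of [read_expression_matrix()]; missing values are written as `NA`.
#'
#' @param x An [expression_matrix()] (or plain named numeric matrix).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
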