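#' Construct a module partition
#'
#' A module partition maps each gene to a positive integer module label;
#' label 0 marks unassigned genes. Labels of non-empty modules are contiguous
#' from 1.
#'
#' @param assignment Named integer vector (gene id -> module label >= 0).
#' @param stages Optional named character vector (module label as name ->
#'   `"early"`/`"middle"`/`"late"`), used by the synthetic generator's truth.
#' @return A named integer vector of class `"module_partition"`.
#' @export
module_partition <- function(assignment, stages = NULL) {
  if (is.null(names(assignment)) || anyDuplicated(names(assignment)))
    stop("assignment must be a named vector with unique gene ids", call. = FALSE)
  ids <- names(assignment)
  assignment <- as.integer(assignment)
  names(assignment) <- ids
  if (any(assignment < 0L) || anyNA(assignment))
    stop("module labels must be integers >= 0", call. = FALSE)
  labs <- sort(unique(assignment[assignment > 0L]))
  if (length(labs) > 0L && !identical(labs, seq_along(labs)))
    stop("non-zero module labels must be contiguous from 1", call. = FALSE)
  structure(assignment, stages = stages, class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  sz <- module_sizes(x)
  cat(sprintf("<module_partition> %d genes, %d modules (sizes: %s), %d unassigned\n",
              length(x), length(sz), paste(sz, collapse = ", "),
              sum(unclass(x) == 0L)))
  invisible(x)
}

#' Module sizes of a partition
#'
#' @param partition A [module_partition()].
#' @return Integer vector of module sizes, named by module label (label 0,
#'   unassigned, is excluded).
#' @export
module_sizes <- function(partition) {
  v <- unclass(partition)
  v <- v[v > 0L]
  if (length(v) == 0L) return(integer(0))
  tab <- table(v)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Member genes of each module
#'
#' @param partition A [module_partition()].
#' @return Named list, one character vector of gene ids per module label.
#' @export
module_members <- function(partition) {
  v <- unclass(partition)
  split(names(v)[v > 0L], v[v > 0L])
}

#' Write a module partition in GMT-like format
#'
#' One line per module: module id, description, then tab-separated member
#' gene ids. Round-trips through [read_modules()]. Unassigned genes (label 0)
#' are not written.
#'
#' @param partition A non-empty [module_partition()].
#' @param path Output file path.
#' @param descriptions Optional character vector of per-module descriptions.
#' @return `path`, invisibly.
#' @export
write_modules <- function(partition, path, descriptions = NULL) {
  mem <- module_members(partition)
  if (length(mem) == 0L)
    stop("empty partition: nothing to write", call. = FALSE)
  if (is.null(descriptions))
    descriptions <- rep("module", length(mem))
  lines <- vapply(seq_along(mem), function(i) {
    paste(c(paste0("M", names(mem)[i]), descriptions[i], mem[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT-like module file
#'
#' @param path Path written by [write_modules()].
#' @return A [module_partition()] over the genes present in the file.
#' @export
read_modules <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty module file", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  assignment <- integer(0)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3L)
      stop("malformed module line ", i, ": need id, description, >=1 member",
           call. = FALSE)
    lab <- as.integer(sub("^M", "", p[1L]))
    genes <- p[-(1:2)]
    assignment[genes] <- lab
  }
  module_partition(assignment)
}

#' Read a clinical table (sample, time, event, optional covariates)
#'
#' TSV with header columns `sample_id`, `time`, `event` and optionally `age`,
#' `gender`, `race`. `time` must be non-negative and `event` in \{0, 1\}.
#'
#' @param path Path to the TSV file.
#' @param expression Optional paired [expression_matrix()] over patients; when
#'   given, sample ids must be a subset of its columns.
#' @return A `data.frame` of class `"clinical_table"`.
#' @export
read_clinical <- function(path, expression = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  clinical_table(df, expression = expression)
}

#' Validate a clinical table
#'
#' @param df Data frame with columns `sample_id`, `time`, `event` and optional
#'   covariates.
#' @inheritParams read_clinical
#' @return `df` with class `"clinical_table"` prepended.
#' @export
clinical_table <- function(df, expression = NULL) {
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids", call. = FALSE)
  if (any(!is.finite(df$time)) || any(df$time < 0))
    stop("time must be finite and >= 0", call. = FALSE)
  if (!all(df$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (event)", call. = FALSE)
  if (!is.null(expression) && !all(df$sample_id %in% colnames(expression)))
    stop("sample ids absent from the paired expression matrix: ",
         paste(setdiff(df$sample_id, colnames(expression)), collapse = ", "),
         call. = FALSE)
  class(df) <- unique(c("clinical_table", class(df)))
  df
}

#' Write a clinical table to TSV
#'
#' @param df A [clinical_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
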