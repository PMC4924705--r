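#' Construct a validated interaction set
#'
#' STRING-style undirected scored edges. Self-loops are dropped and duplicate
#' unordered pairs are collapsed, keeping the maximum of each score channel
#' (conservative retention).
#'
#' @param gene1,gene2 Character vectors of endpoint identifiers.
#' @param experimental,combined Non-negative integer evidence scores per edge.
#' @return A `data.frame` of class `"interaction_set"` with columns
#'   `gene1`, `gene2` (sorted within each pair), `experimental`, `combined`.
#' @export
interaction_set <- function(gene1, gene2, experimental, combined) {
  n <- length(gene1)
  if (length(gene2) != n || length(experimental) != n || length(combined) != n)
    stop("all edge columns must have the same length", call. = FALSE)
  experimental <- as.numeric(experimental)
  combined <- as.numeric(combined)
  if (anyNA(experimental) || anyNA(combined))
    stop("malformed (non-numeric) score", call. = FALSE)
  if (any(experimental < 0) || any(combined < 0))
    stop("scores must be >= 0", call. = FALSE)
  keep <- gene1 != gene2
  a <- pmin(gene1[keep], gene2[keep])
  b <- pmax(gene1[keep], gene2[keep])
  df <- data.frame(gene1 = a, gene2 = b,
                   experimental = experimental[keep], combined = combined[keep],
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0L) {
    key <- paste(df$gene1, df$gene2, sep = "\r")
    if (anyDuplicated(key)) {
      df <- do.call(rbind, lapply(split(df, key), function(d) {
        data.frame(gene1 = d$gene1[1L], gene2 = d$gene2[1L],
                   experimental = max(d$experimental),
                   combined = max(d$combined), stringsAsFactors = FALSE)
      }))
    }
    df <- df[order(df$gene1, df$gene2), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("interaction_set", "data.frame")
  df
}

#' Read and filter a STRING-style edge list
#'
#' Expects a whitespace- or tab-separated file with a header and columns
#' `protein1`, `protein2`, `experimental`, `combined` (by position if names
#' differ). Edges are kept only when `experimental > experimental_min` and
#' `combined > combined_min` (strict inequalities) and, when `universe` is
#' given, both endpoints belong to it. The operation is idempotent: filtering
#' an already-filtered set changes nothing.
#'
#' @param path Path to the edge-list file.
#' @param experimental_min,combined_min Strict lower score thresholds
#'   (defaults 200 and 400).
#' @param universe Optional character vector restricting edge endpoints.
#' @return An [interaction_set()].
#' @export
read_interactions <- function(path, experimental_min = 200, combined_min = 400,
                              universe = NULL) {
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 4L)
    stop("edge list needs columns protein1, protein2, experimental, combined",
         call. = FALSE)
  suppressWarnings({
    es <- as.numeric(raw[[3L]])
    cs <- as.numeric(raw[[4L]])
  })
  bad <- which(is.na(es) | is.na(cs))
  if (length(bad) > 0L)
    stop("malformed score on line ", bad[1L] + 1L, " of ", path, call. = FALSE)
  x <- interaction_set(raw[[1L]], raw[[2L]], es, cs)
  filter_interactions(x, experimental_min, combined_min, universe)
}

#' Filter an interaction set by score thresholds and gene universe
#'
#' @inheritParams read_interactions
#' @param x An [interaction_set()].
#' @return The filtered [interaction_set()].
#' @export
filter_interactions <- function(x, experimental_min = 200, combined_min = 400,
                                universe = NULL) {
  keep <- x$experimental > experimental_min & x$combined > combined_min
  if (!is.null(universe))
    keep <- keep & x$gene1 %in% universe & x$gene2 %in% universe
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("no interactions survive the score/universe filter", call. = FALSE)
  class(out) <- c("interaction_set", "data.frame")
  out
}

#' Write an interaction set to a STRING-style text file
#'
#' @param x An [interaction_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(x, path) {
  df <- data.frame(protein1 = x$gene1, protein2 = x$gene2,
                   experimental = x$experimental, combined = x$combined)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
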