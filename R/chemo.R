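#' Normalize a drug-response matrix per compound
#'
#' Z-scores each compound's log10(IC50) values across cell lines:
#' `(x - mean) / SD` over the non-missing entries (sample SD). Missing values
#' stay missing. Compounds with zero variance are excluded and reported.
#'
#' @param response Compound x cell-line numeric matrix of log10(IC50) values.
#' @return The normalized matrix; attribute `excluded` names zero-variance
#'   compounds that were dropped.
#' @export
normalize_response <- function(response) {
  n_ok <- rowSums(is.finite(unclass(response)))
  if (any(n_ok < 3L))
    stop("every compound needs >= 3 non-missing values", call. = FALSE)
  mu <- rowMeans(response, na.rm = TRUE)
  sdv <- apply(response, 1L, stats::sd, na.rm = TRUE)
  excluded <- rownames(response)[sdv == 0]
  keep <- sdv > 0
  out <- (unclass(response)[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  if (length(excluded) > 0L)
    warning("zero-variance compound(s) excluded: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  attr(out, "excluded") <- excluded
  class(out) <- c("drug_response_matrix", "matrix", "array")
  out
}

#' Classify cell lines as sensitive / resistant / intermediate
#'
#' For one compound's log10(IC50) vector: values strictly greater than
#' `mu + SD` are resistant, strictly less than `mu - SD` are sensitive, and
#' all others intermediate (boundary values are intermediate). `mu` is the
#' mean and `SD` the sample standard deviation of the non-missing values.
#' Because the rule depends only on the z-position, labels are invariant to
#' affine transformation, so classifying before or after
#' [normalize_response()] gives identical labels.
#'
#' @param values Named numeric vector of log10(IC50) values (>= 3
#'   non-missing).
#' @return List with `labels` (named character over non-missing lines), `mu`,
#'   `sd`, `n_sensitive`, `n_resistant`, `n_intermediate`, `degenerate`
#'   (`TRUE` when SD = 0, in which case every line is intermediate).
#' @export
classify_cell_lines <- function(values) {
  ok <- is.finite(values)
  v <- values[ok]
  if (length(v) < 3L) stop("need >= 3 non-missing values", call. = FALSE)
  mu <- mean(v)
  sdv <- stats::sd(v)
  if (sdv == 0) {
    labels <- rep("intermediate", length(v))
    degenerate <- TRUE
  } else {
    labels <- ifelse(v > mu + sdv, "resistant",
                     ifelse(v < mu - sdv, "sensitive", "intermediate"))
    degenerate <- FALSE
  }
  names(labels) <- names(v)
  list(labels = labels, mu = mu, sd = sdv,
       n_sensitive = sum(labels == "sensitive"),
       n_resistant = sum(labels == "resistant"),
       n_intermediate = sum(labels == "intermediate"),
       degenerate = degenerate)
}

#' Classify every compound of a response matrix
#'
#' @param response Compound x cell-line log10(IC50) matrix.
#' @return Named list of class `"sensitivity_labels"`, one
#'   [classify_cell_lines()] result per compound.
#' @export
classify_response <- function(response) {
  out <- lapply(rownames(response),
                function(cm) classify_cell_lines(response[cm, ]))
  names(out) <- rownames(response)
  class(out) <- "sensitivity_labels"
  out
}

#' Filter compounds by sensitive/resistant group sizes
#'
#' Keeps compounds with at least `min_sensitive` sensitive AND at least
#' `min_resistant` resistant cell lines (inclusive boundaries).
#'
#' @param labels A [classify_response()] result.
#' @param min_sensitive,min_resistant Minimum group sizes (default 10 each).
#' @return Character vector of retained compound ids (with a warning when
#'   empty).
#' @export
filter_compounds <- function(labels, min_sensitive = 10, min_resistant = 10) {
  keep <- vapply(labels, function(l)
    l$n_sensitive >= min_sensitive && l$n_resistant >= min_resistant,
    logical(1))
  out <- names(labels)[keep]
  if (length(out) == 0L)
    warning("no compound passes the sensitive/resistant size filter",
            call. = FALSE)
  out
}

#' Per gene-drug differential expression between sensitive and resistant lines
#'
#' For each (gene, compound) combination, Welch's two-sample t-test of the
#' gene's expression in sensitive versus resistant cell lines (intermediate
#' lines excluded). Combinations where either group has fewer than 2
#' expression values are skipped and counted. When both groups are constant
#' and equal the degenerate convention `t = 0`, `p = 1` applies. No
#' multiple-testing correction is applied by default; an optional BH-FDR
#' column can be added.
#'
#' @param expr An [expression_matrix()] over cell lines.
#' @param labels A [classify_response()] result.
#' @param genes Genes to test (default all rows of `expr`).
#' @param compounds Compounds to test (default all labelled compounds; pass a
#'   [filter_compounds()] result to honour the group-size filter).
#' @param alpha Significance threshold for the `significant` flag
#'   (default 0.05).
#' @param fdr Add a Benjamini-Hochberg adjusted column `p_adjusted`
#'   (default `FALSE`).
#' @return Data frame of class `"chemo_association"` with columns `gene`,
#'   `compound`, `t_statistic`, `p_value`, `mean_sensitive`,
#'   `mean_resistant`, `significant`; attribute `n_skipped` counts
#'   undersized-group combinations.
#' @export
gene_drug_association <- function(expr, labels, genes = rownames(expr),
                                  compounds = names(labels), alpha = 0.05,
                                  fdr = FALSE) {
  missing_genes <- setdiff(genes, rownames(expr))
  if (length(missing_genes) > 0L)
    stop("genes absent from expression matrix: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  rows <- vector("list", length(genes) * length(compounds))
  k <- 0L
  n_skipped <- 0L
  for (cm in compounds) {
    lab <- labels[[cm]]$labels
    sens <- intersect(names(lab)[lab == "sensitive"], colnames(expr))
    res <- intersect(names(lab)[lab == "resistant"], colnames(expr))
    if (length(sens) < 2L || length(res) < 2L) {
      n_skipped <- n_skipped + length(genes)
      next
    }
    for (g in genes) {
      xs <- expr[g, sens]
      xr <- expr[g, res]
      if (stats::sd(xs) == 0 && stats::sd(xr) == 0) {
        tt <- if (mean(xs) == mean(xr)) list(statistic = 0, p.value = 1)
        else list(statistic = sign(mean(xs) - mean(xr)) * Inf, p.value = 0)
      } else {
        ht <- stats::t.test(xs, xr, var.equal = FALSE)
        tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
      }
      k <- k + 1L
      rows[[k]] <- data.frame(gene = g, compound = cm,
                              t_statistic = tt$statistic,
                              p_value = tt$p.value,
                              mean_sensitive = mean(xs),
                              mean_resistant = mean(xr),
                              stringsAsFactors = FALSE)
    }
  }
  out <- if (k > 0L) do.call(rbind, rows[seq_len(k)]) else
    data.frame(gene = character(0), compound = character(0),
               t_statistic = numeric(0), p_value = numeric(0),
               mean_sensitive = numeric(0), mean_resistant = numeric(0))
  out$significant <- out$p_value < alpha
  if (fdr) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("chemo_association", "data.frame")
  out
}
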