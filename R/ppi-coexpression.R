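#' Per-interaction Pearson correlation of expression profiles
#'
#' For every edge of an interaction set, computes the Pearson correlation of
#' the two endpoint profiles over the ordered sample columns. Edges with an
#' endpoint missing from the matrix are skipped; edges where either profile
#' has zero variance (PCC undefined) are excluded and counted. Only pairs with
#' at least 3 shared finite observations are evaluated.
#'
#' @param expr An [expression_matrix()].
#' @param interactions An [interaction_set()].
#' @return Data frame with columns `gene1`, `gene2`, `r`, `n_points`.
#'   Attributes `n_skipped_missing` (endpoint absent) and `n_undefined`
#'   (zero variance or < 3 shared points) report the exclusions.
#' @export
pairwise_pcc <- function(expr, interactions) {
  present <- interactions$gene1 %in% rownames(expr) &
    interactions$gene2 %in% rownames(expr)
  n_missing <- sum(!present)
  edges <- interactions[present, , drop = FALSE]
  n <- nrow(edges)
  r <- rep(NA_real_, n)
  np <- integer(n)
  for (k in seq_len(n)) {
    x <- expr[edges$gene1[k], ]
    y <- expr[edges$gene2[k], ]
    ok <- is.finite(x) & is.finite(y)
    np[k] <- sum(ok)
    if (np[k] < 3L) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    r[k] <- stats::cor(x[ok], y[ok])
  }
  defined <- !is.na(r)
  out <- data.frame(gene1 = edges$gene1[defined], gene2 = edges$gene2[defined],
                    r = r[defined], n_points = np[defined],
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped_missing") <- n_missing
  attr(out, "n_undefined") <- sum(!defined)
  out
}

#' Per-edge correlations in two expression layers
#'
#' Convenience wrapper aligning [pairwise_pcc()] results for the protein and
#' mRNA matrices over the same interaction set. Only edges with a defined
#' correlation in both layers are retained (pairwise-complete exclusion), the
#' number dropped being reported.
#'
#' @param protein,mrna Two [expression_matrix()] objects sharing gene ids.
#' @param interactions An [interaction_set()].
#' @return Data frame of class `"edge_correlations"` with columns `gene1`,
#'   `gene2`, `r_protein`, `r_mrna`; attribute `n_excluded` counts edges
#'   undefined in at least one layer.
#' @export
edge_correlations <- function(protein, mrna, interactions) {
  rp <- pairwise_pcc(protein, interactions)
  rm_ <- pairwise_pcc(mrna, interactions)
  key_p <- paste(rp$gene1, rp$gene2, sep = "\r")
  key_m <- paste(rm_$gene1, rm_$gene2, sep = "\r")
  common <- intersect(key_p, key_m)
  ip <- match(common, key_p)
  im <- match(common, key_m)
  out <- data.frame(gene1 = rp$gene1[ip], gene2 = rp$gene2[ip],
                    r_protein = rp$r[ip], r_mrna = rm_$r[im],
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- nrow(interactions) - nrow(out)
  class(out) <- c("edge_correlations", "data.frame")
  out
}

#' Paired comparison of two correlation sets
#'
#' Two-sided paired t-test on the per-edge difference `r_protein - r_mrna`,
#' testing whether one expression layer reflects the interactions better than
#' the other. If every difference is exactly zero the result is `t = 0`,
#' `p = 1` by convention.
#'
#' @param r_protein,r_mrna Aligned numeric vectors of per-edge correlations
#'   (length >= 2).
#' @return List of class `"paired_comparison"` with `mean_protein`,
#'   `mean_mrna`, `mean_diff`, `t_statistic`, `df`, `p_value`, `n_pairs`.
#' @export
compare_pcc_paired <- function(r_protein, r_mrna) {
  if (length(r_protein) != length(r_mrna))
    stop("correlation lists must be aligned (equal length)", call. = FALSE)
  ok <- is.finite(r_protein) & is.finite(r_mrna)
  r_protein <- r_protein[ok]
  r_mrna <- r_mrna[ok]
  n <- length(r_protein)
  if (n < 2L) stop("need >= 2 complete pairs", call. = FALSE)
  d <- r_protein - r_mrna
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (mean(d) != 0)
      stop("all differences identical and non-zero: t undefined", call. = FALSE)
    t_stat <- 0
    p <- 1
  } else {
    t_stat <- mean(d) / (sd_d / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  structure(list(mean_protein = mean(r_protein), mean_mrna = mean(r_mrna),
                 mean_diff = mean(d), t_statistic = t_stat, df = n - 1,
                 p_value = p, n_pairs = n),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(paste0("Paired comparison of per-interaction correlations\n",
                     "  mean r (protein): %.4f\n  mean r (mRNA):    %.4f\n",
                     "  t = %.3f on %d df, p = %.3g (n = %d pairs)\n"),
              x$mean_protein, x$mean_mrna, x$t_statistic, x$df, x$p_value,
              x$n_pairs))
  invisible(x)
}

#' Paired sorted quantiles of two correlation sets (Q-Q table)
#'
#' Sorts both vectors ascending and pairs them by rank; when lengths differ,
#' the longer vector's quantiles are linearly interpolated onto the shorter
#' length (type-7 quantiles), as for a standard Q-Q plot.
#'
#' @param r_protein,r_mrna Non-empty numeric vectors.
#' @return Data frame with columns `q_protein`, `q_mrna`.
#' @export
qq_table <- function(r_protein, r_mrna) {
  if (length(r_protein) == 0L || length(r_mrna) == 0L)
    stop("empty input", call. = FALSE)
  n <- min(length(r_protein), length(r_mrna))
  probs <- if (n == 1L) 0.5 else seq(0, 1, length.out = n)
  qp <- if (length(r_protein) == n) sort(r_protein) else
    unname(stats::quantile(r_protein, probs, type = 7))
  qm <- if (length(r_mrna) == n) sort(r_mrna) else
    unname(stats::quantile(r_mrna, probs, type = 7))
  data.frame(q_protein = qp, q_mrna = qm)
}
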