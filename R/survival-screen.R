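#' Median-split log-rank test
#'
#' Splits samples at the median expression value (high group: `x > median`,
#' low group: `x <= median`; values equal to the median go to the low group)
#' and compares the two survival curves by the standard two-group log-rank
#' chi-square with 1 degree of freedom. The split depends only on ranks, so
#' the statistic is invariant to monotone transformation of `x`.
#'
#' @inheritParams fit_cox
#' @param x Numeric expression vector.
#' @return List of class `"logrank_test"` with `group` (factor high/low),
#'   `observed`/`expected` events in the high group, `chisq`, `df`,
#'   `p_value`.
#' @export
median_split_logrank <- function(time, event, x) {
  n <- length(time)
  if (length(event) != n || length(x) != n)
    stop("time, event and x must have equal length", call. = FALSE)
  med <- stats::median(x)
  group <- factor(ifelse(x > med, "high", "low"), levels = c("low", "high"))
  if (any(table(group) < 2L))
    stop("median split leaves a group with < 2 samples", call. = FALSE)
  res <- logrank_test(time, event, group == "high")
  structure(c(list(group = group), res), class = "logrank_test")
}

# two-group log-rank: g1 is a logical marking group-1 membership
logrank_test <- function(time, event, g1) {
  ev_times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n_t
    if (n_t > 1L)
      V <- V + d * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d) / (n_t - 1)
  }
  if (V == 0) {
    chisq <- 0
    p <- 1
  } else {
    chisq <- (O1 - E1)^2 / V
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  list(observed = O1, expected = E1, variance = V,
       chisq = chisq, df = 1L, p_value = p)
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf(paste0("Median-split log-rank test\n",
                     "  high group: observed %d events, expected %.2f\n",
                     "  chi-square = %.3f on 1 df, p = %.3g\n"),
              x$observed, x$expected, x$chisq, x$p_value))
  invisible(x)
}

#' Two-cohort reproducibility filter
#'
#' Keeps genes that are significant in the discovery cohort
#' (`p < alpha`), significant in the validation cohort, and directionally
#' consistent (same sign of the log hazard ratio in both cohorts). With
#' `sign_only = TRUE` the validation significance requirement is dropped and
#' only sign agreement is demanded.
#'
#' @param discovery,validation [cox_screen()] results over overlapping genes.
#' @param alpha Significance threshold (default 0.05).
#' @param sign_only Validate by sign agreement alone (default `FALSE`).
#' @return Character vector of validated gene ids; attribute
#'   `n_missing_validation` counts discovery-significant genes absent from
#'   the validation screen (dropped).
#' @export
reproducible_screen <- function(discovery, validation, alpha = 0.05,
                                sign_only = FALSE) {
  if (length(intersect(discovery$gene, validation$gene)) == 0L)
    stop("discovery and validation screens share no genes", call. = FALSE)
  disc_sig <- discovery[discovery$p_value < alpha & !discovery$degenerate, ]
  iv <- match(disc_sig$gene, validation$gene)
  missing <- disc_sig$gene[is.na(iv)]
  disc_sig <- disc_sig[!is.na(iv), ]
  val <- validation[iv[!is.na(iv)], ]
  ok <- sign(disc_sig$beta) == sign(val$beta)
  if (!sign_only) ok <- ok & val$p_value < alpha
  out <- disc_sig$gene[ok]
  attr(out, "n_missing_validation") <- length(missing)
  out
}

#' Permutation test of survival-gene enrichment in a module group
#'
#' Observed statistic: the overlap between a stage group's genes and the set
#' of survival-associated genes. The null resamples `|group_genes|` genes
#' from the universe without replacement `n_perm` times; the p-value uses the
#' `(b + 1) / (B + 1)` estimator, so it is never exactly zero.
#'
#' @param group_genes Genes of the stage group (subset of `universe`).
#' @param significant_genes Survival-associated genes (subset of `universe`).
#' @param universe All genes eligible for resampling.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed (RNG state is restored on exit).
#' @return List of class `"permutation_enrichment"` with `p_value`,
#'   `observed`, `null_mean`, `n_perm`.
#' @export
permutation_group_enrichment <- function(group_genes, significant_genes,
                                         universe, n_perm = 10000,
                                         seed = NULL) {
  if (length(group_genes) < 1L) stop("empty group", call. = FALSE)
  if (length(group_genes) > length(universe))
    stop("group larger than universe", call. = FALSE)
  if (!all(group_genes %in% universe) || !all(significant_genes %in% universe))
    stop("group and significant genes must be subsets of the universe",
         call. = FALSE)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  observed <- length(intersect(group_genes, significant_genes))
  sig <- universe %in% significant_genes
  k <- length(unique(group_genes))
  N <- length(universe)
  null_overlap <- vapply(seq_len(n_perm),
                         function(i) sum(sig[sample.int(N, k)]),
                         numeric(1))
  p <- (1 + sum(null_overlap >= observed)) / (1 + n_perm)
  structure(list(p_value = p, observed = observed,
                 null_mean = mean(null_overlap), n_perm = n_perm),
            class = "permutation_enrichment")
}

#' @export
print.permutation_enrichment <- function(x, ...) {
  cat(sprintf(paste0("Permutation group-enrichment test (%d permutations)\n",
                     "  observed overlap %d (null mean %.2f), p = %.4g\n"),
              x$n_perm, x$observed, x$null_mean, x$p_value))
  invisible(x)
}

#' Two-cohort survival screen over stage groups
#'
#' For each developmental stage group: screens its genes by univariate (or
#' covariate-adjusted) Cox regression in the discovery cohort, re-screens the
#' discovery-significant genes in the validation cohort, applies the
#' reproducibility filter, and tests whether the group is enriched for
#' validated survival genes by permutation over the union of all screened
#' genes.
#'
#' @param expr_discovery,clinical_discovery Discovery cohort: an
#'   [expression_matrix()] over patients and its [clinical_table()].
#' @param expr_validation,clinical_validation Validation cohort.
#' @param partition A [module_partition()] of the genes.
#' @param stages Named character vector: module label -> stage
#'   (as from [group_modules()]).
#' @param alpha Per-gene significance threshold (default 0.05).
#' @param n_perm Permutations for the enrichment test (default 10000).
#' @param seed Integer seed for the permutation null.
#' @param covariates Optional clinical covariate names for adjusted fits.
#' @param sign_only Passed to [reproducible_screen()].
#' @return List of class `"survival_screen"`: per-group list with
#'   `genes`, `discovery` / `validation` screens, `significant` (discovery),
#'   `validated`, `enrichment` (permutation test); plus `universe`.
#' @export
survival_screen <- function(expr_discovery, clinical_discovery,
                            expr_validation, clinical_validation,
                            partition, stages, alpha = 0.05, n_perm = 10000,
                            seed = 1L, covariates = NULL, sign_only = FALSE) {
  members <- module_members(partition)
  group_genes <- lapply(c(early = "early", middle = "middle", late = "late"),
                        function(stg) {
                          mods <- names(stages)[stages == stg]
                          unique(unlist(members[mods], use.names = FALSE))
                        })
  group_genes <- Filter(length, group_genes)
  universe <- unique(unlist(group_genes, use.names = FALSE))
  universe <- intersect(universe, rownames(expr_discovery))
  universe <- intersect(universe, rownames(expr_validation))

  groups <- lapply(names(group_genes), function(stg) {
    genes <- intersect(group_genes[[stg]], universe)
    disc <- cox_screen(expr_discovery, clinical_discovery, genes,
                       covariates = covariates)
    sig <- disc$gene[disc$p_value < alpha & !disc$degenerate]
    val <- if (length(sig) > 0L)
      cox_screen(expr_validation, clinical_validation, sig,
                 covariates = covariates)
    validated <- if (length(sig) > 0L)
      reproducible_screen(disc, val, alpha = alpha, sign_only = sign_only)
    else character(0)
    list(genes = genes, discovery = disc, validation = val,
         significant = sig, validated = as.character(validated))
  })
  names(groups) <- names(group_genes)

  all_validated <- unique(unlist(lapply(groups, `[[`, "validated"),
                                 use.names = FALSE))
  for (stg in names(groups)) {
    groups[[stg]]$enrichment <- permutation_group_enrichment(
      groups[[stg]]$genes, all_validated, universe,
      n_perm = n_perm, seed = seed)
  }
  structure(list(groups = groups, universe = universe,
                 validated = all_validated, alpha = alpha),
            class = "survival_screen")
}

#' @export
print.survival_screen <- function(x, ...) {
  cat("Two-cohort survival screen\n")
  for (stg in names(x$groups)) {
    g <- x$groups[[stg]]
    cat(sprintf("  %-6s %4d genes, %3d discovery-significant, %3d validated, enrichment p = %.4g\n",
                stg, length(g$genes), length(g$significant),
                length(g$validated), g$enrichment$p_value))
  }
  invisible(x)
}
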