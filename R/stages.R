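#' Module activity across time points
#'
#' Scores each module at each time point as the arithmetic mean of its member
#' genes' expression values.
#'
#' @param expr An [expression_matrix()] over time points.
#' @param partition A [module_partition()]; every assigned gene must be a row
#'   of `expr`.
#' @return Matrix (modules x time points) of class `"module_activity"`,
#'   rows named by module label.
#' @export
module_activity <- function(expr, partition) {
  members <- module_members(partition)
  for (mod in names(members)) {
    absent <- setdiff(members[[mod]], rownames(expr))
    if (length(absent) > 0L)
      stop("module ", mod, " member(s) absent from matrix: ",
           paste(absent, collapse = ", "), call. = FALSE)
  }
  act <- t(vapply(members,
                  function(g) colMeans(expr[g, , drop = FALSE]),
                  numeric(ncol(expr))))
  dimnames(act) <- list(names(members), colnames(expr))
  structure(act, class = c("module_activity", "matrix", "array"))
}

#' Group modules into developmental stages
#'
#' Standardizes each module's activity profile (z-score per row), clusters
#' modules by average-linkage on Euclidean distance, cuts the tree into
#' `n_groups` clusters, and labels each cluster early / middle / late by the
#' stage block in which its mean standardized activity is largest. When two
#' clusters claim the same stage, the cluster with the larger block mean
#' keeps it and the other takes its next-best block (a message reports the
#' reassignment).
#'
#' @param activity A [module_activity()] matrix with at least `n_groups`
#'   rows; no module may have a constant activity profile.
#' @param n_groups Number of stage groups (default 3).
#' @param blocks Optional list of `n_groups` integer vectors partitioning the
#'   time-point columns, in developmental order; defaults to consecutive
#'   near-equal thirds.
#' @return Named character vector of class `"stage_groups"`:
#'   module label -> stage name.
#' @export
group_modules <- function(activity, n_groups = 3, blocks = NULL) {
  n_mod <- nrow(activity)
  if (n_mod < n_groups)
    stop("fewer modules than groups", call. = FALSE)
  sds <- apply(activity, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant activity profile for module(s): ",
         paste(rownames(activity)[sds == 0], collapse = ", "),
         "; stage grouping is undefined", call. = FALSE)
  if (is.null(blocks)) {
    blocks <- stage_blocks(ncol(activity))[seq_len(n_groups)]
  }
  if (length(blocks) != n_groups)
    stop("need one column block per group", call. = FALSE)
  stage_names <- if (n_groups == 3) c("early", "middle", "late")
  else paste0("stage", seq_len(n_groups))
  names(blocks) <- stage_names

  z <- t(scale(t(unclass(activity))))
  if (n_mod == n_groups) {
    cl <- seq_len(n_mod)
  } else {
    tree <- average_linkage_tree(as.matrix(stats::dist(z)))
    cl <- stats::cutree(tree, k = n_groups)
  }

  # mean standardized activity of each cluster in each stage block
  block_mean <- matrix(NA_real_, n_groups, n_groups,
                       dimnames = list(paste0("c", seq_len(n_groups)),
                                       stage_names))
  for (ci in seq_len(n_groups)) {
    zc <- colMeans(z[cl == ci, , drop = FALSE])
    block_mean[ci, ] <- vapply(blocks, function(b) mean(zc[b]), numeric(1))
  }

  # greedy assignment by decreasing block mean resolves label collisions
  cluster_stage <- rep(NA_character_, n_groups)
  taken <- character(0)
  collided <- FALSE
  for (step in seq_len(n_groups)) {
    bm <- block_mean
    bm[!is.na(cluster_stage), ] <- -Inf
    bm[, taken] <- -Inf
    hit <- which(bm == max(bm), arr.ind = TRUE)[1L, ]
    ci <- hit[1L]; stage <- stage_names[hit[2L]]
    if (stage != stage_names[which.max(block_mean[ci, ])]) collided <- TRUE
    cluster_stage[ci] <- stage
    taken <- c(taken, stage)
  }
  if (collided)
    message("stage-label collision resolved by block-mean magnitude")

  out <- cluster_stage[cl]
  names(out) <- rownames(activity)
  structure(out, class = "stage_groups")
}

#' @export
print.stage_groups <- function(x, ...) {
  v <- unclass(x)
  for (stg in unique(v))
    cat(sprintf("  %-6s: modules %s\n", stg,
                paste(names(v)[v == stg], collapse = ", ")))
  invisible(x)
}
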