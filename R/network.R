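#' Soft-threshold adjacency of an expression matrix
#'
#' Unsigned weighted network: `a_ij = |cor(x_i, x_j)|^power`, with the
#' diagonal forced to 1. Raising the absolute correlation to a power
#' (soft thresholding) suppresses weak edges while keeping the network
#' continuous.
#'
#' @param expr An [expression_matrix()] (genes x samples, >= 3 samples).
#' @param power Soft-threshold exponent (integer >= 1, default 10).
#' @return Symmetric matrix in \[0, 1\] of class `"adjacency_matrix"` with a
#'   `power` attribute.
#' @export
soft_adjacency <- function(expr, power = 10) {
  if (ncol(expr) < 3L) stop("need >= 3 samples", call. = FALSE)
  if (power < 1) stop("power must be >= 1", call. = FALSE)
  sds <- apply(expr, 1L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene(s): ",
         paste(rownames(expr)[sds == 0], collapse = ", "),
         "; filter before building the network", call. = FALSE)
  a <- abs(stats::cor(t(unclass(expr))))^power
  diag(a) <- 1
  structure(a, power = power, class = c("adjacency_matrix", "matrix", "array"))
}

#' Topological overlap matrix
#'
#' For `i != j`,
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` (u over all other nodes) and connectivity
#' `k_i = sum_u a_iu`; the diagonal is 1. TOM augments direct adjacency with
#' shared-neighbourhood strength; `1 - TOM` is the clustering dissimilarity.
#'
#' @param adj Symmetric adjacency matrix with entries in \[0, 1\] and unit
#'   diagonal (as from [soft_adjacency()]).
#' @return Symmetric matrix in \[0, 1\] of class `"tom_matrix"`.
#' @export
topological_overlap <- function(adj) {
  a <- unclass(adj)
  if (!isSymmetric(unname(a), tol = 1e-10))
    stop("adjacency must be symmetric", call. = FALSE)
  if (any(a < 0) || any(a > 1) || anyNA(a))
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  tom <- (tom + t(tom)) / 2   # remove 1-ulp asymmetry from the matrix product
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  structure(tom, class = c("tom_matrix", "matrix", "array"))
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Standard UPGMA agglomeration over a dissimilarity matrix, returning an
#' `hclust`-compatible tree. Ties in the minimum dissimilarity are broken by
#' merging the pair of clusters with the lexicographically smallest position
#' labels, so the tree is fully deterministic.
#'
#' @param diss Symmetric non-negative dissimilarity matrix with zero
#'   diagonal (a matrix or `dist` object); no missing values.
#' @return An object of class `c("upgma_tree", "hclust")`.
#' @export
average_linkage_tree <- function(diss) {
  d <- as.matrix(diss)
  if (anyNA(d)) stop("NaN/NA in dissimilarity matrix", call. = FALSE)
  if (!isSymmetric(unname(d), tol = 1e-10))
    stop("dissimilarity must be symmetric", call. = FALSE)
  if (any(diag(d) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (any(d < 0)) stop("dissimilarities must be >= 0", call. = FALSE)
  n <- nrow(d)
  if (n < 2L) stop("need >= 2 items", call. = FALSE)
  d <- (d + t(d)) / 2   # exact symmetry so ties appear in both triangles
  labels <- rownames(d)
  id <- -seq_len(n)               # hclust coding: negative = leaf
  size <- rep(1L, n)
  alive <- rep(TRUE, n)
  D <- d
  diag(D) <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    Dv <- D
    Dv[!alive, ] <- Inf
    Dv[, !alive] <- Inf
    m <- min(Dv)
    hit <- which(Dv == m, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- hit[1L, 1L]; j <- hit[1L, 2L]
    pair <- c(id[i], id[j])
    merge[s, ] <- pair[order(pair)]
    height[s] <- m
    # Lance-Williams update for average linkage
    upd <- alive & seq_len(n) != i & seq_len(n) != j
    D[i, upd] <- (size[i] * D[i, upd] + size[j] * D[j, upd]) /
      (size[i] + size[j])
    D[upd, i] <- D[i, upd]
    size[i] <- size[i] + size[j]
    alive[j] <- FALSE
    id[i] <- s
  }
  order_ <- tree_leaf_order(merge)
  structure(list(merge = merge, height = height, order = order_,
                 labels = labels, method = "average",
                 dist.method = "user-supplied",
                 call = match.call()),
            class = c("upgma_tree", "hclust"))
}

# leaf order by left-to-right traversal of the merge tree (iterative)
tree_leaf_order <- function(merge) {
  n <- nrow(merge) + 1L
  stack <- nrow(merge)
  out <- integer(0)
  while (length(stack) > 0L) {
    node <- stack[1L]
    stack <- stack[-1L]
    if (node < 0L) {
      out <- c(out, -node)
    } else {
      stack <- c(merge[node, 1L], merge[node, 2L], stack)
    }
  }
  out
}

#' Extract modules from a dendrogram by dynamic tree cut
#'
#' A simple "tree" flavour of dynamic branch cutting. The dendrogram is first
#' cut statically at `cut_height` (default the 99th percentile of merge
#' heights); each resulting branch is then split recursively at its top merge
#' whenever both sub-branches reach `min_module_size` and the branches are
#' separated: under average linkage the top-merge height equals the mean
#' cross-branch dissimilarity, so a merge is a between-module join when that
#' height exceeds `split_ratio` times the larger of the two sub-branches'
#' internal mean dissimilarities. Branches smaller than `min_module_size` are
#' merged into the closest module by average dissimilarity when that distance
#' is within `cut_height`, and otherwise left unassigned (label 0). If the
#' static cut leaves no branch of `min_module_size` (a tree without
#' structure, e.g. all dissimilarities equal), the whole tree is reported as
#' a single module. Module labels are sorted by decreasing size.
#'
#' @param tree An `hclust`-like tree (e.g. from [average_linkage_tree()]).
#' @param diss The dissimilarity matrix the tree was built from.
#' @param min_module_size Smallest admissible module (integer >= 2, default 5).
#' @param cut_height Static cut height; default 0.9 of the tallest merge,
#'   which strips the unstructured top of the tree where isolated genes
#'   attach.
#' @param split_ratio Minimum ratio of cross-branch to within-branch mean
#'   dissimilarity for a recursive split (default 1.12).
#' @return A [module_partition()] over the tree's leaves.
#' @export
dynamic_tree_cut <- function(tree, diss, min_module_size = 5,
                             cut_height = NULL, split_ratio = 1.12) {
  if (min_module_size < 2) stop("min_module_size must be >= 2", call. = FALSE)
  d <- as.matrix(diss)
  h <- tree$height
  n <- nrow(tree$merge) + 1L
  if (n < min_module_size)
    stop("tree has fewer items than min_module_size", call. = FALSE)
  if (is.null(cut_height))
    cut_height <- 0.9 * max(h)

  members <- vector("list", n - 1L)   # leaves of each internal node
  for (s in seq_len(n - 1L)) {
    kids <- tree$merge[s, ]
    members[[s]] <- c(if (kids[1L] < 0L) -kids[1L] else members[[kids[1L]]],
                      if (kids[2L] < 0L) -kids[2L] else members[[kids[2L]]])
  }
  node_members <- function(node)
    if (node < 0L) -node else members[[node]]

  # components after the static cut: subtrees whose top merge is below the
  # cut while the parent merge (if any) is above it
  parent <- integer(n - 1L)
  for (s in seq_len(n - 1L)) {
    kids <- tree$merge[s, ]
    for (kid in kids[kids > 0L]) parent[kid] <- s
  }
  roots <- integer(0)       # internal-node roots of components
  single <- integer(0)      # singleton leaf components
  for (s in seq_len(n - 1L)) {
    above <- h[s] > cut_height
    par_above <- parent[s] == 0L || h[parent[s]] > cut_height
    if (!above && par_above) roots <- c(roots, s)
    if (above) {
      kids <- tree$merge[s, ]
      for (kid in kids[kids < 0L]) single <- c(single, -kid)
    }
  }
  if (parent[n - 1L] == 0L && h[n - 1L] <= cut_height) {
    # whole tree below the cut: single component rooted at the top
    roots <- n - 1L
    single <- integer(0)
  }

  mean_within <- function(mem) {
    if (length(mem) < 2L) return(0)
    sub <- d[mem, mem, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }
  # h[node] is the mean cross-branch dissimilarity under average linkage, so
  # a merge separates its branches when it exceeds the branches' internal
  # scatter by split_ratio. When one branch is below min_module_size it is
  # peeled off (small branches are re-attached to their closest module
  # afterwards) and descent continues into the large branch.
  split_branch <- function(node) {
    if (node < 0L) return(list(-node))
    kids <- tree$merge[node, ]
    m1 <- node_members(kids[1L])
    m2 <- node_members(kids[2L])
    big_enough <- c(length(m1), length(m2)) >= min_module_size
    if (all(big_enough)) {
      within <- max(mean_within(m1), mean_within(m2))
      if (within == 0 || h[node] >= split_ratio * within)
        return(c(split_branch(kids[1L]), split_branch(kids[2L])))
    } else if (any(big_enough)) {
      large <- which(big_enough)[1L]
      large_mem <- if (large == 1L) m1 else m2
      small_mem <- if (large == 1L) m2 else m1
      within <- mean_within(large_mem)
      if (within == 0 || h[node] >= split_ratio * within)
        return(c(list(small_mem),
                 split_branch(kids[large])))
    }
    list(node_members(node))
  }
  branches <- c(unlist(lapply(roots, split_branch), recursive = FALSE),
                lapply(single, identity))

  sizes <- vapply(branches, length, integer(1))
  big <- branches[sizes >= min_module_size]
  small <- branches[sizes < min_module_size]
  if (length(big) == 0L) {
    # no structure at all (e.g. all dissimilarities equal): one module
    big <- list(seq_len(n))
    small <- list()
  }
  assignment <- integer(n)
  if (length(big) > 0L) {
    # deterministic ordering: by decreasing size, then smallest member index
    ord <- order(-vapply(big, length, integer(1)),
                 vapply(big, min, integer(1)))
    big <- big[ord]
    for (m in seq_along(big)) assignment[big[[m]]] <- m
    for (br in small) {
      avg <- vapply(big, function(mod) mean(d[br, mod, drop = FALSE]),
                    numeric(1))
      if (min(avg) <= cut_height)
        assignment[br] <- which.min(avg)
    }
    # re-sort labels by final (post-merge) size
    assignment <- relabel_by_size(assignment)
  }
  labels <- tree$labels
  if (is.null(labels)) labels <- sprintf("item%04d", seq_len(n))
  names(assignment) <- labels
  module_partition(assignment)
}

# compact non-zero labels to 1..K ordered by decreasing size
# (ties: smaller first-member index first)
relabel_by_size <- function(assignment) {
  labs <- unique(assignment[assignment > 0L])
  if (length(labs) == 0L) return(assignment)
  sz <- vapply(labs, function(l) sum(assignment == l), integer(1))
  first <- vapply(labs, function(l) which(assignment == l)[1L], integer(1))
  labs <- labs[order(-sz, first)]
  out <- assignment
  for (m in seq_along(labs)) out[assignment == labs[m]] <- m
  out
}

#' Filter module members by within-module interactions
#'
#' Within each module, keeps only genes with at least one interaction to
#' another member of the same module; modules left without any internally
#' interacting gene are dropped entirely, and labels are re-compacted by
#' decreasing size. This reproduces the screen step where a co-expression
#' module whose members do not interact is discarded.
#'
#' @param partition A [module_partition()].
#' @param interactions An [interaction_set()].
#' @return The filtered [module_partition()] (removed genes become label 0).
#' @export
filter_modules_by_ppi <- function(partition, interactions) {
  v <- unclass(partition)
  out <- integer(length(v))
  names(out) <- names(v)
  for (mod in module_members(partition)) {
    sub <- interactions$gene1 %in% mod & interactions$gene2 %in% mod
    connected <- unique(c(interactions$gene1[sub], interactions$gene2[sub]))
    keep <- intersect(mod, connected)
    out[keep] <- v[keep]
  }
  out <- relabel_by_size(out)
  module_partition(out)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, used
#' to measure recovery of planted module structure. 1 means identical
#' partitions (up to label permutation), 0 the expectation under independent
#' random labelings.
#'
#' @param a,b Label vectors over the same items (any atomic type).
#' @return The adjusted Rand index (numeric scalar).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("partitions must cover the same items", call. = FALSE)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}
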