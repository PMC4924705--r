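test_that("soft adjacency equals elementwise |cor|^power", {
  set.seed(21)
  m <- matrix(rnorm(60), 10, 6,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("t%d", 1:6)))
  expr <- expression_matrix(m, "timepoints")
  adj <- soft_adjacency(expr, power = 10)
  for (i in 1:10) for (j in 1:10) {
    expected <- if (i == j) 1 else abs(cor(m[i, ], m[j, ]))^10
    expect_equal(adj[i, j], expected, tolerance = 1e-12)
  }
  # correlation of exactly -0.5 maps to 0.5^10 = 1/1024
  e2 <- expression_matrix(matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE,
                                 dimnames = list(c("a", "b"), c("t1", "t2", "t3"))),
                          "timepoints")
  expect_equal(soft_adjacency(e2, 10)["a", "b"], 1 / 1024, tolerance = 1e-12)

  cm <- rbind(a = c(1, 1, 1), b = c(1, 2, 3))
  colnames(cm) <- c("t1", "t2", "t3")
  const <- expression_matrix(cm, "timepoints")
  expect_error(soft_adjacency(const), "zero-variance.*a")
})

test_that("topological overlap matches the formula in closed cases", {
  # 2-node network with a = 1: TOM = 1
  a2 <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(topological_overlap(a2)[1, 2], 1)

  # empty off-diagonal network: TOM = 0 off-diagonal
  a0 <- diag(4)
  t0 <- topological_overlap(a0)
  expect_equal(max(t0[upper.tri(t0)]), 0)

  expect_error(topological_overlap(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
  expect_error(topological_overlap(matrix(c(1, 2, 2, 1), 2, 2)), "0, 1")
})

test_that("topological overlap agrees with the brute-force triple loop", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    a <- random_adjacency(n)
    expect_lt(max(abs(unclass(topological_overlap(a)) - tom_brute_force(a))),
              1e-12)
  }
})

test_that("TOM entries stay within [0, 1] on random adjacencies", {
  set.seed(32)
  for (rep in 1:20) {
    tm <- topological_overlap(random_adjacency(sample(4:25, 1)))
    expect_gte(min(tm), 0)
    expect_lte(max(tm), 1)
  }
})

test_that("average linkage reproduces known merge structures", {
  # two tight pairs far apart: first merges at 0.1, final at >= 0.9
  d <- matrix(0.9, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.1
  diag(d) <- 0
  tree <- average_linkage_tree(d)
  expect_equal(tree$height[1:2], c(0.1, 0.1))
  expect_gte(tree$height[3], 0.9)

  # three items at equal distance: all merge heights equal d
  d3 <- matrix(0.4, 3, 3); diag(d3) <- 0
  expect_equal(average_linkage_tree(d3)$height, c(0.4, 0.4))

  expect_error(average_linkage_tree(matrix(c(0, NA, NA, 0), 2, 2)), "NaN|NA")
})

test_that("average linkage agrees with the reference agglomeration", {
  set.seed(33)
  for (rep in 1:5) {
    pts <- matrix(rnorm(24), 12)
    d <- as.matrix(dist(pts))
    mine <- average_linkage_tree(d)
    ref <- hclust(as.dist(d), method = "average")
    expect_equal(mine$height, ref$height, tolerance = 1e-12)
    # identical partitions at every k
    for (k in c(2, 4, 6))
      expect_equal(adjusted_rand_index(cutree(mine, k), cutree(ref, k)), 1)
  }
})

test_that("dynamic tree cut recovers planted block structure", {
  # two clean blocks
  d <- matrix(0.9, 40, 40)
  d[1:20, 1:20] <- 0.1
  d[21:40, 21:40] <- 0.1
  diag(d) <- 0
  part <- dynamic_tree_cut(average_linkage_tree(d), d)
  expect_equal(unname(module_sizes(part)), c(20L, 20L))

  # no structure: a single module containing everything
  deq <- matrix(0.5, 8, 8); diag(deq) <- 0
  part_eq <- dynamic_tree_cut(average_linkage_tree(deq), deq,
                              min_module_size = 2)
  expect_equal(unname(module_sizes(part_eq)), 8L)

  expect_error(dynamic_tree_cut(average_linkage_tree(d), d,
                                min_module_size = 1), ">= 2")
})

test_that("the network pipeline is deterministic and recovers planted modules", {
  spec <- development_sim_spec(c(30, 30, 30, 30),
                               c("early", "middle", "late", "early"),
                               rho = 0.9)
  dev <- simulate_development(spec, seed = 13)
  tom <- topological_overlap(soft_adjacency(dev$protein, 10))
  diss <- 1 - unclass(tom)
  p1 <- dynamic_tree_cut(average_linkage_tree(diss), diss)
  p2 <- dynamic_tree_cut(average_linkage_tree(diss), diss)
  expect_identical(p1, p2)
  expect_gte(adjusted_rand_index(unclass(p1), unclass(dev$truth)), 0.9)
})

test_that("added noise does not improve module recovery on average", {
  base_spec <- development_sim_spec(c(30, 30, 30),
                                    c("early", "middle", "late"), rho = 0.95)
  ari_at_noise <- function(extra_sd) {
    mean(vapply(1:5, function(s) {
      dev <- simulate_development(base_spec, seed = s)
      set.seed(1000 + s)
      noisy <- unclass(dev$protein) +
        matrix(rnorm(length(dev$protein), 0, extra_sd), nrow(dev$protein))
      dimnames(noisy) <- dimnames(dev$protein)
      tom <- topological_overlap(
        soft_adjacency(expression_matrix(noisy, "timepoints"), 10))
      part <- dynamic_tree_cut(average_linkage_tree(1 - unclass(tom)),
                               1 - unclass(tom))
      adjusted_rand_index(unclass(part), unclass(dev$truth))
    }, numeric(1)))
  }
  curve <- vapply(c(0, 0.8, 2.5), ari_at_noise, numeric(1))
  expect_true(all(diff(curve) <= 1e-8))
})

test_that("PPI filtering keeps internally interacting genes only", {
  part <- module_partition(c(A = 1L, B = 1L, C = 1L, D = 2L, E = 2L,
                             F = 3L, G = 3L))
  edges <- interaction_set(c("A", "F", "A"), c("B", "G", "D"),
                           rep(300, 3), rep(500, 3))
  filt <- filter_modules_by_ppi(part, edges)
  mem <- module_members(filt)
  # module {A,B,C} with only edge (A,B): C removed; cross-module edge A-D
  # does not rescue module 2, which has no internal edge and is dropped
  expect_equal(sort(unlist(mem, use.names = FALSE)), c("A", "B", "F", "G"))
  expect_equal(length(mem), 2L)
  expect_equal(unclass(filt)[["C"]], 0L)
  expect_equal(unclass(filt)[["D"]], 0L)

  # a module forming a clique is a fixed point
  clique <- interaction_set(c("A", "A", "B"), c("B", "C", "C"),
                            rep(300, 3), rep(500, 3))
  p1 <- module_partition(c(A = 1L, B = 1L, C = 1L))
  expect_identical(module_members(filter_modules_by_ppi(p1, clique)),
                   module_members(p1))
})

test_that("adjusted Rand index matches the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(77)
  for (rep in 1:10) {
    a <- sample(1:4, 50, TRUE)
    b <- sample(1:3, 50, TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(rep(1:2, 10), rep(2:1, 10)), 1)
})
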