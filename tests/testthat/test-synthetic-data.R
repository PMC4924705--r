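test_that("every generator is deterministic under a fixed seed", {
  spec <- development_sim_spec(c(10, 10), c("early", "late"), background = 5)
  d1 <- simulate_development(spec, seed = 3)
  d2 <- simulate_development(spec, seed = 3)
  expect_identical(d1, d2)

  p1 <- simulate_ppi(d1$truth, 0.5, 0.05, seed = 9)
  expect_identical(p1, simulate_ppi(d1$truth, 0.5, 0.05, seed = 9))

  sspec <- survival_sim_spec(30, c(g0001 = 0.5), n_noise_genes = 3)
  expect_identical(simulate_survival_cohort(sspec, seed = 5),
                   simulate_survival_cohort(sspec, seed = 5))

  dspec <- drug_sim_spec(n_drugs = 4, n_genes = 6,
                         planted_pairs = data.frame(gene = "gene001",
                                                    drug = "drug001",
                                                    delta = 2))
  expect_identical(simulate_drug_response(dspec, seed = 2),
                   simulate_drug_response(dspec, seed = 2))
})

test_that("development generator plants stage-peaked correlated modules", {
  # noiseless limit: rho = 1 makes module members identical
  spec <- development_sim_spec(8, "middle", rho = 1)
  dev <- simulate_development(spec, seed = 1)
  cm <- cor(t(unclass(dev$protein)))
  expect_equal(min(cm), 1, tolerance = 1e-12)

  # block means of the module average profile peak in the declared stage
  spec3 <- development_sim_spec(c(20, 20, 20), c("early", "middle", "late"),
                                rho = 0.9)
  dev3 <- simulate_development(spec3, seed = 2)
  act <- module_activity(dev3$protein, dev3$truth)
  blocks <- list(1:3, 4:6, 7:9)
  for (m in 1:3) {
    bm <- vapply(blocks, function(b) mean(act[m, b]), numeric(1))
    expect_equal(which.max(bm), m)
  }

  expect_error(development_sim_spec(c(10, 10), "early"), "same length")
  expect_error(development_sim_spec(10, "early", rho = 1.2), "rho")
})

test_that("within-module correlation matches the design value rho", {
  mean_pcc <- vapply(1:20, function(s) {
    dev <- simulate_development(development_sim_spec(50, "early", rho = 0.8),
                                seed = s)
    cm <- cor(t(unclass(dev$protein)))
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  expect_lt(abs(mean(mean_pcc) - 0.8), 0.05)
})

test_that("mRNA layer tracks the protein layer at the requested agreement", {
  dev <- planted_development(seed = 8, agreement = 0.6)
  per_gene <- vapply(seq_len(nrow(dev$protein)), function(i)
    cor(dev$protein[i, ], dev$mrna[i, ]), numeric(1))
  expect_lt(abs(mean(per_gene) - 0.6), 0.1)
})

test_that("PPI generator respects edge probabilities and score filters", {
  truth <- module_partition(
    stats::setNames(c(rep(1L, 6), rep(2L, 5)), sprintf("g%02d", 1:11)))
  # p_within = 1, p_between = 0: union of within-module cliques
  full <- simulate_ppi(truth, 1, 0, seed = 1)
  expect_equal(nrow(full), choose(6, 2) + choose(5, 2))
  same_mod <- unclass(truth)[full$gene1] == unclass(truth)[full$gene2]
  expect_true(all(same_mod))

  # p_within = 0 (and 0 between) gives the empty set
  expect_equal(nrow(simulate_ppi(truth, 0, 0, seed = 1)), 0L)

  # binomial expectation on a 20-gene module at p = 0.3
  t20 <- module_partition(stats::setNames(rep(1L, 20), sprintf("g%02d", 1:20)))
  counts <- vapply(1:30, function(s)
    nrow(simulate_ppi(t20, 0.3, 0, seed = s)), numeric(1))
  expected <- 0.3 * choose(20, 2)
  sigma <- sqrt(choose(20, 2) * 0.3 * 0.7)
  expect_lt(abs(mean(counts) - expected), 3 * sigma / sqrt(30))

  # every simulated edge survives the default read filters
  expect_true(all(full$experimental > 200 & full$combined > 400))
  expect_error(simulate_ppi(truth, 0.2, 0.5, seed = 1), "p_between")
})

test_that("survival generator obeys the exponential null and recovers beta", {
  # all beta = 0 with negligible censoring: events ~ Exp(baseline_rate)
  spec <- survival_sim_spec(800, baseline_rate = 0.2, censor_rate = 1e-6,
                            n_noise_genes = 1)
  ch <- simulate_survival_cohort(spec, seed = 4)
  expect_gte(mean(ch$clinical$event), 0.99)
  ks <- suppressWarnings(ks.test(ch$clinical$time, "pexp", 0.2))
  expect_gt(ks$p.value, 0.01)

  # parameter recovery through the Cox screen at n = 1000
  spec2 <- survival_sim_spec(1000, c(g1 = 0.7))
  ch2 <- simulate_survival_cohort(spec2, seed = 12)
  fit <- fit_cox(ch2$clinical$time, ch2$clinical$event,
                 ch2$expression["g1", ])
  expect_lt(abs(fit$beta - 0.7), 0.15)

  expect_error(
    simulate_survival_cohort(
      survival_sim_spec(10, c(missing_gene = 1)),
      expression = expression_matrix(
        matrix(rnorm(10), 1, 10,
               dimnames = list("g1", sprintf("s%02d", 1:10))), "patients")),
    "missing_gene")
})

test_that("drug-response generator plants detectable group differences", {
  dspec <- drug_sim_spec(n_drugs = 3, n_genes = 5,
                         planted_pairs = data.frame(gene = "gene002",
                                                    drug = "drug002",
                                                    delta = 3))
  sim <- simulate_drug_response(dspec, seed = 6)
  lab <- classify_cell_lines(sim$response["drug002", ])
  sens <- names(lab$labels)[lab$labels == "sensitive"]
  res <- names(lab$labels)[lab$labels == "resistant"]
  gap <- mean(sim$expression["gene002", res]) -
    mean(sim$expression["gene002", sens])
  expect_lt(abs(gap - 3), 1.5)  # planted difference delta, up to noise

  expect_error(drug_sim_spec(n_drugs = 2, n_cell_lines = 10), "25")
})
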