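test_that("fit_cox matches the reference partial-likelihood maximizer", {
  skip_if_not_installed("survival")
  set.seed(51)
  for (rep in 1:10) {
    n <- sample(20:40, 1)
    x <- rnorm(n)
    time <- rexp(n, 0.2 * exp(0.5 * x))
    event <- rbinom(n, 1, 0.7)
    if (sum(event) < 2) next
    fit <- fit_cox(time, event, x)
    ref <- survival::coxph(survival::Surv(time, event) ~ x,
                           ties = "breslow")
    if (!fit$converged || abs(unname(coef(ref))) > 10) next
    expect_equal(fit$beta, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(fit$se, unname(sqrt(vcov(ref)[1, 1])), tolerance = 1e-6)
  }

  # tied event times and categorical covariate adjustment
  set.seed(52)
  n <- 50
  x <- rnorm(n)
  age <- rnorm(n, 60, 10)
  sex <- sample(c("f", "m"), n, TRUE)
  time <- ceiling(rexp(n, 0.1 * exp(0.4 * x)))
  event <- rbinom(n, 1, 0.7)
  fit <- fit_cox(time, event, x, covariates = data.frame(age = age,
                                                         sex = sex))
  ref <- survival::coxph(survival::Surv(time, event) ~ x + age + sex,
                         ties = "breslow")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
})

test_that("fit_cox agrees with the grid-search likelihood oracle", {
  set.seed(53)
  for (rep in 1:5) {
    d <- random_cox_dataset()
    expect_lt(abs(d$fit$beta - cox_grid_oracle(d$time, d$event, d$x)), 1e-3)
  }
  # the alternating 6-sample design has an interior maximum
  fit <- fit_cox(1:6, rep(1, 6), c(1, 0, 1, 0, 1, 0))
  expect_lt(abs(fit$beta - cox_grid_oracle(1:6, rep(1, 6),
                                           c(1, 0, 1, 0, 1, 0))), 1e-3)
})

test_that("fit_cox handles degenerate and invalid inputs", {
  fit <- fit_cox(c(1, 2, 3, 4), c(1, 1, 0, 1), rep(2, 4))
  expect_true(fit$degenerate)
  expect_equal(fit$beta, 0)
  expect_equal(fit$p_value, 1)
  expect_error(fit_cox(c(1, 2, 3), c(0, 0, 1), c(1, 2, 3)), "events")
  # complete separation is flagged, not silently reported
  sep_fit <- fit_cox(c(1, 2, 3, 4, 10, 11, 12, 13),
                     rep(1, 8), c(rep(1, 4), rep(0, 4)))
  expect_false(sep_fit$converged)
})

test_that("median-split log-rank matches hand-checkable structure", {
  skip_if_not_installed("survival")
  # identical (time, event) multisets in both groups: chi-square 0, p 1
  time <- c(1, 2, 3, 4, 1, 2, 3, 4)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1)
  x <- c(1, 1, 1, 1, 9, 9, 9, 9)
  ml <- median_split_logrank(time, event, x)
  expect_equal(ml$chisq, 0)
  expect_equal(ml$p_value, 1)

  set.seed(54)
  n <- 30
  x2 <- rnorm(n)
  t2 <- rexp(n, exp(x2))
  e2 <- rbinom(n, 1, 0.8)
  mine <- median_split_logrank(t2, e2, x2)
  ref <- survival::survdiff(survival::Surv(t2, e2) ~ I(x2 > median(x2)))
  expect_equal(mine$chisq, ref$chisq, tolerance = 1e-12)

  # invariant under monotone transformation of expression
  trans <- median_split_logrank(t2, e2, exp(x2))
  expect_equal(trans$chisq, mine$chisq, tolerance = 1e-12)

  expect_error(median_split_logrank(t2, e2, rep(1, n)), "group")
})

test_that("hazard directions agree between Cox and the median split", {
  spec <- survival_sim_spec(200, c(g1 = 1.5))
  ch <- simulate_survival_cohort(spec, seed = 55)
  fit <- fit_cox(ch$clinical$time, ch$clinical$event, ch$expression["g1", ])
  ml <- median_split_logrank(ch$clinical$time, ch$clinical$event,
                             ch$expression["g1", ])
  expect_gt(fit$beta, 0)
  # higher expression means higher hazard: more events than expected in the
  # high group
  expect_gt(ml$observed, ml$expected)
  expect_lt(ml$p_value, 0.05)
})

test_that("the reproducibility filter demands significance and sign agreement", {
  mk <- function(gene, beta, p)
    data.frame(gene = gene, beta = beta, p_value = p, degenerate = FALSE)
  disc <- rbind(mk("a", 0.5, 0.01), mk("b", 0.5, 0.01), mk("c", 0.5, 0.01),
                mk("d", 0.5, 0.20), mk("e", -0.4, 0.02))
  val <- rbind(mk("a", 0.3, 0.01), mk("b", -0.3, 0.01), mk("c", 0.3, 0.20),
               mk("d", 0.5, 0.01), mk("e", -0.2, 0.03))
  out <- reproducible_screen(disc, val)
  expect_equal(sort(as.character(out)), c("a", "e"))

  # sign-only validation keeps directionally consistent genes regardless of
  # validation significance
  out2 <- reproducible_screen(disc, val, sign_only = TRUE)
  expect_equal(sort(as.character(out2)), c("a", "c", "e"))

  # genes absent from validation are dropped and counted
  out3 <- reproducible_screen(disc, val[val$gene != "a", ])
  expect_equal(attr(out3, "n_missing_validation"), 1L)
})

test_that("permutation enrichment is exact, smoothed and reproducible", {
  univ <- sprintf("g%02d", 1:20)
  # group = universe: every draw ties the observed overlap
  all_p <- permutation_group_enrichment(univ, univ[1:7], univ,
                                        n_perm = 200, seed = 1)
  expect_equal(all_p$p_value, 1)

  # matches the exact hypergeometric tail within Monte-Carlo error
  res <- permutation_group_enrichment(univ[1:5], univ[1:4], univ,
                                      n_perm = 10000, seed = 2)
  exact <- phyper(3, 4, 16, 5, lower.tail = FALSE)
  mc_se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(res$p_value - exact), 3 * mc_se)
  expect_gt(res$p_value, 0)  # (b+1)/(B+1) smoothing: never exactly zero

  # reproducible under a fixed seed, without clobbering the caller's RNG
  set.seed(99); before <- runif(1)
  r1 <- permutation_group_enrichment(univ[1:5], univ[1:4], univ,
                                     n_perm = 500, seed = 7)
  r2 <- permutation_group_enrichment(univ[1:5], univ[1:4], univ,
                                     n_perm = 500, seed = 7)
  expect_identical(r1, r2)

  expect_error(permutation_group_enrichment(sprintf("x%d", 1:5),
                                            univ[1], univ), "subset")
  expect_error(permutation_group_enrichment(c(univ, "extra"), univ[1],
                                            univ), "larger than")
})

test_that("the two-cohort screen flags the planted prognostic group", {
  spec <- development_sim_spec(rep(20, 3), c("early", "middle", "late"),
                               rho = 0.9)
  dev <- simulate_development(spec, seed = 56)
  part <- dev$truth
  stages <- attr(part, "stages")
  genes <- names(part)
  prog <- module_members(part)[["1"]][1:6]   # six early-module genes
  betas <- stats::setNames(rep(0.9, 6), prog)
  mk_cohort <- function(n, seed) {
    expr <- expression_matrix(
      matrix(rnorm(length(genes) * n), length(genes), n,
             dimnames = list(genes, sprintf("p%03d", 1:n))), "patients")
    simulate_survival_cohort(survival_sim_spec(n, betas), expr, seed = seed)
  }
  d <- mk_cohort(120, 57)
  v <- mk_cohort(200, 58)
  scr <- survival_screen(d$expression, d$clinical, v$expression, v$clinical,
                         part, stages, n_perm = 500, seed = 59)
  expect_gt(length(scr$groups$early$validated), 0)
  expect_true(all(scr$groups$early$validated %in%
                    scr$groups$early$significant))
  enrich_p <- vapply(scr$groups, function(g) g$enrichment$p_value, numeric(1))
  expect_equal(unname(which.min(enrich_p)), 1L)  # early group most enriched
})
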