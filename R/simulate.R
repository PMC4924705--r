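#' Simulation design for a developmental time series with planted modules
#'
#' Describes a protein/mRNA time-series experiment with co-expressed gene
#' modules peaking at distinct developmental stages. The time axis (default 9
#' points) is split into three consecutive blocks (early / middle / late); a
#' module's template profile has mean 1 inside its stage block and mean -0.5
#' elsewhere, jittered per time point with sd `noise_sd` so that modules
#' sharing a stage remain distinguishable. Per-gene observation noise is
#' scaled from the realized template variance so that the expected
#' within-module pairwise Pearson correlation is approximately `rho`.
#'
#' @param module_sizes Integer vector of planted module sizes (each >= 1).
#' @param stages Character vector (same length) of peak stages, each one of
#'   `"early"`, `"middle"`, `"late"`.
#' @param rho Target within-module correlation in (0, 1]; scalar or one value
#'   per module.
#' @param n_timepoints Number of ordered time points (default 9).
#' @param background Number of unassigned pure-noise genes (default 0).
#' @param noise_sd Template jitter / background profile sd (> 0, default 0.4).
#' @param mrna_agreement Target per-gene correlation between the protein and
#'   mRNA profiles, in \[0, 1\] (default 0.6).
#' @return A list of class `"development_sim_spec"`.
#' @export
development_sim_spec <- function(module_sizes, stages, rho = 0.9,
                                 n_timepoints = 9, background = 0,
                                 noise_sd = 0.4, mrna_agreement = 0.6) {
  if (length(module_sizes) != length(stages))
    stop("module_sizes and stages must have the same length", call. = FALSE)
  if (any(module_sizes < 1L))
    stop("module sizes must be >= 1", call. = FALSE)
  if (!all(stages %in% c("early", "middle", "late")))
    stop("stages must be 'early', 'middle' or 'late'", call. = FALSE)
  rho <- rep_len(rho, length(module_sizes))
  if (any(rho <= 0) || any(rho > 1))
    stop("rho must lie in (0, 1]", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (mrna_agreement < 0 || mrna_agreement > 1)
    stop("mrna_agreement must lie in [0, 1]", call. = FALSE)
  if (n_timepoints < 3L) stop("need >= 3 time points", call. = FALSE)
  structure(list(module_sizes = as.integer(module_sizes), stages = stages,
                 rho = rho, n_timepoints = as.integer(n_timepoints),
                 background = as.integer(background), noise_sd = noise_sd,
                 mrna_agreement = mrna_agreement),
            class = "development_sim_spec")
}

# consecutive early/middle/late column blocks (near-equal thirds)
stage_blocks <- function(n_timepoints) {
  cut_pts <- round(n_timepoints * c(1, 2) / 3)
  list(early = seq_len(cut_pts[1]),
       middle = seq(cut_pts[1] + 1L, cut_pts[2]),
       late = seq(cut_pts[2] + 1L, n_timepoints))
}

#' Simulate paired protein/mRNA developmental expression with planted modules
#'
#' Each planted module receives a stage-peaked template; member genes are the
#' template plus independent Gaussian noise calibrated to the module's target
#' within-module correlation. The mRNA profile of a gene is its protein
#' profile plus further independent noise scaled so that the protein/mRNA
#' profile correlation is approximately `mrna_agreement` (0 yields an
#' independent noise profile). Background genes are pure noise. Deterministic
#' under a fixed seed.
#'
#' @param spec A [development_sim_spec()].
#' @param seed Integer seed.
#' @return List with elements `protein` and `mrna` (both
#'   [expression_matrix()] over time points) and `truth`, a
#'   [module_partition()] whose `stages` attribute maps module labels to
#'   their planted stage.
#' @export
simulate_development <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "development_sim_spec"))
  set.seed(seed)
  tp <- spec$n_timepoints
  blocks <- stage_blocks(tp)
  n_mod <- length(spec$module_sizes)
  n_genes <- sum(spec$module_sizes) + spec$background
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  tp_ids <- sprintf("t%02d", seq_len(tp))

  protein <- matrix(NA_real_, n_genes, tp, dimnames = list(gene_ids, tp_ids))
  assignment <- integer(n_genes)
  names(assignment) <- gene_ids
  row <- 0L
  # per-stage orthogonal bases: each module's identity jitter is made
  # sample-orthogonal to the stage block pattern and to the jitters of
  # earlier modules of the same stage, so that planted modules are
  # distinguishable by construction (between-template correlation is then
  # var_block / (var_block + noise_sd^2), not a random draw)
  basis <- list()
  for (m in seq_len(n_mod)) {
    stage <- spec$stages[m]
    pattern <- rep(-0.5, tp)
    pattern[blocks[[stage]]] <- 1
    if (is.null(basis[[stage]]))
      basis[[stage]] <- matrix(pattern / sqrt(sum(pattern^2)), ncol = 1L)
    B <- basis[[stage]]
    jitter <- stats::rnorm(tp, 0, spec$noise_sd)
    resid <- jitter - B %*% crossprod(B, jitter)
    if (sum(resid^2) > 1e-12 && ncol(B) < tp) {
      jitter <- drop(resid) * sqrt(sum(jitter^2) / sum(resid^2))
      basis[[stage]] <- cbind(B, jitter / sqrt(sum(jitter^2)))
    }
    template <- pattern + jitter
    v_t <- stats::var(template)
    sd_g <- sqrt(v_t * (1 - spec$rho[m]) / spec$rho[m])
    sz <- spec$module_sizes[m]
    idx <- row + seq_len(sz)
    protein[idx, ] <- matrix(rep(template, each = sz), sz, tp) +
      matrix(stats::rnorm(sz * tp, 0, sd_g), sz, tp)
    assignment[idx] <- m
    row <- row + sz
  }
  if (spec$background > 0L) {
    idx <- row + seq_len(spec$background)
    protein[idx, ] <- matrix(stats::rnorm(spec$background * tp, 0, spec$noise_sd),
                             spec$background, tp)
  }

  a <- spec$mrna_agreement
  prot_sd <- apply(protein, 1L, stats::sd)
  if (a == 0) {
    mrna <- matrix(stats::rnorm(n_genes * tp), n_genes, tp) * prot_sd
  } else {
    extra_sd <- prot_sd * sqrt(1 / a^2 - 1)
    mrna <- protein + matrix(stats::rnorm(n_genes * tp), n_genes, tp) * extra_sd
  }
  dimnames(mrna) <- dimnames(protein)

  stages <- spec$stages
  names(stages) <- as.character(seq_len(n_mod))
  list(protein = expression_matrix(protein, "timepoints"),
       mrna = expression_matrix(mrna, "timepoints"),
       truth = module_partition(assignment, stages = stages))
}

#' Simulate a PPI edge list enriched within planted modules
#'
#' Every unordered pair of genes sharing a (non-zero) module becomes an edge
#' with probability `p_within`; every other pair with probability
#' `p_between`. Scores are drawn strictly above the default STRING-style
#' thresholds so every edge survives [read_interactions()] filtering.
#'
#' @param truth A [module_partition()] (label 0 = background).
#' @param p_within,p_between Edge probabilities, `0 <= p_between < p_within <= 1`.
#' @param seed Integer seed.
#' @return An [interaction_set()].
#' @export
simulate_ppi <- function(truth, p_within, p_between = 0, seed = 1L) {
  if (p_between >= p_within && p_within != 0)
    stop("p_between must be < p_within", call. = FALSE)
  if (p_between > p_within)
    stop("p_between must be <= p_within", call. = FALSE)
  if (p_within < 0 || p_within > 1 || p_between < 0 || p_between > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  genes <- names(truth)
  lab <- unclass(truth)
  n <- length(genes)
  ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- sequence((n - 1L):1L) + ii
  same <- lab[ii] == lab[jj] & lab[ii] > 0L
  p <- ifelse(same, p_within, p_between)
  keep <- stats::runif(length(p)) < p
  if (!any(keep)) {
    out <- interaction_set(character(0), character(0), numeric(0), numeric(0))
    return(out)
  }
  ne <- sum(keep)
  interaction_set(genes[ii[keep]], genes[jj[keep]],
                  sample(300:999, ne, replace = TRUE),
                  sample(500:999, ne, replace = TRUE))
}

#' Simulation design for a proportional-hazards survival cohort
#'
#' @param n_samples Number of patients (>= 2).
#' @param gene_betas Named numeric vector: log-hazard coefficient per unit
#'   expression for each prognostic gene (may be empty).
#' @param baseline_rate Exponential baseline hazard rate (> 0, default 0.1).
#' @param censor_rate Exponential censoring rate (> 0, default 0.05).
#' @param n_noise_genes Additional genes with no survival effect, used when no
#'   expression matrix is supplied (default 0).
#' @param covariate_effects Optional named list with any of `age`, `gender`,
#'   `race`: per-unit log-hazard coefficients (age is centred at 60 years
#'   internally; gender codes male = 1; race contributes via two indicator
#'   levels, supply a length-2 vector).
#' @return A list of class `"survival_sim_spec"`.
#' @export
survival_sim_spec <- function(n_samples, gene_betas = numeric(0),
                              baseline_rate = 0.1, censor_rate = 0.05,
                              n_noise_genes = 0, covariate_effects = NULL) {
  if (n_samples < 2L) stop("n_samples must be >= 2", call. = FALSE)
  if (baseline_rate <= 0 || censor_rate <= 0)
    stop("rates must be > 0", call. = FALSE)
  if (length(gene_betas) > 0L && is.null(names(gene_betas)))
    stop("gene_betas must be named by gene id", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples), gene_betas = gene_betas,
                 baseline_rate = baseline_rate, censor_rate = censor_rate,
                 n_noise_genes = as.integer(n_noise_genes),
                 covariate_effects = covariate_effects),
            class = "survival_sim_spec")
}

#' Simulate a survival cohort with planted log-hazard gene effects
#'
#' Event times are exponential with rate
#' `baseline_rate * exp(sum(beta_g * x_g) + covariate terms)`; censoring times
#' are independent exponential with rate `censor_rate`; the observed time is
#' the minimum and the event indicator marks which came first, so the
#' proportional-hazards structure holds by construction.
#'
#' @param spec A [survival_sim_spec()].
#' @param expression Optional [expression_matrix()] (genes x patients). When
#'   absent, expression for all prognostic and noise genes is drawn iid
#'   standard normal.
#' @param seed Integer seed.
#' @return List with `expression` ([expression_matrix()] over patients) and
#'   `clinical` (a [clinical_table()]).
#' @export
simulate_survival_cohort <- function(spec, expression = NULL, seed = 1L) {
  stopifnot(inherits(spec, "survival_sim_spec"))
  set.seed(seed)
  n <- spec$n_samples
  ids <- sprintf("s%04d", seq_len(n))
  if (is.null(expression)) {
    genes <- names(spec$gene_betas)
    if (spec$n_noise_genes > 0L)
      genes <- c(genes, sprintf("noise%04d", seq_len(spec$n_noise_genes)))
    if (length(genes) == 0L)
      stop("no genes: supply gene_betas, n_noise_genes or an expression matrix",
           call. = FALSE)
    expression <- matrix(stats::rnorm(length(genes) * n), length(genes), n,
                         dimnames = list(genes, ids))
    expression <- expression_matrix(expression, "patients")
  } else {
    if (ncol(expression) != n)
      stop("expression must have n_samples columns", call. = FALSE)
    ids <- colnames(expression)
    missing_genes <- setdiff(names(spec$gene_betas), rownames(expression))
    if (length(missing_genes) > 0L)
      stop("gene_betas reference genes absent from expression: ",
           paste(missing_genes, collapse = ", "), call. = FALSE)
  }

  lp <- rep(0, n)
  if (length(spec$gene_betas) > 0L)
    lp <- lp + drop(crossprod(expression[names(spec$gene_betas), , drop = FALSE],
                              spec$gene_betas))
  clin <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  ce <- spec$covariate_effects
  if (!is.null(ce)) {
    clin$age <- round(stats::rnorm(n, 60, 10), 1)
    clin$gender <- sample(c("female", "male"), n, replace = TRUE)
    clin$race <- sample(c("asian", "black", "white"), n, replace = TRUE)
    if (!is.null(ce$age)) lp <- lp + ce$age * (clin$age - 60)
    if (!is.null(ce$gender)) lp <- lp + ce$gender * (clin$gender == "male")
    if (!is.null(ce$race)) {
      rc <- rep_len(ce$race, 2L)
      lp <- lp + rc[1L] * (clin$race == "black") + rc[2L] * (clin$race == "white")
    }
  }
  t_event <- stats::rexp(n, rate = spec$baseline_rate * exp(lp))
  t_cens <- stats::rexp(n, rate = spec$censor_rate)
  clin$time <- pmin(t_event, t_cens)
  clin$event <- as.integer(t_event <= t_cens)
  list(expression = expression, clinical = clinical_table(clin, expression))
}

#' Simulation design for an NCI-60-style drug-response screen
#'
#' @param n_drugs Number of compounds.
#' @param n_cell_lines Number of cell lines (>= 25 so that sensitive/resistant
#'   filtering can succeed; default 60).
#' @param n_genes Number of expression genes (default 50).
#' @param planted_pairs Optional data frame with columns `gene`, `drug`,
#'   `delta`: the planted difference in mean expression between sensitive and
#'   resistant lines for that compound.
#' @param ic50_noise_sd Scale of the standard-normal log10(IC50) values
#'   (default 1).
#' @return A list of class `"drug_sim_spec"`.
#' @export
drug_sim_spec <- function(n_drugs, n_cell_lines = 60, n_genes = 50,
                          planted_pairs = NULL, ic50_noise_sd = 1) {
  if (n_cell_lines < 25L)
    stop("n_cell_lines must be >= 25", call. = FALSE)
  if (!is.null(planted_pairs)) {
    stopifnot(all(c("gene", "drug", "delta") %in% names(planted_pairs)))
    if (any(!is.finite(planted_pairs$delta)))
      stop("delta must be finite", call. = FALSE)
  }
  if (ic50_noise_sd <= 0) stop("ic50_noise_sd must be > 0", call. = FALSE)
  structure(list(n_drugs = as.integer(n_drugs),
                 n_cell_lines = as.integer(n_cell_lines),
                 n_genes = as.integer(n_genes),
                 planted_pairs = planted_pairs,
                 ic50_noise_sd = ic50_noise_sd),
            class = "drug_sim_spec")
}

#' Simulate a drug-response screen with planted gene-drug effects
#'
#' log10(IC50) values are iid normal per compound. For each planted
#' (gene, drug) pair the gene's expression is shifted by `-delta/2` in the
#' cell lines classified sensitive for that drug (mu - SD rule) and by
#' `+delta/2` in resistant lines, so the sensitive/resistant group difference
#' equals `delta`. All other gene-drug combinations are independent.
#'
#' @param spec A [drug_sim_spec()].
#' @param seed Integer seed.
#' @return List with `response` (compound x cell-line log10(IC50) matrix of
#'   class `"drug_response_matrix"`), `expression` ([expression_matrix()] over
#'   cell lines) and `truth` (the planted pairs, possibly `NULL`).
#' @export
simulate_drug_response <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "drug_sim_spec"))
  set.seed(seed)
  cl <- sprintf("cl%03d", seq_len(spec$n_cell_lines))
  drugs <- sprintf("drug%03d", seq_len(spec$n_drugs))
  genes <- sprintf("gene%03d", seq_len(spec$n_genes))
  response <- matrix(stats::rnorm(spec$n_drugs * spec$n_cell_lines,
                                  0, spec$ic50_noise_sd),
                     spec$n_drugs, spec$n_cell_lines,
                     dimnames = list(drugs, cl))
  class(response) <- c("drug_response_matrix", class(response))
  expr <- matrix(stats::rnorm(spec$n_genes * spec$n_cell_lines),
                 spec$n_genes, spec$n_cell_lines,
                 dimnames = list(genes, cl))
  pp <- spec$planted_pairs
  if (!is.null(pp)) {
    for (k in seq_len(nrow(pp))) {
      if (!pp$gene[k] %in% genes || !pp$drug[k] %in% drugs)
        stop("planted pair references unknown gene or drug", call. = FALSE)
      lab <- classify_cell_lines(response[pp$drug[k], ])
      sens <- names(lab$labels)[lab$labels == "sensitive"]
      res <- names(lab$labels)[lab$labels == "resistant"]
      expr[pp$gene[k], sens] <- expr[pp$gene[k], sens] - pp$delta[k] / 2
      expr[pp$gene[k], res] <- expr[pp$gene[k], res] + pp$delta[k] / 2
    }
  }
  list(response = response,
       expression = expression_matrix(expr, "cell_lines"),
       truth = pp)
}
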