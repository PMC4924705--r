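#' Default pipeline configuration over synthetic inputs
#'
#' Bundles every stage parameter plus simulation designs for all four input
#' kinds (developmental time series, PPI edges, two survival cohorts, drug
#' response). All derived seeds come from the single `seed`, so a
#' configuration maps deterministically to its results.
#'
#' @param seed Global integer seed (default 1).
#' @param outdir Output directory for stage artifacts (default
#'   `tempfile("coexsurv-run")`).
#' @param ... Named overrides of any default element (validated by name).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("coexsurv-run"),
                            ...) {
  cfg <- list(
    seed = as.integer(seed),
    outdir = outdir,
    # developmental time series: 6 modules, 2 per stage, plus noise genes
    development = development_sim_spec(
      module_sizes = c(40, 35, 32, 30, 28, 25),
      stages = c("early", "early", "middle", "middle", "late", "late"),
      rho = 0.9, n_timepoints = 9, background = 40,
      noise_sd = 0.4, mrna_agreement = 0.6),
    ppi = list(p_within = 0.25, p_between = 0.02),
    # network / module parameters
    power = 10, min_module_size = 5, cut_height = NULL, split_ratio = 1.12,
    n_groups = 3, stage_blocks = NULL,
    # survival screen: discovery cohort of 60 patients, larger validation
    n_discovery = 60, n_validation = 200,
    baseline_rate = 0.1, censor_rate = 0.05,
    prognostic = list(stage = "early", n_genes = 8, beta = 0.8),
    alpha = 0.05, n_perm = 2000, covariates = NULL, sign_only = FALSE,
    # chemoresponse screen
    n_drugs = 40, n_cell_lines = 60,
    chemo_planted = list(n_pairs = 3, delta = 3),
    min_sensitive = 10, min_resistant = 10)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0L)
    stop("unknown configuration element(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

# small FNV-1a hash over the deparsed configuration, for output provenance
# (the output directory is excluded: it is not part of the analysis)
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL
  txt <- paste(deparse(cfg), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_stage_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# coexsurv %s config_hash=%s",
                     as.character(utils::packageVersion("coexsurv")), hash),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-to-screen analysis pipeline
#'
#' Executes, in order: input simulation, protein-vs-mRNA interaction
#' co-expression comparison, co-expression module detection (soft adjacency,
#' topological overlap, average-linkage clustering, dynamic tree cut, PPI
#' filter), stage grouping, the two-cohort Cox survival screen with
#' permutation group enrichment, and the chemoresponse association screen.
#' Each stage writes a TSV artifact into `config$outdir` (with a provenance
#' header) and logs its filter counts; the run is a pure function of the
#' configuration.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log messages (default `FALSE`).
#' @return A list of class `"pipeline_run"` with each stage's in-memory
#'   result plus `summary`, a key-value data frame of headline counts.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_ <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  seed <- config$seed

  # --- stage 1: simulate inputs -------------------------------------------
  dev <- simulate_development(config$development, seed = seed)
  ppi <- simulate_ppi(dev$truth, config$ppi$p_within, config$ppi$p_between,
                      seed = seed + 1L)
  log_("simulate: %d genes x %d time points, %d interactions",
       nrow(dev$protein), ncol(dev$protein), nrow(ppi))

  # --- stage 2: protein vs mRNA co-expression over interactions -----------
  ec <- edge_correlations(dev$protein, dev$mrna, ppi)
  cmp <- compare_pcc_paired(ec$r_protein, ec$r_mrna)
  write_stage_tsv(ec, file.path(config$outdir, "edge_correlations.tsv"), hash)
  log_("coexpress: %d edges, mean r protein %.3f vs mRNA %.3f (p = %.3g)",
       cmp$n_pairs, cmp$mean_protein, cmp$mean_mrna, cmp$p_value)

  # --- stage 3: co-expression modules -------------------------------------
  adj <- soft_adjacency(dev$protein, power = config$power)
  tom <- topological_overlap(adj)
  tree <- average_linkage_tree(1 - unclass(tom))
  partition <- dynamic_tree_cut(tree, 1 - unclass(tom),
                                min_module_size = config$min_module_size,
                                cut_height = config$cut_height,
                                split_ratio = config$split_ratio)
  filtered <- filter_modules_by_ppi(partition, ppi)
  n_dropped_genes <- sum(unclass(partition) > 0L) - sum(unclass(filtered) > 0L)
  write_modules(filtered, file.path(config$outdir, "modules.gmt"))
  assign_df <- data.frame(gene = names(filtered),
                          module = as.integer(unclass(filtered)))
  write_stage_tsv(assign_df, file.path(config$outdir, "module_assignment.tsv"),
                  hash)
  log_("modules: %d detected (sizes %s), PPI filter dropped %d genes, %d modules kept",
       length(module_sizes(partition)),
       paste(module_sizes(partition), collapse = "/"),
       n_dropped_genes, length(module_sizes(filtered)))

  # --- stage 4: module activity and stage groups --------------------------
  activity <- module_activity(dev$protein, filtered)
  stages <- group_modules(activity, n_groups = config$n_groups,
                          blocks = config$stage_blocks)
  act_df <- data.frame(module = rownames(activity), unclass(activity),
                       stage = unclass(stages), check.names = FALSE)
  write_stage_tsv(act_df, file.path(config$outdir, "module_stages.tsv"), hash)
  log_("stages: %s", paste(sprintf("%s=%s", names(unclass(stages)),
                                   unclass(stages)), collapse = " "))

  # --- stage 5: two-cohort survival screen --------------------------------
  assigned <- names(filtered)[unclass(filtered) > 0L]
  set.seed(seed + 2L)
  prog <- config$prognostic
  target_mods <- names(stages)[unclass(stages) == prog$stage]
  pool <- unlist(module_members(filtered)[target_mods], use.names = FALSE)
  prog_genes <- utils::head(pool, prog$n_genes)
  betas <- stats::setNames(rep(prog$beta, length(prog_genes)), prog_genes)
  spec_d <- survival_sim_spec(config$n_discovery, betas,
                              baseline_rate = config$baseline_rate,
                              censor_rate = config$censor_rate)
  spec_v <- survival_sim_spec(config$n_validation, betas,
                              baseline_rate = config$baseline_rate,
                              censor_rate = config$censor_rate)
  expr_d <- expression_matrix(
    matrix(stats::rnorm(length(assigned) * config$n_discovery),
           length(assigned), config$n_discovery,
           dimnames = list(assigned, sprintf("d%04d", seq_len(config$n_discovery)))),
    "patients")
  expr_v <- expression_matrix(
    matrix(stats::rnorm(length(assigned) * config$n_validation),
           length(assigned), config$n_validation,
           dimnames = list(assigned, sprintf("v%04d", seq_len(config$n_validation)))),
    "patients")
  cohort_d <- simulate_survival_cohort(spec_d, expr_d, seed = seed + 3L)
  cohort_v <- simulate_survival_cohort(spec_v, expr_v, seed = seed + 4L)
  screen <- survival_screen(cohort_d$expression, cohort_d$clinical,
                            cohort_v$expression, cohort_v$clinical,
                            filtered, stages, alpha = config$alpha,
                            n_perm = config$n_perm, seed = seed + 5L,
                            covariates = config$covariates,
                            sign_only = config$sign_only)
  screen_df <- do.call(rbind, lapply(names(screen$groups), function(stg) {
    d <- screen$groups[[stg]]$discovery
    d$stage <- stg
    d
  }))
  write_stage_tsv(screen_df, file.path(config$outdir, "cox_discovery.tsv"),
                  hash)
  for (stg in names(screen$groups))
    log_("survival (%s): %d screened, %d significant, %d validated, enrichment p = %.4g",
         stg, length(screen$groups[[stg]]$genes),
         length(screen$groups[[stg]]$significant),
         length(screen$groups[[stg]]$validated),
         screen$groups[[stg]]$enrichment$p_value)

  # --- stage 6: chemoresponse ---------------------------------------------
  n_pl <- config$chemo_planted$n_pairs
  chemo_spec <- drug_sim_spec(
    n_drugs = config$n_drugs, n_cell_lines = config$n_cell_lines,
    n_genes = max(20L, 2L * n_pl),
    planted_pairs = if (n_pl > 0) data.frame(
      gene = sprintf("gene%03d", seq_len(n_pl)),
      drug = sprintf("drug%03d", seq_len(n_pl)),
      delta = rep(config$chemo_planted$delta, n_pl)))
  chemo <- simulate_drug_response(chemo_spec, seed = seed + 6L)
  labels <- classify_response(chemo$response)
  retained <- filter_compounds(labels, config$min_sensitive,
                               config$min_resistant)
  assoc <- if (length(retained) > 0L)
    gene_drug_association(chemo$expression, labels, compounds = retained,
                          alpha = config$alpha)
  else gene_drug_association(chemo$expression, labels,
                             compounds = character(0), alpha = config$alpha)
  write_stage_tsv(assoc, file.path(config$outdir, "chemo_association.tsv"),
                  hash)
  log_("chemo: %d/%d compounds retained, %d significant gene-drug pairs",
       length(retained), config$n_drugs, sum(assoc$significant))

  # --- summary ------------------------------------------------------------
  kv <- list(
    config_hash = hash,
    seed = seed,
    n_genes = nrow(dev$protein),
    n_interactions = nrow(ppi),
    n_edges_compared = cmp$n_pairs,
    mean_r_protein = sprintf("%.6f", cmp$mean_protein),
    mean_r_mrna = sprintf("%.6f", cmp$mean_mrna),
    paired_t_p = sprintf("%.6g", cmp$p_value),
    n_modules = length(module_sizes(partition)),
    module_sizes = paste(module_sizes(partition), collapse = "/"),
    n_modules_after_ppi = length(module_sizes(filtered)),
    stage_assignment = paste(sprintf("%s=%s", names(unclass(stages)),
                                     unclass(stages)), collapse = ";"))
  for (stg in names(screen$groups)) {
    g <- screen$groups[[stg]]
    kv[[paste0(stg, "_screened")]] <- length(g$genes)
    kv[[paste0(stg, "_significant")]] <- length(g$significant)
    kv[[paste0(stg, "_validated")]] <- length(g$validated)
    kv[[paste0(stg, "_enrichment_p")]] <- sprintf("%.6g", g$enrichment$p_value)
  }
  kv$compounds_retained <- length(retained)
  kv$gene_drug_significant <- sum(assoc$significant)
  summary_df <- data.frame(key = names(kv),
                           value = vapply(kv, as.character, character(1)))
  write_stage_tsv(summary_df, file.path(config$outdir, "summary.tsv"), hash)

  structure(list(config = config, truth = dev$truth,
                 comparison = cmp, partition = partition,
                 filtered_partition = filtered, activity = activity,
                 stages = stages, screen = screen,
                 chemo = list(labels = labels, retained = retained,
                              association = assoc, truth = chemo$truth),
                 summary = summary_df),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("coexsurv pipeline run\n")
  df <- x$summary
  cat(sprintf("  %-24s %s\n", df$key, df$value), sep = "")
  invisible(x)
}
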