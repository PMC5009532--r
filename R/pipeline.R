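# End-to-end orchestration of the method on synthetic cohorts:
# DCEA -> DEA -> DRA -> seed assembly -> per-cohort NMF consensus subtyping
# and survival ordering -> cross-cohort signature -> random baseline ->
# regulatory networks. All randomness flows from one master seed; per-stage
# seeds are derived with small fixed offsets.

#' Pipeline configuration
#'
#' @param seed Master RNG seed (all stage seeds derive from it).
#' @param sim A [sim_config()] defining the synthetic study conditions.
#' @param n_cohorts Number of subtyped tumor cohorts (default 4).
#' @param n_rewired Number of rewired TF modules in the two-condition design
#'   (default 4). All rewired TFs carry subtype programs in the tumor
#'   cohorts; the ones landing in the extreme-prognosis subtypes (3 of 4
#'   under the defaults, mirroring a 6-DRG/3-signature situation) are the
#'   planted signature truth, while intermediate-subtype TFs should be
#'   filtered out by the best/worst consensus.
#' @param dcea_q,dcea_delta,dcea_alpha,n_perm DCEA parameters (see
#'   [run_dcea()]).
#' @param dea_alpha DEG q cutoff.
#' @param dra_alpha DRG q cutoff; `n_rand` TDD resampling draws.
#' @param n_rand TDD resampling draws.
#' @param k_range,n_runs,tau,max_iter,tol Subtyping parameters (see
#'   [subtype_cohort()]).
#' @param baseline_draws Random signatures for the baseline (default 20).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = NULL,
                            n_cohorts = 4L,
                            n_rewired = 4L,
                            dcea_q = 0.75, dcea_delta = 0.5,
                            dcea_alpha = 0.25, n_perm = 200,
                            dea_alpha = 0.05,
                            dra_alpha = 0.05, n_rand = 500,
                            k_range = 2:4, n_runs = 20, tau = 0.90,
                            max_iter = 500, tol = 1e-5,
                            baseline_draws = 20) {
  seed <- as.integer(seed)
  if (is.null(sim)) {
    sim <- sim_config(seed = seed, n_genes = 150L, n_tfs = 10L,
                      targets_per_tf = 8L, n_normal = 50L, n_tumor = 50L,
                      beta_tumor = c(rep(0, n_rewired),
                                     rep(0.9, 10L - n_rewired)),
                      n_samples = 120L)
  }
  structure(list(seed = seed, sim = sim, n_cohorts = as.integer(n_cohorts),
                 n_rewired = as.integer(n_rewired),
                 dcea_q = dcea_q, dcea_delta = dcea_delta,
                 dcea_alpha = dcea_alpha, n_perm = n_perm,
                 dea_alpha = dea_alpha, dra_alpha = dra_alpha,
                 n_rand = n_rand, k_range = k_range, n_runs = n_runs,
                 tau = tau, max_iter = max_iter, tol = tol,
                 baseline_draws = baseline_draws),
            class = "pipeline_config")
}

#' Run the full signature-discovery pipeline on synthetic cohorts
#'
#' Simulates a two-condition (tumor vs normal) cohort with rewired TF
#' modules, runs differential coexpression, differential expression and
#' differential regulation analysis to assemble seed genes; simulates
#' `n_cohorts` subtyped tumor cohorts sharing the planted signature TFs,
#' subtypes each by NMF consensus clustering on the seed genes and orders
#' clusters by prognosis; intersects best/worst-prognosis cluster genes
#' across cohorts and restricts to TFs to obtain the final signature; and
#' (optionally) evaluates the random-signature baseline on the first cohort.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every stage table is
#'   written there as TSV together with a `manifest.tsv` of seeds and
#'   thresholds.
#' @param baseline Logical: run the random-signature baseline (default TRUE).
#' @return List of class `pipeline_result` with elements `two_condition`,
#'   `dcea`, `dea`, `ranking`, `drgs`, `drl`, `seeds`, `cohorts` (per-cohort
#'   subtyping, ordering and log-rank), `consensus`, `signature`,
#'   `signature_logrank_p`, `baseline`, and `truth`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         baseline = TRUE) {
  cfg <- config
  sim <- cfg$sim
  # --- stage 1: two-condition differential regulation ---------------------
  tc <- simulate_two_condition(sim)
  dc <- run_dcea(tc$expr, conditions = c("normal", "tumor"), q = cfg$dcea_q,
                 delta = cfg$dcea_delta, alpha = cfg$dcea_alpha,
                 n_perm = cfg$n_perm, seed = cfg$seed + 11L)
  de <- differential_expression(tc$expr, conditions = c("normal", "tumor"),
                                alpha = cfg$dea_alpha)
  dcgs <- dc$gene_table$gene[dc$gene_table$is_dcg]
  degs <- de$gene[de$is_deg]
  ranking <- rank_regulators(tc$library, dcgs, dcl_pairs(dc),
                             universe = genes(tc$expr),
                             alpha = cfg$dra_alpha, n_rand = cfg$n_rand,
                             seed = cfg$seed + 23L)
  drgs <- select_drgs(ranking, alpha = cfg$dra_alpha)
  drl <- extract_drls(tc$library, dc)
  seeds <- assemble_seeds(drgs, tc$library, degs, dcgs, drl)
  # --- stage 2: per-cohort subtyping and prognosis ordering ---------------
  # all rewired TFs carry subtype programs; the planted signature truth is
  # the subset landing in the extreme-prognosis subtypes
  program_tfs <- tc$truth$rewired_tfs
  cohorts <- vector("list", cfg$n_cohorts)
  names(cohorts) <- sprintf("cohort%d", seq_len(cfg$n_cohorts))
  sig_truth <- NULL
  for (i in seq_len(cfg$n_cohorts)) {
    csim <- sim
    csim$seed <- sim$seed + 100L * i
    co <- simulate_subtyped_cohort(csim, signature_tfs = program_tfs,
                                   cohort = names(cohorts)[i])
    if (is.null(sig_truth)) {
      by_hazard <- order(sim$hazard_per_subtype, decreasing = TRUE)
      extremes <- c(by_hazard[1], by_hazard[sim$k])
      sig_truth <- names(co$tf_subtype)[co$tf_subtype %in% extremes]
    }
    genes_use <- intersect(seeds$all_genes, genes(co$expr))
    if (length(genes_use) < 2)
      stop(sprintf("pipeline aborted at subtyping of %s: fewer than 2 seed ",
                   names(cohorts)[i]),
           "genes present in the cohort")
    st <- subtype_cohort(co$expr, genes_use = genes_use,
                         k_range = cfg$k_range, n_runs = cfg$n_runs,
                         seed = cfg$seed + 100L * i, tau = cfg$tau,
                         max_iter = cfg$max_iter, tol = cfg$tol)
    ord <- order_clusters_by_prognosis(st$labels, co$clinical)
    lr <- logrank_test(co$clinical$survival_time, co$clinical$event,
                       st$labels[co$clinical$sample_id])
    cohorts[[i]] <- list(data = co, subtypes = st, ordering = ord,
                         logrank = lr)
  }
  # --- stage 3: cross-cohort signature distillation -----------------------
  consensus <- cluster_consensus_genes(
    lapply(cohorts, function(x) x$subtypes$gene_sets),
    lapply(cohorts, function(x) x$ordering))
  signature <- restrict_to_tfs(consensus$candidates, tc$library)
  co1 <- cohorts[[1]]
  sig_st <- if (length(signature) >= 2)
    subtype_cohort(co1$data$expr, genes_use = signature,
                   k_range = cfg$k_range, n_runs = cfg$n_runs,
                   seed = cfg$seed + 5000L, tau = cfg$tau,
                   max_iter = cfg$max_iter, tol = cfg$tol)
  else NULL
  sig_p <- if (!is.null(sig_st))
    logrank_test(co1$data$clinical$survival_time, co1$data$clinical$event,
                 sig_st$labels[co1$data$clinical$sample_id])$p
  else NA_real_
  bl <- NULL
  if (baseline && length(consensus$candidates) >= max(2, length(signature))) {
    bl <- random_signature_baseline(
      consensus$candidates, size = max(2, length(signature)),
      n_draws = cfg$baseline_draws, m = co1$data$expr,
      clinical = co1$data$clinical, seed = cfg$seed + 6000L,
      k_range = cfg$k_range, n_runs = cfg$n_runs, tau = cfg$tau,
      max_iter = cfg$max_iter, tol = cfg$tol)
  }
  res <- structure(list(two_condition = tc, dcea = dc, dea = de,
                        ranking = ranking, drgs = drgs, drl = drl,
                        seeds = seeds, cohorts = cohorts,
                        consensus = consensus, signature = signature,
                        signature_subtypes = sig_st,
                        signature_logrank_p = sig_p, baseline = bl,
                        truth = list(rewired_tfs = tc$truth$rewired_tfs,
                                     rewired_targets = tc$truth$rewired_targets,
                                     signature_tfs = sig_truth),
                        config = cfg),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Signature-discovery pipeline result\n")
  cat(sprintf("  DRGs: %s\n", paste(x$drgs, collapse = ", ")))
  cat(sprintf("  seed genes: %d\n", length(x$seeds$all_genes)))
  cat(sprintf("  candidates: %d (best %d, worst %d)\n",
              length(x$consensus$candidates), length(x$consensus$best_set),
              length(x$consensus$worst_set)))
  cat(sprintf("  signature: %s\n", paste(x$signature, collapse = ", ")))
  cat(sprintf("  signature log-rank p (cohort 1): %.3g\n",
              x$signature_logrank_p))
  if (!is.null(x$baseline))
    cat(sprintf("  random-baseline mean p: %.3g over %d draws\n",
                attr(x$baseline, "mean_p"), nrow(x$baseline)))
  invisible(x)
}

#' Write all pipeline stage outputs as TSV under one directory
#'
#' @param res A `pipeline_result`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, `out_dir`.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_tsv(res$dcea$gene_table, p("dcg.tsv"))
  write_tsv(res$dcea$link_table, p("dcl.tsv"))
  write_tsv(res$dea, p("deg.tsv"))
  write_tsv(res$ranking, p("regulator_ranking.tsv"))
  write_tsv(res$drl, p("drl.tsv"))
  write_tsv(data.frame(gene = res$seeds$all_genes,
                       role = ifelse(res$seeds$all_genes %in% res$seeds$tfs,
                                     "tf", "target")),
            p("seeds.tsv"))
  for (nm in names(res$cohorts)) {
    co <- res$cohorts[[nm]]
    write_tsv(data.frame(sample_id = names(co$subtypes$labels),
                         cluster = unname(co$subtypes$labels)),
              p(sprintf("labels_%s.tsv", nm)))
    write_tsv(data.frame(k = as.integer(names(co$subtypes$rho)),
                         cophenetic = unname(co$subtypes$rho),
                         dispersion = unname(co$subtypes$dispersion)),
              p(sprintf("stability_%s.tsv", nm)))
  }
  write_tsv(data.frame(gene = res$consensus$candidates,
                       in_best = res$consensus$candidates %in%
                         res$consensus$best_set,
                       in_worst = res$consensus$candidates %in%
                         res$consensus$worst_set),
            p("candidates.tsv"))
  writeLines(res$signature, p("signature.txt"))
  if (!is.null(res$baseline)) write_tsv(res$baseline, p("baseline_p.tsv"))
  manifest <- data.frame(
    key = c("master_seed", "n_perm", "dcea_q", "dcea_delta", "dcea_alpha",
            "dea_alpha", "dra_alpha", "n_rand", "k_range", "n_runs", "tau",
            "n_cohorts", "signature_logrank_p"),
    value = c(res$config$seed, res$config$n_perm, res$config$dcea_q,
              res$config$dcea_delta, res$config$dcea_alpha,
              res$config$dea_alpha, res$config$dra_alpha, res$config$n_rand,
              paste(range(res$config$k_range), collapse = "-"),
              res$config$n_runs, res$config$tau, res$config$n_cohorts,
              res$signature_logrank_p))
  write_tsv(manifest, p("manifest.tsv"))
  invisible(out_dir)
}
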