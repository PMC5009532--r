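# Synthetic cohort generators. Expression follows a latent-factor model:
# each TF module has TF ~ N(0,1) per sample and target = beta * TF + noise,
# so the population TF-target correlation is analytically beta/sqrt(beta^2 +
# noise_sd^2) and differential coexpression is controlled exactly by moving
# beta between conditions.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic generators with validation. Defaults
#' are the study conditions used throughout the test-suite and acceptance
#' analyses.
#'
#' @param seed Integer RNG seed.
#' @param n_genes Total genes (TFs + module targets + independent background).
#' @param n_tfs Number of TF modules.
#' @param targets_per_tf Targets coupled to each TF.
#' @param n_normal,n_tumor Sample counts for the two-condition design.
#' @param beta_normal,beta_tumor Per-module TF->target coupling coefficients;
#'   scalars are recycled to `n_tfs`. Modules whose coefficients differ
#'   between conditions are the planted "rewired" truth.
#' @param noise_sd Standard deviation of target-level noise.
#' @param de_shift Mean shift (expression units ~ SD units, since TFs are
#'   standard normal) added in the tumor condition to targets of rewired
#'   modules, so rewired targets are differentially expressed as well as
#'   differentially coexpressed.
#' @param k Number of planted subtypes in subtyped cohorts (>= 2).
#' @param n_samples Samples per subtyped cohort (balanced across subtypes).
#' @param beta_cohort Stochastic TF->target coupling inside a subtyped
#'   (tumor) cohort: how strongly a target tracks its TF's sample-to-sample
#'   fluctuation.
#' @param signature_shift Mean shift, in SD units, of each signature TF in
#'   its designated subtype.
#' @param target_response Fraction of `signature_shift` transmitted to a
#'   signature TF's targets as a constitutive baseline shift in that subtype
#'   (the subtype's regulatory program rewires target baselines directly;
#'   only the residual fluctuation couples through `beta_cohort`).
#' @param hazard_per_subtype Exponential death hazards (per year), one per
#'   subtype; all positive.
#' @param censor_horizon Upper bound of the Uniform(0, horizon) censoring
#'   time (years). `0` disables censoring (all events observed).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 300L,
                       n_tfs = 20L,
                       targets_per_tf = 10L,
                       n_normal = 50L,
                       n_tumor = 50L,
                       beta_normal = 0.9,
                       beta_tumor = 0.9,
                       noise_sd = 0.6,
                       de_shift = 1.0,
                       k = 3L,
                       n_samples = 150L,
                       beta_cohort = 0.3,
                       signature_shift = 2.0,
                       target_response = 0.75,
                       hazard_per_subtype = c(1.0, 0.5, 0.2),
                       censor_horizon = 10) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_tfs = as.integer(n_tfs),
              targets_per_tf = as.integer(targets_per_tf),
              n_normal = as.integer(n_normal), n_tumor = as.integer(n_tumor),
              beta_normal = rep_len(beta_normal, n_tfs),
              beta_tumor = rep_len(beta_tumor, n_tfs),
              noise_sd = noise_sd, de_shift = de_shift,
              k = as.integer(k), n_samples = as.integer(n_samples),
              beta_cohort = beta_cohort, signature_shift = signature_shift,
              target_response = target_response,
              hazard_per_subtype = hazard_per_subtype,
              censor_horizon = censor_horizon)
  counts <- c(cfg$n_genes, cfg$n_tfs, cfg$targets_per_tf, cfg$n_normal,
              cfg$n_tumor, cfg$n_samples)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (cfg$k < 2) stop("k must be >= 2")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (length(cfg$hazard_per_subtype) != cfg$k)
    stop("hazard_per_subtype must have one hazard per subtype")
  if (any(cfg$hazard_per_subtype <= 0)) stop("hazards must be positive")
  if (cfg$censor_horizon < 0) stop("censor_horizon must be non-negative")
  if (cfg$n_tfs * (1L + cfg$targets_per_tf) > cfg$n_genes)
    stop("n_tfs * (1 + targets_per_tf) exceeds n_genes")
  structure(cfg, class = "sim_config")
}

sim_gene_ids <- function(cfg) {
  tfs <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  tgt <- sprintf("G%03d", seq_len(cfg$n_tfs * cfg$targets_per_tf))
  n_bg <- cfg$n_genes - length(tfs) - length(tgt)
  bg <- if (n_bg > 0) sprintf("B%03d", seq_len(n_bg)) else character(0)
  list(tfs = tfs, targets = tgt, background = bg,
       module = split(tgt, rep(seq_len(cfg$n_tfs), each = cfg$targets_per_tf)))
}

# Draw one condition's genes x samples block from the latent-factor model.
# tf_shift / target_shift: optional per-TF lists of per-sample mean offsets;
# targets couple to the TF's *fluctuation* and take their own offset, so a
# subtype program can move target baselines without inflating the shared
# latent noise.
sim_condition_block <- function(cfg, ids, n, beta, sample_prefix,
                                tf_shift = NULL, target_shift = NULL) {
  vals <- matrix(0, nrow = cfg$n_genes, ncol = n,
                 dimnames = list(c(ids$tfs, ids$targets, ids$background),
                                 sprintf("%s%03d", sample_prefix, seq_len(n))))
  for (t in seq_len(cfg$n_tfs)) {
    fluct <- stats::rnorm(n)
    tfv <- if (is.null(tf_shift)) fluct else fluct + tf_shift[[t]]
    vals[ids$tfs[t], ] <- tfv
    ts <- if (is.null(target_shift)) 0 else target_shift[[t]]
    for (g in ids$module[[t]])
      vals[g, ] <- beta[t] * fluct + ts + stats::rnorm(n, sd = cfg$noise_sd)
  }
  for (g in ids$background)
    vals[g, ] <- stats::rnorm(n)
  vals
}

#' Simulate a two-condition (tumor vs normal) cohort with rewired modules
#'
#' Each TF module couples its targets to the TF with a condition-specific
#' coefficient; modules whose coefficient differs between conditions are the
#' planted differential-regulation truth. Targets of rewired modules
#' additionally receive a tumor-side mean shift of `de_shift` so they are
#' differentially expressed. Background genes are independent standard
#' normals in both conditions.
#'
#' @param cfg A `sim_config`.
#' @return List with `expr` (an `ExpressionMatrix` with condition labels
#'   `"normal"`/`"tumor"`), `library` (the planted `RegulatoryLibrary`), and
#'   `truth` (list: `rewired_tfs`, `rewired_targets`).
#' @export
simulate_two_condition <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ids <- sim_gene_ids(cfg)
  vn <- sim_condition_block(cfg, ids, cfg$n_normal, cfg$beta_normal, "N")
  vt <- sim_condition_block(cfg, ids, cfg$n_tumor, cfg$beta_tumor, "T")
  rewired <- which(cfg$beta_normal != cfg$beta_tumor)
  rew_targets <- unlist(ids$module[rewired], use.names = FALSE)
  if (length(rew_targets) > 0)
    vt[rew_targets, ] <- vt[rew_targets, , drop = FALSE] + cfg$de_shift
  vals <- cbind(vn, vt)
  cond <- c(rep("normal", cfg$n_normal), rep("tumor", cfg$n_tumor))
  edges <- data.frame(
    regulator = rep(ids$tfs, each = cfg$targets_per_tf),
    target = ids$targets)
  list(expr = expression_matrix(vals, condition = cond),
       library = regulatory_library(edges),
       truth = list(rewired_tfs = ids$tfs[rewired],
                    rewired_targets = rew_targets))
}

#' Simulate a tumor cohort with planted molecular subtypes and survival
#'
#' Samples are split (balanced) into `k` subtypes. Each signature TF is
#' assigned a subtype (round-robin) and its latent value is shifted up by
#' `signature_shift` SD in that subtype; the shift propagates to the TF's
#' module targets through the within-cohort coupling `beta_cohort`. Survival
#' times are exponential with the subtype's hazard, censored at an
#' independent Uniform(0, `censor_horizon`) time.
#'
#' @param cfg A `sim_config`.
#' @param signature_tfs Character vector of TF ids carrying subtype signal;
#'   default: the first `k` TFs.
#' @param tf_subtype Optional named integer vector assigning each signature
#'   TF to the subtype where it is elevated. Default: TFs are dealt
#'   round-robin over the subtypes ordered by prognostic extremeness
#'   (worst-prognosis first, then best, then intermediates), so prognostic
#'   marker TFs land in the extreme subtypes before any intermediate one —
#'   the usual situation for survival-associated markers.
#' @param cohort Cohort tag used for sample ids and the condition label.
#' @return List with `expr` (`ExpressionMatrix`), `clinical`
#'   (`ClinicalTable`), `labels` (integer planted subtype per sample),
#'   `signature_tfs`, and `tf_subtype` (named subtype of each signature TF).
#' @export
simulate_subtyped_cohort <- function(cfg, signature_tfs = NULL,
                                     tf_subtype = NULL,
                                     cohort = "cohort1") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ids <- sim_gene_ids(cfg)
  if (is.null(signature_tfs)) signature_tfs <- ids$tfs[seq_len(cfg$k)]
  if (!all(signature_tfs %in% ids$tfs))
    stop("signature_tfs must be among the simulated TFs")
  n <- cfg$n_samples
  labels <- rep(seq_len(cfg$k), length.out = n)
  if (is.null(tf_subtype)) {
    by_hazard <- order(cfg$hazard_per_subtype, decreasing = TRUE)
    # worst, best, then intermediates (still ordered worst-first)
    seq_prog <- c(by_hazard[1], by_hazard[cfg$k],
                  by_hazard[-c(1, cfg$k)])
    tf_subtype <- stats::setNames(
      rep(seq_prog, length.out = length(signature_tfs)), signature_tfs)
  }
  if (!all(names(tf_subtype) %in% signature_tfs) ||
      !all(tf_subtype %in% seq_len(cfg$k)))
    stop("tf_subtype must map signature TFs to subtypes 1..k")
  tf_shift <- lapply(seq_len(cfg$n_tfs), function(t) {
    tf <- ids$tfs[t]
    if (tf %in% signature_tfs)
      ifelse(labels == tf_subtype[[tf]], cfg$signature_shift, 0)
    else 0
  })
  target_shift <- lapply(tf_shift, function(s) cfg$target_response * s)
  vals <- sim_condition_block(cfg, ids, n,
                              beta = rep(cfg$beta_cohort, cfg$n_tfs),
                              sample_prefix = paste0(cohort, "_S"),
                              tf_shift = tf_shift,
                              target_shift = target_shift)
  death <- stats::rexp(n, rate = cfg$hazard_per_subtype[labels])
  if (cfg$censor_horizon > 0) {
    cens <- stats::runif(n, 0, cfg$censor_horizon)
    time <- pmin(death, cens)
    event <- as.numeric(death <= cens)
  } else {
    time <- death
    event <- rep(1, n)
  }
  clin <- clinical_table(data.frame(sample_id = colnames(vals),
                                    survival_time = time, event = event))
  list(expr = expression_matrix(vals, condition = rep(cohort, n)),
       clinical = clin,
       labels = stats::setNames(labels, colnames(vals)),
       signature_tfs = signature_tfs, tf_subtype = tf_subtype)
}

#' Build a fixture table of differentially regulated links
#'
#' Generates a random DRL-shaped table with exactly `n_links` unique
#' (regulator, target) rows covering `n_tfs` distinct regulators and
#' `n_targets` distinct targets (regulator and target id pools disjoint).
#' Used for worked examples on seed-set assembly.
#'
#' @param n_tfs,n_targets,n_links Structure counts; requires
#'   `n_links >= max(n_tfs, n_targets)` and `n_links <= n_tfs * n_targets`.
#' @param seed RNG seed.
#' @return Data frame with columns regulator, target, r_normal, r_tumor,
#'   link_class.
#' @export
make_fixture_drl_table <- function(n_tfs, n_targets, n_links, seed = 1L) {
  if (n_links < max(n_tfs, n_targets))
    stop("n_links must be >= max(n_tfs, n_targets) to cover both pools")
  if (n_links > n_tfs * n_targets)
    stop(sprintf("infeasible: n_links (%d) > n_tfs * n_targets (%d)",
                 n_links, n_tfs * n_targets))
  set.seed(seed)
  tfs <- sprintf("FTF%02d", seq_len(n_tfs))
  tgt <- sprintf("FTG%03d", seq_len(n_targets))
  # round-robin over both pools covers every TF and every target; the cycle
  # lengths differ only after lcm(n_tfs, n_targets) >= m rows, so no dups
  m <- max(n_tfs, n_targets)
  pairs <- data.frame(regulator = rep_len(tfs, m), target = rep_len(tgt, m))
  all_pairs <- expand.grid(regulator = tfs, target = tgt,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(d) paste(d$regulator, d$target, sep = "\r")
  rest <- all_pairs[!(key(all_pairs) %in% key(pairs)), , drop = FALSE]
  extra <- n_links - nrow(pairs)
  if (extra > 0)
    pairs <- rbind(pairs, rest[sample.int(nrow(rest), extra), , drop = FALSE])
  rn <- round(stats::runif(n_links, 0.6, 0.95), 3)
  rt <- round(stats::runif(n_links, -0.2, 0.2), 3)
  data.frame(regulator = pairs$regulator, target = pairs$target,
             r_normal = rn, r_tumor = rt,
             link_class = ifelse(rt < 0, "differently-signed", "same-signed"),
             row.names = NULL)
}
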