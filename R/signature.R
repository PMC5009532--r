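# Seed-gene assembly and cross-cohort prognostic-signature distillation:
# DRG TFs plus their DEG-and-DCG targets retained through DRL filtering form
# the seed set; per-cohort best/worst-prognosis cluster gene sets are
# intersected across cohorts, restricted to TFs, and evaluated against a
# random-signature baseline and a drug-target enrichment.

#' Assemble the seed-gene set
#'
#' Step 1: candidate targets are the library targets of the DRG TFs that are
#' both differentially expressed (DEG) and differentially coexpressed (DCG).
#' Step 2: a candidate target is retained only if a DRL row links it to a
#' DRG. The seed set is the union of the DRG TFs and the retained targets.
#'
#' @param drgs Character vector of DRG TF ids.
#' @param library A `RegulatoryLibrary`.
#' @param deg_genes Character vector of DEG ids.
#' @param dcg_genes Character vector of DCG ids.
#' @param drl A `DRLTable` (columns regulator, target).
#' @return List of class `SeedSet`: tfs, targets, links (DRL rows restricted
#'   to DRG regulators and retained targets), all_genes.
#' @export
assemble_seeds <- function(drgs, library, deg_genes, dcg_genes, drl) {
  if (length(drgs) == 0) {
    warning("empty DRG set; seed set is empty")
    return(structure(list(tfs = character(0), targets = character(0),
                          links = drl[0, , drop = FALSE],
                          all_genes = character(0)),
                     class = "SeedSet"))
  }
  cand <- unique(library$edges$target[library$edges$regulator %in% drgs])
  cand <- intersect(intersect(cand, deg_genes), dcg_genes)
  keep_links <- drl$regulator %in% drgs & drl$target %in% cand
  links <- drl[keep_links, , drop = FALSE]
  kept <- unique(links$target)
  structure(list(tfs = drgs, targets = kept, links = links,
                 all_genes = union(drgs, kept)),
            class = "SeedSet")
}

#' @export
print.SeedSet <- function(x, ...) {
  cat(sprintf("SeedSet: %d TFs + %d targets = %d seed genes (%d links)\n",
              length(x$tfs), length(x$targets), length(x$all_genes),
              nrow(x$links)))
  invisible(x)
}

#' Intersect best/worst-prognosis cluster genes across cohorts
#'
#' @param cluster_genes Per-cohort list of per-cluster gene sets
#'   (as produced by [subtype_cohort()]: `$gene_sets`).
#' @param orderings Per-cohort prognosis orderings (cluster ids best -> worst,
#'   as from [order_clusters_by_prognosis()]); must align with
#'   `cluster_genes`.
#' @return List: best_set (intersection over cohorts of the best-prognosis
#'   cluster's genes), worst_set (same for worst), candidates (union).
#' @export
cluster_consensus_genes <- function(cluster_genes, orderings) {
  if (length(cluster_genes) < 2) stop("need >= 2 cohorts")
  if (length(orderings) != length(cluster_genes))
    stop("every cohort needs a prognosis ordering")
  best <- worst <- NULL
  for (i in seq_along(cluster_genes)) {
    ord <- orderings[[i]]
    if (is.null(ord) || length(ord) == 0)
      stop(sprintf("cohort %d has no prognosis ordering", i))
    gs <- cluster_genes[[i]]
    b <- gs[[as.character(ord[1])]]
    w <- gs[[as.character(ord[length(ord)])]]
    best <- if (i == 1) b else intersect(best, b)
    worst <- if (i == 1) w else intersect(worst, w)
  }
  list(best_set = best, worst_set = worst,
       candidates = union(best, worst))
}

#' Restrict a candidate gene set to transcription factors
#'
#' TF status is defined by membership in the regulatory library's regulator
#' set.
#'
#' @param candidates Character vector of gene ids.
#' @param library A `RegulatoryLibrary`.
#' @return Character vector: the TF signature.
#' @export
restrict_to_tfs <- function(candidates, library) {
  sig <- intersect(candidates, library$regulators)
  if (length(sig) == 0) warning("no transcription factors among candidates")
  sig
}

#' Random-signature survival baseline
#'
#' Repeatedly draws `size` genes from the candidate pool, re-runs NMF
#' consensus subtyping of the cohort on the drawn genes, and records the
#' multi-group log-rank p-value, giving the null distribution a real
#' signature must beat.
#'
#' @param candidates Candidate gene pool.
#' @param size Signature size to draw (<= length(candidates)).
#' @param n_draws Number of random signatures (>= 1).
#' @param m Cohort `ExpressionMatrix`.
#' @param clinical Matching `ClinicalTable`.
#' @param seed RNG seed.
#' @param ... Passed to [subtype_cohort()] (k_range, n_runs, ...).
#' @return Data frame: draw, p, genes (comma-joined); attribute `mean_p`.
#' @export
random_signature_baseline <- function(candidates, size, n_draws, m, clinical,
                                      seed = 1L, ...) {
  if (size > length(candidates)) stop("size exceeds candidate pool")
  if (n_draws < 1) stop("n_draws must be >= 1")
  set.seed(seed)
  draws <- lapply(seq_len(n_draws), function(i) sort(sample(candidates, size)))
  idx <- match(samples(m), clinical$sample_id)
  # one clustering seed across draws: the baseline's randomness is the gene
  # choice, so identical draws yield identical p-values
  ps <- vapply(seq_len(n_draws), function(i) {
    st <- subtype_cohort(m, genes_use = draws[[i]], seed = seed + 7919L,
                         ...)
    logrank_test(clinical$survival_time[idx], clinical$event[idx],
                 st$labels)$p
  }, numeric(1))
  out <- data.frame(draw = seq_len(n_draws), p = ps,
                    genes = vapply(draws, paste, character(1), collapse = ","))
  attr(out, "mean_p") <- mean(ps)
  out
}

#' Hypergeometric drug-target enrichment of a signature
#'
#' @param signature Character vector of signature gene ids (within universe).
#' @param drug_targets A `GeneSet` (or character vector) of drug-target genes.
#' @param universe Character vector: the expressed-gene universe (non-empty).
#' @return List: x (signature drug targets), n (signature size), K (drug
#'   targets in universe), N (universe size), background_rate (percentage,
#'   one decimal), p (hypergeometric tail P(X >= x)).
#' @export
drug_target_enrichment <- function(signature, drug_targets, universe) {
  if (length(universe) == 0) stop("empty gene universe")
  dt <- if (inherits(drug_targets, "GeneSet")) drug_targets$members
        else as.character(drug_targets)
  if (!all(signature %in% universe))
    stop("signature must be contained in the universe")
  K <- length(intersect(dt, universe))
  N <- length(universe)
  x <- length(intersect(intersect(signature, dt), universe))
  n <- length(signature)
  list(x = x, n = n, K = K, N = N,
       background_rate = round(100 * K / N, 1),
       p = stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE))
}

#' Cross-subtype expression test for one gene
#'
#' Kruskal-Wallis test of a gene's expression across subtype groups, with
#' per-subtype medians.
#'
#' @param m An `ExpressionMatrix`.
#' @param labels Named integer subtype per sample (>= 2 subtypes with >= 2
#'   samples each).
#' @param gene Gene id (must be present in `m`).
#' @return List: medians (named by subtype), statistic, df, p.
#' @export
subtype_expression_test <- function(m, labels, gene) {
  if (!(gene %in% genes(m))) stop(sprintf("gene '%s' absent", gene))
  labels <- labels[samples(m)]
  if (anyNA(labels)) stop("labels must cover all samples")
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 subtypes with >= 2 samples each")
  x <- m$values[gene, ]
  if (stats::sd(x) == 0)  # identical values in every group: no evidence
    return(list(medians = tapply(x, labels, stats::median),
                statistic = 0, df = length(tab) - 1, p = 1))
  kw <- stats::kruskal.test(x, as.factor(labels))
  list(medians = tapply(x, labels, stats::median),
       statistic = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value)
}
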