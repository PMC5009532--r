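# Differential regulation analysis (DRA): rank TFs by enrichment of DCGs
# among their candidate targets (TED, hypergeometric) and by the density of
# DCLs among target pairs relative to random same-size gene sets (TDD),
# then extract the differentially regulated links (DRLs).

#' Targets' enrichment density (TED) for one TF
#'
#' One-sided hypergeometric tail P(X >= x) for the overlap between a TF's
#' candidate targets and the DCG set, within a fixed gene universe.
#'
#' @param tf Regulator id (must be in `library`).
#' @param library A `RegulatoryLibrary`.
#' @param dcg_genes Character vector of DCG ids.
#' @param universe Character vector: the gene population.
#' @return List: x (overlap), n (targets in universe), K (DCGs in universe),
#'   N (universe size), p.
#' @export
ted <- function(tf, library, dcg_genes, universe) {
  if (!(tf %in% library$regulators))
    stop(sprintf("TF '%s' absent from regulatory library", tf))
  tg <- intersect(targets_of(library, tf), universe)
  if (length(tg) == 0)
    stop(sprintf("TF '%s' has no targets in the universe", tf))
  K <- length(intersect(dcg_genes, universe))
  N <- length(universe)
  x <- length(intersect(tg, dcg_genes))
  p <- stats::phyper(x - 1, K, N - K, length(tg), lower.tail = FALSE)
  list(x = x, n = length(tg), K = K, N = N, p = p)
}

#' Targets' DCL density (TDD) for one TF
#'
#' Observed density = number of DCLs with both endpoints among the TF's
#' targets, over `choose(n_targets, 2)`. Significance by resampling random
#' gene sets of the same size from the universe:
#' `p = (1 + #\{density_rand >= density_obs\}) / (n_rand + 1)`.
#'
#' @param tf Regulator id.
#' @param library A `RegulatoryLibrary`.
#' @param dcl_keys Character vector of canonical DCL pair keys
#'   (see [pair_key()]).
#' @param universe Gene population to resample from.
#' @param n_rand Number of random sets (default 1000).
#' @param seed RNG seed.
#' @return List: density, p, n_targets.
#' @export
tdd <- function(tf, library, dcl_keys, universe, n_rand = 1000, seed = 1L) {
  tg <- intersect(targets_of(library, tf), universe)
  if (length(tg) < 2)
    stop(sprintf("TF '%s' has < 2 targets in the universe; TDD undefined", tf))
  dens <- function(gs) {
    pr <- utils::combn(sort(gs), 2)
    mean(pair_key(pr[1, ], pr[2, ]) %in% dcl_keys)
  }
  obs <- dens(tg)
  set.seed(seed)
  ge <- 0L
  for (i in seq_len(n_rand)) {
    rnd <- sample(universe, length(tg))
    if (dens(rnd) >= obs) ge <- ge + 1L
  }
  list(density = obs, p = (1 + ge) / (n_rand + 1), n_targets = length(tg))
}

#' Rank all regulators by TED and TDD
#'
#' Computes TED and TDD for every library TF with targets in the universe,
#' applies BH correction across TFs for each statistic, and flags TFs
#' significant in both. TFs with fewer than 2 universe targets have TDD
#' undefined (`NA`, never flagged) and are reported with a message.
#'
#' @param library A `RegulatoryLibrary`.
#' @param dcg_genes DCG ids.
#' @param dcl_keys Canonical DCL pair keys ([dcl_pairs()]).
#' @param universe Gene population.
#' @param alpha Significance cutoff on BH q for both statistics (default 0.05).
#' @param n_rand TDD resampling draws (default 1000).
#' @param seed RNG seed.
#' @return Data frame of class `RegulatorRanking`: tf, n_targets, ted_x,
#'   ted_p, ted_q, tdd_density, tdd_p, tdd_q, significant_both.
#' @export
rank_regulators <- function(library, dcg_genes, dcl_keys, universe,
                            alpha = 0.05, n_rand = 1000, seed = 1L) {
  tfs <- library$regulators
  n_tg <- vapply(tfs, function(tf)
    length(intersect(targets_of(library, tf), universe)), integer(1))
  tfs <- tfs[n_tg >= 1]
  if (length(tfs) == 0)
    return(structure(data.frame(tf = character(0)),
                     class = c("RegulatorRanking", "data.frame")))
  ted_res <- lapply(tfs, ted, library = library, dcg_genes = dcg_genes,
                    universe = universe)
  has_tdd <- n_tg[n_tg >= 1] >= 2
  if (any(!has_tdd))
    message(sprintf("TDD undefined for %d TF(s) with < 2 targets",
                    sum(!has_tdd)))
  tdd_res <- vector("list", length(tfs))
  for (i in seq_along(tfs)) {
    if (has_tdd[i])
      tdd_res[[i]] <- tdd(tfs[i], library, dcl_keys, universe,
                          n_rand = n_rand, seed = seed + i)
  }
  out <- data.frame(
    tf = tfs,
    n_targets = vapply(ted_res, `[[`, numeric(1), "n"),
    ted_x = vapply(ted_res, `[[`, numeric(1), "x"),
    ted_p = vapply(ted_res, `[[`, numeric(1), "p"),
    tdd_density = vapply(tdd_res, function(z)
      if (is.null(z)) NA_real_ else z$density, numeric(1)),
    tdd_p = vapply(tdd_res, function(z)
      if (is.null(z)) NA_real_ else z$p, numeric(1)),
    row.names = NULL)
  out$ted_q <- stats::p.adjust(out$ted_p, method = "BH")
  out$tdd_q <- NA_real_
  out$tdd_q[!is.na(out$tdd_p)] <-
    stats::p.adjust(out$tdd_p[!is.na(out$tdd_p)], method = "BH")
  out$significant_both <- !is.na(out$tdd_q) &
    out$ted_q < alpha & out$tdd_q < alpha
  class(out) <- c("RegulatorRanking", "data.frame")
  out
}

#' Select differentially regulated genes (DRGs)
#'
#' TFs significant in both TED and TDD (BH q below `alpha` in each).
#'
#' @param ranking A `RegulatorRanking`.
#' @param alpha Cutoff on both q-values (default 0.05).
#' @return Character vector of TF ids.
#' @export
select_drgs <- function(ranking, alpha = 0.05) {
  if (nrow(ranking) == 0) return(character(0))
  ranking$tf[!is.na(ranking$tdd_q) &
               ranking$ted_q < alpha & ranking$tdd_q < alpha]
}

#' Extract differentially regulated links (DRLs)
#'
#' Library edges whose unordered gene pair is a DCL; orientation is not
#' required to agree since coexpression is symmetric. Correlations and link
#' class are copied from the DCEA link table.
#'
#' @param library A `RegulatoryLibrary`.
#' @param dc A `DCResult` (or classified link table).
#' @return Data frame of class `DRLTable`: regulator, target, r_normal,
#'   r_tumor, link_class.
#' @export
extract_drls <- function(library, dc) {
  lt <- if (inherits(dc, "DCResult")) dc$link_table else dc
  lt <- lt[lt$is_dcl, , drop = FALSE]
  keys <- pair_key(lt$gene_a, lt$gene_b)
  ed <- library$edges
  idx <- match(pair_key(ed$regulator, ed$target), keys)
  keep <- !is.na(idx)
  out <- data.frame(regulator = ed$regulator[keep], target = ed$target[keep],
                    r_normal = lt$r_a[idx[keep]], r_tumor = lt$r_b[idx[keep]],
                    link_class = lt$link_class[idx[keep]], row.names = NULL)
  class(out) <- c("DRLTable", "data.frame")
  out
}
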