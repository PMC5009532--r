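# Differential coexpression analysis (DCEA): per-gene differential
# coexpression scores (DCGs) and per-pair differential coexpression links
# (DCLs) between two conditions.
#
# Conventions: Pearson correlation within each condition; half-thresholding
# link filter at a quantile of the pooled |r| distribution; DCp-style
# root-mean-square delta-r gene score; significance by permuting condition
# labels; Benjamini-Hochberg correction.

#' Within-condition pairwise Pearson correlations
#'
#' @param m An `ExpressionMatrix` with condition labels.
#' @param condition Condition whose samples to use (>= 3 required).
#' @return List: `r` (genes x genes Pearson correlation matrix; rows/columns
#'   of zero-variance genes are `NA`), `zero_var` (logical per gene).
#' @export
pairwise_correlation <- function(m, condition) {
  sub <- subset_condition(m, condition)
  if (ncol(sub$values) < 3)
    stop(sprintf("condition '%s' has < 3 samples", condition))
  sds <- apply(sub$values, 1, stats::sd)
  zero_var <- sds == 0
  r <- suppressWarnings(stats::cor(t(sub$values)))
  r[zero_var, ] <- NA_real_
  r[, zero_var] <- NA_real_
  list(r = r, zero_var = stats::setNames(zero_var, genes(m)))
}

#' Half-thresholding link filter
#'
#' Pools the |r| values of all defined gene pairs from both conditions and
#' retains a pair iff its |r| in EITHER condition exceeds the `q`-th quantile
#' of that pooled distribution.
#'
#' @param corr_a,corr_b Outputs of [pairwise_correlation()] for the two
#'   conditions, on the same gene universe.
#' @param q Quantile in (0, 1); default 0.75.
#' @return Data frame of retained unordered pairs with columns `gene_a`,
#'   `gene_b`, `r_a`, `r_b`; attribute `threshold` holds the |r| cutoff.
#' @export
filter_links <- function(corr_a, corr_b, q = 0.75) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  if (!identical(rownames(corr_a$r), rownames(corr_b$r)))
    stop("correlation tables must share one gene universe")
  gn <- rownames(corr_a$r)
  ut <- upper.tri(corr_a$r)
  ra <- corr_a$r[ut]
  rb <- corr_b$r[ut]
  ok <- !is.na(ra) & !is.na(rb)
  pooled <- abs(c(ra[ok], rb[ok]))
  if (length(pooled) == 0) stop("no defined gene pairs")
  thr <- stats::quantile(pooled, q, names = FALSE)
  keep <- ok & (abs(ra) > thr | abs(rb) > thr)
  idx <- which(ut, arr.ind = TRUE)[keep, , drop = FALSE]
  out <- data.frame(gene_a = gn[idx[, 1]], gene_b = gn[idx[, 2]],
                    r_a = ra[keep], r_b = rb[keep], row.names = NULL)
  attr(out, "threshold") <- thr
  out
}

#' Per-gene differential coexpression score
#'
#' DCp-style statistic: the root mean square of the correlation change over a
#' gene's retained links, `sqrt(sum((r_a - r_b)^2) / n_links)`. Genes with no
#' retained link score 0.
#'
#' @param links Retained pair table from [filter_links()] (or any data frame
#'   with `gene_a`, `gene_b`, `r_a`, `r_b`).
#' @param gene_universe Character vector of all genes to score.
#' @return Named numeric vector of non-negative scores over `gene_universe`.
#' @export
dc_scores <- function(links, gene_universe) {
  d2 <- (links$r_a - links$r_b)^2
  g <- factor(c(links$gene_a, links$gene_b), levels = gene_universe)
  ss <- tapply(c(d2, d2), g, sum, default = 0)
  nn <- tapply(rep(1, 2 * length(d2)), g, sum, default = 0)
  sc <- ifelse(nn > 0, sqrt(ss / pmax(nn, 1)), 0)
  stats::setNames(as.numeric(sc), gene_universe)
}

#' Classify differential coexpression links
#'
#' A retained pair is a DCL iff `|r_a - r_b| >= delta`. DCLs whose
#' correlations agree in sign are "same-signed"; sign-discordant DCLs are
#' "switched" when both |r| pass the link-filter cutoff and
#' "differently-signed" otherwise.
#'
#' @param links Retained pair table from [filter_links()] (carries the filter
#'   `threshold` attribute, or pass `threshold` explicitly).
#' @param delta Correlation-change cutoff in (0, 2]; default 0.5.
#' @param threshold |r| cutoff used for the switched class; defaults to the
#'   `threshold` attribute of `links`.
#' @return `links` with added columns `delta_r`, `is_dcl`, `link_class`
#'   (`NA` class for non-DCLs).
#' @export
classify_dcls <- function(links, delta = 0.5, threshold = NULL) {
  if (delta <= 0 || delta > 2) stop("delta must be in (0, 2]")
  if (is.null(threshold)) threshold <- attr(links, "threshold")
  if (is.null(threshold)) stop("no filter threshold available")
  dr <- abs(links$r_a - links$r_b)
  is_dcl <- dr >= delta
  sign_agree <- links$r_a * links$r_b >= 0
  cls <- ifelse(sign_agree, "same-signed",
                ifelse(abs(links$r_a) > threshold & abs(links$r_b) > threshold,
                       "switched", "differently-signed"))
  links$delta_r <- dr
  links$is_dcl <- is_dcl
  links$link_class <- ifelse(is_dcl, cls, NA_character_)
  links
}

#' Permutation significance of differential coexpression scores
#'
#' Permutes the condition labels across samples and recomputes the whole
#' observed statistic from scratch on each permuted split: correlation
#' tables for both pseudo-conditions, the half-thresholding link filter at
#' the same pooled-|r| quantile, and the per-gene rms delta-r score. (The
#' filter must be re-derived per permutation: scoring permuted correlations
#' on the observed link set would bias observed scores upward, since those
#' links were selected for extremeness on the observed split.) Per-gene
#' p-values use the add-one estimator
#' `p = (1 + #\{permuted score >= observed\}) / (n_perm + 1)`; q-values are
#' Benjamini-Hochberg over all scored genes.
#'
#' @param m Two-condition `ExpressionMatrix`.
#' @param observed Named vector of observed scores ([dc_scores()]).
#' @param conditions Length-2 character vector naming the two conditions.
#' @param q Link-filter quantile used for the observed scores.
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed.
#' @param alpha q-value cutoff for the DCG flag; default 0.25.
#' @return Data frame: gene, dc_score, p, q, is_dcg.
#' @export
permutation_significance <- function(m, observed, conditions, q = 0.75,
                                     n_perm = 500, seed = 1L, alpha = 0.25) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  set.seed(seed)
  gn <- names(observed)
  ng <- length(gn)
  ut <- which(upper.tri(matrix(0, ng, ng)), arr.ind = TRUE)
  ia <- ut[, 1]
  ib <- ut[, 2]
  n_a <- sum(m$condition == conditions[1])
  n_b <- sum(m$condition == conditions[2])
  if (n_a + n_b != ncol(m$values))
    stop("conditions must cover all samples")
  X <- t(m$values)  # samples x genes
  ge <- rep(0L, ng)
  for (p in seq_len(n_perm)) {
    ord <- sample.int(n_a + n_b)
    ra <- suppressWarnings(stats::cor(X[ord[seq_len(n_a)], , drop = FALSE]))
    rb <- suppressWarnings(stats::cor(X[ord[n_a + seq_len(n_b)], , drop = FALSE]))
    va <- ra[ut]
    vb <- rb[ut]
    ok <- !is.na(va) & !is.na(vb)
    thr <- stats::quantile(abs(c(va[ok], vb[ok])), q, names = FALSE)
    keep <- ok & (abs(va) > thr | abs(vb) > thr)
    d2 <- (va[keep] - vb[keep])^2
    ss <- rep(0, ng)
    cnt <- rep(0L, ng)
    tab <- rowsum(c(d2, d2), c(ia[keep], ib[keep]))
    idx <- as.integer(rownames(tab))
    ss[idx] <- tab[, 1]
    cnt_tab <- rowsum(rep(1L, 2L * length(d2)), c(ia[keep], ib[keep]))
    cnt[idx] <- cnt_tab[, 1]
    perm_score <- ifelse(cnt > 0, sqrt(ss / pmax(cnt, 1)), 0)
    ge <- ge + (perm_score >= observed)
  }
  pval <- (1 + ge) / (n_perm + 1)
  qval <- stats::p.adjust(pval, method = "BH")
  data.frame(gene = gn, dc_score = unname(observed), p = pval, q = qval,
             is_dcg = qval < alpha, row.names = NULL)
}

#' Run the full differential coexpression analysis
#'
#' Convenience wrapper: correlations per condition, half-thresholding link
#' filter, DCL classification, gene scoring and permutation significance.
#'
#' @param m Two-condition `ExpressionMatrix`.
#' @param conditions Length-2 character vector of condition labels
#'   (default the sorted unique labels, e.g. `c("normal", "tumor")`).
#' @param q Link-filter quantile (default 0.75).
#' @param delta DCL correlation-change cutoff (default 0.5).
#' @param alpha DCG q-value cutoff (default 0.25).
#' @param n_perm Permutations for gene significance (default 500).
#' @param seed RNG seed.
#' @return List of class `DCResult`: `gene_table` (gene, dc_score, p, q,
#'   is_dcg), `link_table` (classified retained pairs), `threshold`,
#'   `conditions`, and the filter/DCL parameters used.
#' @export
run_dcea <- function(m, conditions = NULL, q = 0.75, delta = 0.5,
                     alpha = 0.25, n_perm = 500, seed = 1L) {
  if (is.null(conditions)) conditions <- sort(unique(m$condition))
  if (length(conditions) != 2) stop("exactly two conditions required")
  ca <- pairwise_correlation(m, conditions[1])
  cb <- pairwise_correlation(m, conditions[2])
  links <- filter_links(ca, cb, q = q)
  links <- classify_dcls(links, delta = delta)
  obs <- dc_scores(links, genes(m))
  gt <- permutation_significance(m, obs, conditions, q = q,
                                 n_perm = n_perm, seed = seed, alpha = alpha)
  structure(list(gene_table = gt, link_table = links,
                 threshold = attr(links, "threshold"),
                 conditions = conditions,
                 params = list(q = q, delta = delta, alpha = alpha,
                               n_perm = n_perm, seed = seed)),
            class = "DCResult")
}

#' @export
print.DCResult <- function(x, ...) {
  cat(sprintf(
    "DCResult: %d genes (%d DCGs at q<%.2f), %d retained links (%d DCLs)\n",
    nrow(x$gene_table), sum(x$gene_table$is_dcg), x$params$alpha,
    nrow(x$link_table), sum(x$link_table$is_dcl)))
  invisible(x)
}

#' DCL pairs of a DCEA result as canonical keys
#'
#' @param dc A `DCResult` (or a classified link table).
#' @return Character vector of sorted `"a|b"` keys, one per DCL.
#' @export
dcl_pairs <- function(dc) {
  lt <- if (inherits(dc, "DCResult")) dc$link_table else dc
  lt <- lt[lt$is_dcl, , drop = FALSE]
  pair_key(lt$gene_a, lt$gene_b)
}

#' Canonical unordered pair key
#' @param a,b Gene id vectors.
#' @return `"x|y"` with `x <= y` lexicographically.
#' @export
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}
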