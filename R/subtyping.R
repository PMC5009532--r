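# NMF consensus clustering of tumor samples: Brunet-style multiplicative
# updates minimizing the KL divergence D(V || WH), repeated from random
# starts; co-clustering frequencies form a consensus matrix whose stability
# over k is summarized by the cophenetic correlation coefficient.

#' Per-gene min-max scaling to [0, 1]
#'
#' Makes a real-valued (possibly negative, log-like) matrix nonnegative for
#' NMF and equalizes gene influence. Constant rows map to all-zero.
#'
#' @param m An `ExpressionMatrix` or numeric matrix.
#' @return Numeric matrix with every row in `[0, 1]` (or all zero).
#' @export
nonneg_transform <- function(m) {
  v <- if (inherits(m, "ExpressionMatrix")) m$values else m
  if (!all(is.finite(v))) stop("values must be finite")
  rmin <- apply(v, 1, min)
  rmax <- apply(v, 1, max)
  span <- rmax - rmin
  out <- (v - rmin) / ifelse(span == 0, 1, span)
  out[span == 0, ] <- 0
  out
}

#' Fit one NMF model by Brunet KL multiplicative updates
#'
#' Factorizes a nonnegative matrix `V` (genes x samples) as `W %*% H`
#' (`W`: genes x k, `H`: k x samples, both nonnegative), minimizing the
#' generalized Kullback-Leibler divergence with the classic multiplicative
#' update rules. Initialization is uniform random from `seed`; iteration
#' stops at `max_iter` or when the relative objective decrease over a
#' 10-iteration window falls below `tol`.
#'
#' @param V Nonnegative numeric matrix.
#' @param k Factorization rank; at most `min(dim(V))` (equality is the
#'   exact-rank edge case needed when clustering a panel of only k genes,
#'   e.g. a three-gene signature into three subtypes).
#' @param seed RNG seed.
#' @param max_iter Maximum iterations (default 2000).
#' @param tol Relative objective-change tolerance (default 1e-6).
#' @return List of class `NMFModel`: W, H, objective, objective_trace,
#'   n_iter, k, seed.
#' @export
nmf_fit <- function(V, k, seed = 1L, max_iter = 2000, tol = 1e-6) {
  if (any(V < 0)) stop("V must be nonnegative")
  if (k > min(dim(V))) stop("k must be <= min(dim(V))")
  set.seed(seed)
  n <- nrow(V); m <- ncol(V)
  eps <- .Machine$double.eps
  W <- matrix(stats::runif(n * k), n, k)
  H <- matrix(stats::runif(k * m), k, m)
  kl <- function(WH) {
    pos <- V > 0
    sum(V[pos] * log(V[pos] / pmax(WH[pos], eps))) - sum(V) + sum(WH)
  }
  obj <- kl(W %*% H)
  trace <- obj
  it <- 0L
  repeat {
    for (s in seq_len(10L)) {
      it <- it + 1L
      WH <- pmax(W %*% H, eps)
      H <- H * (crossprod(W, V / WH)) / pmax(colSums(W), eps)
      WH <- pmax(W %*% H, eps)
      W <- W * ((V / WH) %*% t(H)) / rep(pmax(rowSums(H), eps), each = n)
      if (it >= max_iter) break
    }
    new_obj <- kl(W %*% H)
    trace <- c(trace, new_obj)
    done <- it >= max_iter ||
      (obj - new_obj) <= tol * max(abs(obj), eps)
    obj <- new_obj
    if (done) break
  }
  structure(list(W = W, H = H, objective = obj, objective_trace = trace,
                 n_iter = it, k = k, seed = seed),
            class = "NMFModel")
}

#' Consensus clustering at a fixed rank k
#'
#' Runs [nmf_fit()] from `n_runs` random starts (seeds `seed + 1 ...
#' seed + n_runs`). Per run, two samples are connected iff they share the
#' argmax metagene of `H`; the consensus matrix is the mean connectivity.
#' Samples are then clustered by average-linkage hierarchical clustering of
#' `1 - consensus`, and the cophenetic correlation coefficient is the Pearson
#' correlation between that dendrogram's cophenetic distances and
#' `1 - consensus` (defined as 1 when either is constant, i.e. perfectly
#' stable).
#'
#' @param V Nonnegative matrix (genes x samples).
#' @param k Number of clusters.
#' @param n_runs Number of random restarts (>= 10).
#' @param seed Base RNG seed.
#' @param max_iter,tol Passed to [nmf_fit()].
#' @return List: consensus (samples x samples), rho (cophenetic correlation),
#'   dispersion (mean of `4 * (consensus - 1/2)^2`, 1 for a perfectly crisp
#'   consensus), labels (named integer cluster per sample, from the
#'   dendrogram cut), best_model (lowest-objective `NMFModel`), k.
#' @export
consensus_cluster <- function(V, k, n_runs = 50, seed = 1L,
                              max_iter = 2000, tol = 1e-6) {
  if (n_runs < 10) stop("n_runs must be >= 10")
  m <- ncol(V)
  consensus <- matrix(0, m, m)
  best <- NULL
  for (r in seq_len(n_runs)) {
    fit <- nmf_fit(V, k, seed = seed + r, max_iter = max_iter, tol = tol)
    lab <- apply(fit$H, 2, which.max)
    consensus <- consensus + outer(lab, lab, "==")
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  consensus <- consensus / n_runs
  dimnames(consensus) <- list(colnames(V), colnames(V))
  d <- stats::as.dist(1 - consensus)
  hc <- stats::hclust(d, method = "average")
  coph <- stats::cophenetic(hc)
  rho <- if (stats::sd(d) == 0 || stats::sd(coph) == 0) 1
         else stats::cor(coph, d)
  labels <- stats::cutree(hc, k = k)
  list(consensus = consensus, rho = rho,
       dispersion = mean(4 * (consensus - 0.5)^2), labels = labels,
       best_model = best, k = k)
}

#' Choose the number of clusters from a stability profile
#'
#' The largest scanned k whose stability coefficient is at least `tau`
#' (clusters as stable as possible while k as large as possible); if none
#' qualifies, the k with the maximal coefficient (smallest such k on ties).
#' The profile may be cophenetic correlations or consensus dispersions;
#' [subtype_cohort()] feeds dispersion by default, which stays sharp where
#' the cophenetic coefficient saturates (nested over-splits keep the
#' consensus tree-like at any k).
#'
#' @param rho Numeric stability coefficients named by k.
#' @param tau Stability threshold (default 0.95).
#' @return Integer: chosen k.
#' @export
choose_k <- function(rho, tau = 0.95) {
  ks <- as.integer(names(rho))
  if (length(ks) == 0 || any(is.na(ks))) stop("rho must be named by k")
  ok <- rho >= tau
  if (any(ok)) max(ks[ok]) else ks[which.max(rho)]
}

#' Assign genes to clusters through the metagenes
#'
#' Each gene goes to the metagene with the maximal entry of its
#' (max-normalized) `W` row; all-zero rows (constant genes) belong to no
#' cluster. A cluster's metagene is the argmax-`H` metagene most frequent
#' among its samples; the cluster's gene set is the genes of that metagene.
#'
#' @param model An `NMFModel` fitted at the chosen k.
#' @param labels Named integer cluster label per sample (same sample order
#'   as the columns of `model$H`).
#' @param gene_ids Gene ids for the rows of `model$W`.
#' @return List, one character vector of gene ids per cluster
#'   (names `"1" ... "k"`).
#' @export
cluster_gene_sets <- function(model, labels, gene_ids) {
  W <- model$W
  nonzero <- rowSums(W) > 0
  gene_mg <- apply(W, 1, which.max)  # ties -> lowest metagene index
  samp_mg <- apply(model$H, 2, which.max)
  out <- vector("list", length(unique(labels)))
  names(out) <- sort(unique(labels))
  for (cl in names(out)) {
    mgs <- samp_mg[labels == as.integer(cl)]
    mg <- as.integer(names(which.max(table(mgs))))
    out[[cl]] <- gene_ids[nonzero & gene_mg == mg]
  }
  out
}

#' Order clusters from best to worst prognosis
#'
#' Clusters are sorted by decreasing Kaplan-Meier median survival; clusters
#' whose KM curve never reaches 0.5 (median undefined) use the mean observed
#' time as fallback, and remaining ties break by cluster index.
#'
#' @param labels Named integer cluster per sample.
#' @param clinical A `ClinicalTable` covering the labelled samples.
#' @return Integer vector of cluster ids, best prognosis first.
#' @export
order_clusters_by_prognosis <- function(labels, clinical) {
  idx <- match(names(labels), clinical$sample_id)
  if (anyNA(idx)) stop("clinical table is missing labelled samples")
  cl_ids <- sort(unique(labels))
  score <- vapply(cl_ids, function(cl) {
    sel <- labels == cl
    if (sum(sel) < 2) stop(sprintf("cluster %d has < 2 samples", cl))
    km <- km_estimate(clinical$survival_time[idx][sel],
                      clinical$event[idx][sel])
    if (is.na(km$median)) mean(clinical$survival_time[idx][sel])
    else km$median
  }, numeric(1))
  cl_ids[order(-score, cl_ids)]
}

#' Scan k, pick the stable model order, and label a cohort
#'
#' Convenience wrapper over [nonneg_transform()], [consensus_cluster()] and
#' [choose_k()] used by the pipeline.
#'
#' @param m An `ExpressionMatrix`.
#' @param genes_use Gene subset to cluster on (default: all genes).
#' @param k_range Candidate ks (default 2:4).
#' @param n_runs Restarts per k (default 30).
#' @param seed Base RNG seed.
#' @param tau Stability threshold for [choose_k()] (default 0.90 on the
#'   dispersion scale).
#' @param stability Which stability profile drives model-order selection:
#'   `"dispersion"` (default; consensus crispness) or `"cophenetic"`.
#' @param max_iter,tol Passed to [nmf_fit()].
#' @return List of class `SubtypeLabeling`: labels, k, stability (profile
#'   used for selection, per scanned k), rho (cophenetic, per scanned k),
#'   dispersion (per scanned k), consensus (at chosen k), model (best NMF
#'   fit at chosen k), gene_sets (per-cluster gene sets), genes_used.
#' @export
subtype_cohort <- function(m, genes_use = NULL, k_range = 2:4, n_runs = 30,
                           seed = 1L, tau = 0.90,
                           stability = c("dispersion", "cophenetic"),
                           max_iter = 2000, tol = 1e-6) {
  stability <- match.arg(stability)
  if (is.null(genes_use)) genes_use <- genes(m)
  genes_use <- intersect(genes_use, genes(m))
  if (length(genes_use) < 2) stop("need >= 2 genes to cluster on")
  k_range <- k_range[k_range <= length(genes_use) & k_range < ncol(m$values)]
  if (length(k_range) == 0) stop("no feasible k in k_range for this panel")
  V <- nonneg_transform(m$values[genes_use, , drop = FALSE])
  runs <- lapply(k_range, function(k)
    consensus_cluster(V, k, n_runs = n_runs, seed = seed + 1000L * k,
                      max_iter = max_iter, tol = tol))
  rho <- stats::setNames(vapply(runs, `[[`, numeric(1), "rho"), k_range)
  disp <- stats::setNames(vapply(runs, `[[`, numeric(1), "dispersion"),
                          k_range)
  stab <- if (stability == "dispersion") disp else rho
  k <- choose_k(stab, tau = tau)
  chosen <- runs[[match(k, k_range)]]
  gs <- cluster_gene_sets(chosen$best_model, chosen$labels, genes_use)
  structure(list(labels = chosen$labels, k = k, stability = stab,
                 rho = rho, dispersion = disp,
                 consensus = chosen$consensus, model = chosen$best_model,
                 gene_sets = gs, genes_used = genes_use),
            class = "SubtypeLabeling")
}

#' @export
print.SubtypeLabeling <- function(x, ...) {
  cat(sprintf(
    "SubtypeLabeling: k = %d over %d samples\n  dispersion: %s\n  cophenetic: %s\n",
    x$k, length(x$labels),
    paste(sprintf("k%s=%.3f", names(x$dispersion), x$dispersion),
          collapse = ", "),
    paste(sprintf("k%s=%.3f", names(x$rho), x$rho), collapse = ", ")))
  invisible(x)
}
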