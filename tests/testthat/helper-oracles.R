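# Shared fixtures and independent oracles used across the suite.

# small expression matrix with explicit values
tiny_em <- function(values, samples = NULL, condition = NULL) {
  if (is.null(colnames(values)) && !is.null(samples))
    colnames(values) <- samples
  expression_matrix(values, condition = condition)
}

# write a matrix as the TSV layout read_expression expects
write_expr_tsv <- function(values, path, gene_col = rownames(values)) {
  df <- cbind(gene = gene_col, as.data.frame(values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# one-sided hypergeometric tail P(X >= x) by direct enumeration
hyper_tail_enum <- function(x, K, N, n) {
  i <- x:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# hand product-limit estimator over distinct event times
km_oracle <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  s <- 1
  out <- numeric(0)
  for (t in unique(times)) {
    at_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / at_risk)
    out <- c(out, s)
  }
  stats::setNames(out, unique(times))
}

# two-group log-rank chi-square by direct O-E tabulation
logrank_oracle_2g <- function(times, events, group) {
  ev_times <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (t in ev_times) {
    n <- sum(times >= t)
    n1 <- sum(times >= t & group == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# rank-based AUROC of a score for a binary truth
auroc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# a small deterministic two-condition matrix with one rewired module
small_rewired_sim <- function(seed = 42L, n_genes = 60L, n_tfs = 4L,
                              targets_per_tf = 6L) {
  cfg <- sim_config(seed = seed, n_genes = n_genes, n_tfs = n_tfs,
                    targets_per_tf = targets_per_tf,
                    n_normal = 40L, n_tumor = 40L,
                    beta_tumor = c(0, rep(0.9, n_tfs - 1)))
  simulate_two_condition(cfg)
}
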