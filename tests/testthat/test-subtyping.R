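test_that("min-max transform maps rows to [0,1] and constants to zero", {
  v <- rbind(a = c(-2, 0, 2), b = c(5, 5, 5), c = c(0, 0.5, 1))
  out <- nonneg_transform(v)
  expect_equal(unname(out["a", ]), c(0, 0.5, 1))
  expect_equal(unname(out["b", ]), c(0, 0, 0))
  expect_equal(unname(out["c", ]), c(0, 0.5, 1))  # already scaled: unchanged
})

test_that("KL-NMF is deterministic, monotone, and recovers exact factorizations", {
  set.seed(41)
  W0 <- matrix(runif(30 * 3), 30, 3)
  H0 <- matrix(runif(3 * 20), 3, 20)
  V <- W0 %*% H0
  f1 <- nmf_fit(V, 3, seed = 2, max_iter = 3000, tol = 1e-10)
  f2 <- nmf_fit(V, 3, seed = 2, max_iter = 3000, tol = 1e-10)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
  # objective trace never increases
  expect_true(all(diff(f1$objective_trace) <= 1e-8))
  # exactly representable at the true rank: near-zero divergence
  expect_lt(f1$objective / sum(V), 1e-4)
  # rank-1 approximation cannot beat rank-3 on the same data
  f_r1 <- nmf_fit(V, 1, seed = 2, max_iter = 2000, tol = 1e-10)
  expect_gt(f_r1$objective, f1$objective)

  expect_error(nmf_fit(V, 25), "k must be")
  expect_error(nmf_fit(V - 10, 2), "nonnegative")
})

test_that("consensus matrices are valid and stable under identical seeds", {
  set.seed(42)
  V <- matrix(runif(15 * 24), 15, 24,
              dimnames = list(NULL, paste0("s", 1:24)))
  cc1 <- consensus_cluster(V, 2, n_runs = 10, seed = 3, max_iter = 200,
                           tol = 1e-4)
  cc2 <- consensus_cluster(V, 2, n_runs = 10, seed = 3, max_iter = 200,
                           tol = 1e-4)
  expect_identical(cc1$consensus, cc2$consensus)
  expect_true(isSymmetric(cc1$consensus))
  expect_true(all(diag(cc1$consensus) == 1))
  expect_true(all(cc1$consensus >= 0 & cc1$consensus <= 1))
  expect_true(cc1$rho >= -1 && cc1$rho <= 1)
  expect_true(cc1$dispersion >= 0 && cc1$dispersion <= 1)
  expect_error(consensus_cluster(V, 2, n_runs = 5), ">= 10")
})

test_that("model-order selection takes the largest stable k with fallback", {
  expect_equal(choose_k(c(`2` = 0.99, `3` = 0.99, `4` = 0.80), tau = 0.95), 3L)
  expect_equal(choose_k(c(`2` = 0.90, `3` = 0.94, `4` = 0.80), tau = 0.95), 3L)
  expect_equal(choose_k(c(`2` = 0.99, `3` = 0.99, `4` = 0.99), tau = 0.95), 4L)
  expect_error(choose_k(c(0.9, 0.8)), "named")
})

test_that("genes follow their dominant metagene; dead rows belong nowhere", {
  model <- list(W = rbind(g1 = c(0.9, 0.1, 0.0),
                          g2 = c(0.0, 0.0, 0.0),
                          g3 = c(0.1, 0.8, 0.1),
                          g4 = c(0.2, 0.2, 0.6)),
                H = rbind(c(5, 5, 0, 0, 0, 0),
                          c(0, 0, 5, 5, 0, 0),
                          c(0, 0, 0, 0, 5, 5)),
                k = 3)
  labels <- stats::setNames(c(1, 1, 2, 2, 3, 3), paste0("s", 1:6))
  gs <- cluster_gene_sets(model, labels, paste0("g", 1:4))
  expect_equal(gs[["1"]], "g1")
  expect_equal(gs[["2"]], "g3")
  expect_equal(gs[["3"]], "g4")
  expect_false("g2" %in% unlist(gs))
})

test_that("clusters order by KM median survival with deterministic ties", {
  set.seed(44)
  n <- 270
  labels <- stats::setNames(rep(1:3, each = n / 3), paste0("s", 1:n))
  haz <- c(0.2, 0.5, 1.0)
  times <- rexp(n, rate = haz[labels])
  clin <- clinical_table(data.frame(sample_id = names(labels),
                                    survival_time = times,
                                    event = 1))
  expect_equal(order_clusters_by_prognosis(labels, clin), c(1L, 2L, 3L))

  # identical clusters tie-break by index; k = 1 is trivial
  lab2 <- stats::setNames(rep(1:2, each = 3), paste0("t", 1:6))
  clin2 <- clinical_table(data.frame(sample_id = names(lab2),
                                     survival_time = rep(c(1, 2, 3), 2),
                                     event = 1))
  expect_equal(order_clusters_by_prognosis(lab2, clin2), c(1L, 2L))
  lab1 <- stats::setNames(rep(1L, 3), paste0("t", 1:3))
  expect_equal(order_clusters_by_prognosis(lab1, clin2[1:3, ]), 1L)
})

test_that("planted three-subtype cohorts are recovered end to end", {
  cfg <- sim_config(seed = 51, n_genes = 40, n_tfs = 3, targets_per_tf = 8,
                    n_samples = 120)
  co <- simulate_subtyped_cohort(cfg)
  panel <- c(co$signature_tfs, sprintf("G%03d", 1:24))
  st <- subtype_cohort(co$expr, genes_use = panel, k_range = 2:4,
                       n_runs = 15, seed = 9, max_iter = 800, tol = 1e-6)
  expect_equal(st$k, 3L)
  expect_gte(mclust::adjustedRandIndex(st$labels, co$labels), 0.9)
  # each signature TF's gene set sits in the metagene of its own subtype:
  # the cluster holding most of subtype s's samples should carry the TF
  for (tf in co$signature_tfs) {
    own <- co$tf_subtype[[tf]]
    cl <- names(which.max(table(st$labels[co$labels == own])))
    expect_true(tf %in% st$gene_sets[[cl]])
  }
})
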