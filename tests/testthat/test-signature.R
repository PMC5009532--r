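test_that("seed assembly reproduces the 6-TF/82-target/93-link worked example", {
  drl <- make_fixture_drl_table(6, 82, 93, seed = 1)
  lib <- regulatory_library(drl[, c("regulator", "target")])
  drgs <- unique(drl$regulator)
  all_targets <- unique(drl$target)
  seeds <- assemble_seeds(drgs, lib, deg_genes = all_targets,
                          dcg_genes = all_targets, drl = drl)
  expect_length(seeds$all_genes, 88)
  expect_length(seeds$tfs, 6)
  expect_length(seeds$targets, 82)
  expect_equal(nrow(seeds$links), 93)
})

test_that("seed assembly enforces DEG-and-DCG and DRL-link filters monotonically", {
  lib <- regulatory_library(data.frame(
    regulator = c("T1", "T1", "T1", "T2"),
    target = c("A", "B", "C", "D")))
  drl <- data.frame(regulator = c("T1", "T1"), target = c("A", "C"),
                    r_normal = 0.8, r_tumor = -0.1, link_class = "same-signed")
  # B is DEG but not DCG -> dropped at step 1; C is DEG+DCG with a DRL -> kept
  s <- assemble_seeds(c("T1"), lib, deg_genes = c("A", "B", "C"),
                      dcg_genes = c("A", "C"), drl = drl)
  expect_setequal(s$targets, c("A", "C"))
  expect_setequal(s$all_genes, c("T1", "A", "C"))
  # A passes step 1 but loses its DRL -> dropped at step 2
  s2 <- assemble_seeds(c("T1"), lib, deg_genes = c("A", "C"),
                       dcg_genes = c("A", "C"), drl = drl[2, ])
  expect_setequal(s2$targets, "C")
  # monotonicity: shrinking the DEG set never enlarges the seed set
  s3 <- assemble_seeds(c("T1"), lib, deg_genes = "C",
                       dcg_genes = c("A", "C"), drl = drl)
  expect_true(all(s3$all_genes %in% s$all_genes))
  expect_warning(s0 <- assemble_seeds(character(0), lib, "A", "A", drl),
                 "empty")
  expect_length(s0$all_genes, 0)
})

test_that("consensus candidates are the 14+6 best/worst intersections", {
  shared_best <- sprintf("B%02d", 1:14)
  shared_worst <- sprintf("W%02d", 1:6)
  gsets <- list()
  ords <- list()
  for (i in 1:4) {
    gsets[[i]] <- list(`1` = c(shared_best, sprintf("X%d", i)),
                       `2` = c(sprintf("M%d", i)),
                       `3` = c(shared_worst, sprintf("Y%d", i)))
    ords[[i]] <- c(1L, 2L, 3L)
  }
  cons <- cluster_consensus_genes(gsets, ords)
  expect_setequal(cons$best_set, shared_best)
  expect_setequal(cons$worst_set, shared_worst)
  expect_length(cons$candidates, 20)

  # cohort order does not matter
  perm <- c(3, 1, 4, 2)
  expect_equal(cluster_consensus_genes(gsets[perm], ords[perm])$candidates,
               cons$candidates)

  # degenerate intersections
  one <- list(list(`1` = "Z", `2` = "Q"), list(`1` = "Z", `2` = "R"))
  expect_equal(cluster_consensus_genes(one, list(1:2, 1:2))$candidates, "Z")
  disj <- list(list(`1` = "A", `2` = "B"), list(`1` = "C", `2` = "D"))
  expect_length(cluster_consensus_genes(disj, list(1:2, 1:2))$candidates, 0)
  expect_error(cluster_consensus_genes(gsets[1], ords[1]), ">= 2 cohorts")
  expect_error(cluster_consensus_genes(gsets, list(NULL, 1:3, 1:3, 1:3)),
               "ordering")
})

test_that("TF restriction keeps exactly the library regulators", {
  lib <- regulatory_library(data.frame(regulator = c("TFa", "TFb", "TFc"),
                                       target = c("g1", "g2", "g3")))
  expect_setequal(restrict_to_tfs(c("TFa", "g1", "TFb", "g9"), lib),
                  c("TFa", "TFb"))
  expect_warning(none <- restrict_to_tfs(c("g1", "g2"), lib), "no transcription")
  expect_length(none, 0)
  expect_setequal(restrict_to_tfs(c("TFa", "TFb", "TFc"), lib),
                  c("TFa", "TFb", "TFc"))
})

test_that("drug-target enrichment reports the printed background rate and exact tails", {
  # the expressed-gene universe with 1277 drug targets out of 20284 genes
  universe <- sprintf("g%05d", 1:20284)
  targets <- universe[1:1277]
  sig <- c(universe[1], universe[20000], universe[20001])
  enr <- drug_target_enrichment(sig, targets, universe)
  expect_equal(enr$background_rate, 6.3)
  expect_equal(enr$K, 1277)
  expect_equal(enr$x, 1)
  expect_equal(enr$p, hyper_tail_enum(1, 1277, 20284, 3), tolerance = 1e-10)

  # small-universe enumeration oracle
  uni <- paste0("u", 1:20)
  enr2 <- drug_target_enrichment(uni[1:4], uni[1:5], uni)
  expect_equal(enr2$p, 5 / 4845, tolerance = 1e-12)
  # empty overlap: certainty
  enr0 <- drug_target_enrichment(uni[10:12], uni[1:5], uni)
  expect_equal(enr0$p, 1)
  expect_error(drug_target_enrichment("z", uni[1:5], uni), "contained")
  expect_error(drug_target_enrichment("u1", "u2", character(0)), "empty")
})

test_that("cross-subtype expression test flags planted shifts and degenerates to p = 1", {
  set.seed(71)
  n <- 150
  labels <- stats::setNames(rep(1:3, each = n / 3), paste0("s", 1:n))
  v <- matrix(rnorm(2 * n), 2, n,
              dimnames = list(c("hit", "flat"), names(labels)))
  v["hit", labels == 2] <- v["hit", labels == 2] + 2
  m <- expression_matrix(v)
  res <- subtype_expression_test(m, labels, "hit")
  expect_lt(res$p, 1e-6)
  expect_equal(unname(which.max(res$medians)), 2L)

  # constant gene: statistic 0, p 1
  v2 <- v; v2["flat", ] <- 3
  res0 <- subtype_expression_test(expression_matrix(v2), labels, "flat")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)

  # two-group case agrees with the rank statistic computed by hand
  lab2 <- stats::setNames(c(1, 1, 1, 2, 2, 2), paste0("t", 1:6))
  v3 <- matrix(c(1.2, 0.8, 1.9, 3.1, 2.5, 4.0), 1, 6,
               dimnames = list("g", names(lab2)))
  res2 <- subtype_expression_test(expression_matrix(v3), lab2, "g")
  r <- rank(v3[1, ])
  H <- 12 / (6 * 7) * sum(tapply(r, lab2, sum)^2 / 3) - 3 * 7
  expect_equal(res2$statistic, H, tolerance = 1e-10)

  expect_error(subtype_expression_test(m, labels, "nope"), "absent")
})

test_that("random signature baselines are reproducible and degenerate correctly", {
  cfg <- sim_config(seed = 72, n_genes = 30, n_tfs = 3, targets_per_tf = 6,
                    n_samples = 90)
  co <- simulate_subtyped_cohort(cfg)
  cands <- c(co$signature_tfs, "G001", "G007", "G013")
  bl <- random_signature_baseline(cands, size = 3, n_draws = 2,
                                  m = co$expr, clinical = co$clinical,
                                  seed = 5, k_range = 2:3, n_runs = 10,
                                  max_iter = 300, tol = 1e-4)
  bl2 <- random_signature_baseline(cands, size = 3, n_draws = 2,
                                   m = co$expr, clinical = co$clinical,
                                   seed = 5, k_range = 2:3, n_runs = 10,
                                   max_iter = 300, tol = 1e-4)
  expect_identical(bl$p, bl2$p)
  expect_equal(attr(bl, "mean_p"), mean(bl$p))

  # pool of exactly `size` genes: every draw identical, zero variance
  bl_fix <- random_signature_baseline(co$signature_tfs, size = 3, n_draws = 3,
                                      m = co$expr, clinical = co$clinical,
                                      seed = 6, k_range = 2:3, n_runs = 10,
                                      max_iter = 300, tol = 1e-4)
  expect_equal(var(bl_fix$p), 0)
  expect_error(random_signature_baseline(cands, size = 10, n_draws = 1,
                                         m = co$expr, clinical = co$clinical),
               "exceeds")
})
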