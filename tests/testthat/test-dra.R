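toy_library <- function() {
  regulatory_library(data.frame(
    regulator = c("T1", "T1", "T1", "T1", "T2", "T2", "T3"),
    target = c("A", "B", "C", "D", "E", "F", "G")))
}

test_that("TED equals the exact hypergeometric tail", {
  lib <- toy_library()
  universe <- c(sprintf("U%02d", 1:13), "A", "B", "C", "D", "E", "F", "G")
  # N = 20, K = 5 DCGs, T1 has n = 4 targets, all 4 are DCGs
  dcgs <- c("A", "B", "C", "D", "U01")
  res <- ted("T1", lib, dcgs, universe)
  expect_equal(res$x, 4)
  expect_equal(res$p, hyper_tail_enum(4, 5, 20, 4), tolerance = 1e-12)
  expect_equal(res$p, 5 / 4845, tolerance = 1e-12)

  # x = 0: tail at its minimum is certainty
  expect_equal(ted("T2", lib, c("U01", "U02"), universe)$p, 1)
  # every gene a DCG: enrichment beyond certainty impossible
  expect_equal(ted("T1", lib, universe, universe)$p, 1)
  expect_error(ted("T9", lib, dcgs, universe), "absent")
})

test_that("TDD density counts DCLs among target pairs and calibrates by resampling", {
  lib <- regulatory_library(data.frame(regulator = rep("T1", 3),
                                       target = c("A", "B", "C")))
  universe <- c("A", "B", "C", paste0("U", 1:17))
  res <- tdd("T1", lib, pair_key("A", "B"), universe, n_rand = 200, seed = 1)
  expect_equal(res$density, 1 / 3)

  none <- tdd("T1", lib, character(0), universe, n_rand = 200, seed = 1)
  expect_equal(none$density, 0)
  expect_equal(none$p, 1)

  # all target pairs are DCLs, background DCL-free: p at the resampling floor
  all_dcl <- pair_key(c("A", "A", "B"), c("B", "C", "C"))
  strong <- tdd("T1", lib, all_dcl, universe, n_rand = 500, seed = 2)
  expect_equal(strong$density, 1)
  expect_lt(strong$p, 0.02)

  solo <- regulatory_library(data.frame(regulator = "T1", target = "A"))
  expect_error(tdd("T1", solo, character(0), universe), "< 2 targets")
})

test_that("DRG selection requires significance in both TED and TDD", {
  rk <- data.frame(tf = c("T1", "T2", "T3", "T4"),
                   ted_q = c(0.01, 0.01, 0.20, 0.03),
                   tdd_q = c(0.02, 0.30, 0.01, NA))
  class(rk) <- c("RegulatorRanking", "data.frame")
  expect_equal(select_drgs(rk, alpha = 0.05), "T1")
  expect_equal(select_drgs(rk[0, ], alpha = 0.05), character(0))
  # brute-force agreement
  expect_setequal(select_drgs(rk, 0.25),
                  rk$tf[!is.na(rk$tdd_q) & rk$ted_q < 0.25 & rk$tdd_q < 0.25])
})

test_that("DRL extraction is exactly the library-edge / DCL-pair intersection", {
  set.seed(31)
  lib <- regulatory_library(data.frame(
    regulator = sample(paste0("T", 1:4), 30, replace = TRUE),
    target = sample(paste0("G", 1:10), 30, replace = TRUE)))
  lt <- data.frame(gene_a = sample(c(paste0("T", 1:4), paste0("G", 1:10)), 40,
                                   replace = TRUE),
                   gene_b = sample(paste0("G", 1:10), 40, replace = TRUE),
                   r_a = runif(40, -1, 1), r_b = runif(40, -1, 1))
  lt <- lt[lt$gene_a != lt$gene_b, ]
  lt$is_dcl <- abs(lt$r_a - lt$r_b) >= 0.5
  lt$link_class <- ifelse(lt$is_dcl, "same-signed", NA)
  drl <- extract_drls(lib, lt)
  keys <- pair_key(lt$gene_a[lt$is_dcl], lt$gene_b[lt$is_dcl])
  # brute force over every library edge
  for (i in seq_len(nrow(lib$edges))) {
    in_drl <- any(drl$regulator == lib$edges$regulator[i] &
                    drl$target == lib$edges$target[i])
    expect_equal(in_drl, pair_key(lib$edges$regulator[i],
                                  lib$edges$target[i]) %in% keys)
  }
  # invariants: DRLs are library edges and DCL pairs
  expect_true(all(paste(drl$regulator, drl$target) %in%
                    paste(lib$edges$regulator, lib$edges$target)))
  expect_true(all(pair_key(drl$regulator, drl$target) %in% keys))
})

test_that("planted rewired TFs dominate the regulator ranking", {
  cfg <- sim_config(seed = 17, n_genes = 150, n_tfs = 10, targets_per_tf = 8,
                    n_normal = 50, n_tumor = 50,
                    beta_tumor = c(0, 0, rep(0.9, 8)))
  sim <- simulate_two_condition(cfg)
  dc <- run_dcea(sim$expr, conditions = c("normal", "tumor"),
                 n_perm = 150, seed = 5)
  dcgs <- dc$gene_table$gene[dc$gene_table$is_dcg]
  rk <- rank_regulators(sim$library, dcgs, dcl_pairs(dc), genes(sim$expr),
                        n_rand = 300, seed = 6)
  top_ted <- rk$tf[order(rk$ted_p)][1:5]
  top_tdd <- rk$tf[order(rk$tdd_p)][1:5]
  expect_true(all(c("TF01", "TF02") %in% top_ted))
  expect_true(all(c("TF01", "TF02") %in% top_tdd))
  expect_setequal(select_drgs(rk, 0.05), c("TF01", "TF02"))
})
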