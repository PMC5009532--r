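make_corr_fixture <- function() {
  # 5 genes x 5 samples per condition with hand-controllable correlations
  set.seed(5)
  v <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  expression_matrix(v, condition = rep(c("normal", "tumor"), each = 5))
}

test_that("within-condition Pearson correlations match hand computation", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  v <- rbind(gA = x, gB = y, gC = -x, gD = 2 * x + 1)
  colnames(v) <- paste0("s", 1:5)
  m <- expression_matrix(v, condition = rep("tumor", 5))
  r <- pairwise_correlation(m, "tumor")$r
  # hand Pearson: sum(dx*dy) = 10, sum(dx^2) = 10, sum(dy^2) = 14.8
  expect_equal(r["gA", "gB"], 10 / sqrt(10 * 14.8), tolerance = 1e-12)
  expect_equal(r["gA", "gD"], 1)   # affine copy
  expect_equal(r["gA", "gC"], -1)  # negated copy

  expect_error(pairwise_correlation(
    expression_matrix(v[, 1:2], condition = rep("tumor", 2)), "tumor"),
    "< 3 samples")
})

test_that("zero-variance genes are excluded from links, not errors", {
  v <- rbind(gA = c(1, 2, 3, 4), gB = c(4, 3, 2, 1), gC = c(0, 0, 0, 0))
  colnames(v) <- paste0("s", 1:4)
  m <- expression_matrix(v, condition = rep("tumor", 4))
  pc <- pairwise_correlation(m, "tumor")
  expect_true(pc$zero_var[["gC"]])
  expect_true(all(is.na(pc$r["gC", ])))
})

test_that("half-thresholding filter matches brute-force enumeration", {
  m <- make_corr_fixture()
  ca <- pairwise_correlation(m, "normal")
  cb <- pairwise_correlation(m, "tumor")
  links <- filter_links(ca, cb, q = 0.75)
  # brute force over all 10 unordered pairs
  gn <- genes(m)
  pooled <- c()
  pairs <- t(combn(gn, 2))
  for (i in seq_len(nrow(pairs)))
    pooled <- c(pooled, abs(ca$r[pairs[i, 1], pairs[i, 2]]),
                abs(cb$r[pairs[i, 1], pairs[i, 2]]))
  thr <- quantile(pooled, 0.75, names = FALSE)
  keep <- apply(pairs, 1, function(p)
    abs(ca$r[p[1], p[2]]) > thr | abs(cb$r[p[1], p[2]]) > thr)
  expect_setequal(pair_key(links$gene_a, links$gene_b),
                  pair_key(pairs[keep, 1], pairs[keep, 2]))
  expect_equal(attr(links, "threshold"), thr)

  # limits: q -> 0 keeps every defined pair; q -> 1 keeps only the argmax
  expect_equal(nrow(filter_links(ca, cb, q = 1e-6)), 10L)
  top <- filter_links(ca, cb, q = 1 - 1e-9)
  expect_equal(nrow(top), 1L)
  expect_equal(max(abs(c(top$r_a, top$r_b))), max(pooled))
  expect_error(filter_links(ca, cb, q = 1), "in \\(0, 1\\)")
})

test_that("dc scores follow the rms delta-r closed form", {
  links <- data.frame(gene_a = c("g1", "g1", "g1"),
                      gene_b = c("g2", "g3", "g4"),
                      r_a = c(0.7, 0.2, 0.4), r_b = c(0.2, 0.5, 0.3))
  # delta r = 0.5, -0.3, 0.1 on g1's three links
  sc <- dc_scores(links, paste0("g", 1:5))
  expect_equal(unname(sc["g1"]), sqrt(0.35 / 3), tolerance = 1e-12)
  expect_equal(unname(sc["g5"]), 0)  # no retained link
  # identical correlation tables give zero scores
  same <- transform(links, r_b = r_a)
  expect_true(all(dc_scores(same, paste0("g", 1:5)) == 0))
  # single link with full sign switch
  one <- data.frame(gene_a = "g1", gene_b = "g2", r_a = 0.9, r_b = -0.9)
  expect_equal(unname(dc_scores(one, c("g1", "g2"))[["g1"]]), 1.8)
})

test_that("dc scores are invariant to sample order, gene order and label swap", {
  sim <- small_rewired_sim()
  m <- sim$expr
  run <- function(mm) {
    ca <- pairwise_correlation(mm, "normal")
    cb <- pairwise_correlation(mm, "tumor")
    dc_scores(filter_links(ca, cb, 0.75), genes(mm))
  }
  base <- run(m)

  perm_s <- sample(ncol(m$values))
  m_s <- expression_matrix(m$values[, perm_s], condition = m$condition[perm_s])
  expect_equal(run(m_s), base)

  perm_g <- sample(nrow(m$values))
  m_g <- expression_matrix(m$values[perm_g, ], condition = m$condition)
  expect_equal(run(m_g)[names(base)], base)

  swapped <- c(normal = "tumor", tumor = "normal")[m$condition]
  m_sw <- expression_matrix(m$values, condition = unname(swapped))
  expect_equal(run(m_sw), base)
})

test_that("DCL classification applies the delta and sign rules", {
  links <- data.frame(gene_a = c("a", "a", "b", "c"),
                      gene_b = c("b", "c", "c", "d"),
                      r_a = c(0.9, 0.8, 0.4, 0.6),
                      r_b = c(0.88, -0.7, -0.3, 0.05))
  attr(links, "threshold") <- 0.5
  out <- classify_dcls(links, delta = 0.5)
  expect_false(out$is_dcl[1])                       # |0.9 - 0.88| < 0.5
  expect_true(out$is_dcl[2])
  expect_equal(out$link_class[2], "switched")       # both |r| > 0.5
  expect_equal(out$link_class[3], "differently-signed")
  expect_equal(out$link_class[4], "same-signed")
  expect_error(classify_dcls(links, delta = 0), "delta")

  # brute-force agreement on a random 20-pair fixture
  set.seed(8)
  rnd <- data.frame(gene_a = paste0("x", 1:20), gene_b = paste0("y", 1:20),
                    r_a = runif(20, -1, 1), r_b = runif(20, -1, 1))
  attr(rnd, "threshold") <- 0.3
  got <- classify_dcls(rnd, delta = 0.5)
  expect_equal(got$is_dcl, abs(rnd$r_a - rnd$r_b) >= 0.5)
  for (i in which(got$is_dcl)) {
    expected <- if (rnd$r_a[i] * rnd$r_b[i] >= 0) "same-signed"
      else if (abs(rnd$r_a[i]) > 0.3 && abs(rnd$r_b[i]) > 0.3) "switched"
      else "differently-signed"
    expect_equal(got$link_class[i], expected)
  }
})

test_that("permutation p-values are valid and flag planted rewiring", {
  sim <- small_rewired_sim()
  dc <- run_dcea(sim$expr, conditions = c("normal", "tumor"),
                 n_perm = 150, seed = 99)
  gt <- dc$gene_table
  expect_true(all(gt$p >= 1 / 151 & gt$p <= 1))
  expect_true(all(gt$q >= gt$p - 1e-12))
  # every rewired target is called with small p
  expect_true(all(gt$p[gt$gene %in% sim$truth$rewired_targets] < 0.05))
  # a gene with observed score zero gets p = 1
  obs <- stats::setNames(dc$gene_table$dc_score, dc$gene_table$gene)
  obs[] <- 0
  p0 <- permutation_significance(sim$expr, obs, c("normal", "tumor"),
                                 q = 0.75, n_perm = 100, seed = 1)
  expect_true(all(p0$p == 1))
  expect_error(permutation_significance(sim$expr, obs, c("normal", "tumor"),
                                        n_perm = 50), ">= 100")
})
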