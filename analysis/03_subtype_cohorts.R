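#!/usr/bin/env Rscript
# NMF consensus subtyping of each simulated tumor cohort on the seed genes,
# model-order selection by consensus stability, prognosis ordering of the
# clusters and per-cohort log-rank tests. Writes results/subtypes/.

library(dcsig)

cohorts <- "results/cohorts"
out <- "results/subtypes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

seeds <- read.delim("results/dra/seeds.tsv")$gene

for (i in 1:4) {
  expr <- read_expression(file.path(cohorts, sprintf("cohort%d_expr.tsv", i)))
  clin <- read_clinical(file.path(cohorts, sprintf("cohort%d_clinical.tsv", i)))
  st <- subtype_cohort(expr, genes_use = intersect(seeds, genes(expr)),
                       k_range = 2:4, n_runs = 20, seed = 100L * i,
                       max_iter = 500, tol = 1e-5)
  ord <- order_clusters_by_prognosis(st$labels, clin)
  lr <- logrank_test(clin$survival_time, clin$event,
                     st$labels[clin$sample_id])
  message(sprintf(
    "cohort %d: k = %d (dispersion %s), prognosis order %s, log-rank p = %.3g",
    i, st$k, paste(sprintf("%.2f", st$dispersion), collapse = "/"),
    paste(ord, collapse = " > "), lr$p))
  write_tsv(data.frame(sample_id = names(st$labels),
                       cluster = unname(st$labels)),
            file.path(out, sprintf("labels_cohort%d.tsv", i)))
  write_tsv(data.frame(k = as.integer(names(st$rho)),
                       cophenetic = unname(st$rho),
                       dispersion = unname(st$dispersion)),
            file.path(out, sprintf("stability_cohort%d.tsv", i)))
  gene_rows <- do.call(rbind, lapply(names(st$gene_sets), function(cl)
    if (length(st$gene_sets[[cl]]) > 0)
      data.frame(cluster = cl, gene = st$gene_sets[[cl]])))
  write_tsv(gene_rows, file.path(out, sprintf("cluster_genes_cohort%d.tsv", i)))
  write_tsv(data.frame(rank = seq_along(ord), cluster = ord),
            file.path(out, sprintf("prognosis_order_cohort%d.tsv", i)))
}
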