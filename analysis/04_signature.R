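#!/usr/bin/env Rscript
# Cross-cohort signature distillation: intersect best/worst-prognosis
# cluster genes over the four cohorts, restrict to transcription factors,
# evaluate the signature against random same-size draws and against a
# synthetic drug-target list, and fit per-gene Cox hazard ratios.
# Writes results/signature/.

library(dcsig)

out <- "results/signature"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

lib <- read_edges("results/cohorts/tf_target_library.tsv", header = TRUE)

gsets <- list(); ords <- list()
for (i in 1:4) {
  cg <- read.delim(sprintf("results/subtypes/cluster_genes_cohort%d.tsv", i))
  gsets[[i]] <- split(cg$gene, as.character(cg$cluster))
  ords[[i]] <- read.delim(
    sprintf("results/subtypes/prognosis_order_cohort%d.tsv", i))$cluster
}
cons <- cluster_consensus_genes(gsets, ords)
message(sprintf("consensus: %d best, %d worst, %d candidates",
                length(cons$best_set), length(cons$worst_set),
                length(cons$candidates)))
write_tsv(data.frame(gene = cons$candidates,
                     in_best = cons$candidates %in% cons$best_set,
                     in_worst = cons$candidates %in% cons$worst_set),
          file.path(out, "candidates.tsv"))

signature <- restrict_to_tfs(cons$candidates, lib)
message("TF signature: ", paste(signature, collapse = ", "))
writeLines(signature, file.path(out, "signature.txt"))

expr1 <- read_expression("results/cohorts/cohort1_expr.tsv")
clin1 <- read_clinical("results/cohorts/cohort1_clinical.tsv")

st <- subtype_cohort(expr1, genes_use = signature, k_range = 2:4,
                     n_runs = 20, seed = 77L, max_iter = 500, tol = 1e-5)
lr <- logrank_test(clin1$survival_time, clin1$event,
                   st$labels[clin1$sample_id])
message(sprintf("signature subtyping of cohort 1: k = %d, log-rank p = %.3g",
                st$k, lr$p))

bl <- random_signature_baseline(cons$candidates, size = length(signature),
                                n_draws = 20, m = expr1, clinical = clin1,
                                seed = 78L, k_range = 2:4, n_runs = 20,
                                max_iter = 500, tol = 1e-5)
message(sprintf("random baseline: mean p = %.3g over %d draws (signature p %s)",
                attr(bl, "mean_p"), nrow(bl),
                ifelse(lr$p < attr(bl, "mean_p"), "beats the mean", "does not")))
write_tsv(bl, file.path(out, "baseline_p.tsv"))

# synthetic drug-target list over the cohort's gene universe: the planted
# worst-prognosis TF plus a random tenth of the universe
set.seed(79)
uni <- genes(expr1)
drug_targets <- union(sample(uni, round(0.1 * length(uni))), signature[1])
enr <- drug_target_enrichment(signature, drug_targets, uni)
message(sprintf(
  "drug-target enrichment: %d/%d signature genes, background %.1f%%, p = %.3g",
  enr$x, enr$n, enr$background_rate, enr$p))
write_tsv(data.frame(x = enr$x, n = enr$n, K = enr$K, N = enr$N,
                     background_rate_pct = enr$background_rate, p = enr$p),
          file.path(out, "enrichment.tsv"))

hr <- cox_hr_table(expr1, clin1, genes_use = signature)
write_tsv(hr, file.path(out, "signature_hr.tsv"))
print(hr)

for (g in signature) {
  tst <- subtype_expression_test(expr1, st$labels, g)
  message(sprintf("%s across subtypes: medians %s, Kruskal-Wallis p = %.3g",
                  g, paste(sprintf("%.2f", tst$medians), collapse = "/"),
                  tst$p))
}
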