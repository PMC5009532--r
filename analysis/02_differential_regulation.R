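#!/usr/bin/env Rscript
# Differential coexpression (DCG/DCL), differential expression (DEG) and
# differential regulation (TED/TDD -> DRG, DRL) analysis of the simulated
# two-condition cohort, ending in the seed-gene set. Reads the TSVs written
# by 01_simulate_cohorts.R and writes stage tables under results/dra/.

library(dcsig)

cohorts <- "results/cohorts"
out <- "results/dra"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

expr <- read_expression(file.path(cohorts, "two_condition_expr.tsv"))
samp <- read.delim(file.path(cohorts, "two_condition_samples.tsv"))
expr <- expression_matrix(expr$values,
                          condition = samp$condition[match(samples(expr),
                                                           samp$sample_id)])
lib <- read_edges(file.path(cohorts, "tf_target_library.tsv"), header = TRUE)

dc <- run_dcea(expr, conditions = c("normal", "tumor"),
               q = 0.75, delta = 0.5, alpha = 0.25, n_perm = 200, seed = 12L)
print(dc)
write_tsv(dc$gene_table, file.path(out, "dcg.tsv"))
write_tsv(dc$link_table, file.path(out, "dcl.tsv"))

de <- differential_expression(expr, conditions = c("normal", "tumor"))
message(sprintf("DEGs at BH q < 0.05: %d of %d", sum(de$is_deg), nrow(de)))
write_tsv(de, file.path(out, "deg.tsv"))

dcgs <- dc$gene_table$gene[dc$gene_table$is_dcg]
rk <- rank_regulators(lib, dcgs, dcl_pairs(dc), genes(expr),
                      alpha = 0.05, n_rand = 500, seed = 24L)
write_tsv(rk, file.path(out, "regulator_ranking.tsv"))

drgs <- select_drgs(rk, alpha = 0.05)
message("DRGs (significant in both TED and TDD): ",
        paste(drgs, collapse = ", "))

drl <- extract_drls(lib, dc)
write_tsv(drl, file.path(out, "drl.tsv"))

seeds <- assemble_seeds(drgs, lib, de$gene[de$is_deg], dcgs, drl)
print(seeds)
write_tsv(data.frame(gene = seeds$all_genes,
                     role = ifelse(seeds$all_genes %in% seeds$tfs,
                                   "tf", "target")),
          file.path(out, "seeds.tsv"))
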