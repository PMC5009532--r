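#!/usr/bin/env Rscript
# Subtype-specific regulatory networks by stepwise linear regression of each
# seed target on its library TFs, within the worst-prognosis subtype of
# cohort 1 and within the simulated normal samples, plus the edge-by-edge
# differential comparison. Writes results/networks/.

library(dcsig)

out <- "results/networks"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

lib <- read_edges("results/cohorts/tf_target_library.tsv", header = TRUE)
seeds <- read.delim("results/dra/seeds.tsv")$gene
seed_lib <- regulatory_library(
  lib$edges[lib$edges$regulator %in% seeds & lib$edges$target %in% seeds, ])

# normal condition: the normal half of the two-condition cohort
expr_tc <- read_expression("results/cohorts/two_condition_expr.tsv")
samp <- read.delim("results/cohorts/two_condition_samples.tsv")
expr_tc <- expression_matrix(
  expr_tc$values, condition = samp$condition[match(samples(expr_tc),
                                                   samp$sample_id)])
net_normal <- fit_network(subset_condition(expr_tc, "normal"), seed_lib,
                          label = "normal")
# tumor condition: the rewired seed modules are uncoupled here, so their
# edges should be lost relative to the normal network
net_tumor <- fit_network(subset_condition(expr_tc, "tumor"), seed_lib,
                         label = "tumor")

# worst-prognosis subtype of cohort 1
expr1 <- read_expression("results/cohorts/cohort1_expr.tsv")
labels <- read.delim("results/subtypes/labels_cohort1.tsv")
ord <- read.delim("results/subtypes/prognosis_order_cohort1.tsv")$cluster
worst <- labels$sample_id[labels$cluster == ord[length(ord)]]
expr_worst <- expression_matrix(expr1$values[, worst, drop = FALSE])
net_worst <- fit_network(expr_worst, seed_lib, label = "worst")

for (net in list(net_normal, net_tumor, net_worst)) {
  kept <- net$edges[net$edges$present, ]
  message(sprintf("network '%s': %d/%d edges retained, mean |efficacy| %.2f",
                  net$label, nrow(kept), nrow(net$edges),
                  mean(abs(kept$efficacy))))
  write_tsv(net$edges, file.path(out, sprintf("network_%s.tsv", net$label)))
}

cmp <- differential_network(net_normal, net_tumor)
write_tsv(cmp, file.path(out, "network_diff_normal_vs_tumor.tsv"))
message("normal vs tumor (planted rewiring - seed-module edges lost in tumor):")
print(table(cmp$status))

cmp_w <- differential_network(net_normal, net_worst)
write_tsv(cmp_w, file.path(out, "network_diff_normal_vs_worst.tsv"))
message("normal vs worst-prognosis subtype (weaker within-tumor coupling):")
print(table(cmp_w$status))
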