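#!/usr/bin/env Rscript
# Generate the synthetic study cohorts used by the downstream analyses:
# a two-condition (tumor vs normal) discovery cohort with four rewired TF
# modules, and four subtyped tumor cohorts sharing the planted signature
# TFs. Everything is written as TSV under results/cohorts/.

library(dcsig)

out <- "results/cohorts"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- pipeline_config(seed = 1L)
sim <- cfg$sim

tc <- simulate_two_condition(sim)
write_expression(tc$expr, file.path(out, "two_condition_expr.tsv"))
write_tsv(data.frame(sample_id = samples(tc$expr),
                     condition = unname(tc$expr$condition)),
          file.path(out, "two_condition_samples.tsv"))
write_tsv(tc$library$edges, file.path(out, "tf_target_library.tsv"))
write_tsv(data.frame(gene = c(tc$truth$rewired_tfs, tc$truth$rewired_targets),
                     role = rep(c("rewired_tf", "rewired_target"),
                                c(length(tc$truth$rewired_tfs),
                                  length(tc$truth$rewired_targets)))),
          file.path(out, "rewired_truth.tsv"))

message(sprintf("two-condition cohort: %d genes x %d samples, %d rewired modules",
                nrow(tc$expr$values), ncol(tc$expr$values),
                length(tc$truth$rewired_tfs)))

for (i in seq_len(cfg$n_cohorts)) {
  csim <- sim
  csim$seed <- sim$seed + 100L * i
  co <- simulate_subtyped_cohort(csim, signature_tfs = tc$truth$rewired_tfs,
                                 cohort = sprintf("cohort%d", i))
  write_expression(co$expr, file.path(out, sprintf("cohort%d_expr.tsv", i)))
  write_tsv(co$clinical, file.path(out, sprintf("cohort%d_clinical.tsv", i)))
  write_tsv(data.frame(sample_id = names(co$labels),
                       subtype = unname(co$labels)),
            file.path(out, sprintf("cohort%d_truth_labels.tsv", i)))
  message(sprintf("cohort %d: %d samples, %d events", i,
                  nrow(co$clinical), sum(co$clinical$event)))
}
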