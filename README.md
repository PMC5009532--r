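# dcsig — differential-coexpression subtyping and prognostic signature discovery

`dcsig` is an R implementation of an integrated strategy for finding
*compact* prognostic transcription-factor (TF) signatures from gene
expression data. The premise: differentially **expressed** genes are often
downstream consequences of disease, while differentially **regulated**
genes — TFs whose coupling to their targets changes between conditions —
are closer to its causes. The pipeline therefore:

1. **DCEA** — scores differential coexpression between two conditions
   (tumor vs normal). Gene pairs pass a half-thresholding filter (|r| above
   the pooled quantile *q* in either condition); gene *i* gets the
   root-mean-square correlation change over its retained links,
   `dc_score(i) = sqrt( Σ_j (r_A(ij) − r_B(ij))² / |L(i)| )`,
   with label-permutation p-values (the filter is re-derived inside every
   permutation) and BH correction; link changes `|Δr| ≥ δ` are classified
   DCLs (same-signed / differently-signed / switched).
2. **DEA** — per-gene Welch t-tests with BH correction.
3. **DRA** — ranks each library TF by **TED** (hypergeometric enrichment
   of DCGs among its targets) and **TDD** (density of DCLs among target
   pairs vs same-size random gene sets); TFs significant in *both* are the
   differentially regulated genes (DRGs), and library edges whose pair is
   a DCL are the differentially regulated links (DRLs).
4. **Seed assembly** — DRG targets that are DEG *and* DCG and keep a DRL
   form, together with the DRGs, the seed-gene set.
5. **Subtyping** — Brunet-style KL-NMF consensus clustering of each tumor
   cohort on the seed genes; model order chosen from consensus stability
   (dispersion, with the cophenetic coefficient reported alongside);
   clusters ordered by Kaplan–Meier median survival and compared by the
   k-group log-rank test; per-gene Cox hazard ratios per SD of expression.
6. **Signature** — best- and worst-prognosis cluster gene sets intersected
   across cohorts, united, and restricted to TFs; evaluated against random
   same-size signatures, drug-target (hypergeometric) enrichment, and
   cross-subtype Kruskal–Wallis tests.
7. **Networks** — subtype-specific TF→target regulatory networks by
   BIC-guided stepwise linear regression on standardized expression, with
   per-edge regulation efficacies and gained/lost/sign-flipped comparisons
   between conditions.

Because real multi-cohort tumor data cannot ship with a package, `dcsig`
includes first-class synthetic generators with planted structure — rewired
TF modules for the two-condition design, and subtyped cohorts with
signature-TF shifts and exponential survival — so the entire pipeline is
exercised and validated end to end. The methods vignette
(`vignettes/methods.Rmd`) documents every model, default and design choice.

## Worked example

```r
library(dcsig)

cfg <- pipeline_config(seed = 1)   # synthetic study conditions
res <- run_pipeline(cfg)           # DCEA -> DEA -> DRA -> seeds -> subtypes -> signature
print(res)
```

```
Signature-discovery pipeline result
  DRGs: TF01, TF02, TF03, TF04
  seed genes: 35
  candidates: 26 (best 9, worst 17)
  signature: TF02, TF01, TF04
  signature log-rank p (cohort 1): 0.000508
  random-baseline mean p: 0.12 over 20 draws
```

Reading this: four TF modules were planted as rewired (coupling 0.9 in
normal, 0 in tumor) and all four are recovered as DRGs; with their
filtered targets they yield 35 seed genes. Subtyping four simulated
cohorts on the seeds finds k = 3 subtypes each; intersecting the best- and
worst-prognosis cluster genes across cohorts leaves 26 candidates, whose
TF members are exactly the three planted extreme-subtype signature TFs
(`TF03`, which marks the intermediate subtype, is correctly excluded).
The recovered signature stratifies survival in cohort 1 at p ≈ 5e-4,
far below the mean p of 20 random three-gene signatures drawn from the
same candidate pool.

Per-gene hazard ratios behave as prognostic markers should — the
best-prognosis TF protective, the worst-prognosis TFs harmful (from
`analysis/04_signature.R`):

```
  gene        hr       beta        se       wald_p
1 TF02 0.7057755 -0.3484580 0.1039232 0.0007993069
2 TF01 1.2234060  0.2016388 0.1127947 0.0738306938
3 TF04 1.4736171  0.3877200 0.1093391 0.0003910805
```

## Analysis workflow

The `analysis/` scripts run the same study step by step, writing every
stage table under `results/`:

```sh
Rscript analysis/01_simulate_cohorts.R        # cohorts + planted truth
Rscript analysis/02_differential_regulation.R # DCG/DCL, DEG, TED/TDD, DRLs, seeds
Rscript analysis/03_subtype_cohorts.R         # NMF consensus subtypes + survival
Rscript analysis/04_signature.R               # candidates, signature, baseline, HRs
Rscript analysis/05_networks.R                # stepwise networks + differential edges
```

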