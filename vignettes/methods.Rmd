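---
title: "From differential regulation to a compact prognostic TF signature: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From differential regulation to a compact prognostic TF signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dcsig` implements an integrated pipeline for discovering small prognostic
transcription-factor (TF) signatures from gene expression: differential
coexpression analysis between two conditions, TF-level differential
regulation analysis, seed-gene assembly, NMF consensus subtyping of tumor
cohorts, survival-based distillation of a cross-cohort signature, and
subtype-specific regulatory-network inference. This vignette explains the
statistical models behind each stage, the tunable parameters and their
defaults, what the synthetic generators do and do not emulate, and the
design choices made where the method left room for them.

## The scientific idea

Differentially *expressed* genes are often downstream consequences of a
disease process; differentially *regulated* genes — TFs whose coupling to
their targets changes between healthy and diseased tissue — are closer to
its causes. The pipeline therefore prioritizes TFs by regulatory change
rather than expression change, uses their surviving targets to subtype
tumors, and keeps only genes that consistently mark the extreme-prognosis
subtypes across several cohorts. The end product is deliberately small (a
handful of TFs) so it is clinically measurable, and its validity is judged
by survival stratification, not by fit to expression alone.

## Differential coexpression (DCEA)

Within each condition the pipeline computes the Pearson correlation of
every gene pair. Three conventions then define the analysis:

* **Half-thresholding link filter.** The |r| values of both conditions are
  pooled; a pair is retained iff its |r| in *either* condition exceeds the
  `q`-th pooled quantile (`q = 0.75` by default). This keeps pairs that are
  strongly coupled in at least one condition — exactly the pairs whose
  change is interpretable.
* **Gene score.** For gene *i* with retained links *L(i)*,
  `dc_score(i) = sqrt( sum_{j in L(i)} (r_A(i,j) - r_B(i,j))^2 / |L(i)| )` —
  a root-mean-square correlation change. Genes with no retained link score 0.
* **Link classes.** A retained pair is a differential coexpression link
  (DCL) iff `|r_A - r_B| >= delta` (`delta = 0.5`). Sign-concordant DCLs are
  *same-signed*; discordant ones are *switched* when both |r| pass the
  filter cutoff and *differently-signed* otherwise.

Significance comes from permuting condition labels. One subtlety matters:
the permuted statistic must recompute the **whole** functional — including
the link filter — on each permuted split. Scoring permuted correlations on
the observed (selected) link set biases every observed score upward,
because those links were chosen for extremeness on the observed split; with
the filter re-derived per permutation, null p-values are uniform (the test
suite checks this by KS test). P-values use the add-one estimator
`(1 + #{perm >= obs}) / (n_perm + 1)`, so `p = 0` is impossible; genes are
flagged as differentially coexpressed (DCGs) at BH `q < 0.25` — a
deliberately permissive default, because the later intersection filters do
the real pruning.

Zero-variance genes (e.g. zero-filled missing genes) are excluded from
links rather than raising errors.

## Differential expression (DEA)

A per-gene Welch t-test on log-scale values with BH correction
(`alpha = 0.05`). A moderated (empirical-Bayes) test would share variance
information across genes; the plain Welch test was chosen because the
pipeline consumes only the binary DEG flag, and the Welch null is exactly
testable. Genes with zero variance in both groups get `p = 1`: a constant
gene cannot witness change.

## Differential regulation (DRA)

Given a candidate TF→target library, two statistics rank each TF:

* **TED** (targets' enrichment density): the one-sided hypergeometric tail
  `P(X >= x)` for the overlap between the TF's targets and the DCG set in
  the expressed-gene universe — the minimal formalization of "enrichment".
* **TDD** (targets' DCL density): the fraction of target pairs that are
  DCLs, calibrated by drawing `n_rand = 1000` random gene sets of the same
  size from the universe (add-one empirical p). TFs with fewer than two
  targets have no pair density and are excluded with a message.

Both p-vectors are BH-corrected across TFs, and a TF is a differentially
regulated gene (DRG) only when **both** q-values fall below `alpha = 0.05`
— a conjunction, not a union. Whether significance should be judged on raw
p or adjusted q is not dictated by the method's description; q was chosen
as the more conservative, multiplicity-aware reading.

Differentially regulated links (DRLs) are simply library edges whose
unordered pair is a DCL; orientation is not required to agree because
coexpression is symmetric.

## Seed assembly

Candidate targets of the DRGs must be DEG *and* DCG (step 1) and must keep
a DRL to some DRG (step 2); seeds are the DRGs plus the surviving targets.
On a regulatory table with 6 TFs, 82 distinct targets and 93 links this
yields the 88-gene seed-set size the worked examples check. Assembly is
monotone: shrinking the DEG or DCG sets can only shrink the seed set.

## NMF consensus subtyping

Seed-gene expression is made nonnegative by per-gene min-max scaling (the
cohorts may mix log and linear scales with negative values; scaling also
equalizes gene influence — a deterministic, scale-free choice; constant
genes map to zero and join no metagene). Factorization uses the classic
KL-divergence multiplicative updates (`W, H >= 0`, uniform random
initialization, `max_iter = 2000`, relative tolerance `1e-6` over
10-iteration windows; the objective is checked to be non-increasing).

Each of `n_runs` restarts assigns samples to their argmax metagene; the
mean of the resulting connectivity matrices is the consensus matrix.
Samples are finally labelled by cutting the average-linkage dendrogram of
`1 - consensus` at k, while gene–metagene assignment (for the cluster gene
sets) uses the lowest-objective run's `W` rows.

**Model-order selection.** Two stability summaries are computed per k:

* the *cophenetic correlation* between the dendrogram's cophenetic
  distances and `1 - consensus`, and
* the *dispersion coefficient* `mean(4 * (C - 1/2)^2)`, which is 1 exactly
  when the consensus is binary (perfectly reproducible clustering).

The chooser takes the largest k whose stability is at least `tau`, falling
back to the argmax when none qualifies. It is fed the **dispersion** by
default (`tau = 0.90`). The reason is a structural property worth spelling
out: when k exceeds the true order, the surplus splits produced by
different restarts are usually *nested inside* the true clusters, so the
consensus matrix remains perfectly tree-like and the cophenetic correlation
stays above 0.95 no matter how unstable the extra split is — it measures
tree-likeness, not crispness. The dispersion collapses exactly there
(within-block consensus values fall toward 1/2) and cleanly identifies the
planted order in simulation, so it drives the automated choice; the
cophenetic profile is still computed and reported for inspection. For the
same reason a dedicated stability threshold (0.90 on the dispersion scale)
applies rather than the 0.95 conventionally quoted for cophenetic values.

Rank bounds: `k <= min(dim(V))` is allowed, including equality — clustering
a 3-gene signature panel into 3 subtypes is exactly the exact-rank edge
case the method needs; infeasible ks are dropped from the scan. The default
scan is `k in 2:4`, bracketing the planted order of the synthetic cohorts;
wider scans are a parameter away.

Clusters are ordered by decreasing Kaplan–Meier median survival (mean
observed time when the curve never reaches 0.5; remaining ties break by
cluster index).

## Survival machinery

Kaplan–Meier estimation, the k-group log-rank test and univariate Cox
models are delegated to the `survival` package (`survfit`, `survdiff`,
`coxph` with Efron ties — ties are common in year-resolution data), behind
validating wrappers; the test suite checks them against hand-computed
product-limit values and an explicit observed-minus-expected tabulation.
Hazard ratios are fitted on expression standardized to unit variance, so
`HR` is per SD of expression and no arbitrary high/low cutpoint is needed;
`HR > 1` means high expression associates with earlier death.

## Signature distillation and evaluation

Per cohort, the best- and worst-prognosis clusters contribute their gene
sets; intersecting each across cohorts and uniting the two intersections
gives the candidate pool, and the final signature is the candidates that
are library regulators (TF status is defined by the library, keeping the
pipeline self-contained). Three evaluations accompany it:

* **Random-signature baseline**: repeated same-size draws from the
  candidate pool, each re-subtyped and log-rank tested; the whole p-value
  list is reported (not only its mean) and a real signature should beat the
  mean. One clustering seed is shared across draws so identical draws give
  identical p-values.
* **Drug-target enrichment**: hypergeometric tail of the signature's
  overlap with a drug-target list, with the background rate reported as a
  percentage of the expressed universe (1,277 of 20,284 gives the 6.3%
  worked example).
* **Cross-subtype expression**: Kruskal–Wallis test per signature gene
  (chosen as the standard distribution-free k-group location test);
  constant genes return statistic 0, p 1.

## Regulatory networks

Within one group's samples (a subtype, or the normal condition), each
target is regressed on its library TFs by bidirectional stepwise selection
on standardized variables starting from the empty model. The default
selection penalty is `log(n)` (BIC) rather than AIC: with AIC's fixed
penalty of 2, a spurious candidate survives with probability
`P(chi-sq_1 > 2) = 0.157`, so null targets would keep edges in a third of
fits and edge precision could not reach the intended 0.9; BIC brings the
per-candidate false-inclusion rate to ~0.03 at n = 100 while leaving power
for standardized effects >= 0.5 essentially at 1. Candidates enter in
lexicographic order, making ties deterministic. The fitted standardized
coefficients are the regulation *efficacies* (sign = activation vs
repression, magnitude = strength); groups under 10 samples are refused.
Edge-by-edge comparison of two networks labels each library edge
`absent-both`, `gained`, `lost`, `sign-flipped` or `stable`.

## The synthetic study conditions

The generators exist so every stage is testable without any cohort
download; their defaults are the package's study conditions.

**Two-condition cohort** (`simulate_two_condition`): each TF module has a
standard-normal latent TF and targets `beta_c * TF + N(0, noise_sd^2)`
(`noise_sd = 0.6`), giving the analytically controlled within-condition
correlation `r = beta / sqrt(beta^2 + noise_sd^2)`; background genes are
independent noise. Modules whose `beta` differs between conditions
(typically `0.9 -> 0`) are the rewired truth. Rewired-module targets also
receive a 1-SD tumor-side mean shift: differential regulation in real
tumors is accompanied by differential expression of the affected targets,
and without it the seed-assembly rule (DEG **and** DCG) could never fire.

**Subtyped cohorts** (`simulate_subtyped_cohort`): balanced subtypes; each
signature TF is elevated by `signature_shift` SD (default 2) in its
designated subtype. Two couplings are deliberately separated: the subtype
program shifts target *baselines* directly by
`target_response * signature_shift` (default 0.75), while targets track the
TF's sample-to-sample *fluctuation* only weakly (`beta_cohort = 0.3`). The
separation reflects that a constitutive program rewires target baselines
stably, whereas moment-to-moment TF fluctuation couples loosely; it also
matters statistically — if the entire shift travelled through the shared
latent factor, module targets would carry no class information beyond the
TF itself and no clustering method could exceed ~85% accuracy at 2-SD
shifts, contradicting what clearly subtyped cohorts look like. Signature
TFs are dealt round-robin over the subtypes ordered worst-prognosis,
best-prognosis, then intermediates, so survival-associated markers land in
the extreme subtypes first; intermediate-subtype programs exist but their
TFs should be *excluded* by the best/worst consensus — the pipeline's
end-to-end test plants four program TFs and expects exactly the three
extreme ones back. Survival is exponential with per-subtype hazards
(defaults 1.0, 0.5, 0.2 per year) under independent uniform censoring
(horizon 10 years).

What the generators do **not** emulate: microarray noise models, batch
effects, probe-level artifacts, non-proportional hazards, correlated
censoring, overlapping regulons, or any raw-data processing. Passing tests
therefore demonstrate that the machinery recovers planted structure under
its stated model — not that real cohorts would yield any particular genes.

## Problem sizes and numerical choices

The test-suite and acceptance analyses run at deliberate desk scale:
300-gene/100-sample matrices with 500 permutations for calibration and
recovery; four 120-sample cohorts, 20 NMF restarts per k over `k in 2:4`
and 200 permutations inside the end-to-end replicates; 1000 resampling
draws for TDD; 20 random baselines. Add-one estimators keep empirical
p-values off zero; `1e-16`-floored denominators keep the multiplicative
updates defined; all stage seeds derive from one master seed, so every run
is exactly reproducible from its manifest.

## Known limitations

* Pearson correlation only; no soft-thresholding or alternative
  coexpression measures.
* Exactly two conditions in DCEA/DEA.
* The DCG/DCL thresholds are conventions of this implementation; absolute
  DCG counts are therefore not comparable across implementations of the
  same idea.
* Gene–cluster attribution via argmax of `W` is one of several defensible
  conventions and matters only through the cross-cohort intersection.
* Univariate Cox models without covariate adjustment or proportionality
  diagnostics.
* Stepwise selection inherits the usual caveats of selected inference —
  efficacies are reported without post-selection confidence intervals.
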