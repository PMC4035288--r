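---
title: "Deriving grade signatures and reclassifying G2 breast tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving grade signatures and reclassifying G2 breast tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradeweaver)
```

## The problem

Histological grading assigns breast tumors to G1 (well differentiated,
good prognosis), G3 (poorly differentiated, poor prognosis) or G2 in
between. G1 and G3 are molecularly and clinically distinct; G2 is not a
coherent third state but, on the working hypothesis of this package, a
mixture of G1-like and G3-like tumors that pathology cannot separate.
`gradeweaver` derives a grade signature by requiring three independent
layers of evidence to agree — differential mRNA expression between G1 and
G3, a concordant gene-level copy-number alteration, and an
oppositely-directed miRNA that targets the gene — and then uses the
signature to re-assign each G2 tumor to G1\* or G3\*, validating the
split against relapse-free survival.

## Differential expression

For a two-class contrast the per-feature statistic is

$$d_i = \frac{\bar{x}_{iB} - \bar{x}_{iA}}{s_i + s_0}, \qquad
s_i = \sqrt{\left(\tfrac{1}{n_A} + \tfrac{1}{n_B}\right)
\frac{SS_{iA} + SS_{iB}}{n_A + n_B - 2}},$$

with $SS$ the within-class sums of squared deviations. The fudge factor
$s_0$ prevents low-variance features from dominating: candidates are the
0, 5, …, 100 percentiles of $\{s_i\}$, and `choose_s0()` picks the one
minimizing the coefficient of variation of the median absolute deviation
of $d$ across deciles of $s_i$ (ties to the smallest percentile), making
the spread of $d$ approximately independent of $s_i$.

Q-values come from a permutation null: for `B` label shuffles (or the
complete enumeration when `B = "all"`),

$$q_i = \min\!\left(1,\;
\frac{\tfrac{1}{B}\sum_b \#\{j : |d^{*}_{jb}| \ge |d_i|\}}
     {\#\{j : |d_j| \ge |d_i|\}}\right),$$

with the null proportion $\pi_0$ fixed at 1 — deliberately conservative,
since the pipeline's downstream intersections amplify any false positive.
A running maximum down the $|d|$-ranked list enforces monotonicity so a
weaker feature can never get a smaller q than a stronger one.
Zero-variance features with $s_0 = 0$ are flagged and assigned $d = 0$,
$q = 1$ rather than raising an error. Calls use q < 0.01 by default, the
threshold applied to both mRNAs and miRNAs.

Merged sub-cohorts are harmonized first. `batch_adjust()` offers an exact
location/scale mode (`meanvar`: each batch rescaled per gene to the
weighted grand mean and pooled within-batch sd — idempotent by
construction) and a parametric empirical-Bayes mode (`eb`): per-gene
standardization, then per-batch gene-wise means shrunk toward a normal
prior and variances toward an inverse-gamma prior, hyperparameters by
method of moments across genes, in a single (non-iterated) step. The
one-step estimator keeps the procedure in closed form and testable
against an independent re-derivation; with thousands of genes the
difference from an iterated solution is negligible.

## Copy number and integration

Segments are classified gain/loss against thresholds appropriate to the
encoding — absolute copies (gain ≥ 2.5, loss ≤ 1.5, diploid 2; the
default) or log2 ratio (±0.3). A gene is gained/lost in a sample iff its
interval overlaps a gain/loss segment by at least one base; coordinates
are 0-based half-open everywhere (BED convention) to keep a single
internal convention. Overlap with both a gain and a loss in one sample is
a conflict, excluded from counts: the simplest rule that avoids double
counting. Any-overlap (rather than majority-overlap) calling is used
because an alteration touching any part of a gene can affect its dosage.
Per grade, genes are ranked by their dominant alteration frequency
`max(gain_freq, loss_freq)` and the top K (default 6000) kept — one
combined ranking with lexical tie-breaks so results are deterministic;
each selected gene joins the amplified set if gains dominate, else the
deleted set.

Stage II intersects calls with CNA per grade: up-in-G3 ∩ amplified-in-G3,
down-in-G3 ∩ deleted-in-G3, and the G1-side mirror images, where "up in
G1" is bookkept as "down in G3" — one G1-vs-G3 contrast is run and read
in both directions rather than running per-grade contrasts. Stage III
gates each stage-II set by miRNA targets in the opposite direction
(classes 1–4); a gene appearing in classes of both grades is kept in
both, and the union deduplicates into the gene signature (likewise for
miRNAs). `downsize_signature()` intersects a candidate with the *union*
of reference signatures — a gene needs support from any one published
signature, not all of them — and reports per-reference membership.

## Classifier

The SVM treats the soft-margin optimizer (kernlab's SMO) as an
exchangeable component: all three kernels — linear $x \cdot y$, RBF
$\exp(-\gamma\|x-y\|^2)$, ANOVA $(\sum_d \exp(-\gamma (x_d-y_d)^2))^p$
(degree $p$ = 1 by default; unspecified in common usage) — are authored
here and supplied as precomputed Gram matrices. The default grid takes
$\gamma, C \in \{5j/30 : j = 1..30\}$: 30 evenly spaced values in (0, 5],
zero excluded because $C = 0$ and $\gamma = 0$ are degenerate. Grid
selection maximizes mean accuracy under seeded, stratified k-fold
cross-validation (k = 10 by default) inside the training data only — a
flat rather than nested search, documented as such; fold-level metrics
give normal-approximation 95% CIs ($\bar{m} \pm 1.96\,s/\sqrt{k}$,
clipped to [0, 1]). Sensitivity is G3 recall and specificity G1 recall
throughout; AUC is the rank (Mann-Whitney) statistic of the decision
scores with ties counted ½.

`reclassify_g2()` runs the three-step workflow: grid-search and train on
G1/G3; assign each G2 sample to G1\*/G3\*; re-run the same grid search on
the G2 samples under their new labels and evaluate on the original G1/G3
samples (single train/test: Wald binomial CIs, test-set rank AUC). The
retrain re-searches the grid rather than reusing the step-1 parameters
(`reuse_params = TRUE` gives the alternative); if either starred class
ends up with fewer than two members the retrain is skipped and flagged
degenerate.

## Survival validation

Kaplan-Meier product-limit curves, the unweighted two-group log-rank test
(p from $\chi^2_1$), and a univariate Cox model provide the validation
layer, computed via the `survival` package. Ties are handled by the
Breslow approximation (Efron available via a flag) — survival times in
months tie often, and Breslow keeps the partial likelihood simple enough
to verify against a brute-force grid maximization in the tests. Hazard
ratios are $\exp(\hat\beta)$ with Wald 95% CIs; a diverging coefficient
(complete separation of events) raises an error recommending exact or
penalized methods rather than returning a meaningless estimate. The three
planned comparisons are G1\* vs G3\* (the signal), and G1 vs G1\* / G3 vs
G3\* (expected null if reclassification is faithful). Comparisons with an
empty group, or with no events at all (log-rank $\chi^2 = 0$, p = 1), are
flagged degenerate instead of erroring.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the pipeline
assumes, with planted ground truth for recovery tests:

* **Grades and the G2 mixture.** Each G2 sample draws a latent label, G3
  with probability `g2_mixture_prop` (default 0.5), and its expression,
  copy number and hazard all follow the latent label with no attenuation
  — the cleanest realization of the mixture hypothesis and a sharp
  recovery target.
* **Expression.** Gene × sample values are
  baseline + grade effect (±`delta` at the informative genes in latent-G3
  samples) + per-batch gene-wise Gaussian shift + scaled Gaussian noise.
  Defaults `delta = 1.5`, `noise_sd = 1` (log2 units) sit in the range
  typical of moderate microarray effects; the defaults use three
  sub-cohorts with shift sd 0.4 and noise scales 0.9–1.15. miRNAs use the
  same additive Gaussian model (arrays, not sequencing counts).
* **CNA.** Informative genes carry gains (CN 3) in the concordant latent
  grade and losses (CN 1) in the other, each at frequency
  `cna_gain_freq`/`cna_loss_freq` (default 0.6) per sample, as one
  segment per altered gene on a toy genome (single chromosome, gene *i*
  at [*i*·1000, *i*·1000 + 500)) — enough to exercise the interval logic
  without a real annotation.
* **miRNAs.** Planted miRNAs partition the informative genes into target
  blocks (`targets_per_mirna`, default 5) and move by `mirna_effect`
  opposite to their targets; background miRNAs target random null genes.
* **Survival.** Relapse times are exponential with `hazard_g1 = 0.01`
  and `hazard_g3 = 0.04` per month (hazard ratio 4, median relapse-free
  survival ≈ 69 vs 17 months); each subject is censored with probability
  `censor_rate` (default 0.3) at a Uniform(0, t) instant.
* **Determinism.** One seed, one RNG stream: the same configuration
  reproduces every artifact byte-for-byte.

Default group sizes are 78/78/78, matching a balanced three-group design;
`balance_groups()` subsamples unbalanced cohorts to equal sizes.

What the generator does *not* emulate — probe-level noise, realistic
segment-length and LD structure, dosage-to-expression coupling, correlated
gene networks, non-exponential hazards — bounds what passing tests show:
they demonstrate that each stage recovers the structure it assumes, not
that the pipeline is robust to every artifact of real microarray data.

## Numerical and design choices

* Permutations are full label shuffles (not balanced-only), seed
  recorded in the result; `B = "all"` enumerates every distinct label
  assignment for exact small-sample nulls.
* The pipeline's master seed fans out to per-stage sub-seeds via a small
  string hash (`stage_seed()`), so any stage can be re-run in isolation
  and reports reproduce byte-for-byte (no timestamps in the JSON).
* Copy-number encoding (absolute vs log2 ratio) is a config switch
  defaulting to absolute; SEG inputs in 1-based inclusive coordinates
  must be pre-converted to 0-based half-open.
* Tests and examples run the generator and classifier at reduced sizes
  (hundreds of genes, 5-fold CV, grids of a few values); the package
  defaults above are the study-scale settings.

## Limitations

Only binary G1/G3 classification is supported (G2 enters as test data
only); no multivariate or time-varying Cox models; no probe-level
processing, segmentation, or miRNA target prediction — normalized
matrices, SEG segments and a target table are consumed as given. The
stage-III signature inherits every upstream threshold (q, CNA thresholds,
top-K); classes are sensitive to the target map's completeness, and an
empty map yields empty classes with a warning.
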