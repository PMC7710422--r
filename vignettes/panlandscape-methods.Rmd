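---
title: "Methods: the multi-omic landscape pipeline and its synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the multi-omic landscape pipeline and its synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`panlandscape` re-implements a pan-cancer multi-omic landscape analysis of a
small gene family — by default the six hypoxia-inducible factor genes — as a
set of independently testable stages over tabular omic layers, together with
a synthetic cohort generator that plants known effects in every layer. This
vignette records the statistical model of each stage, the defaults and why
they were chosen, what the generator does and does not emulate, and the
design decisions that were genuinely open.

## Data model

Every omic layer travels as a genes × samples matrix with declared value
semantics (`raw_count`, `normalized_expression`, `beta`, `cnv_call`,
`protein_level`, `drug_auc`); validation is semantics-aware (beta in [0, 1],
calls in {−2..2}, counts non-negative integers). Samples carry TCGA-style
barcodes; field 3 identifies the participant and the first two characters of
field 4 the sample-type code. We use the conventional code table — 01–09
tumor-derived, 10–19 normal-derived — and specifically 01 (primary tumor)
and 11 (solid tissue normal); tumor/normal layers are matched per
participant, and cross-layer correlations are computed on barcode-matched
samples only. Somatic mutations are a MAF table that additionally carries
the full cohort sample universe, so unmutated samples enter frequency
denominators.

## Stage models

**Differential expression.** Counts are normalized by median-of-ratios size
factors (rescaled to geometric mean 1 so that identical samples get factor
1); the log2 fold change is `log2((mean_tumor + 0.5) / (mean_normal + 0.5))`
on the normalized scale, and the p-value a Welch two-sample t on
`log2(normalized + 1)`. The named DE engine of the original analysis is a
dispersion-shrinking negative-binomial model; we deliberately substitute
this fully specified statistic because the landscape's claims rest on the
fold-change and FDR gates, not on the engine, and an explicitly defined
statistic is exactly testable. Gates: |log2FC| ≥ 1 *boundary inclusive*
("fold change cutoff 2" read as FC ≥ 2) and Benjamini–Hochberg FDR < 0.05,
computed within each cancer across the tested genes. The pseudocounts (0.5
in the fold change, 1 in the log transform) are stated so tests can assert
exact values. Zero-variance degenerate groups give p = 1 when means agree
and p = 0 otherwise.

**CNV.** Gene-level thresholded calls use the conventional five-level
coding; segmentation is upstream and out of scope. Event percentages are
simple sample fractions. The ">5% CNV shown" display rule is strict (a gene
at exactly 5.0% is hidden) and, by default, applies to the *union* of the
four event categories; whether the original figure filtered per category or
on the union is not decidable from the text, so both are supported
(`display_rule = "per_category"`). Call–expression association is Spearman
with average ranks; the integer call itself is the CNV variable.

**Methylation.** Gene-level beta values (promoter probes are assumed
collapsed upstream, e.g. by averaging; the collapsing rule is not part of
the pipeline precisely because the original probe selection is unknown).
The tumor–normal test is Student's pooled-variance t — pooled rather than
Welch because the source names Student's t. Methylation–expression
correlation is Spearman on barcode-matched samples.

**Mutation.** A sample is "mutated" for a gene if it has ≥ 1 non-silent
record; Silent is excluded from frequency by default (`include_silent`
flips this) but retained in the classification spectra under its own label.
Multi-hit samples count once. Single-base substitutions are collapsed to
the six pyrimidine-context classes (G>C → C>G etc.); indels and multi-base
alleles are non-SNV.

**Pathway activity.** RPPA components are centered on their median and
scaled by their standard deviation (n − 1 convention, stated for
exactness); zero-variance components are dropped with a warning, and the
operation is idempotent. The per-sample score is the sign-weighted *mean*
over available members — the combination rule is unstated in the source;
the mean (rather than the sum) keeps scores comparable across pathways of
different sizes. Expression is median-split (strictly greater than the
median goes high; ties go low — stated for determinism at even n), groups
are compared with Student's t, and FDR is BH per cancer across all
gene × pathway tests, mirroring per-cancer heatmap cells. The cross-cancer
summary reports the percentage of cancers activated (`pathway_a`) and
inhibited (`pathway_i`), and the heatmap filter keeps pairs functional in
at least 5 cancer types (inclusive). The ten hallmark pathway definitions
shipped with the generator are synthetic placeholders (four members each,
two pathways with an inhibitory member); real antibody-to-pathway maps are
an input file in any real-data application.

**Drug response.** Spearman ρ between cell-line expression and drug AUC is
the headline statistic (the Results of the source use Spearman; its Methods
mention a Pearson-of-Z variant, available via `method = "pearson"`).
ρ is Fisher-Z transformed (`atanh`, after clipping to ±(1 − 10⁻¹²) to keep
z finite at |ρ| = 1), p comes from the t-approximation, and the garbled
"family error rate of z-scores less than 0.025" is resolved as the only
self-consistent reading: a two-tailed test at family-wise α = 0.05 (0.025
per tail), Bonferroni-corrected over all gene × drug pairs. Positive ρ is
resistance (higher AUC). The resampling comparison uses mean |ρ| over the
designated target pairs — absolute value because both sensitivity and
resistance count as "related" — against same-size draws without replacement
from non-target pairs, with the add-one empirical p
`(1 + #{null ≥ obs}) / (1 + iterations)`.

**Survival.** The source reports favorable/unfavorable calls per gene but
never states its survival methodology; this stage is therefore an explicit
stand-in, designed to recover a planted hazard direction: median split
(ties low), standard two-group log-rank (hypergeometric
observed/expected accumulation, χ² with 1 df), direction from the sign of
the high group's observed-minus-expected death count. A log-rank on a
median split needs no iterative fitting and matches the binary presentation
of the original figure; no hazard ratio is estimated. Calls are per-gene at
α = 0.05 without multiplicity correction (as in the per-gene landscape
figure); `adjust = TRUE` applies BH.

Shared numerical conventions: Spearman p-values use the t-approximation
`t = ρ √((n−2)/(1−ρ²))` everywhere (including at small n, where R's
`cor.test` would switch to an exact method); fewer than 3 complete pairs or
a constant margin yields a missing-value record, never a crash; BH excludes
`NA` p-values from the family size.

## The synthetic cohort generator

`generate_cohort()` emulates the data universe the landscape consumes — it
is a study-conditions generator, not a TCGA simulator:

- **Counts**: negative binomial, gene baselines log-uniform in
  [2⁴, 2¹²], one global dispersion (default 0.1; the simplest model that
  makes the DE test non-trivial), tumor means multiplied by
  2^(planted log2FC).
- **CNV**: per-gene event rates; default target-gene burden is 55%
  (25/10/15/5% for het-amp/hom-amp/het-del/hom-del) — the high-burden
  regime of amplified oncogene loci, and the regime in which a dosage
  slope of 0.5 is recoverable at 60 tumors; background genes are nearly
  neutral (3%). Expression means are further multiplied by
  `1 + slope · call / 2`.
- **Methylation**: logit-normal beta values (sd 0.5 on the logit scale),
  tumor mean shifted by the planted beta delta; the logit-scale noise is
  shared into the expression model with the planted slope, so
  methylation–expression correlation is real, not coincidental.
- **Mutations**: per-(sample, gene) Bernoulli with the planted frequency;
  classifications 70% missense, 10% nonsense, 10% silent, 10% frameshift
  deletion; half of SNVs are forced into the C>G class (the class the
  landscape reports as dominant). Because 10% of planted variants are
  Silent, the default silent-excluding frequency estimates ≈ 0.9 × the
  planted probability; recovery checks either include Silent or account
  for the factor.
- **RPPA**: members are standard normal, with ±shift/|members| added to
  expression-high samples (sign per member role), so the planted PAS
  displacement is `shift / |members|`.
- **Drugs**: Gaussian copula — AUC latent = ρ·z_gene + √(1−ρ²)·noise —
  so the planted ρ is the true Pearson correlation (Spearman sees the
  usual (6/π)·asin(ρ/2) attenuation, ≈ 0.58 for 0.6).
- **Survival**: exponential times; hazard ratio 2 (unfavorable) or 0.5
  (favorable) between realized median-split expression groups; independent
  exponential censoring tuned to ≈ 30% censored.

One realized expression value per sample links the layers (CNV dosage and
methylation feed the count means; PAS grouping and survival hazards follow
the realized counts), so cross-layer recovery tests exercise real
dependence. The whole bundle is a deterministic function of the
configuration, including its seed.

Default cohort sizes are 20 tumors + 20 matched normals per cancer, 300
cell lines, 30 drugs. Planted defaults mirror the landscape's reported
qualitative findings: log2FC ±2; ARNT dosage slope 0.5; HIF3A
hyper-/HIF1A hypo-methylation at |Δβ| = 0.2 with negative
expression coupling; mutation probabilities 0.26 (EPAS1, HIF3A) and 0.17
(ARNTL) matching the reported ~26%/~17% marks; PAS displacement 4 (i.e. 1
PAS unit over 4 members, a clearly "functional" pathway shift) for
HIF1A→EMT, HIF3A→PI3K/AKT and an inhibitory ARNT→Cell Cycle; three
EPAS1-sensitizing drugs at ρ = −0.6; HIF1A unfavorable and ARNTL favorable.

What the generator does **not** emulate: real TCGA effect-size and
sample-size distributions, probe-level methylation, mutational signatures
beyond the C>G excess, batch effects, subtype structure, or dependence
between drugs. Passing recovery tests therefore demonstrates that each
stage detects what it claims to detect under its stated model — not that
the original biological findings reproduce.

## Verification strategy and problem sizes

Each statistic is checked two ways: against an independent brute-force
oracle (step-up definition for BH on an exhaustive grid of p-vectors of
length ≤ 6; rank-then-Pearson over all 120 permutations of 5 values;
hand-accumulated log-rank on all fixture datasets of ≤ 8 samples; textbook
pooled/Welch t formulas on 3+3 inputs), and by parameter recovery on
planted cohorts over 100 seeded replicates per stage, at stage-appropriate
sizes: 20+20 samples for expression and methylation, 60 tumors for CNV
dosage, 40 tumors for pathway activity, 200 tumors for survival and
mutation frequency, 300 cell lines for drugs. Null calibration uses a
500-background-gene cohort with all effects zero (per-stage significant
call rate at FDR 0.05), 100 replicates of a 100 × 50 × 100 null drug panel
(Bonferroni family-wise error), and 200 null resampling runs (empirical-p
hit rate at 0.05). These sizes keep the default suite in the low minutes on
one CPU while leaving comfortable statistical margins.

## Limitations

- The DE statistic approximates, but is not, the shrinkage-based engine of
  the original analysis; at very small n or extreme dispersion the two can
  disagree.
- Gene-level inputs only: no probe, segment, or isoform resolution.
- The survival stage is a defined stand-in for an unstated methodology.
- Pathway membership and signs are configuration, not curated biology.
- The resampling null treats gene × drug pairs as exchangeable, ignoring
  correlation among drugs sharing a target.
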