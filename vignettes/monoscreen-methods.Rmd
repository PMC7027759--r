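---
title: "Methods: GRS-based screening for monogenic diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GRS-based screening for monogenic diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monoscreen)
```

## The screening model

Essentially all autoimmune Type 1 diabetes arises on a high polygenic-risk
background dominated by HLA class II. A small panel of SNPs summarized as

$$\mathrm{GRS}_j = \sum_i w_i\, g_{ij}, \qquad w_i = \ln(\mathrm{OR}_i),
\quad g_{ij} \in \{0,1,2\},$$

therefore separates Type 1 diabetes from aetiologies that are independent
of that background, monogenic diabetes in particular. The score is
reported as the raw weighted sum — not divided by the number of SNPs — so
that it lives on the scale of the published reference summaries (Type 1
diabetes median 10.7, controls 8.1). A child with recent-onset diabetes
whose GRS sits where population controls sit is a candidate for monogenic
gene sequencing; a child with a typical Type 1 diabetes score is not. The
package combines this score with triple islet-autoantibody status and a
consanguinity flag, the three pieces of evidence a screening pathway in a
highly consanguineous population would use.

Logistic regression on the single score is deliberately omitted: a
monotone transform of the predictor leaves its ROC curve unchanged, so the
score's ROC already is the regression's ROC.

## Genotype handling

Panel variants are located in a VCF by chromosome and position with allele
agreement, not by identifier (identifiers drift between builds). Matching
is attempted on REF/ALT as given, then with risk/other swapped. Weight
table alleles are defined on the positive strand; a pair that matches only
after complementation is a strand inconsistency and raises an error — for
an A/T or C/G SNP a silent flip is indistinguishable from a genuine strand
error, so no automatic flipping is ever performed.

Missing calls on a nine-SNP panel are consequential (one missing HLA tag
can move a score by up to 4 units), so the default policy is `fail`.
`skip` (score over typed SNPs) and `mean_impute` (dosage replaced by
2·p̂ from the cohort's observed calls) are explicit opt-ins; with no
missing calls all three agree exactly, which is tested.

## Centiles and the summary-form reference

The reference distribution for "Type 1 diabetes centiles" is available
only as a published median and IQR, so the package represents it as
Normal(median, σ) with σ = IQR/1.349 — 1.349 being the IQR of a standard
normal in σ units. Centiles are then 100·Φ((s − m)/σ) and the score at a
centile is the corresponding normal quantile. This approximation is the
documented stand-in for the unavailable empirical reference: on the six
published monogenic cases it reproduces the published centiles to within
about 1.5 centile points (one of them, 14.6, exactly), and the 15th
centile of the reference distribution comes out at 9.2 to one decimal —
the published screening threshold.

Empirical references (a score vector) use mid-rank counting for centiles,
chosen to be consistent with the Mann-Whitney AUC: the centile of a score
equals 100× its Mann-Whitney placement against the reference sample.
Quantiles use type-7 linear interpolation, R's default, and the same
convention is used for every median/IQR the package reports.

The closed-form AUC between two summary-form distributions is the
binormal expression Φ((m₁ − m₀)/√(σ₁² + σ₀²)). Applied to the published
case/control summaries it gives 0.863, consistent with the published
0.87 (95% CI 0.86–0.88). A value below 0.5 (inverted medians) is returned
unmodified; orientation is the caller's decision.

## Antibody panel

Positivity thresholds are the assay cut-offs set at the 97.5th centile of
1500 controls: GAD ≥ 11 U/ml, IA2 ≥ 7.5 U/ml, ZnT8 ≥ 65 U/ml, compared
inclusively. Subjects with any failed assay are excluded from panel
denominators (`tested = FALSE`) rather than imputed, and denominators are
carried alongside every percentage. Venn cells partition tested subjects
by construction; the incremental-yield identity
`n_with_added = n_base_pos + n_added_only` and the threshold monotonicity
property (raising a cut-off never increases a count) are tested.

## Runs of homozygosity

The consanguinity evidence in the motivating study came from a read-level
homozygosity method; this package instead provides a conventional
genotype-window ROH caller, and keeps the downstream decision rule
unchanged. A run is a stretch of consecutive non-missing calls with at
most `max_het` heterozygotes (default 1), at least `min_snps` variants
(default 50) and no inter-variant gap above `max_gap_bp` (default 1 Mb).
Conventions worth stating:

- Missing calls are removed before scanning: they neither break nor extend
  a run, so output is invariant to padding the input with missing calls.
- Candidate runs start and end on homozygous calls; unspent het budget is
  not used to append edge heterozygotes.
- Where overlapping runs both qualify (a het near a boundary), a greedy
  left-to-right scan keeps the longest run at each start, so reported
  segments never overlap. The detector works on the run-length encoding of
  the het track, which makes it linear in the number of het runs.

The decision rule on top is exactly the study's: flagged when segments
longer than 3 Mb cover more than 3% of the genome, both comparisons
strict as printed; the level corresponds roughly to second-cousin
parental relatedness. Known first/second-cousin parentage is an input
annotation OR-ed with the computed flag. The genome size is supplied, not
inferred, so toy genomes are testable.

## Discrimination statistics

The AUC is computed by the midrank formula (concordant pairs + half ties
over n₊·n₋), tested against an O(n²) pair-counting oracle to 1e-12 and
cross-checked against an independent ROC implementation. Orientation is
explicit; the screening orientation is `lower_in_pos` (monogenic cases
carry low scores).

The published analysis does not state its CI method, so the default is
DeLong's asymptotic interval, with a class-stratified, seeded percentile
bootstrap as the alternative; a degenerate point AUC of exactly 0 or 1 has
no DeLong variance and falls back to the bootstrap with a warning.

The screening threshold implements the full-sensitivity rule: the
smallest value on a 0.1 grid strictly above every monogenic score, with
the classification rule *score < threshold ⇒ screen positive* (the grid
matches the one-decimal precision of the published threshold, and the
strict inequality matches its "<9.2" semantics). On the six published
monogenic scores this yields 9.2 with sensitivity 1. Number needed to
test is ceil[(sens·n₊ + (1−spec)·n₋)/(sens·n₊)]; at sensitivity 1.00,
specificity 0.82 and 6 vs 121 children it equals 5.

Group comparisons follow small-cohort practice: proportions by chi-squared
test, switching to Fisher's exact test when any expected cell is below 5 —
unavoidable with a group of six, and the only way a 0/6 vs 84/119 contrast
yields a finite exact p (0.00096, printed as 0.001). Continuous variables
use the Wilcoxon rank-sum test, exact when both groups have ≤25
observations, otherwise the normal approximation with continuity
correction; with ties R falls back to the approximation internally. The
test actually used is reported in every row. Type-I error of this
procedure under a simulated null is checked against its nominal 5% level
in the test suite.

## The synthetic cohort generator

The generator's purpose is to reproduce the *statistical structure* the
analysis assumes, at the study's size (6 monogenic vs 121 Type 1
diabetes), so every pipeline stage runs and can be closed-loop tested
without external data.

**Genotypes.** Dosages are Binomial(2, p) per variant under
Hardy-Weinberg. Control-like subjects (and monogenic children, per the
study premise that they carry background risk-allele load) use the
panel's control frequencies p₀; Type 1 diabetes subjects use case
frequencies p₁ = p₀·OR/(1 − p₀ + p₀·OR), the transform that preserves the
per-allele odds ratio. The bundled panel's weights and control
frequencies are synthetic: two large-effect HLA-like tags plus seven
moderate loci, with the eighteen (wᵢ, p₀ᵢ) values calibrated once — by
matching the first two moments of the implied score distributions — so
that simulated cohorts reproduce the published control summary 8.1
(6.9–9.4) and case summary 10.7 (9.7–11.7). They are not population
allele-frequency estimates, and the file is labelled synthetic.

**Antibodies.** Per-assay positivity comes from a probit model with one
shared latent factor: uₐ = λz + √(1−λ²)eₐ, positive when uₐ exceeds the
cut-off giving the target marginal rates (59/121, 39/121, 31/121). The
single loading λ is calibrated by bisection so the model's triple-positive
probability (a one-dimensional integral over z) equals 12/121; with
λ = 0 the assays are independent and the triple rate collapses to the
product of marginals, which is tested. One scalar loading cannot match
singles, doubles and triples simultaneously — the double-positive rate
overshoots (≈0.22 vs 0.17) — accepted as the cost of a one-parameter
dependence model; the Venn partition property holds regardless. Titres
are drawn from a sub-threshold beta component (negatives) or a
supra-threshold gamma component (positives) anchored at each assay's
cut-off; monogenic subjects draw only the negative component and are
antibody-negative by construction, as in the study.

**Consanguinity.** A fraction 41/127 of subjects is assigned
consanguineous status. Consanguineous subjects receive ~Pois(12) planted
ROH segments with gamma(shape 4, scale 5 Mb) lengths — about 8% of a 3 Gb
genome, the level expected for first-cousin offspring; outbred subjects
receive a few sporadic sub-3 Mb stretches. Dense marker calls are
heterozygous with probability 0.32 outside segments and 0.002 inside.
The generator→detector closed loop (simulate, call ROH, apply the 3%/3 Mb
rule) recovers the planted status with flag rates ≥0.9 / ≤0.05.

**Determinism.** Every stochastic operation is a pure function of
(config, seed); a single global seed is split hierarchically into
subsystem seeds so genotypes, antibodies and each subject's ROH track can
be regenerated independently but reproducibly. RNG state is saved and
restored around every seeded block.

**What the generator does not emulate.** Linkage disequilibrium between
panel SNPs, real (unknown) Iranian allele frequencies, population
structure, assay measurement error, titre decay with diabetes duration,
genotyping missingness patterns, and recombination-driven ROH placement.
Passing closed-loop tests therefore demonstrates the pipeline's internal
consistency at realistic effect sizes, not population realism.

## Problem sizes and numerical choices

Tests run the generator at study size for score analyses and on a toy
genome for ROH work: 200 Mb across 4 chromosomes at 50 kb marker spacing,
with the consanguineous segment-length scale reduced to a 6 Mb mean so
segments sit well inside the short toy chromosomes while staying far above
the 3 Mb rule; the closed-loop flag-rate check uses 500 subjects, and
stochastic calibration checks use 5,000–20,000 draws. Defaults remain
study-scale (3 Gb, 22 chromosomes, 50 kb spacing). The marker spacing
interacts with `min_snps`: at 50 kb a 3 Mb segment contains 60 markers,
just above the 50-marker floor, so spacings much above 60 kb would blind
the detector to rule-relevant segments.

Other fixed choices: threshold grid 0.1; strict inequalities in the
ROH rule; inclusive antibody cut-offs; type-7 quantiles everywhere;
mid-rank tie handling; bootstrap 2,000 replicates by default; percentile
bootstrap rather than BCa (simplicity, and the interval is secondary to
DeLong); output files carry full precision with rounding applied only in
rendered reports, and every output file records the seed and thresholds
actually used.

## Known limitations

- The bundled panel is a calibrated synthetic stand-in; clinical use
  requires the real weight table for the assay actually genotyped.
- Summary-form centiles inherit the normal approximation; published
  centiles are matched only to ~1.5 points.
- The full-sensitivity threshold is a training-data rule: with six cases
  its specificity estimate is optimistic and seed-dependent, visible in
  the README example where the simulated monogenic maximum falls in the
  control upper tail.
- The ROH caller assumes a dense, roughly even marker grid; very uneven
  panels interact with `max_gap_bp` and `min_snps` and may need retuning.
- Two-group comparison only; multi-class discrimination (e.g. against
  MODY and Type 2 diabetes in older cohorts) is out of scope.
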