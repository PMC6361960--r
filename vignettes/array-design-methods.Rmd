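---
title: "Methods: designing and evaluating a population-optimized genotyping array"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: designing and evaluating a population-optimized genotyping array}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagarray)
```

`tagarray` implements the array-design workflow used for modern
population-specific biobank genotyping chips: candidate screening against a
truth platform, budgeted tag-SNP selection from a phased reference panel,
functional-content modules, and imputation-based evaluation, with a
quantitative-trait GWAS layer on top. This vignette documents the models,
the parameters that matter, and the design decisions taken where the
methodology leaves room.

## Screening model

Candidates are screened on two axes before they are eligible for content.

**Dosage r²** is the squared Pearson correlation between the assay's
dosages (continuous, 0–2) and true genotypes (0/1/2) over shared samples;
pairs with a missing value on either side are dropped. Squaring makes the
statistic sign-blind: an assay that systematically reads the flipped allele
scores 1.0. We deliberately do not add an effect-direction check — the
screening contract is about linear recoverability of the genotype, and
allele-flip repair is a harmonization problem, not a validation one. When
either vector is constant the correlation is undefined and the variant is
reported as such (and fails validation) rather than being scored 0.

**Cross-platform F<sub>ST</sub>** treats the two platforms' call sets as two
populations. The default estimator is Nei's: with alternate-allele
frequencies $p_A, p_B$ (non-missing denominators),
$H_S = \tfrac{1}{2}\,(2p_Aq_A + 2p_Bq_B)$,
$H_T = 2\bar p\bar q$, $F_{ST} = (H_T - H_S)/H_T$, defined as 0 when
$H_T = 0$. We chose Nei over Weir–Cockerham as the default because it is a
closed-form function of the two frequencies — exactly the quantity a
batch-effect screen cares about — and trivially testable by hand
arithmetic; the sample-size-weighted Weir–Cockerham estimator is available
via `platform_fst(..., method = "wc")` for users comparing platforms with
very unequal cohort sizes.

A variant is **validated** iff dosage r² ≥ 0.7 *and* F<sub>ST</sub> ≤ 0.025,
both inclusive at the boundary.

**Hardy–Weinberg** filtering uses the exact conditional test: given the
allele totals, the P value sums the probabilities of every heterozygote
count no more probable than the one observed,
$$P(n_{Aa}) = \frac{n!\,2^{n_{Aa}}\,n_A!\,n_a!}
                   {n_{AA}!\,n_{Aa}!\,n_{aa}!\,(2n)!}.$$
No mid-p correction is applied: the filter threshold (P < 10⁻⁶) sits deep
in the tail where the plain exact test is the conservative, standard choice
for rare variants, and the plain sum is what a brute-force enumeration
reproduces exactly. A chi-square test would misbehave at exactly the rare
variants this toolkit is designed to keep.

QC removes a variant when call rate < 95%, HWE P < 10⁻⁶, or (depending on
content type) MAF < 1% or minor allele count < 2 — the MAC rule is the
exome-style variant used for rare functional content, switched by
`qc_filter(use_mac = TRUE)`.

## Tag selection

The imputation-aware selection used by array vendors is proprietary. We
approximate its objective with pairwise-r² maximum coverage, the standard
design proxy: pairwise r² from phased haplotype counts lower-bounds what
imputation can recover from a tag, and the coverage-counting threshold
(r² ≥ 0.8 within ±250 kb) mirrors the threshold at which the evaluation
counts a variant as captured. Targets are the panel variants with MAF ≥ 1%;
rarer variants are deliberately not part of the tagging objective — they are
the functional module's job, matching the tag/functional split of real
array designs.

Greedy maximum coverage adds, at each step, the candidate covering the most
currently uncovered targets, so coverage is monotone in budget, per-step
gains are non-increasing, and the selection is within a factor (1 − 1/e) of
the budget-constrained optimum. Ties break by higher candidate MAF (a
higher-MAF assay is easier to genotype and tags more alleles), then by
smaller genomic position; with the tie rule the selection is fully
deterministic. The budget is a user parameter: in real designs it reflects
platform capacity, not an algorithmic rule.

**Strand ambiguity.** A/T and C/G variants cannot be strand-resolved from
allele labels and are excluded from content *except* for (i) indispensable
tags — a selected tag is indispensable iff removing it would leave some
covered target with no alternative candidate at r² ≥ 0.8; (ii)
nonsynonymous SNPs with design-population MAF ≥ 0.1%; (iii) members of a
known-interest list. "Indispensable" is not defined by the protocol we
follow; the no-substitute operationalization is ours and is computed by
`indispensable_tags()`.

## Imputation and coverage

Evaluation imputes held-out target samples from the remaining panel with a
minimal Li–Stephens copying HMM. Hidden state: which reference haplotype is
being copied. Transitions between adjacent reference sites at distance $d$
bp switch to a uniformly chosen haplotype with probability
$1 - e^{-\rho d}$ (default $\rho$ = 10⁻⁶/bp, of the order of the
population-scaled recombination rate per bp; the evaluation pipeline uses
the panel's own template-switch rate when known). Typed sites emit the
target allele with mismatch probability $\varepsilon$ (default 10⁻³);
untyped sites emit nothing, and their allele posterior is the posterior
probability that the copied haplotype carries the alternate allele. The
diploid problem is run as two independent haploid chains on the target's
two haplotypes — targets are phased by construction in this toolkit (the
generator emits phased haplotypes), which keeps the model exactly
factorizable and lets an exhaustive sum over copying paths serve as a
reference implementation at small sizes. Pre-phasing of genuinely unphased
targets is out of scope.

Numerically the forward–backward pass renormalizes at every site (underflow
protection), handles the single-site edge case directly, and treats
chromosome changes as forced switches. Posterior triples are validated to
sum to 1 within 10⁻⁶.

The **info score** is the IMPUTE-style observed/expected dosage-variance
ratio: with per-sample $e_i = p_{i1} + 2p_{i2}$, $f_i = p_{i1} + 4p_{i2}$
and $\hat\theta = \sum e_i / 2N$,
$$\mathrm{info} = 1 - \frac{\sum_i (f_i - e_i^2)}{2N\,\hat\theta(1-\hat\theta)},$$
with info = 1 by convention when $\hat\theta \in \{0, 1\}$. Hard calls give
exactly 1; posteriors equal to the Hardy–Weinberg genotype distribution
carry no information and give exactly 0 — these algebraic limits are the
score's unit tests. Values below 0 are mathematically possible and are
reported unclamped; threshold comparisons use the raw value.

**Genomic coverage** is the fraction of reference variants with MAF ≥ 1%
captured by the array: directly typed variants count as covered (coverage
measures variation captured directly *or* through LD/imputation), untyped
variants count when info ≥ 0.8. Whether typed variants belong in the
denominator is ambiguous in the protocols this follows; we include them,
which makes coverage monotone under manifest growth — a property the test
suite asserts. Strata: common (MAF ≥ 5%) and low-frequency (1–5%).
Per-window coverage uses half-open 5 Mb bins from position 1 per
chromosome; the final partial bin reports its own mean rather than being
dropped.

## GWAS layer

LDL cholesterol is computed by the Friedewald formula (TC − HDL − TG/5,
mg/dL), set missing above TG 400 mg/dL (strict: 400 computes). All traits
except total cholesterol are ln-transformed; lipid-lowering therapy blanks
the lipid traits and liver-affecting medication blanks AST/ALT (the
medication lists themselves are caller-supplied flags — they are cohort
metadata, not genetics). Association is ordinary least squares on allele
dosage with age, sex and recruitment-area covariates; sex is 0/1 and area
is one-hot against its first level, so betas are reproducible across
implementations. The genome scan residualizes trait and dosages against
covariates once (Frisch–Waugh–Lovell) and then fits each variant as a
single regression — algebraically identical to the per-variant fit, which
the tests verify against `lm()` and an independent normal-equations solve.

Signal selection: leads at P ≤ 5×10⁻⁸ with MAF ≥ 1%; nonsynonymous
candidates at P < 10⁻⁴ and MAF > 0 inside a qualifying locus. A locus is
the ±500 kb window around any variant with P ≤ 5×10⁻⁷ and qualifies iff it
contains at least one *distinct* supporting variant at P ≤ 10⁻⁴ (a lead
alone does not qualify; the candidate itself may serve as the supporting
signal). The 500 kb half-width mirrors the only explicitly stated window in
the protocol (the 1 Mb centred novelty window); "locus" is otherwise
undefined. Boundary directions — ≤ for leads, centers and support, strict <
for candidates and the replication threshold (P < 0.05, same-sign beta) —
follow the protocol's wording and each has a unit test. MAF for the
candidate clause is the discovery-sample MAF (whether a reference-panel
frequency was meant is unstated; the discovery frequency is the one the
pipeline always has).

## Synthetic data: what it does and does not emulate

The generator exists so that every stage runs on data with known truth.

* **Panel**: founder haplotypes drawn site-independently from a frequency
  spectrum (default: alternate-allele frequency uniform on 0.05–0.95), and
  each output haplotype built as a founder mosaic with per-bp template
  switch rate. Defaults: 24 founder haplotypes, 200 output haplotypes,
  2000 variants over 10 Mb, switch rate 2×10⁻⁶/bp (≈ 500 kb expected
  segments). The founder count is the LD knob: mosaic LD scales like
  1/n_founders, and 24 founders keeps realized MAFs within
  Kolmogorov–Smirnov distance 0.1 of the requested spectrum while leaving
  enough haplotype structure for imputation to work with. What this model
  does *not* produce: recombination hotspots, allele-age/frequency
  correlation, many very strong pairwise-r² proxies (founder alleles are
  independent across sites, so r² between nearby variants is driven by
  template sharing, not by mutation on shared backgrounds). Consequently
  direct pairwise tagging multiplicity is lower than in real human data and
  the imputation step, not the r²-tagging step, carries most of the
  coverage — a caveat to keep in mind when reading absolute coverage
  numbers from synthetic runs.
* **Divergence**: per-variant frequencies redrawn from a Balding–Nichols
  distribution (one-parameter F knob, the expected F<sub>ST</sub>), then
  haplotypes resampled site-independently. LD is not preserved; this is a
  frequency-drift fixture for the F<sub>ST</sub> screen, nothing more.
* **Genotyping**: truth is the haplotype-pair sum; calls go missing
  independently at `missing_rate` and are otherwise perturbed to one of the
  two other genotype states uniformly at `error_rate` — the simplest
  symmetric model that exercises concordance and dosage-r² machinery.
  Blind duplicates share truth but get independent noise, giving a
  closed-form expected duplicate concordance of $(1-e)^2 + e^2/2$.
* **Phenotypes**: additive genetic effects plus Gaussian noise, matching
  the analysis model; missing genotypes contribute their variant's mean
  dosage so missingness does not shift the phenotype scale.

All generators are deterministic in their seed.

## Problem sizes and a power caveat

The test suite and the acceptance script run at desk scale by choice:
2000-variant panels (5000 for the end-to-end design run), 100–1000
samples, and a GWAS cohort of n = 2000 for the planted-signal experiment.
One consequence deserves a number. The planted nonsynonymous causal variant
is sized at ~1% variance explained, so its association non-centrality is
about n·R² ≈ 20 (E[z] ≈ 4.5), while the candidate-selection rule requires a
locus lead at P ≤ 5×10⁻⁷ (z ≈ 5.0). Recovery of the planted variant through
the full selection rule is therefore a coin with success probability well
below one half at this scale — the acceptance script reports the measured
recovery rate honestly rather than inflating the planted effect. Detecting
a 1%-variance variant through a 5×10⁻⁷ locus gate simply needs a larger
cohort than the desk-scale run uses; the global-null behaviour (no leads,
uniform p-values) is the calibration half of that experiment and is
insensitive to scale.

## Known limitations

* Pairwise-r² tagging is a proxy objective; no multi-marker (haplotype)
  tagging.
* The imputation HMM assumes phased targets and biallelic sites; no
  pre-phasing, no multiallelic splitting.
* Indels are keyed like SNVs by (chrom, pos, alleles); cross-platform indel
  normalization (left-alignment, representation differences) is out of
  scope, so literal identity is required there too.
* No relatedness/mixed-model association, genomic control, meta-analysis
  or conditional analysis.
* Annotations are consumed, never produced: consequence classes and
  damaging flags come from the caller (or the synthetic generator).
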