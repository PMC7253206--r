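---
title: "Dissecting cis- and trans-regulatory divergence from allele-specific expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting cis- and trans-regulatory divergence from allele-specific expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistrans)
```

## The question the package answers

When a wild and a cultivated accession diverge in gene expression, the change
can be *cis*-acting — a variant linked to the gene itself (promoter,
enhancer) that shifts only its own allele — or *trans*-acting — a change in a
diffusible regulator that affects both alleles. The two are separable in an
F1 hybrid: both parental alleles sit in the same nuclei, exposed to the same
trans environment, so any allelic imbalance measured at transcribed SNPs must
be cis. Comparing the hybrid's allelic ratio with the parents' expression
ratio then isolates the trans part.

`cistrans` implements this dissection for a wild x cultivated design with an
F1 hybrid and three replicates per genotype: gene-level allele counting from
reciprocal pseudoreference alignments, negative-binomial likelihood-ratio
tests, a seven-category classifier, dominance-of-expression and
fruit-morphometric statistics, and coexpression-neighborhood analyses — plus
a generator that simulates all of these inputs with known ground truth.

## Statistical model

Counts are modeled as NB2: `Var(Y) = mu + phi * mu^2`, with a log link and
log library size factors as fixed offsets. Size factors come from the
median-of-ratios estimator (geometric-mean reference over genes positive in
every library). For allele-resolved data each parental replicate is one
library, while the two alleles of an F1 replicate share that library's
factor — they were sequenced together, so their within-replicate ratio is
normalization-free.

Three hypotheses are tested per gene, each a one-degree-of-freedom
likelihood-ratio contrast under the saturated generation-by-allele group
model:

* **parental** divergence: wild vs cultivated expression in F0
  (`~ allele` vs `~ 1` within F0);
* **cis** (allelic imbalance): wild vs cultivated allele within the F1
  (`~ allele` vs `~ 1` within F1);
* **trans**: the allele-by-generation interaction
  (`~ allele + generation + allele:generation` vs the additive model) —
  significant when the parents' ratio differs from the hybrid's allelic
  ratio.

### Dispersion and the reference distribution

Each gene's dispersion is estimated once, by Cox–Reid adjusted profile
likelihood under the saturated four-group model on all twelve observations,
and held fixed for every fit of that gene. Two numerical facts drove the
remaining choices, both measured on null simulations during development:

* With a *known* dispersion, the chi-squared reference for the LRT is well
  calibrated even at n = 3 (empirical type-I ~5.5% at nominal 5%).
* With a dispersion *estimated from six observations* (the parental-only
  design of `parental_de()`), the chi-squared reference is strongly
  anticonservative (~12%), because genes whose within-group scatter is by
  chance small get both a small dispersion and a large statistic.

`parental_de()` therefore uses a quasi-likelihood F reference: the LRT
statistic scaled by the Pearson dispersion of the full fit, referred to
F(df, residual df). This is the standard construction for small-sample GLM
count testing and restores the nominal level (~5%). The ASE engine, whose
dispersion rests on eight residual degrees of freedom, uses the plain
chi-squared LRT — the construction the field's reference tools use — which
is adequately calibrated there. With a user-supplied fixed dispersion, both
paths use the chi-squared reference.

No information is shared across genes: per-gene dispersion estimation
without empirical-Bayes shrinkage is a deliberate scope decision, and the
main respect in which the machinery is simpler than DESeq2 or edgeR.
Numerical equality with those tools is not promised, only qualitative
agreement.

### Classification

With P, H, T the BH-adjusted significance (within each test family,
FDR 5% by default) of the parental, cis and trans tests:

| P | H | T | category        |
|---|---|---|-----------------|
| – | – | – | conserved       |
| + | + | – | cis_only        |
| + | – | + | trans_only      |
| + | + | + | cis_plus_trans (components same sign) |
| + | + | + | cis_by_trans (components opposing) |
| – | + | + | compensatory    |
| any other pattern | | | ambiguous |

The effect decomposition is computed from size-factor-normalized mean
counts with a pseudocount of 0.5 per cell (configurable): the cis component
is the hybrid allelic log2 ratio, the trans component the parental log2
ratio minus the hybrid one, so the two sum to the parental effect by
construction. A zero-valued component under joint cis/trans significance
has no direction and falls to `ambiguous` with a message. The cis
percentage, `100 |cis| / (|cis| + |trans|)`, summarises the relative
contribution and is averaged within bins of absolute parental effect.

## Dominance of expression and of morphology

For any trait measured in wild parent (W), cultivated parent (C) and hybrid
(F1) — per-genotype medians of normalized expression, raw fruit
measurements, or PC1 of the transformed shape traits — the package computes
the additive effect `a = (W − C)/2`, the dominance deviation
`d = F1 − (W + C)/2`, and the degree of dominance `k = d/a`. `k` is
undefined when `|a| < 1e-9` (relevant only off the DEG set, where `a` can
vanish; the epsilon avoids infinities without changing any interpretable
value). Inheritance bins: additive in the open interval (−0.25, 0.25);
cultivated-pattern partially recessive for k in [0.25, 1.25]; partially
dominant for [−1.25, −0.25]; transgressive strictly beyond |1.25|. The
boundary points belong to the partial-dominance bins because the additivity
interval is stated open and transgression strictly beyond the bound.

Shape descriptors are the ImageJ set: aspect ratio MaA/MiA, roundness
`4A/(pi MaA^2)`, circularity `4 pi A / perimeter^2`. A variant of
circularity with the aspect ratio in the numerator appears in some method
descriptions; it is dimensionally inconsistent (it does not equal 1 for a
circle measured in physical units) and is treated as a transcription slip,
but remains available via `circularity = "aspect_ratio"` for audit.
Size-like traits are log10-transformed; the bounded ratio traits get the
arcsine-square-root transform, with values clipped to [0, 1] first (noise
can push a near-circular fruit's roundness slightly above 1; clipping is
warned about). PCA is computed on the correlation matrix — the transformed
traits mix scales — and each component's sign is fixed so its
largest-magnitude loading is positive, making orientations reproducible.

## The synthetic-data generator

`simulate_ase_counts()` draws NB2 counts under the same model the tests
assume. With cis effect c and trans effect t (log2), baseline m0 and library
factor s:

* F0 wild allele: `s * 2^(m0 + (c+t)/2)`; F0 cultivated:
  `s * 2^(m0 − (c+t)/2)` — the parental ratio is `c + t`.
* F1 wild allele: `s * 2^(m0 − 1 + c/2 + trans_dominance * t/4)`, and
  mirrored for the cultivated allele — the allelic ratio is exactly `c`,
  each allele carries half the library, and `trans_dominance` tilts the
  hybrid's overall trans environment (0 = additive on the log scale).

Defaults mirror the design this analysis targets: three replicates per genotype, baseline
log2 mean 8 (~256 reads), equal category proportions. No empirical
dispersion estimate is available for this system; the default `phi = 0.05` is a conventional
bulk-RNA-seq biological-replicate value, flagged as a convention. Effect
magnitudes default to 2 log2 units. Two category conventions deserve
explanation:

* **compensatory** genes have `t = −c` exactly, so parents express equally
  despite hybrid allelic imbalance.
* **cis_by_trans** genes cannot have equal opposing magnitudes — that is
  compensation — so the generator gives them a half-magnitude cis component
  opposed by a full-magnitude trans component. Placing the larger magnitude
  on the trans side mirrors the empirical asymmetry in hybrid ASE studies,
  where trans effects are the larger ones; it is also the orientation under
  which all three defining signals of the category remain detectable at
  n = 3, since the interaction contrast carries twice the sampling variance
  of the within-generation contrasts.

A consequence of log-scale additivity worth knowing: for trans-only genes
with `trans_dominance = 0` the hybrid total sits at the *geometric*
midparent, so the linear-scale degree of dominance concentrates at
`−sign(t)/3` for |t| = 2, not at 0. For cis-only genes the hybrid total
equals the *arithmetic* midparent exactly and k concentrates at 0 — the
familiar observation that cis-regulated genes inherit additively.

Seeding is hierarchical: one master seed, with per-gene substreams derived
deterministically, so a gene's draws do not depend on how many genes are
simulated and fixed seeds give bit-identical tables.

`simulate_snp_pairs()` emits the paired VCF-style records the extraction
module consumes — reciprocal heterozygous genotypes with mirrored allele
depths — and can contaminate a configurable fraction with one randomly
chosen rule violation (non-reciprocal genotype, homozygosity, low QUAL,
depth mismatch) to exercise the filters. `simulate_morphometrics()` draws
ellipse-like fruit dimensions per genotype with the hybrid mean at
midparent + k*a and mean-preserving lognormal noise; the default parents are
a small round fruit (9 x 8 mm) and an elongated large one (80 x 15 mm).

## What the simulations do and do not show

The generator reproduces the count structure the tests assume: NB noise,
library-size variation, reciprocal SNP records, known effect sizes. It does
**not** simulate read-mapping bias toward the reference allele, positional
correlation of SNPs within a gene, dispersion heterogeneity across genes,
GC or length effects, or genuinely ambiguous regulatory architectures.
Passing recovery tests therefore demonstrates the statistical machinery is
correct and calibrated under its own assumptions — not that real pepper data
meet those assumptions. On real data the filters (QUAL > 30, DP > 20 strict,
genotype and depth reciprocity, shared positions across replicates) are the
main defense against mapping artefacts, which is why they are implemented
exactly as printed and tested at their boundaries.

Validation problem sizes, chosen to make Monte-Carlo noise small relative to
the tolerances while keeping the suite quick: 3,000 genes (500 per category)
for classifier recovery; 2,000 null genes for the type-I check; 10,000 genes
for the compensatory cancellation check; 20 fruits per genotype for
morphometric recovery; 50 random graphs of up to 8 nodes against the
exhaustive betweenness oracle.

## Other design decisions

* **Low-expression rule.** "Per-genotype median below five" is read as
  *all* genotypes below threshold (default), preserving genes silenced in
  one parent — biologically the most interesting ASE cases; the strict
  *any*-genotype rule is available via `drop_if = "any_below"`. The
  boundary median of exactly 5 is retained ("smaller than five").
* **Depth reciprocity.** The mirrored-depth requirement between the two
  alignment views defaults to exact equality, with a relative-tolerance
  mode (10%) available, since alignments to two different pseudoreferences
  rarely give identical depths; both modes are tested.
* **Allele orientation.** In the cultivated-view VCF the reference allele
  is the cultivated allele and the alternative the wild allele (and
  mirrored in the wild view); counts are read from the cultivated view,
  which equals the wild view under exact reciprocity.
* **Multi-gene SNPs** go to the widest covering gene model, ties broken
  lexicographically; BED intervals are converted to 1-based inclusive
  coordinates on read.
* **Multiple testing** is BH within each test family (parental, cis,
  trans), not pooled across families.
* **Numerical floors.** P-values are floored at 1e-300; LRT statistics are
  clamped at 0; generator means below 1e-8 are clamped before sampling;
  linear predictors are capped at |eta| = 30 inside IRLS.
* **Betweenness** uses unweighted shortest paths (mutual information is a
  coexpression strength, not a path cost), normalized per connected
  component by (n−1)(n−2)/2; a weighted option uses 1/MI as length.
  "Closest neighbors" of a gene are its direct neighbors.
* **Pipeline interface.** The orchestrator is an R function,
  `run_pipeline(pipeline_config(...))`, returning a JSON-serializable
  report; in an R-native analysis package the functions themselves are the
  command surface, so no shell wrapper is shipped.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_ase_counts(simulation_config(n_genes = 500, seed = 1))
calls <- regulatory_divergence(sim$profile, alpha = 0.05)
glance(calls)
autoplot(calls)

totals <- ase_totals(sim$profile)
de <- parental_de(totals$counts, totals$metadata)
dom <- dominance_for_degs(de, genotype_medians(totals$counts, totals$metadata))
glance(dom)
plot_k_distribution(dom)
```

## Known limitations

* Per-gene dispersion estimation without cross-gene shrinkage is noisier
  than the moderated estimators of DESeq2/edgeR; at very low counts the
  tests lose power accordingly.
* The parental test inside `regulatory_divergence()` uses the allele
  profile's F0 counts, i.e. the parental libraries restricted to ASE-informative
  genes; a genome-wide `parental_de()` run on the full count matrix can give
  slightly different q-values for the same gene because the BH family
  differs.
* The classifier's `ambiguous` class absorbs every significance pattern
  without a coherent regulatory reading (e.g. parental divergence with
  neither cis nor trans evidence); its size grows with miscalibration, so
  it doubles as a diagnostic.
* Reproducing real per-category gene counts requires raw sequencing reads,
  which are not shipped here; the package validates the machinery on
  synthetic truth instead.
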