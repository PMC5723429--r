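---
title: "Methods and design notes for cocoamap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for cocoamap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocoamap)
```

`cocoamap` implements the computational pipeline around a mid-density
(15,000 bead-type) Infinium SNP genotyping array for cacao, an outbreeding
diploid tree crop with ten chromosomes: designing the SNP panel from two
variant-discovery datasets, quality-controlling array genotypes, analysing
F1 full-sib ("CP") mapping populations, comparing platforms, deriving yield
and disease phenotypes, and scanning for QTL. Because the underlying field
data are not public, a seeded synthetic F1-cross generator stands in for
them; every claim the test suite makes is a claim about data generated by
that model.

## The genotype model

A biallelic call is stored as the count of the alternate allele (0, 1, 2,
`NA`), so Mendelian transmission is arithmetic: a parent with genotype $g$
transmits the alternate allele with probability $g/2$, and the expected
progeny distribution of a parent pair is the convolution of the two
transmission Bernoullis. All positions are 1-based and inclusive.

Two quality scores accompany array data. GenTrain is a per-locus clustering
quality score; GenCall is a per-call confidence. The one published filtering
sentence conflates them, so the package applies each at its native
granularity: loci with GenTrain < 0.4 are dropped, individual calls with
GenCall < 0.2 are blanked, and loci left with no data are dropped. Both
comparisons are strict (`<`), mirroring the published "(<0.4)" / "(<0.2)"
notation; a score exactly at a threshold survives. Absent scores pass and
are counted in the filter report. The operation is idempotent.

## CP segregation machinery

Markers in an outbred full-sib family are typed by which parent is
heterozygous: `lmxll` (mother only), `nnxnp` (father only), `hkxhk` (both),
or uninformative. The unknown-parent inference takes the known maternal
genotype and the observed progeny genotype counts at a locus, computes the
Pearson chi-square against the Mendelian expectation under each of the three
candidate father genotypes (over categories with positive expectation), and
returns the candidate with the smallest statistic.

Observed progeny in a category the candidate deems impossible are tolerated
up to 2% of the family size (absorbing genotyping error); beyond that the
candidate receives $+\infty$. This tolerance matters: under a symmetric
0.5% per-call error model the impossible-class mass at a
homozygote-by-homozygote locus is approximately Poisson with mean 1.2 in a
family of 249, and the 2% budget (about 5 calls) is rarely exceeded, so
whole-genome father recovery exceeds 99% (100% with error-free data). At 1%
error the Poisson mean doubles and the budget overflows at roughly one locus
in ten of that class, costing the true model its candidacy there; recovery
degrades to about 98%. The tolerance is configurable for noisier platforms.
Ties within $10^{-9}$ flag the locus ambiguous, with a deterministic
preference order (HOM_REF < HET < HOM_ALT) recorded.

A trio locus counts as typed when all three calls are present, and as a
Mendelian error when the progeny genotype has probability zero given the
parents. Individuals with an error rate of 3% *or more* (inclusive) are
off-types; the locus/individual missingness gates used before map
construction are exclusive (> 5%, > 15%), each following its published
phrasing. Duplicate loci and duplicate individuals keep the first listed.
Distortion is the raw Pearson chi-square against the segregation type's
ratio (1:1 or 1:2:1), without continuity correction, and loci above 15 are
removed (15.0 exactly survives).

JoinMap export writes the CP `.loc` format with `ll/lm`, `nn/np`,
`hh/hk/kk` tokens and `--` for missing. Linkage phase is not determined;
`hkxhk` letters default to h = reference allele, and the letter-to-allele
mapping of every locus is written to a sidecar so the convention is
auditable. Map construction itself (JoinMap's ML ordering) is out of scope.

## Panel design

Candidate variants pass inclusive gates (Phred >= 20, alternate frequency
>= 20%, >= 2 supporting reads, SNV only). The proximity rule removes every
candidate with another variant within 60 bp *inclusive* — both members of a
close pair go, because an Infinium probe reads the flanking 60-mer and
either variant corrupts the other's probe window; an optional context set
(variants that are not themselves candidates) also triggers removal. Merging
the transcript- and genome-discovery datasets keeps the intersection keyed
by position, with genome-dataset metadata winning and allele conflicts
excluded and reported.

Gene prioritisation intersects gene models with published QTL intervals
(1-bp overlap, 1-based inclusive) and tests functional-term enrichment with
a one-sided hypergeometric per term plus Benjamini–Hochberg correction —
the published account names no test, so this choice is ours and is the
field default. Within each priority gene exactly one SNP survives, ranked
by: unique flanking sequence, then missense effect, then single-bead-type
allele pair, then ADT score (strictly greater than 0.9 to be eligible at
all), with a positional tie-break for determinism.

Anchor markers are apportioned to chromosomes proportionally to gene-model
content by the largest-remainder method (unstated in the source; chosen
because it sums exactly to the target and is deterministic), with seeded
uniform down-sampling and fill. Gap filling treats chromosome termini as
virtual markers (so telomeric deserts get filled), repeatedly locating the
largest genome-wide gap and inserting the pool variant nearest its
midpoint, while the Infinium II bead budget holds: A/T and C/G SNPs cost
two bead-types, the other four pairs one. 13,530 SNPs of which 1,470 are
A/T or C/G consume exactly the 15,000 bead budget.

## Concordance

Cross-platform comparison counts jointly called loci into a 3×3 grid (array
in rows, sequencing in columns). Reported percents are half-up-rounded
integers with the raw ratio always retained. Pooling sums grids and
recomputes the percent from the pooled counts. The bundled published
control-clone grids reproduce the pooled 63,543 comparisons at 95%
concordance and the discordance profile (2,725 of the discordant calls are
array-het/sequencing-hom; 162 are opposite homozygotes). Two published
numbers are *not* derivable from the published grids themselves — one
clone's printed integer percent and the pooled discordant total — and the
package reports what the grids actually give (99.63% → 100, and 3,034).

## Derived traits

Monthly observations per tree (healthy, frosty-pod-infected and other sick
pods, wilted cherelles, wet bean weight) are summed over the collection
window. Derived responses: cherelle wilt ratio = cherelles / (cherelles +
total pods); percent sick and percent FP relative to total pods;
probability of monilia = observations with at least one FP pod over
observations with pods present; fresh weight per pod. Undefined ratios
(zero denominators) propagate as missing, never zero — a tree with no pods
carries no information about its infection ratios. "Sick" excludes FP by
definition, and the generator enforces that.

## QTL scan

Predictors are centered per segregation type: `lmxll`/`nnxnp` use a ±1/2
indicator of the segregating parent's transmitted allele (1 df); `hkxhk`
uses additive = alt count − 1 and dominance = heterozygote indicator − 1/2
(2 df). The published analysis ran mixed models in proprietary software
without stating a coding; for an unreplicated F1 a fixed-effects
least-squares fit with these codings is equivalent in expectation and fully
reproducible, and is what the package does (a deliberate simplification).
Each marker is tested jointly on its predictors with a Wald chi-square
(difference in residual sums of squares over the full model's error
variance); p-values use the chi-square asymptote, which at n = 200 yields a
type-I rate of about 0.053 at nominal 0.05 — inside the calibration band
the suite checks — and `-log10(p)` is computed on the log scale so extreme
peaks do not underflow. Percent variance explained is the incremental
R-squared of the marker over the cofactor-only model (the published
definition is not given; this one is documented and monotone in the test).

The significance threshold is alpha / Meff, where Meff is the Li–Ji
effective number of tests: for each linkage group, the eigenvalues
$\lambda_i$ of the additive-coding correlation matrix contribute
$I(\lambda_i \ge 1) + (\lambda_i - \lfloor\lambda_i\rfloor)$, and groups
are summed genome-wide (per-group computation is the documented behaviour
of the software the study used; the study is silent). Pairwise-complete
correlations can leak tiny negative eigenvalues, which are clamped to zero;
zero-variance markers are excluded.

Composite scanning starts from the plain scan, picks cofactors by greedy
peak selection (take the strongest significant marker, mask its ±10 cM
neighbourhood on its linkage group, repeat), rescans with each tested
marker's model excluding cofactors within 10 cM of it on the same linkage
group, and stops when the cofactor set stabilises or after two composite
iterations — the behaviour the study reported. One-peak-per-contiguous-run
selection was rejected: when two linked QTL produce one unbroken
significant stretch it yields a single cofactor and can never separate
them, while greedy peaks condition on both and open the valley between.
QTL regions in the summary are maximal runs of significant markers
(p below threshold and explained variance strictly above 4%) within 10 cM
of each other; each reports peak, physical and genetic bounds from the
outermost significant markers, and the favorable parental allele implied by
the sign of the additive effect (for `hkxhk`, both parents segregate the
same pair; true linkage phase is out of scope).

## The synthetic cross

The generator draws per-marker population alternate-allele frequencies from
Uniform(0.1, 0.9), then makes each parent heterozygous with its target
probability (phase random) or homozygous with the frequency deciding which
allele. The default targets mirror the two study crosses: a 90.1% × 20.5%
heterozygosity pair (high-het mother by mostly homozygous father) and a
50% × 58.8% pair for the unknown-father family. Gametes follow a Markov
walk along each linkage group with Haldane switch probabilities
$r = (1 - e^{-2d/100})/2$ for adjacent-marker distance $d$ cM — chosen over
Kosambi because it is analytically testable (no interference). Genotyping
error is a symmetric state flip by default, with an optional het-to-hom
bias to emulate the array-vs-sequencing discordance profile; missingness is
uniform; off-types are Hardy–Weinberg draws from the population
frequencies. Traits are monthly records: Poisson counts with log-means
shifted by the planted QTL's additive/dominance values, a logistic monthly
infection indicator for frosty pod, and Gaussian wet weight around a
pod-proportional mean. Physical positions are laid at 350,000 bp/cM, within
the range estimated for the cacao genome. All randomness flows from one
seed through named substreams, so stages can be regenerated independently
and byte-identically.

What the generator does not emulate: real linkage-disequilibrium and
population structure of cacao germplasm, locus-specific error and
missingness (both are homogeneous here), segregation distortion of
biological origin, map-construction uncertainty (simulated map positions
are the truth), and the intensity-level behaviour of the array (GenTrain /
GenCall scores are consumed, never modelled). Passing tests therefore
demonstrate correctness of the algorithms under Mendelian assumptions, not
performance on any particular field dataset.

## Numerical and scale choices

Chi-square ties use a $10^{-9}$ absolute tolerance. The concordance
integer uses half-up rounding (R's `round()` is half-to-even). The suite
and the acceptance script use problem sizes chosen to keep the full run in
minutes on one core while leaving Monte-Carlo error well inside every
asserted band: 3,600 markers × 249 progeny for parent inference, 1,000
markers × 720 progeny for the off-type screen, 500 markers × 200 progeny ×
150–200 replicates for null calibration (Monte-Carlo SE ≈ 0.002 on a band
of ±0.01), and 100 replicates at n = 576 for detection power. Each
replicate draws its own seeded substream.

## Known limitations

True interval mapping between markers, kinship/mixed-model correction,
GLM links for count traits, heritability estimation, linkage-map
construction and probe design are all out of scope. The favorable-allele
report identifies the beneficial allele at the peak marker, not a phased
parental haplotype across a region.
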