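---
title: "Methods: eQTL mapping and epistatic networks in hybrid F2 crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eQTL mapping and epistatic networks in hybrid F2 crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hybridqtl implements a complete expression-QTL analysis for an F2
intercross between two inbred lines, of the kind used to dissect hybrid
male sterility in house mice (*Mus musculus musculus* x *M. m. domesticus*).
This vignette explains the statistical machinery, the tunable parameters,
what the synthetic-data generator does and does not emulate, and the design
choices made where the procedure was genuinely open.

## The cross and its genotype model

All individuals are F2 males from an intercross of two inbred lines, "A"
(domesticus-like) and "B" (musculus-like). Autosomal genotypes take three
classes (AA, AB, BB); the male X is hemizygous with two classes (A, B),
inherited as a single recombinant maternal gamete. Genotypes are observed
at a sparse marker panel, so all mapping works on genotype *probabilities*
computed at every marker plus pseudomarkers on a `step = 2` cM grid.

The probabilities come from a hidden Markov model per chromosome and
individual: hidden states are the true genotypes, transitions between
adjacent grid positions derive from the interval recombination fraction
under the configured map function, and emissions allow a genotyping error
rate (`error_rate = 0.001` by default): the observed class has probability
$1 - \epsilon$ and each wrong class $\epsilon/(k-1)$; missing observations
emit uniformly. The autosomal F2 transition matrix is the tensor product of
two independent gamete chains,

$$
T(r) = \begin{pmatrix}
(1-r)^2 & 2r(1-r) & r^2 \\
r(1-r) & (1-r)^2 + r^2 & r(1-r) \\
r^2 & 2r(1-r) & (1-r)^2
\end{pmatrix},
$$

and the X-male chain is the single-gamete two-state analogue. Posterior
class probabilities are obtained by forward-backward smoothing; the unit
tests verify exact (1e-9) agreement with brute-force enumeration over all
gamete configurations on small chromosomes.

Three map functions are available. Carter-Falconer is the default for
analysis because it models the strong positive crossover interference of
the mouse; its inverse (cM to recombination fraction) has no closed form
and is computed by bracketed root finding on the forward function to
1e-10 cM. Haldane and Kosambi use their closed-form inverses.

## Interval mapping

Single-QTL genome scans are computed two ways:

* **Haley-Knott regression** (`method = "hk"`): the trait is regressed on
  the posterior genotype-class probabilities at each grid position (plus
  any covariate terms), and
  $\mathrm{LOD} = \tfrac{n}{2}\log_{10}(RSS_0/RSS_1)$ against a null
  containing only the intercept and covariate terms. This is the vectorised
  workhorse: one QR decomposition per position serves every trait and every
  permutation simultaneously.
* **EM interval mapping** (`method = "em"`): a normal mixture with
  class-specific means and a common variance, weighted by the genotype
  probabilities, iterated to a relative log-likelihood change below 1e-6
  (at most 1000 iterations). At a fully typed marker the mixture collapses
  and EM equals HK; the tests assert agreement to 0.01 there and exact
  equality of HK with the closed-form two-regression LOD.

Expression traits are transformed to **normal quantile ranks**,
$\Phi^{-1}((r_i - 0.5)/n)$ with average ranks for ties, before mapping.
After the transform every trait has the same marginal distribution, so a
single transformed trait's permutation null applies to all of them. The
$(r - 0.5)/n$ plotting position is one of several conventions; it is
symmetric and keeps the extremes finite.

Positions with zero residual variance (perfect fit) are capped (the RSS is
floored at 1e-12) and reported with a warning rather than returning an
infinite LOD.

### Significance thresholds

Two permutation schemes are implemented, both stratified into autosomes
and X:

* **Single transcript**: one transformed trait is shuffled across
  individuals; the per-permutation maximum LOD is recorded separately over
  the autosomes and over the X. The genome-wide level `alpha = 0.05` is
  partitioned between the strata in proportion to map length, and the X
  stratum's permutation count is scaled up by the autosome/X length ratio
  (about 16 for a mouse-like map) so its much smaller tail probability is
  still estimable (when the autosomes get 10,000 permutations, a
  mouse-like map calls for roughly 158,000 on the X).
* **Dataset-wide**: the assignment of individual ids to expression columns
  is permuted once per replicate - preserving the correlation structure
  among transcripts - every trait is scanned, and the maximum over all
  transcripts per stratum is recorded. The resulting threshold bounds the
  probability of a single false eQTL anywhere in the dataset and is
  therefore much more conservative.

Thresholds are upper empirical quantiles, `sorted[ceiling((1-alpha) * n)]`.
Per-chromosome maximum LODs convert to permutation P values as
$(1 + \#\{\text{null} \ge \text{obs}\})/(n_{perm}+1)$; this choice of
tail rule keeps P in $(0, 1]$ and is the natural reading when only
chromosome maxima are retained. False-discovery control uses Storey
q-values with the "smoother" $\pi_0$: $\hat\pi_0(\lambda)$ on the grid
$\lambda = 0.05, \dots, 0.95$, a df-3 cubic smoothing spline evaluated at
$\lambda = 0.95$, clamped to $[1/n, 1]$ (permutation P values are discrete,
so the raw estimate can exceed 1).

**1.5-LOD support intervals** take the outermost grid positions within 1.5
LOD of the (leftmost) peak, extended outward by one grid position where
available. Applied literally, a two-peak profile whose flanks both clear
the drop yields one wide interval spanning both peaks; this documented
behaviour matches the rule rather than attempting peak deconvolution.

## Misexpression

Misexpression is defined against the two parental lines:

* **F1 groups**: a transcript is over(under)-expressed when its F1 mean is
  above (below) *both* parental means, both Welch tests are significant at
  q <= 0.05, and both mean differences exceed `mis_delta = 0.5` log2 units.
* **F2 individuals**: a single value is over(under)-expressed when it lies
  outside both parental means by more than `max(0.5, 2 x SE)` where SE is
  the standard error of the *nearer parental group mean*. An F2 contributes
  one value, so it has no SE of its own; the parental-group reading is the
  only self-consistent one and is used throughout (including dominance
  classification below).

Counts of misexpressed transcripts per individual, split over/under x
autosome/X, are square-root transformed and mapped as quantitative
phenotypes with the same scan-and-permute machinery. Pearson correlations
of each transcript with a fertility phenotype (canonically relative testis
weight) are summarised per chromosome as fractions of significantly
positive and negative probes at q <= 0.05 (the q-value criterion for
correlations is this package's choice of convention).

## The eQTL catalogue

Per trait and chromosome, at most one record is retained: the leftmost
position of maximum LOD, if it exceeds the stratum threshold. Records are
partitioned by the probe's annotated position: **cis** within
`cis_window = 5` cM on the same chromosome, **trans** on a different
chromosome, and **excluded** for same-chromosome peaks beyond the window
(possible long-range cis regulation, dropped from hotspot analyses).

Dominance is classified from genotype-class means at the *typed marker
nearest the peak* - pseudomarkers have no observed classes, so the nearest
marker's observed genotypes are used. With class SE = SD/sqrt(n) and at
least 3 individuals per class: additive when the heterozygote mean is
intermediate and more than 2 SE from both homozygote means; dominant when
it is within 2 SE of one homozygote and beyond 2 SE of the other;
over/underdominant when it lies outside the homozygote range and more than
2 SE beyond the extreme homozygote. "Within" is tested inclusively so
noiseless class means classify exactly. Effect size is the absolute
difference between extreme homozygote (or hemizygote) means; X-male
records are `additive_hemizygous` since dominance is undefined with one
allele copy.

Enrichment of annotation sets among QTT uses the upper-tail
hypergeometric test with Bonferroni adjustment. The **sterile allele** of
a hotspot is inferred by majority vote among member QTT with F1
misexpression calls: an F1-underexpressed transcript votes for the member
eQTL's low-expression class, an F1-overexpressed one for its high class.
The vote needs at least 20 members and 60% concordance, and the
heterozygous class is eligible only when at least half the member eQTL are
over/underdominant. The size and concordance gates are package choices
(the source procedure is qualitative); both are configurable arguments.

## Trans hotspots

Trans eQTL are counted in sliding windows of `hotspot_window = 4` cM
anchored at every grid position, half-open `[start, start + 4)` and
truncated at the chromosome end; a truncated window is closed at the end
so the terminal grid position is always covered, and zero-width anchors at
the very end are dropped. Truncated windows keep their true (shorter) size.

The null model reassigns each trans eQTL independently to a uniformly
chosen grid position on a chromosome *other than its probe's chromosome*
(preserving trans status and the per-probe eQTL count). Per permutation
the maximum window count is recorded separately for each distinct window
size, and a window is flagged when its count strictly exceeds the
`1 - alpha` quantile of the same-size maxima. The alternative reading of
"another chromosome" - different from the observed eQTL's chromosome - is
available via `anchor = "eqtl"`. Overlapping or adjacent flagged windows
merge into one hotspot spanning their union; merged hotspots inherit
member-window significance rather than re-testing at the merged size.

Co-localization with sterility-QTL intervals keeps the intervals fixed and
redraws hotspot positions: the observed number of non-overlapping
intervals of the observed cM sizes is placed uniformly at grid anchors
(rejection sampling, at most 10,000 attempts), and three statistics are
scored per permutation - hotspots overlapping any interval, grid positions
inside both, and total overlapping cM - each with an upper-tail
permutation P value.

## Conditional mapping of interactions

Under the Dobzhansky-Muller model, hybrid incompatibilities are negative
epistatic interactions, and full two-dimensional pair scans of tens of
thousands of transcripts are hopelessly underpowered. Conditional mapping
instead fixes a candidate locus (a hotspot marker) as a genotype covariate
and scans each trait twice on the same individuals: an **additive** model
(locus + covariate) and a **full** model adding locus x covariate
interaction terms. The interaction LOD is
$\mathrm{LOD}_i = \mathrm{LOD}_f - \mathrm{LOD}_a \ge 0$ by nesting.

The covariate genotype is the most probable class at the covariate marker
(ties treated as missing; covariates sit at typed markers where the
probabilities are near-degenerate). Its design columns are the additive
dosage and a heterozygote indicator (dosage only on the X); the
interaction block is covariate dosage x scan dosage, plus het x het
probability when both loci are autosomal - 2 interaction df for
autosome x autosome and 1 when either locus is X-male. Positions within 5
cM of the covariate are masked to prevent trivial self-interactions from
collinearity; only this guard is applied, not a whole-chromosome mask.

Thresholds for $\mathrm{LOD}_f$, $\mathrm{LOD}_a$, and $\mathrm{LOD}_i$
come from **same-seed permutations**: each permutation shuffles the trait
once and scans that same shuffled vector under both models, so the
permutation's interaction LOD is the difference of paired profiles, never
mixed across permutations. An interaction eQTL requires both
$\mathrm{LOD}_f$ and $\mathrm{LOD}_i$ to exceed their thresholds; the
joint rule is conservative (the two exceedances are positively dependent,
so the joint null rate is below alpha, not alpha squared). Interaction
hotspots reuse the sliding-window machinery on the trans subset of
interaction eQTL.

Hotspot regions and covariate positions become network nodes after
single-linkage merging of same-chromosome regions closer than
`node_merge_mb = 12.8` Mb (about the average spacing of a ~200-marker
mouse panel); edges point covariate to peak with the summed interaction
eQTL count, and edges present in both orientations are flagged reciprocal.

## The synthetic-cross generator

Every stage is testable without external data because the generator
produces crosses with known ground truth:

* **Map**: 19 autosomes (50-90 cM) plus an 84 cM X, markers every 8 cM
  (about 200 genome-wide), Mb = 2 x cM.
* **Genotypes**: gametes from a sequential crossover process with
  independent interval recombinations (no interference) under the Haldane
  map function. The analysis HMM assumes Markov transitions, which this
  process satisfies exactly; the Carter-Falconer default in analysis
  differs negligibly at the 8 cM marker spacing. A chi-square interference
  model is deliberately out of scope.
* **Expression**: value = parental-lineage baseline + genotype-dependent
  effects + N(0, `noise_sd = 0.5`) on the log2 scale. Cis effects are the
  homozygote difference at a linked marker; master regulators apply a
  per-mode class multiplier (additive (0, 0.5, 1), dominant (0, 0, 1) /
  (0, 1, 1), overdominant (0, 1, 0), underdominant (0, -1, 0)); epistatic
  effects apply only in named two-locus classes, and the product-contrast
  helper yields exactly zero marginal means under 1:2:1 segregation.
  Parental and F1 control samples (8/8 parents, 4 fertile DxM and 6
  sterile MxD F1s, matching the emulated study) are generated from the
  same rules with fixed genotypes.
* **Phenotypes**: four sterility traits (testis weight, sperm count,
  abnormal sperm, tubule area) with genotype-dependent means, supporting
  underdominant loci (sterile heterozygotes, the chromosome-17 pattern)
  and Dobzhansky-Muller sterility confined to an incompatible two-locus
  class.

The generator emulates the *statistical* structure the analysis assumes -
group means, Gaussian noise, Markov genotypes - and none of the
technical structure of real microarray data: no probe effects, spatial
artifacts, intensity-dependent variance, or cell-composition shifts.
Passing tests therefore demonstrate that the machinery is correct and
calibrated under its own assumptions, not that those assumptions hold for
any particular real dataset.

## Numerical and design choices

* cM coordinates are chromosome-local with origin at the first marker;
  intervals are closed on cM; Mb is for reporting only, interpolated
  linearly between flanking markers (clamped at the ends with a warning).
* Fertile-subset selection standardises the four sterility traits over
  complete cases (individuals missing any trait are dropped from the PCA
  only), orients PC1 by the sign of the first trait's loading (higher =
  more fertile), and keeps ids strictly above the 20th percentile.
  Degenerate all-constant input returns the full set with a warning.
* Peak ties break to the leftmost grid position everywhere.
* Stage seeds derive from the master seed by fixed offsets
  (`seed + 104729 * offset` mod 2^31-ish), so stages rerun independently
  yet reproducibly; every generator and permutation routine is a pure
  function of its inputs and seed.
* EM mixtures guard empty classes (a class with no posterior mass has its
  coefficient zeroed) and floor the variance at 1e-12.
* Permutation thresholds use `method = "hk"`; EM and HK agree closely for
  normal-quantile-transformed traits, and the vectorised HK engine makes
  ratio-scaled X permutation counts affordable.

## Problem sizes in the test-suite experiments

The packaged experiments run at desk scale, chosen to finish in minutes
while leaving the measured properties interpretable: calibration of the
single-transcript threshold uses 500 replicate null traits at 200
permutations each on a five-autosome genome (a single stratum, so the
nominal alpha applies undivided); hotspot-null calibration uses 200
replicate datasets of 5,000 uniformly reassigned trans eQTL on a
19-autosome map with even chromosome lengths (keeping the set of truncated
window sizes small); master-regulator recovery plants 800 affected
transcripts among 1,000 on the full mouse-like map at n = 300, with a
one-residual-SD per-target effect (direct LOD around 8, comparable to
observed trans-eQTL strengths; much larger per-target effects would let
chance inter-chromosomal correlation of the master genotype induce
correlated secondary clusters, which the reassignment null rightly calls
as hotspots); epistasis
recovery and the fertile-subset contrast use 20 seeded runs each at
n = 300. Publication-scale permutation counts (10,000/158,550, 360
dataset-wide) are reached by raising the `qtl_config()` counts.

## Limitations

* Standard Haley-Knott regression is used for phenotype scans; the
  extended (heteroskedasticity-aware) variant is not implemented, which
  matters only for raw (not quantile-transformed) traits with strongly
  non-normal residuals.
* Multiple-QTL model selection, composite interval mapping, and full 2-D
  pair scans are out of scope, as is genetic-map estimation.
* The per-size hotspot thresholds control each window-size family at
  alpha; genomes whose chromosome lengths generate many distinct truncated
  sizes accumulate slight family-wise inflation (the even-length
  calibration genome keeps this negligible).
* Sterile-allele inference implements the F1-concordance criterion;
  cell-type enrichment sets are consumed as optional evidence only.
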