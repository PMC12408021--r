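---
title: "Methods and modelling choices in apmicro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in apmicro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmicro)
```

`apmicro` implements a strain-resolved, longitudinal case-control analysis
of infant gut metagenomes. The motivating setting is food protein-induced
allergic proctocolitis (AP), a non-IgE-mediated food allergy of early
infancy: two arms of infants (cases with AP, unaffected controls) are
sampled repeatedly across the first year of life, and the questions range
from community-level (does diversity or stability differ?) through
species-level (which taxa are differentially abundant, controlling for
age, delivery and probiotic exposure?) down to strain- and gene-level
(are there disease-associated lineages, and what genes distinguish
them?). This vignette records the models the package implements, the
defaults it chooses where the underlying methods literature is silent,
and the limits of what its synthetic-data tests demonstrate.

## Cohort model

Clinical data live in a `cohort_table()`: infant-level covariates (group,
sex, delivery mode, initial feeding, first-year probiotic use) plus
per-sample age and symptom state. Case infants pass through three states —
pre-symptomatic, symptomatic, resolved — and the container enforces that
these appear in that order along age within each infant; controls carry a
single `control` state.

**Age bins.** Collection ages are grouped into half-open intervals
`[lo, hi)` bracketing the scheduled pediatric visits, with default edges
0, 0.35, 0.75, 1.5, 3, 5, 8, 10.5 and 14 months. The half-open,
lower-edge-inclusive convention is a deterministic choice; a sample at
exactly 0.35 months belongs to the 2-week visit, and ages at or beyond
the last edge are refused rather than silently clamped.

**Disease-state subsets.** To avoid over-weighting densely sampled
infants, per-phase analyses use one sample per infant: the *last*
pre-symptomatic, *first* symptomatic, and *first* resolved sample. Age
ties break by lexicographic sample id so the selection is reproducible.

**Age matching.** Case samples are paired one-to-one with control samples
by minimising the total absolute age difference — the linear sum
assignment (Hungarian) problem, solved by `clue::solve_LSAP()`. When the
sides are unequal the surplus on the larger side is reported unmatched.
The test suite checks the solution against exhaustive enumeration for all
instances with up to eight samples per side.

**Demographics.** Group-wise covariate comparisons use two-sided Fisher's
exact tests; reported odds ratios apply the Haldane–Anscombe 0.5
correction only when a cell is empty (the test itself is exact).

## Community metrics

Alpha diversity uses Chao1 (`S_obs + f1^2 / (2 f2)`, bias-corrected to
`S_obs + f1(f1-1)/2` when no doubletons exist) and Shannon entropy in
nats. Chao1 requires counts; on relative-abundance input it degrades to
observed richness with a warning, because singletons are undefined
without counts.

Beta diversity offers Bray–Curtis (via `vegan::vegdist`) and Aitchison
distance — Euclidean distance between centred log-ratio transformed
compositions. Zeros are replaced by a pseudocount before the clr; the
default is **half the minimum non-zero value in the table**, a common
convention that keeps the replacement below every observed value. The
pseudocount is exposed because clr-based distances are sensitive to it.

Ordination is classical metric PCoA: double-centre the squared-distance
Gram matrix, eigendecompose, and drop negative eigenvalues from the
variance denominator (they arise for non-Euclidean dissimilarities).
Axis signs follow a fixed convention — the largest-magnitude score on
each axis is positive — so ordinations are reproducible across runs and
platforms. A one-way ANOVA of axis-1 scores by group quantifies
group-level separation along the leading gradient.

**Stability.** For each pair of consecutive age bins, the within-infant
Bray–Curtis distance (an infant's sample in bin *t* vs its sample in bin
*t+1*) is compared with between-infant distances across the same bins.
When an infant has several samples in a bin, the one closest to the bin
midpoint is used. Comparisons use Welch (unequal-variance) t-tests
throughout: distance distributions are bounded and often heteroscedastic
across strata, and the Welch form costs nothing when variances happen to
be equal. A second Welch test compares within-infant distances between
cases and controls per transition.

## Differential abundance model

The per-feature association model follows the common microbiome
multivariable-linear-model design: relative abundances are arcsine
square-root transformed (`asin(sqrt(x))`, variance-stabilising for
proportions), features are filtered to those reaching 0.1% abundance in
at least 10% of samples, and each retained feature is regressed by
ordinary least squares on the encoded fixed effects — symptom group,
delivery mode, age at collection, and probiotic use, with treatment
coding referenced at control / vaginal / no-probiotic. Wald t-tests give
per-covariate p-values; Benjamini–Hochberg correction is applied across
features within each covariate, and the conventional significance rule is
p < 0.05 with q < 0.25.

The 10% prevalence floor completes a one-sided abundance rule with the
customary default of this model family; both thresholds are arguments.

**Longitudinal handling.** Repeated samples per infant violate OLS
independence. Two modes are provided. The disease-state subsets are
one-sample-per-infant by construction. For age-window analyses the
default reduces to one sample per infant — the sample closest to the
window midpoint (ties by sample id) — before fitting. This trades a
little efficiency for unbiased per-infant weighting and transparent
degrees of freedom; a mixed-effects extension is a natural follow-on but
is deliberately out of scope, and no claim is made that either mode is
identical to any published pipeline's internal handling.

## MinHash sketches and Mash distances

Genome relatedness uses bottom-`s` MinHash sketching of canonical k-mers
(the lexicographic minimum of each k-mer and its reverse complement),
with defaults k = 21 and s = 1000, the customary genome-sketching
parameters. Hashing is the splitmix64 finaliser on the 2-bit k-mer code,
truncated to the top 53 bits so hash values are exactly representable as
R doubles; selection, set semantics and the Jaccard estimator all operate
on the truncated values, so the scheme is internally consistent and
deterministic across platforms. K-mers containing ambiguous bases are
skipped. No bit-compatibility with any external sketching tool is
promised — the contract is metric equivalence: the estimator converges to
the true k-mer Jaccard (checked against an exact k-mer-set oracle), and
the distance `d = -(1/k) log(2j/(1+j))` is symmetric, zero iff the
sketches coincide, and monotone in j. Disjoint sketches saturate at
d = 1.

The stratified comparison splits within-species genome pairs into
*related* (same infant) and *unrelated* pairs and tests related vs
unrelated, and case vs control within related pairs, with two-sided
Mann–Whitney U tests — chosen over t-tests because Mash distances are
bounded, skewed, and heavily tied near zero for clonal pairs. Completely
tied comparisons report p = 1 rather than NaN. Species are ranked by MAG
count with lexicographic tie-break, and the top 20 are tested by default.

## Strain trees and the clade enrichment scan

Trees are built by neighbour joining (`ape::nj`) from either normalised
Hamming distances on marker-SNV haplotypes (ambiguous sites excluded
pairwise) or Jaccard distances on pangenome gene content. Jaccard is
preferred over Hamming for gene content because incomplete MAGs shrink
gene sets roughly uniformly, which Jaccard tolerates. NJ can emit
negative branch lengths on non-additive input; these are clamped to zero
with the deficit transferred to the sibling edge, preserving path lengths
as closely as possible. Topology, not branch lengths, is the contract:
the suite verifies exact recovery on additive matrices and invariance to
input order.

The **clade scan** is the package's core bespoke procedure. Every
internal node with at least `min_leaves = 6` leaves is tested by a 1-df
chi-square goodness-of-fit of its case/control leaf split against the
expected case fraction, without continuity correction; `p < 0.05` flags a
clade, mirroring the pie-chart convention of annotating only nodes whose
composition departs from the null split. Three deliberate choices:

* **Expected fraction.** The default is the observed case share of the
  leaf set, which equals 0.5 for balanced case-control selections; an
  explicit `expected_case_fraction = 0.5` forces the even-split null. The
  two differ on unbalanced inputs, so the choice is an argument, not a
  constant.
* **No multiple-testing correction across nodes by default**, matching
  the per-node flagging convention; `adjust = TRUE` adds BH q-values
  across tested nodes, and `maximal = TRUE` keeps only significant nodes
  whose parent is not significant, de-duplicating nested signals.
* **Infant-oriented clades** (all leaves from one infant) are flagged for
  every node regardless of size — a single-leaf node is infant-oriented
  by definition — because single-infant clades are relatedness, not
  disease, signals.

The chi-square is an approximation: for clades near the minimum size its
per-node level is not exactly 0.05, and under label permutation on
realistic tree shapes the flagged-node fraction sits near but not exactly
at nominal (the calibration tests allow a three-point band). Exact
binomial or permutation p-values would be straightforward replacements
where exactness matters.

**Clade-unique genes** are genes present in at least 95% of the clade's
genomes and at most 5% of the rest. The tolerance (rather than a strict
100%/0% rule) absorbs MAG incompleteness and contamination; both
thresholds are arguments. Term enrichment on the resulting gene set is a
one-sided hypergeometric over-representation test against a user-supplied
gene-to-term map with BH correction across terms — the annotation content
itself (e.g. a curated pathway database) is the user's input, not the
package's.

## MAG quality tiers

Bins are tiered by the literal rule: high if completeness ≥ 85 and
contamination < 5; medium if 50 ≤ completeness < 85 and contamination
< 5; otherwise low. Boundary semantics are exactly as written —
completeness 85 is high-eligible, contamination 5 is not.

## Classification protocol

The case/control classifier is a class-weighted random forest on
standardised relative abundances. Features must exceed 1% mean relative
abundance, and therapeutically administered probiotic species can be
excluded by name: their abundance reflects exposure (which is itself
correlated with being a case) rather than endogenous community state, so
leaving them in inflates apparent performance.

Evaluation is stratified 5-fold cross-validation with all adaptive steps
inside the training folds only: standardisation parameters, and the
iterative feature elimination that drops the lowest-Gini decile per
round until at most `n_keep = 120` features remain. A leakage canary in
the test suite confirms the fold hygiene: a feature equal to the label is
learned almost perfectly, while a feature informative only in held-out
portions of the data is not exploited. Forest defaults are 500 trees,
unlimited depth, and the square-root feature-subsampling rule; all are
arguments. Age-stratified models (≤ 4 months, > 6 months on collection
age) are obtained by windowing the samples before training.

Attribution is **signed permutation importance**: the drop in mean
predicted true-class probability when a feature is permuted, signed by
the correlation between the feature and the predicted case probability.
This covers the interpretive use of Shapley-value summaries — a ranking
with direction — without further dependencies; exact Shapley computation
can be slotted in behind the same interface where an implementation is
available. Duplicated features split their importance in an
order-dependent way, as for any permutation scheme on correlated inputs.

## The synthetic cohort generator

Every analysis stage is exercisable on `sim_config()` +
`generate_cohort()` + `generate_abundances()` + `generate_strain_data()`
+ `generate_mags()` with no external data. The defaults encode the study
conditions the package is designed around:

* 163 infants, 84/79 case/control split; scheduled visits at 0.1, 0.5,
  1, 2, 4, 6, 9, 12 months with Gaussian jitter (sd 0.15 months,
  truncated at zero); 57% visit attendance, giving a median of about
  four samples per infant and roughly 740 samples.
* Symptom onset ages are log-normal with median 0.5 months and sdlog
  0.81 (matching a 0.3–0.9 interquartile range); resolution is onset
  plus a log-normal delay (median 5 months), which places resolved
  samples at a median age near 8.6 months. States derive from these
  ages; a sample on the onset day counts as symptomatic.
* Probiotic use is drawn at 85.7% in cases vs 20.3% in controls; sex,
  delivery and feeding frequencies are balanced across arms (45% female,
  65% vaginal, 63/27/10% exclusive/partial/formula feeding).
* Counts are Dirichlet-multinomial: per-taxon log-weights combine a
  baseline, an age slope on `log1p(age)`, a per-infant per-taxon normal
  intercept, planted case/control effects in configurable age windows
  (default: a 2-fold *Escherichia coli* case effect at 0–2 months), and
  a large probiotic-species boost in exposed infants. The
  Dirichlet-multinomial was chosen as the noise model because marker-based
  profilers report compositions with strong overdispersion relative to
  multinomial sampling; the concentration parameter is exposed.
* A handful of founder taxa dominate at birth while the remaining taxa
  rise with age, so richness and evenness grow over the first year
  (age–diversity correlations near 0.6–0.8). The infant-intercept sd
  (0.5) and concentration (50) were fixed once so that three properties
  hold jointly at the defaults: within-infant distances are clearly
  smaller than between-infant distances, group-null p-values are
  uniform, and the planted 2-fold effect at 160 infants is recovered
  with q < 0.25 in at least 90% of seeds — the generator is calibrated
  to be a usable testbed, not tuned per test.
* Strain data: the probiotic species gets near-clonal haplotypes in
  exposed carriers (per-site divergence 5e-4, i.e. pairwise distances
  around 0.001) and more diverse haplotypes (2%) in unexposed carriers;
  the planted-clade species gets a 120-genome pangenome (1000 core, 600
  random accessory genes at 35% carriage) over ~72 infants with up to
  two genomes per infant, a 12-genome planted clade carrying 223 genes
  unique to it, and 50 kb genome backbones with between-infant (1%) and
  within-infant (0.1%) divergence for sketching. The planted clade is
  drawn entirely from case samples: with on the order of a hundred
  tested nodes per scan, a weaker clade signal is regularly out-scored
  by the null minimum, and a pure clade (chi-square 12 at size 12) is
  what makes the planted structure the dominant signal it is meant to
  be.
* MAG records: 98.4% of samples yield bins; counts per yielding sample
  are zero-truncated Poisson (mean 12.4); completeness ~ 100·Beta(1.227,
  0.397) and contamination ~ 100·Beta(1, 24), solved numerically so the
  default tier split is approximately 36.6/20.8/42.6% high/medium/low.

All randomness flows from one integer seed through fixed per-generator
sub-streams, so regenerating one artifact never shifts another, and
every generator is byte-reproducible under a fixed seed.

**What the generator does not emulate.** Read-level error, assembly and
binning artefacts, taxonomic misassignment, genuinely compositional
zero-inflation structure, feeding biochemistry, visit-attendance patterns
correlated with disease activity (attendance is a free, independent
parameter), and horizontal gene transfer. Passing tests therefore
demonstrate that the implementations are correct and calibrated on data
with the assumed statistical structure — not that the pipeline's power or
error rates transfer quantitatively to real cohorts.

## Problem sizes and numerical conventions

The test suite and the acceptance script run the full default cohort
(163 infants, ~740 samples, 60 taxa), 120-genome strain sets with 50 kb
backbones, and 20-seed Monte-Carlo loops for the recovery and power
properties — sizes chosen so the whole suite completes in a few minutes
on one core while keeping every estimate's Monte-Carlo error well inside
the asserted bands. Deterministic tie-breaks are documented at every
choice point (lexicographic sample ids, lowest-index NJ pairs,
lexicographic species ranking); relative tables are validated to close
to 1 within 1e-6; proportions are the internal unit, with percentages
only at I/O boundaries.
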