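---
title: "Methods: depth-stratified metatranscriptome analysis with stratameta"
author: "stratameta authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: depth-stratified metatranscriptome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratameta)
```

## The problem this package addresses

In a stratified water column, sinking organic matter is processed by
prokaryotic communities whose composition and function change sharply with
depth. Community metatranscriptomics quantifies that change at the level of
transcribed open reading frames (ORFs): which taxa transcribe
carbohydrate-active enzymes (CAZymes), peptidases (PEPs) and membrane
transporters (TPs), and how a taxon's *relative investment* in degradation
versus uptake shifts between the surface and depth. `stratameta` implements
the downstream statistics of such a study as a tested, reusable pipeline:
consensus functional annotation, count normalization, richness/evenness
estimation, transformation-based ordination and permutation inference, and
taxon-resolved gene-system investment log ratios, exercised end to end on a
synthetic stratified-community generator with known ground truth.

All computations start from four inputs: an ORF x sample count matrix with
ORF lengths, a per-ORF taxonomy lineage (with an rRNA-overlap flag produced
upstream), raw multi-tool functional prediction tables, and per-sample
metadata (depth, month, replicate, environmental covariates). Upstream
sequence processing (assembly, ORF calling, read mapping, HMM searches,
phylogenetic placement) is out of scope; its outputs are consumed as plain
tables.

## Data model and input filters

The central container is `OrfExperiment`, an S4 class extending
`SummarizedExperiment`: the `counts` assay holds non-negative integer
transcript counts, `rowData` carries `length_bp` and the taxonomy lineage
(domain to genus, with empty cells normalized to the reserved sentinel
`"unclassified"`), and `colData` the sample metadata. Validity enforces
unique identifiers, integral non-negative counts and positive lengths, so
malformed inputs fail at construction rather than mid-analysis.

Two global filters precede all statistics. `filterRrnaOverlaps()` removes
ORFs flagged as overlapping predicted rRNA genes -- the flag is an input
because overlap detection is a sequence-level upstream step; a flag-based
design is also agnostic to whether removal happens before or after taxonomy
assignment, which the pipeline does not need to know. `subsetProkaryotes()`
keeps Bacteria and Archaea. The two filters commute (a tested invariant) and
each records its removal count in the object metadata, so a run manifest can
report the full ORF funnel.

## Consensus CAZyme classification

Raw CAZyme predictions come from three tool families: alignment
("diamond"-style, percent identity), profile ("hmmer"-style, coverage) and
peptide-pattern ("hotpep"-style, hit count and frequency). The consensus in
`consensusCazyme()` has two rules:

1. **Single-tool ORFs** are kept only above the tool's quality threshold:
   identity >= 50, coverage >= 0.5, hits >= 10. Exclusion uses strict `<`,
   so a metric *exactly at* the threshold is retained; boundary fixtures pin
   this down.
2. **Multi-tool ORFs** are ranked per candidate family, first by the number
   of tools voting for the family, then by the sum over supporting tools of
   a normalized quality score in [0, 1]: identity/100 for alignment,
   coverage for profile, and `min(1, hits/hits_cap) x frequency / max
   frequency within the ORF` for the pattern tool (`hits_cap = 100`).
   Exact ties break lexicographically by family label and are flagged in the
   `provenance` column.

The ranking inputs (votes, relative identity, coverage, relative hits plus
frequency) are fixed by the consensus scheme this mirrors, but their exact
arithmetic combination is not; the vote-then-quality-sum combination used
here was chosen because it is monotone in every raw metric, scale-free, and
deterministic, and it is exposed as configurable (`thresholds`, `hits_cap`)
rather than presented as canonical. The whole classifier is verified against
an independently coded brute-force oracle over an exhaustive grid of tool
combinations and boundary metrics (117 cases), with exact agreement
required.

Peptidases map profile accessions to MEROPS families; transporters map TCDB
profile hits to families after applying the two shipped manual corrections
(PF00909 to the Amt family, TC 1.A.11; PF00654 to the ClC family, TC
2.A.49). For both, multi-domain ORFs resolve to the highest-scoring hit --
one label per ORF per system, matching how the summaries are reported;
whether multi-domain ORFs should instead count once per domain is genuinely
open, and per-ORF resolution was chosen as the conservative reading.
Marker genes (radA, amoA) are gated on the profile's recommended gathering
score; hcd labels come from an upstream phylogenetic placement and are
accepted as given; amt is carried as both a transporter and a marker, and an
ORF may legitimately hold one label per system.

## Normalization

* `countsPerMillion()` and `tpm()` rescale each sample to 1e6; TPM first
  divides counts by ORF length in kilobases (the standard length unit --
  only a constant, but fixed for clarity).
* `abundanceFilter()` keeps ORFs with at least `min_cpm = 5` cpm in at least
  `min_samples = 2` samples. The threshold is inclusive (`>=`): where the
  two available wordings of the rule disagree ("at least 5" vs "> 5"), the
  methods-style wording wins and the alternative is available as
  `strict = TRUE`. The filter is computed once on the full prokaryote
  matrix and never iterated, because recomputing cpm on the filtered matrix
  can demote further ORFs; one filtered set is reused by all analyses.
* `hellingerTransform()` takes the square root of per-sample relative
  abundances, making Euclidean distances between samples appropriate for
  community counts (the transformation-based PCA/RDA approach).
* `srsNormalize()` implements scaling with ranked subsampling: counts are
  scaled to a common total `C_min` (default: the smallest library), integer
  parts kept, and the leftover counts assigned by fractional-part rank.
  Rank ties are resolved by a seeded uniform choice among the tied ORFs --
  the method leaves ties to chance, and the seed makes that chance
  reproducible. Column totals equal `C_min` exactly and every normalized
  count is within one of its scaled value. The common `C_min` is not
  specified by the protocol this follows; the smallest library is the
  default because it never discards a sample.

## Diversity

Richness and evenness are estimated on SRS-normalized integer counts (the
estimators reject fractional input). Chao1 uses the bias-corrected form
`S + F1(F1-1) / (2(F2+1))`, which stays finite when no doubletons exist;
the classic `S + F1^2/(2 F2)` form is available by flag. Pielou's J uses
natural logarithms (any base cancels except through `ln S`; natural log is
the convention). Functional-subset diversity (e.g. CAZyme richness per
sample) is computed at the ORF level within the subset, and each subset
submatrix is SRS-normalized to its own smallest total so that richness is
comparable across samples within the subset. Depth-layer comparisons use
one-way ANOVA with Tukey HSD; layers with a single sample are excluded with
a warning, and a fully degenerate response (no variation at all) is reported
as F = 0, p = 1.

## Ordination and multivariate inference

PCA operates on the Hellinger matrix with samples as observations and ORFs
centered. For constrained analysis, environmental covariates are
z-standardized and screened by `selectEnvVariables()`: while any pairwise
|Pearson r| >= 0.9, the member of the worst pair with the larger mean
absolute correlation is dropped; then variables with variance inflation
factors >= 10 are dropped largest-first. Both loops are deterministic.
Ammonium values below the detection limit (0.2 uM) are replaced by 0.001
(`imputeBelowDetection()`) so the variable remains usable in the RDA.

`rdaOrdination()` delegates the least-squares constrained ordination to
vegan and runs three seeded Monte Carlo permutation-test families: global,
sequential per-axis, and marginal per-variable (each variable given all
others -- a type-III-style test; the alternative sequential scheme is a
deliberate non-choice because variable order is arbitrary here). Holm
correction is applied within each family. Permutations are free permutations
of sample rows; no restricted/block scheme is imposed. Adjusted R^2 uses
Ezekiel's formula. p-values are bounded below by `1/(n_permutations + 1)`.
A detrended-correspondence gradient-length suitability check is out of
scope; users porting this to real data should run one first.

`variancePartition()` decomposes the full-model adjusted R^2 over 2-4
predictors into unique and shared fractions by Moebius inversion over the
adjusted R^2 of every predictor-subset RDA; the fractions are additive to
the full-model value by construction (tested to 1e-6, and cross-checked
against vegan's varpart). Shared fractions can be slightly negative, as is
standard for adjusted-R^2 partitions. More than four variables are refused
(2^k subset models).

`permanovaTest()` partitions squared Euclidean distances on the Hellinger
matrix (consistent with the PCA/clustering input; the dissimilarity is not
otherwise dictated) with a seeded permutation p-value and
`R2 = SS_between / SS_total`. `hierarchicalClusters()` z-scores ORF rows of
the Hellinger matrix ("scaled" Hellinger -- the z-scoring interpretation is
the only well-defined reading, and a flag disables it), computes Euclidean
distances and Ward.D2 linkage, and reports both an elbow curve and mean
silhouette widths over k; the automatic `chosen_k` is the silhouette
maximum, with the elbow curve reported for graphical inspection only.

## Investment log ratios and marker-gene ratios

`systemTotals()` sums member-ORF TPM per (taxon, sample, gene system); an
ORF contributes to every system it is assigned to. `investmentLogRatios()`
computes, per taxon, depth and month, the per-replicate
`log2(system_A / system_B)` and then the mean and SD across biological
replicates -- a mean of log ratios, not a log of mean ratios, matching
"mean log ratio +/- SD (n = 2)" reporting. Log base 2 is used so that +/-1
reads as a 2-fold difference ("3- to 4-fold" statements translate
directly); the base is configurable. A replicate with one zero system sum
substitutes half the smallest positive system total in the table and is
flagged; a replicate with both sums zero is excluded and flagged. The
ratios are TPM-based (the family-level abundance summaries are TPM-based),
while taxon relative transcription and marker percentages are computed from
raw-count fractions ("percentage of total transcripts"); both bases are
invariant to per-sample scaling, and the TPM/count choice for the ratios is
switchable in principle via the matrix handed to `systemTotals()`.

Marker analysis reports per-sample percentages of total transcripts for
radA, amoA, hcd and amt, replicate means +/- SD per depth and month, and
`log2(marker/radA)` ratios against the single-copy reference radA.
Community-wide percentages (not per-taxon percentages) are used, following
the "percentage of total transcripts" convention. Alongside the per-stratum
means, a pooled estimator -- `log2` of abundances summed over all samples --
is attached: in strata where the archaeal order is rare the per-replicate
log ratio is noisy and biased (the log of a small-count ratio), whereas the
pooled ratio of sums is stable; recovery checks therefore use the pooled
form while the per-stratum table mirrors the figure-style reporting.

## The synthetic generator and what passing tests mean

`generateDataset()` emulates the study design: nine focal prokaryotic
orders, depths of 5/15/50/75/100 m sampled in July and September with two
biological replicates, lognormal library sizes with mean 2e5 reads. Each
order follows a logistic depth-activity profile (surface specialists,
depth specialists, one depth-stable clade) with a September multiplier;
within an order, transcription is allocated to CAZyme/PEP/TP/marker/other
fractions whose CAZyme/PEP log2 ratio follows a programmed linear
trajectory in depth, so the investment statistics have exact ground truth.
Replicate scatter is Dirichlet-multinomial with concentration 5000, i.e. a
coefficient of variation around 5% for a mid-abundance order -- moderate
scatter for biological duplicates; `Inf` disables it. Marker folds default
to amoA:radA = 4 and hcd:radA = 3, within the stated 3- to 4-fold range.
Environmental covariates follow the canonical stratified shapes
(temperature/oxygen/DOC decreasing, nutrients increasing, Chl a with a
subsurface July maximum and a surface September maximum), with July
ammonium censored below the 0.2 uM detection limit; several covariates are
depth-collinear by construction so that variable selection has real work to
do. Small eukaryotic and rRNA-flagged contaminant blocks exercise the input
filters, and all ground truth is stated conditional on the retained
prokaryote set.

Deliberate simplifications: ORF lengths are constant (1000 bp) by default,
so TPM- and count-based shares coincide and length bias is exercised only in
unit tests of `tpm()`; annotation tables are lossless by default (no
sub-threshold or unmapped records unless configured), so recovery error
reflects sampling noise rather than annotation loss; every order carries the
same number of ORFs; and no sequence-level artifacts (chimeras, mapping
bias, UMI-type effects) are simulated. Passing recovery tests therefore
demonstrates that the statistics faithfully invert the generative model at
realistic depth coverage -- not that they are robust to annotation error or
assembly artifacts in real data.

## Problem sizes and numerical choices in the test suite

The suite runs at deliberately modest sizes chosen to make the checked
properties sharp: classifier-oracle equivalence on the exhaustive 117-case
boundary grid; transform identities on 100 random matrices (unit Hellinger
norm to 1e-12, column sums to 1e-6); type-I error of PERMANOVA and the RDA
global test on 500 structureless datasets of 20 samples x 50 ORFs with 199
permutations each (acceptance band 3-7% rejection at alpha = 0.05);
variance-partition additivity to 1e-6 on 50 random designs; and parameter
recovery at the default generator design -- the depth-collinear covariate
significant after Holm in at least 95 of 100 seeds, surface/deep clustering
ARI >= 0.9, CAZyme/PEP trajectory mean absolute error <= 0.3 (averaged over
10 seeds), and the amoA:radA fold recovered as pooled log2 in 2.0 +/- 0.2
(averaged over 50 seeds). The SRS expectation-preservation check uses a
column whose leftover allocation randomizes across a single fractional-tie
group, because that is precisely the regime in which SRS is unbiased per
count; with unequal fractional parts the integer allocation is deterministic
and within-one-count accuracy, not unbiasedness, is the guarantee.

## Known limitations

* The consensus ranking arithmetic is one defensible member of a family of
  monotone combinations; totals at the family level can differ under other
  choices (votes and thresholds are unaffected).
* Richness comparisons are conditional on the SRS depth; the smallest
  library sets it, so one shallow library lowers resolution everywhere.
* Marginal RDA tests lose power when surviving predictors remain partially
  collinear; the selection step mitigates but does not remove this.
* The pipeline assumes biological replicates are exchangeable within a
  depth-month stratum; no nested or repeated-measures structure is modelled.
* Percentages and TPM are compositional; the log-ratio analyses respect
  this, but the per-taxon percentage tables should not be read as absolute
  activities.
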