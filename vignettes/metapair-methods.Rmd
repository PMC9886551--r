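---
title: "Methods: paired primary-metastasis multiomics analysis with metapair"
author: "metapair maintainers"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: paired primary-metastasis multiomics analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`metapair` re-implements, as a tested pipeline, the statistical machinery
used to compare matched primary and metastatic breast tumors across four
data types: bulk RNA-seq counts, Infinium-style CpG beta values, somatic
variant calls with read-level evidence, and denoised log2 copy-ratio
tracks. The package does not align reads, call variants or process array
IDATs; it consumes the standard downstream artifacts (count matrices,
M/U intensities with detection p-values, MAF-like variant records,
copy-ratio tracks) and implements everything from there.

Two design commitments shape the package. First, every analysis is
*paired*: the unit of inference is the participant, with the primary
tumor and one or more metastases as repeated measures, so the core model
throughout is a linear mixed model with a participant random intercept.
Second, every stage is testable without controlled-access data: the
synthetic cohort generator plants known effects and records them in a
truth object, and the test suite checks recovery against that truth.

# The expression chain

Raw counts move through tagged stages (`counts` → `normalized` → `log2`
→ `batch_corrected` → `normal_adjusted`), enforced by the
`StagedExpression` container so a matrix cannot be log-transformed twice
or batch-corrected before normalization.

* **Normalization.** Two interchangeable front ends: upper-quartile
  scaling (each sample's 75th percentile of nonzero counts brought to a
  fixed target, default the cohort's geometric-mean upper quartile —
  the constant is arbitrary and cancels in all downstream contrasts)
  and median-of-ratios size factors as implemented in DESeq2, with
  genes below a mean normalized count of 10 flagged out.
* **Filter and transform.** Genes expressed (count > 0) in at least 70%
  of samples are kept; values map to log2(v) with zeros returned to
  zero. We read "expressed" as strictly positive; a higher floor is a
  parameter (`expressedFraction` covers the proportion, not the floor).
* **Batch correction.** FFPE-versus-FF offsets are removed per gene by
  subtracting batch means re-centered to the gene's grand mean. This is
  the least-squares fit with a batch factor; we implement it directly
  (rather than delegating) because the pipeline's contract is exact
  grand-mean preservation, which sum-to-zero parameterizations do not
  guarantee for unbalanced batches. The result agrees with
  `limma::removeBatchEffect` up to a per-gene constant.
* **Normal-tissue contamination.** Metastases carry stroma from their
  host organ. Site signatures are derived by per-gene two-group linear
  models of each normal tissue versus normal breast (upregulated genes
  at FDR < 1e-5), unioned, and then pruned of genes also upregulated in
  primary tumors versus normal breast (FDR < 0.01) — those are tumor
  biology, not contamination. The final set is removed from the
  batch-corrected matrix. By construction |final| = |union| − |overlap|.
* **Scores.** A signature score is the unweighted mean of member-gene
  values (configurable to median; the upstream module definitions do
  not fix a combining rule). A metagene is the mean of member signature
  scores — used for the 16-signature immune metagene — or of member
  genes directly, as for the MHC class I metagene (HLA-A/B/C, B2M,
  TAP1/2, NLRC5).
* **Pair concordance.** On a gene subset, each member of a pair is
  correlated (Pearson) with every other sample; the pair is concordant
  when each member's best-correlated other sample is its partner.

# Receptor inference and intrinsic subtyping

Missing ER/HER2 clinical statuses are inferred from ESR1/ERBB2
expression with a ROC/Youden cutoff fitted on the labeled samples
(candidate cutoffs are midpoints between consecutive sorted unique
marker values; ties in Youden's J break toward the smaller cutoff for
determinism; higher marker means positive). Known labels are never
overwritten.

For classification the package uses the field's dedicated normalization
branch: within each preservation group, rows are median-centered and
columns standardized; then an ER/HER2 subgroup-specific centering is
applied. The subgroup centering values default to self-calibration
(each subgroup's own gene medians) but accept an external calibration
table. A caution established by our benchmarks: with self-calibration
on a small cohort where subtype and receptor status are strongly
confounded, the subgroup medians absorb centroid signal and the method
can underperform plain median centering; its documented advantage —
removing receptor-driven nuisance without distorting subtype signal —
holds when the centering constants come from a large reference cohort,
which is how the published method is applied. The test suite benchmarks
exactly that regime.

Calls are nearest-centroid by Spearman correlation (Pearson available)
against a 50-gene centroid table read from TSV; at least 40 centroid
genes must be present or classification aborts with a coverage report;
correlation ties break by the fixed subtype order LumA, LumB, HER2E,
Basal, Normal-like and are flagged. The shipped/generated centroids are
synthetic — any real centroid table in the same TSV layout drops in.

Subtype switching is tabulated per participant: a case switches if
*any* metastasis is called differently from the primary, with a second
count that ignores transitions into or out of Normal-like (a call that
usually reflects low tumor cellularity). The per-participant any-met
rule is a documented choice; a per-metastasis tabulation can be derived
from the returned transitions table.

# Methylation screens

Beta values are M/(M+U) with detection-p masking at 0.05. The screens
are built on probe universes defined by an 8-tissue normal panel:

* **Hypomethylation** runs on distal enhancer-like (dELS) CpGs more
  than 2 kb from a TSS whose mean beta exceeds 0.8 in *every* normal
  tissue. Methylation loss at such probes cannot be explained by
  stromal admixture from the metastatic site, which is the point of the
  design.
* **Hypermethylation** runs on CpGs with mean beta at or below 0.2 in
  every tissue.
* Probes differing between FF and FFPE samples (Welch q < 0.01 *and*
  |Δ mean beta| > 0.25, jointly) are removed first as preservation
  artifacts.

Each probe is fit with `beta ~ group + purity + (1 | participant)` by
REML; p-values use Satterthwaite degrees of freedom via lmerTest, with
Benjamini-Hochberg adjustment across the screened set and a sign gate
matching the screen direction. We model observed beta with purity as a
covariate rather than deconvolving beta by purity: dilution by
(1 − purity) stroma shrinks effects toward the stromal value, and the
covariate absorbs the purity-correlated component while leaving the
estimate's sign and the test calibrated (the suite checks type-I error
in [0.035, 0.065] at alpha 0.05 over 2,000 null probes). When the
random-intercept variance collapses, the fit degrades to an ordinary
linear model and is flagged; non-converging probes are reported with
missing statistics, never dropped.

Enrichment of DNA-binding factors at significant CpGs uses 200-bp
windows centered on each CpG — [pos − 100, pos + 100) in 0-based
half-open coordinates; any nonempty intersection with a binding
interval counts — against the full screened universe as background,
with two-sided Fisher tests and BH across factors. Putative enhancer
targets take up to 10 nearest genes within 1 Mb on each side of a CpG,
intersected with a predicted-target whitelist; term over-representation
is a one-sided Fisher test. Gene-level promoter methylation calls
aggregate a gene's promoter CpGs (mean by default, max available) and
call methylated at aggregate ≥ 0.4 — the published analyses state the
0.4 threshold but not the aggregation rule, so it is explicit and
configurable here.

Heat-map sample ordering is a deterministic four-key sort: primary's
subtype call (fixed subtype order), decreasing primary median beta,
primary before its metastases, metastases by decreasing purity, with
participant/sample id as final tie-breaks.

# FFPE variant filters and mutation comparison

Three filters target formalin artifacts, applied only to variants from
FFPE samples (fresh-frozen variants pass through annotated
`not_applicable`):

1. **Corrected VAF**: the local mismatch rate — mismatched bases over
   total aligned bases in a ±10-bp pileup window, excluding the variant
   column itself so the variant allele is not counted against itself
   (configurable) — is subtracted from the VAF; below 4% fails (exactly
   4% passes; "below" is strict).
2. **Read start diversity**: more than 15 supporting reads require at
   least 4 unique soft-trimmed start positions; more than 5 require at
   least 2; 5 or fewer always pass (no stated requirement).
3. **Unique nearest read end**: per read, whichever soft-trimmed
   coordinate is closer to the variant is recorded (ties to the start);
   the same bucket thresholds apply to the unique recorded positions.

The mutation matrix keeps the nine protein-altering classifications,
requires a gene to be mutated in ≥ 10 samples, and is binary with full
provenance. Primary calls not present in a paired metastasis are
removed at variant granularity; metastases aggregate per participant by
any-met OR; per-gene 2×2 tables are tested with the two-sided
minimum-likelihood Fisher exact test and BH-adjusted. On the published
per-gene frequencies over 39 aggregated pairs this reproduces the
printed p-values (0.006 and 0.003 at three decimals); the percentages
are computed over the 39 aggregated pairs, the reading that reproduces
both printed values.

# Copy number

Segment scores are means of gene-level log2 copy ratios over predefined
segment gene lists (the shipped demo segments are synthetic; a real
segment table is an optional input). Binarization uses strict cutoffs
(gain > 0.2, loss < −0.2; exactly ±0.2 is neutral), and per-segment
gain/loss tables are Fisher-tested between groups with BH within each
direction.

Focal deletions are called from 50-fold binned tracks (consecutive runs
of 50 records averaged, final partial bin kept and flagged): a call at
a gene requires some bin within 40 kb of the gene span with tumor log2
< −0.75 and normal-minus-tumor difference > 0.25 (the somatic gate that
excludes germline dips). "~40 kb upstream" is generalized to either
flank, configurable, because the caller serves any locus. A
purity-adjusted single-gene variant divides the observed log2 by purity
and calls below −0.4; the published description ("adjusted by tumor
purity (>−0.4)") does not state the formula, so the division rule — the
small-deviation linearization of the dilution model — is adopted,
flagged and configurable.

# The synthetic cohort generator

`syntheticConfig()` defaults describe the emulated study: 55
participants, each with one primary and at least one metastasis (about
a third with more than one), sites weighted liver 28 : lung 13 : lymph
node 12 : brain 11 : other 16, a basal-enriched subtype mix (40% basal,
35% luminal, 10% HER2E, 15% normal-like), mostly-FFPE primaries with
fresh-frozen metastases, and purity uniform on [0.3, 0.95] (tumors
below 30% nuclei fail pathology review). One global seed spawns a
fixed-offset substream per data type, so adding one data type never
perturbs another's draws, and a fixed seed reproduces the cohort
bit-for-bit.

Expression counts are negative binomial (size 20) around exponentiated
log2 means composed of: gene baseline; subtype centroid over the 50
classifier genes; a scalar participant effect plus a gene-specific
participant profile (sd 0.5) shared between a primary and its
metastases — without this individual profile, pair concordance would
have no signal to find; FFPE offsets (sd 0.5); site-matched
contamination elevation (default 4-fold); an immune-activity component
over the immune-signature and MHC genes; and an ER-driven shift over
the classifier genes (sd 0.5) with receptor status probabilistically
linked to subtype. Normal-tissue reference matrices share the same
baselines with their own contamination genes elevated.

Methylation: constitutive probe classes are genuinely constitutive —
identical normal-panel means in every tissue, which is what the
> 0.8 / ≤ 0.2 screens select for — with tissue variation confined to a
tissue-variable class; observed beta is the purity mixture
`purity · tumor + (1 − purity) · stroma` (stroma from the sample's host
tissue) plus measurement noise (sd 0.02) and sparse detection masking.
Hypomethylation (Δbeta 0.3 by default) is planted in metastasis tumor
cells at 50 constitutively methylated dELS probes, hypermethylation at
30 unmethylated probes, FFPE bias (+0.4) at 5% of probes, and HLA-A
promoter methylation in a subset of participants' metastases.

Variants: artifacts (30% by default, assigned to FFPE samples) draw one
of three failure modes — stacked read starts, stacked variant-proximal
read ends, or a noisy mismatch window that drags the corrected VAF
below 4% — while real variants have dispersed coordinates and clean
windows. Copy ratios: 1-kb bins with Gaussian noise (sd 0.05); focal
deletions (depth −1.2) are planted crossing the HLA-A-like gene span so
that, after 50-fold smoothing, a fully deleted bin is guaranteed within
the 40-kb proximity window — a 150-kb event placed entirely upstream
cannot satisfy the caller's geometry once averaged into 50-kb bins,
which is a property of the smoothing, not of the caller. Upstream
proximity gating is exercised separately with directly constructed
tracks. Whole-segment gains (+0.5) and losses (−0.5) are planted in the
gene-level matrix.

What the generator does *not* emulate: read-level sequence context,
probe chemistry, copy-number/LOH allele structure, clonal substructure,
and realistic correlation between data types beyond shared purity and
labels. Passing recovery tests therefore demonstrates that the
*operations* implement their contracts under the stated noise models,
not that real-data effect sizes would be recovered at these rates.

# Numerical choices and degenerate inputs

* Fisher tests use the minimum-likelihood two-sided convention (the
  R convention); zero-margin tables return p = 1 with a flag.
* BH adjustment excludes missing p-values from the family size so NA
  never corrupts neighbors.
* Youden ties break toward the smaller cutoff; correlation ties in
  classification break by the fixed subtype order; variance ties in
  top-variable probe selection break lexicographically by probe id —
  every ordering in the package is deterministic.
* Constant responses, single-class labels, zero-variance groups,
  all-masked probes and zero-margin tables all return flagged
  degenerate results rather than errors wherever the contract calls
  for it.

# Problem sizes used in the test suite

The suite runs desk-scale cohorts chosen to keep each property
informative: 8-participant cohorts for structural checks; 30 pairs,
1,000 probes and 50 planted CpGs for the hypomethylation recovery and
false-discovery check; 2,000 replicates for mixed-model type-I
calibration; 40 participants for subtype recovery; 1,200 variants
(~500 artifacts) for filter recovery; 20 noise-only track replicates
for the focal-deletion false-call rate; exhaustive enumeration of all
2×2 tables with total ≤ 40 against a binomial-coefficient oracle; and
a structured enumeration (read counts 1-8 crossed with unique-position
counts, read lengths and boundary VAF/mismatch grids over a 30-bp span,
plus 500 randomized configurations) against an independently coded
brute-force filter — the full multiset space of read configurations is
combinatorially infeasible, and the structured family covers every
decision boundary of the three filters.

# Known limitations

* The shipped centroids, segment definitions and signature libraries
  are synthetic stand-ins with the same file layouts as the real
  resources; conclusions about real tumors require the real tables.
* Purity enters the methylation screens as a covariate, not a
  deconvolution; strongly purity-confounded designs will lose power
  (larger standard errors) though estimates stay unbiased, as the
  simulation checks assert.
* The mixed model fits one probe/signature at a time; there is no
  information sharing across features (no empirical-Bayes shrinkage).
* `pairRestrictPrimaryCalls` matches variants by exact
  chrom/pos/ref/alt; indel representation differences between callers
  would need upstream normalization.
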