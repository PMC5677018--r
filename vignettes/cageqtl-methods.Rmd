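---
title: "Methods: promoter-usage and enhancer-activity QTL mapping from CAGE data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter-usage and enhancer-activity QTL mapping from CAGE data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and numerical choices behind
`cageqtl`, in the spirit of the long-form methods documentation that
accompanies normalization and QTL packages. Nothing here is a result; every
empirical claim about the package's behaviour is computed by the test suite
or by `scripts/acceptance.R`.

## The measurement model

CAGE tags mark transcription start sites at single-base resolution. Three
phenotype families are derived from the same per-sample CTSS streams
(chrom, position, strand, tag count):

* **Promoter expression** — tag counts aggregated per CAGE peak on the
  gene's strand, normalized within samples to tags-per-million (TPM) and
  between samples by relative log expression (RLE). Peaks with mean
  expression below 0.5 RLE-TPM across the cohort are removed; the boundary
  value is kept.
* **Enhancer activity** — for an enhancer with midpoint $m$, the flanking
  windows $R = [m-200, m)$ on the minus strand and $F = [m, m+200)$ on the
  plus strand are quantified per sample, taken through the same TPM → RLE
  chain ("twice normalized"), and summed: activity$_s = F_s + R_s$.
* **Gene-level expression** — the sum of a gene's promoter tag counts,
  normalized the same way; this stands in for an RNA-seq quantification in
  the replication (π1) analysis.

### RLE normalization

The size factor of sample $j$ is the median over features (restricted to
features nonzero in every sample) of value / geometric-mean-across-samples,
rescaled so factors have geometric mean 1. Zero handling follows the
standard median-of-ratios estimator. Two exact invariants are asserted in
the tests: renormalizing an RLE-normalized matrix returns factors of 1 (to
1e-8), and scaling one sample's raw column by $c$ rescales the whole
normalized matrix by the single global factor $c^{1/S}$ ($S$ samples),
leaving every relative expression profile unchanged — with a
self-inclusive geometric-mean reference, strictly columnwise invariance is
not attainable, and the global-factor form is the invariance that holds
exactly.

## cis-QTL mapping

Phenotypes are transformed per feature by a rank-based inverse-normal
transform by default (`transform = "rank"`); `"log"` and `"none"` are
available — the transform question is genuinely open for CAGE counts, and
the rank transform guards the linear model against the long right tail of
tag counts, at the cost of reporting slopes on the normal-score scale.
Slope-recovery checks therefore use `"log"`, where the regression slope
estimates the generative per-allele log effect directly.

Covariates (3 genotype PCs; 20 expression PCs for promoters, 12 for
enhancers) are regressed out of the phenotype once, and permutations
shuffle the residuals rather than refitting covariates per permutation —
the standard fast scheme for permutation-based cis scans. The nominal
p-value of each variant uses the t statistic of the correlation with
df = n − 2 − (number of covariates), correcting the degrees of freedom for
the prior residualization.

The *cis* window of a phenotype is its TAD: the stranded 5′ end of a CAGE
peak (the midpoint for an enhancer) is looked up in the TAD intervals, and
all TAD variants are candidates. A phenotype falling outside every TAD
falls back to a ±1 Mb window and is counted in a log. Lead-variant ties on
p are broken by genomic position for reproducibility.

The best in-window association is adjusted for multiplicity with 1000
permutations. Two modes are provided, because published descriptions of
the 1000-permutation scheme do not always say which is used: `empirical`
((1 + #{perm best p ≤ observed})/(1 + N)) and `beta` (maximum-likelihood
fit of a two-parameter Beta distribution to the permutation minima,
adjusted p = its CDF at the observed minimum; the default, falling back to
empirical below 100 permutations). The tests assert the two agree within
±0.02 in the p ∈ [0.01, 0.5] range at 1000 permutations, and that the
empirical form reproduces exhaustive enumeration exactly at n = 7.

Genome-wide FDR control uses the Storey estimator:
$\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))$ on
λ ∈ {0.05, …, 0.95}, smoothed with a cubic spline (df = 3) and evaluated
at λ = 0.95, clipped to (0, 1]; q-values are the usual step-up minimum.
Significance is q < 0.05 throughout.

Permutation seeds are derived per phenotype from the global seed
(`derive_seed`), so results do not depend on evaluation order.

## Promoter-usage classification

All peaks of a puQTL-associated gene are re-tested against the gene's lead
variant (the variant of its most significant peak-level association — the
variant-sharing rule is implied rather than stated in the source
methodology, and sharing one variant per gene is the only reading that
makes the per-gene effect pattern well defined). Peaks under 200 nt apart
collapse into promoter units by single linkage — with more than two peaks,
pairwise chaining (0, 150, 300 → one unit) was chosen over span-based
collapsing; each unit inherits its most significant peak's β and p. The
group rules, with per-unit significance p < 0.05 and effect-size ratio
ER = |max β|/|min β| over significant units:

| situation | group |
|---|---|
| one promoter unit | 1 |
| exactly one significant unit | 2 |
| ≥ 2 significant units, mixed signs | 3 |
| ≥ 2 significant, same sign, ER ≤ 2 | 4 |
| ≥ 2 significant, same sign, ER > 2 | 5 |

ER = 2 exactly is group 4 ("> 2" is strict). A gene whose units all fail
p < 0.05 despite genome-wide significance is internally inconsistent; it
is flagged and assigned group 2 on its best unit rather than dropped.

## Enhancer detection and directionality

Tag clusters are computed on CTSS pooled across all samples — the
bidirectional-transcription pattern is a property of the locus, not of one
library — while activity is quantified per sample. Clustering finds all
segments maximal under the score (tags) − d·(spanned bases) for some
density d: a segment's `max_density` is the smallest prefix/suffix density
(where it splits), its `min_density` the densest flanking run (where it
merges into a larger segment), and it is a cluster iff the first exceeds
the second. Discovery is recursive (split at the minimal-density
prefix/suffix); each candidate's merge density is then computed exactly,
which makes the output identical to a closed-form enumeration of all
maximal segments — the test suite checks this identity against an
independent O(n²) oracle. Filters: ≥ 5 tags, max/min density ≥ 2
(single-position clusters have infinite max density and pass — the
density-fold constraint targets diffuse clusters), length ≤ 200 nt.

An enhancer is bidirectional if ≥ 1 plus-strand and ≥ 1 minus-strand
cluster overlap [mid − 400, mid + 400). The directionality score
D = (F − R)/(F + R) is cohort-level, computed from across-sample sums of
normalized window expression; |D| < 0.8 (strict) keeps non-promoter-like
regions, and enhancers with zero activity in more than a configurable
fraction of samples (default 50/154, mirroring an absolute cutoff of 50 in
a 154-sample cohort) are dropped. Window conventions (R left-closed
minus-strand, F right plus-strand) follow the divergent-eRNA convention;
F + R = 0 leaves D undefined and the enhancer is dropped with a log entry.

## Integration statistics

**π1.** π1 = 1 − π̂0 over the replication p-values of significant QTLs in
the gene-level data, with a bootstrap standard error (100 resamples) since
a point estimate alone hides its instability at small m.

**RTC.** For a QTL/GWAS variant pair in an interval of N variants, the
phenotype is residualized on each interval variant in turn and the QTL
variant's association with each residual is recorded. The rank counts the
pseudo-corrections that destroy the QTL association more than the GWAS
correction does; RTC = (N − rank)/N, so 1 means removing the GWAS variant
is the most destructive correction (same underlying signal) and values
near 0.5 arise for independent signals. RTC > 0.9 flags high confidence.
The interval defaults to the TAD set (recombination-interval files can be
supplied instead; TADs are the natural interval already used as cis
windows here).

**Matched GWAS enrichment.** A QTL variant overlaps if it matches a
catalog variant or lies within ±500 kb of one with r² > 0.5. The null
redraws each QTL variant from non-QTL variants matched on MAF decile and
log-spaced TSS-distance bin (10 bins each; widened to the MAF bin, then to
all non-QTL variants, when empty), 1000 times. The odds ratio compares
observed odds with the mean permuted odds; the CI uses the 2.5/97.5
permutation percentiles (percentile CI chosen; no analytic form is
implied by the method), and the empirical p respects the 1/(N+1) floor.

**CIT.** For a triplet (variant L, mediator M, outcome T), four component
tests: (1) T ~ L; (2) M ~ L | T; (3) T ~ M | L; (4) an equivalence test of
L ⊥ T | M. The omnibus p is the maximum; both causal directions are tested
by swapping M and T, which makes the directional results exactly symmetric
under relabeling. Genotype enters all four regressions saturated (one
indicator per genotype class): with count-derived phenotypes the allelic
effect need not be linear in dosage, and a linear-only adjustment lets the
shared nonlinearity masquerade as conditional dependence between the two
children of the same variant (this measurably inflated the
independent-topology false-positive rate before the change). Component 4
permutes the *mediator* within strata of its fitted values on L (for a
dosage, the genotype classes; quartiles otherwise): the permuted mediator
keeps its dependence on L but severs its link to T, so the F statistic of
the L block in T ~ M\* + L follows the no-mediation alternative, and
p4 = (1 + #{F\* ≤ F_obs})/(B + 1) is small precisely when the observed
conditional association is far below that alternative — evidence of
complete mediation. B = 500 by default. Permuting L within those strata
instead would be a no-op for a three-level dosage, which is why the
mediator is the permuted variable. Triplet-level calls apply Storey FDR at
5% per direction.

**TSS annotation.** Four-step hierarchy: (1) peaks within 500 nt upstream
of an annotated TSS on the same strand, or inside a 5′-UTR first exon or
first intron → "Annotated gene"; (2) otherwise by chromatin state:
enhancer → "eRNA/enhancer", promoter state → step 3, else "other";
(3) promoter-state peaks overlapping a gene body on the opposite strand →
"Antisense promoter", the rest "Putative promoter" with an
intragenic/intergenic context. "Antisense" is operationalized as
opposite-strand gene-body overlap; the source description ("based on
genomic localization") leaves the boundary open.

## The synthetic cohort

The generator's defaults describe the emulated study: 154 unrelated
samples (tests use 150 where a condition states it), one chromosome tiled
by 1-Mb TADs, ~700–900 genes with 1–7 promoters (weights favouring 1–2,
giving ≈ 2 peaks/gene), 100 enhancer regions ≥ 1 kb from any promoter,
20,000 variants, and per-sample library sizes log-normal around
2 × 10⁵ tags (scaled down from sequencing-scale depth so a full run fits
in minutes; all rates and effect scales are depth-free).

* **Genotypes.** Haplotypes arise by block copy-with-mutation: each LD
  block (20 kb) has a template haplotype; a two-state Markov chain along
  the block (switch rate 0.1 per variant, stationary minor-branch
  frequency drawn from MAF ∈ [0.05, 0.5]) decides template vs complement,
  then alleles flip with probability 0.01. This yields immediate-neighbour
  r² ≈ 0.7 within blocks, independence across blocks, and exact MAF
  control. Variants with cohort alternative-allele count < 10 are removed,
  as in the genotype-filtering rule the pipeline also applies on read.
* **Counts.** Negative binomial with log link: expected log count =
  baseline + slope × dosage (+ mediation term) + log depth. Dispersion
  0.1 (CV ≈ 0.33 at high counts) matches typical CAGE biological
  replication; the generative model itself is a package choice — the
  source methodology states none.
* **Planted effects.** ~30% of genes and ~40% of enhancers receive a cis
  variant from their own TAD with per-allele log slopes 0.5–1.5, signed;
  multi-promoter genes are planted with the full pattern range
  (single-peak, opposite-sign, same-sign similar, same-sign different) so
  every classification group has ground truth. Mediated topologies drive
  the paired promoter through the *measured* enhancer activity (log
  normalized counts), with extra log-normal noise (sd 1.0) on the
  promoter: making the outcome depend on the measured mediator keeps
  conditional independence exactly true in the causal direction, which is
  what the CIT's operating characteristics are defined against.
* **Enhancer transcription.** Active enhancers (70%) emit balanced NB
  counts on both flanks (two CTSS positions per side); 15% of regions are
  instead unidirectional (promoter-like) and must be rejected by the |D|
  filter. Inactive regions emit trace background and are caught by the
  null-expression filter.

What the generator does **not** emulate: mappability and sequence
composition biases, sample contamination and relatedness, population
stratification beyond what PCs remove, trans effects, overlapping genes,
multi-chromosome genomes, and realistic LD decay beyond the two-level
block structure. Passing tests therefore demonstrate correctness of the
statistical machinery under a controlled generative model, not robustness
to every artefact of real CAGE libraries.

## Numerical choices and problem sizes

Ties in lead-variant selection break by position; Beta fitting uses
Nelder-Mead on log-shape parameters from a method-of-moments start;
missing dosages are mean-imputed per variant (flag kept); monomorphic
variants are skipped and logged; degenerate RLE (no all-nonzero feature)
is an error for promoters and a factors-of-1 fallback with a message for
enhancer windows, whose count matrix is legitimately sparse.

The test suite exercises the study conditions at desk scale: the
end-to-end run uses 150 samples × ~2000 peaks × 100 enhancers × 20,000
variants with 1000 permutations (≈ 2–3 min); FDR/power characteristics use
200 phenotypes × 10 replicates; CIT operating characteristics use 100
replicates of 150-sample triplets; Paraclu is verified against its
brute-force oracle on inputs of ≤ 30 positions, where enumeration is
exact. These sizes are the package's chosen verification scales: large
enough for the asserted properties to be stable, small enough to run
routinely.

## Known limitations

* The pipeline orchestrator runs the synthetic study; real data flows
  through the same stage functions via the format readers, but no
  end-to-end real-data driver (sample-identity checks, chunked IO for
  9M-variant genotype panels) is provided.
* Only additive single-variant models: no conditional passes, no
  interaction or trans QTLs.
* The Beta approximation assumes the permutation minima are
  Beta-distributed, an approximation that degrades in tiny windows; the
  empirical mode is the fallback of record.
* RTC is computed against a user-supplied interval set (TADs by default);
  recombination-hotspot intervals would be the closer match to the
  original construction.
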