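---
title: "Methods: quantifying glucose-induced transcriptional and chromatin memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying glucose-induced transcriptional and chromatin memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucomem)
```

## The scientific question

Endothelial cells transiently exposed to high glucose (HG) retain molecular
alterations after glucose normalization — the *metabolic (glycemic) memory*
implicated in the long-term vascular complications of diabetes. `glucomem`
implements the integrative analysis used to quantify this memory in bulk
RNA-seq and ATAC-seq data from HUVEC-style experiments:

1. differential expression of each treatment arm (HG; memory, i.e. HG
   followed by normal glucose; each arm with or without sulforaphane (SF)
   or NRF2 overexpression (OE)) against a normoglycemic control;
2. differential chromatin accessibility between the same arms;
3. annotation of accessible regions by genomic feature, and promotion of
   differentially accessible regions (DARs) co-marked by H3K4me1 and
   H3K27ac to *differentially accessible putative enhancers* (DAEs);
4. assignment of candidate target genes to each DAE within its
   topologically associating domain (TAD), with direction concordance;
5. set algebra over the resulting feature sets: shared/unique calls across
   arms and *restoration* (loss of a differential call) under SF or
   NRF2-OE;
6. bZIP-core motif enrichment in promoters of down-regulated genes and in
   DAE windows, and gene-set over-representation.

Because the raw sequencing stages (alignment, peak calling) are outside
the package's scope, every stage is exercised instead on a synthetic study
with planted ground truth; the generator is first-class, tested code.

## Differential expression

Counts $K_{gj}$ for gene $g$ in sample $j$ are normalized with
median-of-ratios size factors: over the features with positive counts in
every sample,

$$ s_j = \operatorname{median}_g \frac{K_{gj}}{(\prod_{j'} K_{gj'})^{1/m}}, $$

rescaled so that $\prod_j s_j^{1/m} = 1$. If no feature is positive
everywhere the function stops rather than silently switching to a
pseudo-reference — an all-dropout matrix deserves the analyst's attention.

The contrast between a reference arm $A$ and a treatment arm $B$ uses a
moment/Wald negative-binomial test. With normalized counts $y = K/s$,
group means $\hat\mu_A, \hat\mu_B$, and a single pooled moment dispersion

$$ \hat\alpha = \operatorname{median}_g \max\!\left(0,
   \frac{\hat v_g - \bar y_g}{\bar y_g^2}\right), $$

where $\hat v_g$ and $\bar y_g$ are the within-group pooled variance and
mean, the effect and its Wald statistic are

$$ \widehat{\mathrm{LFC}}_g = \log_2 \frac{\hat\mu_B + c}{\hat\mu_A + c},
   \qquad
   \mathrm{SE}^2 = \frac{1}{(\ln 2)^2}\left[
   \frac{1/\hat\mu_A + \hat\alpha}{n_A} +
   \frac{1/\hat\mu_B + \hat\alpha}{n_B}\right], $$

with pseudo-count $c = 0.5$ (bounded fold changes for zero groups) and a
two-sided normal p-value. Benjamini–Hochberg adjustment runs over tested
features; all-zero features are excluded from the adjustment (an
independent-filtering analogue) and reported with $p = 1$,
$\mathrm{LFC} = 0$, `padj = NA`. A gene is called differential when
`padj < 0.05` **and** `|log2FC| > 0.5` (strict inequalities).

This is deliberately a transparent moment estimator, not a shrinkage fit:
its acceptance surface is parameter recovery on synthetic truth. With 10
replicates per arm the null type-I rate sits at the nominal 0.05 within
three binomial standard errors; at 3 replicates the estimator is mildly
anti-conservative (the pooled moment dispersion is median-biased low), but
the two-threshold call rule keeps the realized false discovery rate near
the nominal level in the recovery tests (200 planted $|\mathrm{LFC}| = 2$
genes among 2,000, $n = 3$, $\alpha = 0.05$: sensitivity $\ge 0.8$, FDR
$\le 0.10$).

## Differential accessibility

Replicate peak sets are first reduced to a *consensus*: a peak from the
first replicate is retained iff it overlaps ($\ge 1$ bp) a peak in every
other replicate, and is reported as the merged span of all peaks involved;
overlapping spans are merged so the consensus is non-overlapping.

The differential test pools replicates within each condition and scales
pooled counts to tags-per-10-million using the condition's pooled library
total (so multiplying one condition's counts by any constant changes
nothing — normalization absorbs it exactly). For each region the reference
rate is floored, $\lambda = \max(x_{\mathrm{ref}}, 1)$, and the upper tail
$P(X \ge \lceil x_{\mathrm{trt}} \rceil \mid \lambda)$ is evaluated by
exact Poisson tail summation; the opposite direction swaps the roles. The
fold change uses the floored normalized counts on both sides,
$\max(x_{\mathrm{trt}},1)/\max(x_{\mathrm{ref}},1)$, so that swapping
conditions inverts the fold exactly. A region is a DAR when the fold gate
(`fold > 1.5` or `< 1/1.5`) **and** the tail gate (`p < 1e-4`) both hold;
the numerical choices are:

* floor at 1 normalized tag — avoids a zero-rate degenerate tail and
  unbounded folds;
* observed counts ceiled to integers — Poisson support is integral;
* no pseudo-count beyond the floor.

Replicate pooling (rather than a replicate-aware variant) is the
documented convention of the tags-per-ten-million normalization used by
standard peak-differential tools.

## Annotation, enhancers, TAD linkage

Regions are classified by the position of their midpoint with precedence
**promoter > exon > intron > intergenic**, the standard peak-annotation
ordering; the promoter window is strand-aware TSS−1000..TSS+100. Midpoint
classification guarantees exactly one class per region, matching
pie-chart semantics.

A DAR becomes a DAE when it overlaps ($\ge 1$ bp) at least one H3K4me1
peak **and** at least one H3K27ac peak. "Enriched with both marks" is
interpreted as peak co-overlap, not a signal-intensity threshold; the DAE
inherits its accessibility direction, and the DAE set is by construction a
subset of the DAR set.

Each DAE's candidate *regulatory domain* is the TAD containing its
midpoint (half-open containment; a DAE spanning a boundary is assigned by
the midpoint rule). Candidate targets are the genes of a configurable DEG
filter — by default the genes differential in *both* the HG and memory
arms (the intersection; the union is available) — whose TSS lies in the
same TAD. A link is *concordant* when the accessibility direction matches
the expression direction. In the per-enhancer summary a DAE with at least
one target counts once and is concordant if *any* of its links is; the
percentage is rounded half away from zero to an integer, the same rounding
used for every reported percentage.

## Restoration and the memory report

*Restoration* under an intervention (SF or NRF2-OE) means loss of the
differential call versus the same control: the not-restored set is the
intersection of the baseline and intervention call sets, the restored set
is the difference. The default rule does not examine the direction of the
remaining call — it mirrors the "remained differentially expressed"
phrasing of the underlying question — and a stricter direction-aware
variant (`restoration_directional()`) is available. Shared DEGs are
reported both as the plain intersection and as the direction-matched
intersection.

`build_report()` collects every count and integer percentage into one
structure whose serialization is canonical (fixed field order, full
precision): byte-identical reports certify identical analyses, and
`validate_memory_report()` recomputes every percentage from the stored
numerator/denominator and checks the conservation identities
(restored + not-restored = baseline, shared $\le$ either side, concordant
$\le$ linked).

## Motif enrichment

Motifs are position frequency matrices (JASPAR-style text); counts become
probabilities with a pseudocount of 0.25 per cell and log2-odds against
the background base frequencies. Scanning is ZOOPS (zero-or-one occurrence
per sequence): a sequence is a hit when any window on either strand scores
at least `threshold_frac` (default 0.8) of the motif's maximum achievable
score. Promoter windows are strand-aware TSS−1000..TSS+100
(reverse-complemented for minus-strand genes); DAE windows are ±50 bp
around the peak midpoint.

Enrichment compares target and background hit counts with a
hypergeometric upper tail, BH-adjusted across motifs. When no background
is supplied, a seeded dinucleotide-preserving shuffle of the targets
(3 copies each, Altschul–Erickson Eulerian-walk construction) serves as
background — a GC/dinucleotide-composition control that needs no external
data. This shuffle default is a documented choice; a scan against
user-supplied background sequences is equally supported.

## The synthetic study generator

The generator emulates the design the pipeline is meant for:

* 7 expression arms — control, HG, memory, memory+SF, HG+SF, OE-HG,
  OE-memory — with 3 replicates each (21 samples), and 4 accessibility
  arms — control, HG, memory, memory+SF — with 2 replicates each;
* a miniature genome (default 2 × 1.5 Mb) whose TADs tile each chromosome
  back-to-back, so every TSS and candidate enhancer lies in exactly one
  TAD; genes are laid out in slots with strand-aware promoters, and
  candidate enhancer regions are placed only in non-promoter
  (intronic/intergenic) space and never across a TAD boundary;
* NB counts with $\mathrm{Var} = \mu + \alpha\mu^2$ and per-sample factors
  $s_r \sim U(0.8, 1.2)$; planted class labels from a closed vocabulary
  (shared / HG-unique / memory-unique, up/down, optional `sf_restored` /
  `oe_restored` tags) deterministically define each feature's planted
  log2FC per condition;
* sequences with the bZIP core TGA(C/G)TCA embedded at rate
  `p_target = 0.8` into promoters of planted down-DEGs (on the gene's
  strand) and into the central ±43 bp of enhancer-class regions (so the
  occurrence falls inside the ±50 bp scan window), next to decoy motifs in
  the PFM library;
* gene sets seeded from the planted classes so over-representation is
  recoverable, plus purely random sets.

Defaults were fixed once, on design grounds: RNA dispersion
$\alpha = 0.05$ and baseline means $U(50, 500)$ (typical bulk RNA-seq
moderate-expression behaviour); planted expression effects
$|\mathrm{LFC}| = 2$ (clearly separated from the 0.5 call threshold at
$n = 3$); ATAC dispersion $\alpha = 0.005$ with means $U(200, 600)$ —
pooled consensus-peak tag counts across high-quality replicates are
modelled as near-Poisson, which is also what a Poisson differential test
presumes; planted accessibility effects fold 2; planted differential
fractions near 10 % of regions and 25 % of genes, keeping the
composition bias of total-count normalization second-order. The
default-seed study completes the whole pipeline in a few seconds.

With a fixed seed the generator is byte-identical across runs; each stage
draws from its own derived seed so stages can be regenerated
independently.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: read-level artifacts (GC bias, duplicate
and mitochondrial reads, fragment-length structure), gene length and
isoform structure, correlated biological replicate variation, realistic
TAD size distributions and nested sub-domains, signal-intensity gradation
of histone marks, and linkage disequilibrium between neighbouring
regulatory elements. Recovery rates on this generator measure the
implementation's correctness and calibration, not expected performance on
any particular real data set.

## Problem sizes used by the tests

The recovery suites run at sizes chosen to give stable statistics in
seconds: 2,000 genes with 200 planted effects for expression recovery and
null calibration (10 replicates per arm for the calibration check, where
the Wald normal approximation is accurate); 1,000 regions with 100 planted
fold-2 effects for accessibility recovery; 1,000-instance random panels
for the brute-force oracle comparisons of the interval, annotation and TAD
engines; and the full default study for end-to-end determinism.

## Known limitations

* The DE test is a moment/Wald stand-in: no dispersion shrinkage, no
  LFC moderation; at 2–3 replicates its raw p-values are mildly
  anti-conservative.
* The Poisson accessibility test treats pooled counts as a single
  observation per condition; replicate-level biological variability beyond
  the planted dispersion is not modelled in the test itself (only the
  fold gate protects against it).
* Midpoint rules (annotation, TAD assignment) are decisive but coarse for
  regions comparable in size to the features they are assigned to.
* The enhancer definition is binary peak co-overlap; signal-strength
  evidence is not weighed.
* ZOOPS scanning reports presence, not occurrence counts or positional
  preference.
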