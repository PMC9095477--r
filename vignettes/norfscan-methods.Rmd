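---
title: "norfscan: methods and design notes"
author: "norfscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{norfscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What the package does

`norfscan` implements a complete analysis for studying **novel open reading
frames (nORFs)** — transcribed and translatable genomic regions outside
conventionally annotated protein-coding ORFs — in case–control brain
transcriptomes, and for relating them to two classes of regulatory genomic
features: **human accelerated regions (HARs)**, grouped by the clade in which
the element is otherwise conserved (vHAR: vertebrates, mHAR: mammals, pHAR:
non-human primates), and **transposable elements (TEs)**. The final stage
asks whether nORFs that lie near HARs are over-represented inside
disorder-associated GWAS loci, using a permutation test.

The pipeline has five analysis stages, each usable on its own:

1. **nORF curation** — Ribo-seq abundance tables are converted to TPM, and a
   quantile-binned noise filter retains nORFs whose expression variability is
   below that of canonical ORFs (cORFs) of matched mean. nORFs are then
   classified by reading frame relative to annotated CDS, in-frame entries are
   removed (with exceptions, below), and duplicate exon chains are collapsed.
2. **Transcript matching** — transcripts expressed above TPM > 0.1 in at
   least 10% of samples (pseudoautosomal entries removed) are matched to
   nORFs by intron-chain equality or exon-boundary containment; only
   non-protein-coding biotypes are retained.
3. **Differential expression** — TMM-normalized log2(CPM + 0.5) values are
   fitted per transcript with a linear mixed model (random intercept per
   individual), the diagnosis contrast is Wald-tested, and
   Benjamini–Hochberg FDR < 0.05 defines DE transcripts; DE nORFs inherit
   from their matched transcripts. A Fisher test checks whether DE
   transcripts are enriched for nORF-containing ones, and a chrY/XIST check
   validates the sex metadata.
4. **HAR/TE association** — multi-source HAR lists are merged into unique
   HARs with provenance; nORFs are associated with HARs within ±100 kb (1 kb
   sensitivity window available) and with TEs in the 2 kb strand-aware
   upstream window (TEs overlapping the nORF itself are excluded); features
   overlapping DE-transcript spans are designated DE; DE nORF–DE TE pairs
   are screened for correlated expression with a dual Pearson + Spearman
   gate (|r| > 0.5 and p < 0.05 on both).
5. **Loci enrichment** — GWAS summary statistics are QC-filtered (HWE
   p < 1e-4 or MAF < 0.05 removed), stratified by association p (1e-2 …
   1e-7), greedily LD-clumped (index p < 1e-4, r² ≥ 0.1 joins, 3 Mb window),
   MHC-collapsed to the most median index, and turned into loci (SNPs with
   r² > 0.5 within 250 kb of an index). nORF target families (all nORF-HARs
   and the vHAR/mHAR/pHAR subsets) are tested for locus overlap with a
   two-round permutation procedure (5000 + 5000 by default).

A sixth module simulates **every input with planted ground truth**, so the
whole pipeline is testable without any external data.

# Models and key procedures

## The low-noise filter

All ORFs — canonical and non-canonical together — are ranked by mean TPM and
cut into `Q` bins of near-equal occupancy (`Q = 4000` at production scale;
ties in mean are broken by ORF id so the result is order-invariant). Within
each bin the baseline is the **median sample SD of the canonical ORFs**; a
non-canonical ORF is low-noise iff its SD is *strictly* below the baseline.
Bins without canonical members flag nothing and are reported. Two readings
of the published procedure were possible — bin all ORFs jointly, or bin
cORFs only and map nORFs in; we bin **jointly**, which guarantees that each
nORF is compared with cORFs of similar mean whenever the bin contains any.
SD is the sample (n−1) standard deviation. At desk scale the default `Q` is
capped at the ORF count with a warning; the pipeline additionally keeps
roughly 20 ORFs per bin so the canonical baseline never empties.

## Frame classification and the exception rule

An nORF's codon positions are projected through **spliced (exonic-base)
coordinates** onto every overlapping same-strand CDS — genomic distance
would misclassify any pair straddling an intron. The offset between nORF and
CDS spliced indices is constant within each shared exonic segment, so one
anchor base per segment decides the frame; the nORF is in-frame only if all
shared segments agree at offset ≡ 0 (mod 3). In-frame nORFs are removed
unless their upstream category is `readthrough`, `extended`, `uORF` or
`truncated` — those labels describe legitimate in-frame variants of the
canonical ORF rather than redundant re-detections of it.

## The mixed model

Per transcript we fit `y = Xβ + b[individual] + e`, `b ~ N(0, σ_b²)`, by
REML, profiling the variance ratio `λ = σ_b²/σ_e²` in a 1-D optimization —
the marginal covariance `I + λZZ'` is block diagonal, so each profile
evaluation is a set of rank-one updates to fixed crossproducts and costs
O(groups · p²). The diagnosis effect is Wald-tested against a *t*
distribution with `n − rank(X) − 1` residual degrees of freedom. This is an
approximation (no Satterthwaite correction); the published analysis used a
mixed-model package without stating its test, so calibration is established
by simulation instead (null type-I error within [0.03, 0.07] and a uniform
p-value distribution, checked in the test suite). With all-singleton groups
the estimator collapses exactly to OLS. Covariates enter as given columns;
covariate discovery (surrogate variables etc.) is out of scope.

TMM factors, log-CPM, BH adjustment, the two-tailed Fisher test (sum of
hypergeometric probabilities ≤ the observed table's) and the Pearson/
Spearman t-transform p-values are implemented in-package; edgeR,
`p.adjust`, `fisher.test`, `chisq.test` and lme4 serve as independent
cross-checks in the tests, never as the implementation. Exception:
GTF/BED parsing and interval algebra are delegated to rtracklayer,
GenomicRanges and IRanges, which are the field's reference implementations.

## Windows and boundaries

All in-memory intervals are `GRanges` (1-based, closed) — the Bioconductor
convention — with BED's 0-based half-open coordinates converted at I/O.
Overlap and distance semantics match the half-open formulation exactly:
abutting intervals do not overlap and are at distance 0. Merging is
bookended (distance-0 neighbours merge), strand-agnostic, and idempotent.
For the HAR window, a gap exactly equal to the window still associates
(boundary inclusive); `window = 0` degenerates to pure overlap. The TE
upstream window is **strand-aware** (2 kb before the span start on `+`,
after the span end on `−`); the source of this convention does not state
strand handling, so a strand-agnostic-left switch is provided
(`strandAware = FALSE`). DE designation of HARs/TEs uses the transcript's
genomic span (introns included), because retained-intron features are a
central finding; an exon-level mode is available via `exonLevel = TRUE`.

## Clumping, loci, MHC

Clumping is greedy in ascending p (ties: position, then rsid): each
unassigned SNP with p < 1e-4 seeds a clump and absorbs unassigned SNPs
within 3 Mb at r² ≥ 0.1; missing r² entries count as 0. Among index SNPs in
the MHC (hg19 chr6:28,477,797–33,448,354 by default) only the clump with
the **median** index position survives — "most median" is undefined for
even counts, so the lower median is taken. Loci span the index and all SNPs
with r² > 0.5 (strict) within 250 kb; a lone index yields a single-base
locus.

## Two-round permutation enrichment

Overlapping targets and overlapping reference nORFs are merged first;
sex-chromosome entries are excluded (the GWAS has no sex-chromosome SNPs).
The statistic is the number of loci overlapping ≥ 1 merged target. Round 1
draws `n_perm` uniform same-size subsets of the merged reference and
reports `p = (1 + #{T* ≥ T}) / (1 + n_perm)` (the +1 guard keeps p > 0).
Round 2 corrects across the tested family (strata × target subsets): each
round-1 null draw is assigned its own empirical p against its test's null
distribution, the minimum across the family forms the null of the family
minimum, and the corrected p is the (guarded) fraction of replicates whose
minimum is ≤ the observed empirical p. Re-using the round-1 statistics
rather than drawing a fresh second round costs O(n_perm) instead of
O(n_perm²) and makes `corrected ≥ empirical` a theorem rather than a
tendency; the referenced tool's exact scheme is not reproducible from its
description, so ours is validated by calibration (null uniformity) instead
of by equivalence. Null sampling is not length-matched by default; a
quintile length-matched mode exists behind `lengthMatched = TRUE` because
the reference tool corrects for gene length without stating its binning.

# The synthetic world

`simulateScenario()` drives all generators from one seed (per-stage seeds
are derived by a stable hash of the stage name, so adding a stage never
reshuffles another's randomness). The stated world:

* **Genome**: chrS1/chrS2 (5 Mb each) plus chrSY (0.4 Mb) carrying
  male-only genes; an XIST-like lincRNA on chrS1 anchors the sex QC.
* **Annotation**: 80 non-overlapping single-transcript genes, 1–4 exons,
  biotype mix 40% protein-coding, 20% retained intron, 15% processed
  transcript, 15% lincRNA, 10% antisense — the biotypes that dominate real
  nORF-containing transcripts.
* **nORFs**: 60 chains — 60% spliced sub-chains of non-coding transcripts
  (recoverable by matching), 25% inside CDS (alternating in/alt frame),
  15% intergenic.
* **Ribo-seq**: 200 cORFs and the nORFs share one 25-level mean grid;
  counts are mean × (1 + m·0.3·z) with SD multiplier m = 1 for cORFs and
  planted m = 0.5 (low-noise, 75%) or 2.0 (decoys) for nORFs.
* **Case–control counts**: negative binomial, dispersion 0.2, log-link;
  baselines 2^U(4,9); planted |log2 FC| in [0.8, 2] for 15% of autosomal
  transcripts per case group (labelled SCZ and BD); random intercept
  SD 0.3 on the log scale with a quarter of individuals contributing two
  samples; a small age covariate. These are defaults a bulk brain RNA-seq
  analyst would call ordinary; the dispersion and intercept SD follow the
  stated design.
* **Features**: planted HARs within ±100 kb of their nORF (group labels
  assignable per pair), planted TEs inside the 2 kb upstream window; decoys
  far outside every window, so association recall and specificity are
  scored exactly. Group frequencies default to the published unique-HAR
  composition (45.4 / 11.0 / 43.6% for vHAR/mHAR/pHAR).
* **GWAS**: 1500 SNPs in blocks of 8 (within-block r² ~ U(0.6, 0.95),
  between-block 0 — provided as a sparse table, since clumping consumes
  only r²); p uniform except in causal loci (10^−U(4.5, 8.5)); 5% of SNPs
  planted to fail MAF/HWE QC.
* **Planted co-location**: one pHAR family of nORFs sits inside ±10 kb
  causal regions; a same-size vHAR decoy family does not. Planted pairs are
  drawn among hosted, low-noise, non-edge nORFs — i.e. among nORFs that
  will be in the curated, transcribed set — because the co-location claim
  concerns the analyzed database, not entries the noise filter is designed
  to discard.

What the generator does **not** emulate: read-level sequencing noise,
alignment and assembly artefacts, batch structure and surrogate variables,
LD derived from real genotypes, overlapping gene models, and length-biased
sampling of detected ORFs. A green end-to-end test therefore establishes
that the statistical machinery recovers planted structure at realistic
sizes — not that the pipeline is robust to upstream artefacts it never
sees.

# Numerical choices and degenerate inputs

* TPM requires positive lengths and errors on all-zero columns.
* TMM uses the published trims (0.3 on M, 0.5%/95% on A at 0.05), the
  upper-quartile reference rule, precision weighting, and rescaling to
  geometric mean 1; an all-zero sample is an error.
* `bhAdjust` excludes NA p-values from the test count and propagates them.
* Fisher's odds ratio is the sample cross-product ratio, reported as
  Inf/0/NaN on zero cells; a zero margin is an error. Table enumeration
  uses a 1e-12 relative tolerance on "probability ≤ observed".
* Zero-variance transcripts are skipped (reported, not fitted); zero-
  variance correlation vectors yield NA and are never significant.
* Constant XIST makes the sex clustering degenerate: warning, no flags.
* Dedup ties are broken by the lexicographically smallest id; quantile-bin
  ties by ORF id; clump ties by position then rsid — every tie-break is
  deterministic, and the whole pipeline is a pure function of (inputs,
  config, seed). Output floats are serialized at 6 significant digits so
  manifest hashes are comparable across runs.

# Known limitations

* The Wald/residual-df test is anti-conservative for very few individuals;
  with the simulated sizes its type-I error is within [0.03, 0.07].
* TE expression is inherited from the containing DE transcript (the
  upstream quantification is out of scope), so TE-level correlations are
  transcript-level correlations in disguise; the tables say so.
* The enrichment's permutation scheme is this package's own (calibrated,
  documented above), not a re-implementation of the referenced tool.
* One assembly per run; no liftOver, no FASTA/BAM handling, no read-level
  simulation, no genotype-based r².
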