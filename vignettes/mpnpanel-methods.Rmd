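---
title: "Methods: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpnpanel)
```

This vignette is the package's own account of what it computes and why: the
triage model and its assumptions, the validation metric conventions, the
synthetic-data generator's statistical structure, and the places where the
design was genuinely open and a choice had to be made. It states no
empirical result that the test suite does not itself compute.

## The setting

A targeted amplicon panel sequences the hotspot exons of 22 myeloid genes to
a ~5000× depth target, aimed at myeloproliferative neoplasm (MPN) screening:
JAK2/CALR/MPL driver mutations plus prognostically relevant co-mutations
(ASXL1, TET2, SF3B1, SRSF2, U2AF1, ...). Two callers run per sample: a
small-variant caller (SNVs and small indels; blind to large duplications)
and a structural caller (frameshifts, large deletions, medium insertions,
tandem duplications; blind to SNVs). The package takes their VCFs, an
annotation table (region class, population MAFs, dbSNP/ClinVar/COSMIC), an
amplicon manifest and per-amplicon depth tables, and produces a reviewed
somatic variant list, assay-performance metrics and coverage QC.

## Coordinates and keys

All internal coordinates are 1-based inclusive (VCF-native); BED manifests
are converted on read and the conversion is its own inverse. A variant is
identified by `(chrom, pos, ref, alt)` after normalization. Chromosome names
are normalized to `chrN`.

### Trim-based normalization and its limits

The two callers pad indels differently. `normalize_keys()` trims shared
*leading* context first (advancing `pos`, always retaining at least one base
per allele — the indel anchor), then shared *trailing* context. This walks
representations rightward through repeat context, so paddings that extend
the minimal representation to the left all reach one fixed point; the
operation is idempotent and preserves inserted/deleted length.

A known limitation, inherent to reference-free trimming: a representation
padded with *trailing* context right-shifts further than the minimal
representation can (the minimal form carries no information about downstream
bases), so the two may normalize to adjacent anchors. Full unification would
require reference-genome left-alignment, deliberately kept out of the core
(no FASTA dependency); downstream truth matching absorbs the residue with an
insertion-anchor tolerance of ±5 bases at equal inserted length.
Duplications are represented as insertions at the duplication start (one
keyspace for matching).

## The triage cascade

Stages run in a fixed order; each call receives exactly one status.

| Stage | Rule | Default |
|---|---|---|
| Region | keep `region_class == "exonic"` (splicing/intronic/UTR excluded) | — |
| Population | exclude if *any present* MAF ≥ cutoff | 1% |
| Artifact | exclude if VAF < threshold, or key in a majority of samples without pathogenicity evidence | 5%; majority = strictly > 50% |
| Rescue | re-admit artifact exclusions with VAF in `[low, high)` and ClinVar P/LP or COSMIC-pathogenic | `[1%, 5%)` |

Decisions behind the knobs:

* **"Any database" MAF rule.** A variant at ≥ 1% in any of 1000 Genomes,
  ExAC, ESP6500, gnomAD is removed as a presumed germline polymorphism —
  conservative germline removal. Absent frequencies are `NA`, never 0:
  absence must neither trigger the exclusion nor count as evidence of
  rarity.
* **Strict "< 5%" exclusion.** A VAF of exactly 5% survives; the artifact
  clause is written as an exclusion test `vaf < 0.05`.
* **Recurrence exemption.** Without it, a true driver present in most of a
  small cohort (JAK2 V617F in 7/10 samples) would be discarded as a
  systematic artifact. Evidence = ClinVar pathogenic/likely-pathogenic, a
  COSMIC-pathogenic flag, or any COSMIC id. The *rescue* lane is stricter:
  a bare COSMIC id is not an assertion of pathogenicity, so rescue requires
  ClinVar P/LP or COSMIC-pathogenic.
* **Rescue floor at 1%.** The assay's somatic VAF detection limit; calls
  below it are not interpretable as real.
* **Novelty.** Putative novel ⇔ exact allele absent from dbSNP *and* no
  ClinVar assertion *and* no COSMIC id. Membership of an rsID cluster with
  a different allele does not defeat novelty (a 67-base insertion can share
  a cluster with a 1-base duplication and still be new).
* **Sanger flag, inclusive at 15%.** Sanger sequencing detects alleles down
  to roughly 15–20% VAF. The flag marks eligibility only; confirmation
  outcomes are data, not rules (a 10.6% frameshift can still confirm).
* **Unique-variant counting.** A unique variant is a normalized key; the
  same key in several samples counts once in summary totals.
* **Degenerate cohorts.** `run_triage()` on a cohort whose calls all fall at
  the region/MAF stages skips the artifact stage (there is no cohort left to
  measure recurrence on); the standalone `filter_artifacts()` operation
  still rejects an empty cohort as a usage error.

## Validation metrics

* **Cells.** Sensitivity is counted over (truth variant × replicate) pairs
  of the merged call set. An alternative per-app counting mode
  (opportunities per eligible caller: SNVs small-only, > 25-base events
  structural-only, other indels both) is available behind
  `counting = "per_app"`, since published headline sensitivities sometimes
  imply per-app denominators.
* **Negative sites.** Specificity needs a defined negative space on a
  targeted panel. Convention: for each replicate, every truth variant known
  across *all* standards that is absent from that replicate's own standard
  is one negative evaluable site. With the four standards shipped here the
  cross-standard union is 26 unique variants, so a wild-type replicate with
  one false positive gives specificity 26/27 ≈ 96.3%. All-negative
  replicates with zero calls still contribute negatives.
* **Concordance.** Jaccard index between detected truth-variant sets of two
  replicates of the same standard (1.0 when both empty); intra-run compares
  pairs within a run, inter-run across runs. A "fraction of truth detected
  in both" alternative sits behind `method = "both_detected"`.
* **Limit of detection.** The lowest expected-VAF tier whose truth variants
  are detected in *every* replicate. The report always prints the 1%
  analysis floor beside it: a headline "1% LoD" refers to the analysis
  floor, while the lowest manufactured tier is 1.3%.

## Coverage QC and GC windows

Pooled per-amplicon means are flagged `critical_below_100` (< 100×),
`warn_below_1000` (< 1000×), else `ok`; thresholds are configuration with
these defaults. GC profiles use non-overlapping 30-bp windows tiled from
position 1; a trailing partial window is kept iff it spans ≥ half a window
(a sequence shorter than half a window is still one window — the degenerate
case is only the empty sequence). `N` bases are excluded from both numerator
and denominator. The GC–depth association uses Spearman rank correlation;
with constant ranks it is reported as 0 with an explicit tie note rather
than `NA`, so reports stay machine-readable.

## The synthetic-data generator

The generator is first-class, tested code: it produces every input the
pipeline consumes, with the statistical structure the analysis assumes.
What it emulates, and the stated world it encodes:

* **Panel**: 219 amplicons over the 22 genes, lengths 150–250, fixed
  geometry with seeded lengths. GC is a mixture: a truncated-normal bulk
  (mean 0.48, capped at 0.56) plus a small high-GC tail (8% of amplicons,
  uniform 0.55–0.585) sitting on the dropout slope but above the warn
  threshold, and three forced dropout amplicons — an MPL-exon-10 analogue
  at GC 0.61 and two warn-band analogues (DNMT3A exon 17 at 0.590, TP53
  exon 4/5 at 0.595). Real hotspot coordinates are used for the JAK2, CALR
  and MPL anchors to keep fixtures recognisable; all other coordinates are
  a synthetic GRCh37-like namespace.
* **Coverage**: depth ~ LogNormal(log(target · m(gc)), σ) with target
  5000×, σ = 0.3 and a logistic dropout multiplier
  m(gc) = plogis((0.58 − gc)/width) rescaled so a 0.45-GC amplicon sits at
  1. The width default is 0.006: the stated behaviour is that the 0.61-GC
  amplicon drops below 100× (it lands at ~33× expected) while amplicons at
  ≤ 0.57 GC stay above ~4000×; a broader slope (e.g. width 0.015) cannot
  produce both a < 100× amplicon at GC 0.61 and a > 1000× panel elsewhere,
  so the narrow width is the consistent choice. With σ = 0 depths equal
  their expectation exactly — that deterministic table is the packaged
  stand-in for the assay's per-amplicon depth table (216/219 above
  1000×, two warn, one critical).
* **Calls**: alt reads ~ Binomial(depth, true VAF); a variant is emitted iff
  alt ≥ 4 and alt/depth ≥ 1% (at 5000× the 1% VAF floor is the binding
  constraint, matching the assay's stated limit). SNVs go to the
  small-variant caller only, > 25-base events to the structural caller
  only, other indels to both. The 1.3%-tier-at-low-depth dropout follows
  from this model: Binomial(depth < 100, 0.013) leaves fewer than 4 alt
  reads with probability ≈ 0.97 — the mechanism behind a missed low-VAF
  MPL W515L replicate.
* **Artifacts**: per-sample counts ~ Poisson(3); VAFs ~ Beta(1.2, 60)
  rejection-sampled into (0, 0.04]. The truncation encodes that these are
  noise-floor errors living strictly below the 5% retention threshold;
  untruncated Beta(1.2, 60) puts ~7% of its mass above 5%, which would
  contradict the generator's own contract that planted somatic variants are
  recovered with precision 1. Systematic artifacts are 2 fixed keys placed
  in 80% of samples at 5–12% VAF — excluded by recurrence, not by the VAF
  clause.
* **Cohort**: 10 samples, 7 with a JAK2-like SNV driver (VAF 10–90%), 3
  with a CALR-like 52-base frameshift deletion (VAF 10–40%), 0–4 somatic
  passengers each (VAF 6–55%), 15 germline heterozygotes each with
  population MAFs 2–40% (a quarter of the pool at non-exonic positions),
  and exactly one low-VAF (2.5%) COSMIC-pathogenic variant planted in one
  sample to exercise the rescue lane. Every emitted call carries its class
  and expected triage status.

What the generator does *not* emulate — and hence what a green test does not
establish: read-level errors and their substitution spectra, strand bias,
alignment artifacts around homopolymers, tumour purity and subclonal
structure, batch effects between runs, and annotation errors. Synthetic
recovery tests validate the *logic* of the cascade against its stated rules,
not the assay's real-world error profile.

Determinism: all draws derive from `sim_config(seed)`; identical configs
give byte-identical outputs, and the RNG state of the calling session is
restored afterwards.

## Numerical and formatting choices

* VAF is stored as a fraction and rendered as one-decimal percent in
  reports; the VCF reader accepts a 0.005 absolute mismatch between a
  stated `AF` and `AD/DP` to absorb that rounding.
* `FORMAT/AF` takes precedence over `AD/DP` when both are present (the
  caller's own estimate may include error correction); which fields a given
  vendor app emits is not standardized, so precedence is a package
  convention.
* All writers emit deterministic column and row order (chrom, pos, alt,
  sample); reports are byte-identical across runs on identical inputs, and
  the renderer does no arithmetic beyond percent formatting.
* Metric denominators of zero yield `NA`, never a silent 0 or 1.

## Known limitations

* Trim-only normalization cannot re-anchor trailing-padded indel
  representations (see above); supply-your-own left-alignment is the
  documented escape hatch.
* The headline validation percentages of the motivating assay (99.2%
  sensitivity, 97.7% PPV, 98.8%/99.0% concordances) depend on per-variant
  replicate detail that is not published; the package reproduces the metric
  *conventions* (including the 26/27 specificity arithmetic) but does not
  assert those numbers.
* Germline/somatic posterior modelling, CHIP calling and ACMG
  classification are out of scope.
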