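# mpnpanel

Post-variant-calling analysis for targeted amplicon myeloid gene panels, built
around the validation and clinical screening workflow of a custom 22-gene
myeloproliferative neoplasm (MPN) panel (ABL1, ASXL1, CALR, CBL, CEBPA, CSF3R,
DNMT3A, EZH2, FLT3, IDH1, IDH2, JAK2, KIT, MPL, NPM1, PDGFRA, RUNX1, SF3B1,
SRSF2, TET2, TP53, U2AF1).

## Who it is for

Labs running amplicon panels with two complementary variant callers — a
small-variant caller (SNVs, small indels) and a structural caller (large
deletions, medium insertions, tandem duplications) — who need a reproducible,
auditable route from raw call sets to a reviewed somatic variant list and a
set of assay-performance metrics. Everything downstream of variant calling is
covered; alignment and calling themselves are consumed as VCF inputs.

## What it computes

**Call-set reconciliation.** Variant keys are normalized by context trimming
(shared leading context removed first, keeping one anchor base, then shared
trailing context) so the two callers' indel representations meet in one
keyspace; the per-sample union keeps the small-variant caller's VAF for
events ≤ 25 bases and the structural caller's for larger events, recording
provenance for both.

**Somatic triage** (per cohort, with full audit trail). For each call with
annotation record (region class, population MAFs, dbSNP/ClinVar/COSMIC):

1. *Region filter*: only exonic variants are kept.
2. *Population filter*: excluded if any reported minor allele frequency
   (1000 Genomes, ExAC, ESP6500, gnomAD) is ≥ 1%. Absent frequencies never
   exclude.
3. *Artifact filter*: excluded if VAF < 5%, or if the key recurs in a
   majority (> 50%) of cohort samples without database pathogenicity
   evidence (the exemption keeps true recurrent drivers such as JAK2 V617F).
4. *Pathogenic rescue*: artifact-stage exclusions with VAF in [1%, 5%) and a
   ClinVar pathogenic/likely-pathogenic assertion or COSMIC-pathogenic entry
   are re-admitted.

Survivors are classified *putative novel* (exact allele absent from dbSNP,
ClinVar and COSMIC) or *reported*, and flagged Sanger-eligible at VAF ≥ 15%
(the sensitivity floor of Sanger confirmation).

**Panel validation.** Replicate runs of reference standards (a wild-type
negative, 5% and 1.3% VAF tiers, and a 20-variant myeloid mix) are scored
against truth sets: sensitivity tp/(tp+fn) over truth-variant × replicate
cells, specificity tn/(tn+fp) with negative evaluable sites defined as the
cross-standard truth-variant union absent from each replicate's own standard,
PPV, intra-/inter-run Jaccard concordance, and limit of detection (lowest
fully detected VAF tier, reported beside the 1% analysis floor).

**Coverage QC.** Per-amplicon pooled mean depths with warn (< 1000×) and
critical (< 100×) flags, on-target rate, GC content in 30-bp windows, and the
Spearman association between amplicon GC and depth (GC-rich amplicons drop
out of PCR-based libraries).

**Synthetic data.** `sim_config()` / `generate_cohort()` /
`generate_reference_standards()` / `simulate_coverage()` /
`simulate_callset()` generate a full synthetic world — 219-amplicon panel
with a high-GC dropout amplicon (the MPL exon 10 analogue), truth sets,
binomial VAF sampling at ~5000× depth, low-VAF error artifacts,
cohort-recurrent systematic artifacts, germline polymorphisms, and a
10-sample MPN-like cohort (7 JAK2-like, 3 CALR-like drivers) — with known
ground-truth labels for every emitted call. Identical seeds give
byte-identical outputs.

## Worked example

The packaged fixtures reproduce the clinical cohort: 28 reviewed variant
occurrences (21 unique) across 10 clinical samples.

```r
library(mpnpanel)

res <- run_triage(mpn_table2_calls(), mpn_table2_annotations())
res
#> <triage_result> 21 unique variants in -> 21 after region+MAF -> 20 retained + 1 rescued

demographics_summary(mpn_table1())$median_age
#> [1] 52   # range 30-79

report <- render_report(triage = res,
                        demographics = demographics_summary(mpn_table1()))
writeLines(head(report$markdown, 9))
#> # Panel analysis report
#>
#> ## Cohort
#> - 10 samples; median diagnosis age 52 (range 30-79)
#>
#> ## Variant triage
#> - 21 unique variants in; 21 after region and MAF filters; 20 retained (VAF > 5%) + 1 rescued (pathogenic, 1-5% VAF)
```

The 20 retained unique variants break down as 11 nonsynonymous SNVs, 2
synonymous SNVs, 2 frameshift insertions, 3 frameshift deletions and 2
stopgains; 7 samples carry JAK2 V617F and 3 carry CALR frameshift drivers;
4 variants are putative novel; the rescued variant is the TET2 stopgain at
1.4% VAF with a pathogenic COSMIC entry. Coverage QC on the synthetic
per-amplicon table reproduces the assay's structure:

```r
qc <- summarize_amplicon_coverage(synthetic_coverage_fixture(sim_config(seed = 1)))
sum(qc$rows$mean_depth_overall > 1000)   # 216 of 219 amplicons (98.6%)
table(qc$rows$flag)
#> critical_below_100    ok    warn_below_1000
#>                  1   216                  2
```

The one critical amplicon is the GC-0.61 MPL exon 10 analogue — the dropout
mechanism behind missed low-VAF MPL W515L calls.

## Command line

```sh
Rscript -e 'mpnpanel::panel_cli()' simulate --seed 7 --out-dir sim/
Rscript -e 'mpnpanel::panel_cli()' merge --small sim/S01.small.vcf \
    --structural sim/S01.structural.vcf --out sim/S01.merged.vcf
Rscript -e 'mpnpanel::panel_cli()' triage --fixture table2 --out-dir out/
Rscript -e 'mpnpanel::panel_cli()' coverage-qc --coverage sim/coverage.tsv \
    --gc sim/panel_gc.tsv --out-dir out/
```

Exit codes: 0 success, 1 validation error, 2 I/O or usage error. A wrapper
script is installed under `inst/cli/mpnpanel`.

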