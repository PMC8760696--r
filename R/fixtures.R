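# Packaged clinical-cohort fixtures: the 10-sample demographics table and
# the reviewed variant table (28 occurrences of 21 unique variants across
# the 10 samples), shipped under inst/extdata.
#
# Variant identities (gene, cDNA/protein notation, consequence, VAF, sample,
# database memberships) are the assay's reviewed calls; genomic keys use
# published coordinates where available (JAK2 V617F locus, ASXL1 insertion
# anchor) and plausible reconstructed GRCh37-style coordinates elsewhere —
# reconstructed allele sequences are synthetic. Downstream logic never
# depends on the absolute coordinates.

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "mpnpanel")
  if (!nzchar(p)) stop_fmt("packaged fixture not found: %s", name)
  p
}

#' Clinical cohort demographics fixture
#'
#' Ten MPN samples (3 ET, 3 PV, 4 PMF) with age, sex, ethnicity, blood
#' counts, hepatosplenomegaly, constitutional symptoms and smoking history.
#'
#' @return data.frame, one row per sample.
#' @export
mpn_table1 <- function() {
  read.delim(fixture_path("table1_cohort.tsv"), stringsAsFactors = FALSE,
             colClasses = c(sample_id = "character"))
}

#' Reviewed variant occurrences fixture
#'
#' The 28 reviewed variant occurrences (21 unique variants) detected across
#' the 10 clinical samples, with per-occurrence VAFs. Depth is fixed at the
#' 5000x panel target; `alt_reads` is derived from the printed one-decimal
#' percent VAF. Events larger than 25 bases carry `caller = "structural"`.
#'
#' @return call-set data.frame (see [read_callset()]).
#' @export
mpn_table2_calls <- function() {
  df <- read.delim(fixture_path("table2_calls.tsv"),
                   stringsAsFactors = FALSE,
                   colClasses = c(sample_id = "character"))
  depth <- 5000L
  vaf <- df$vaf_percent / 100
  calls <- data.frame(
    sample_id = df$sample_id, chrom = df$chrom, pos = df$pos, ref = df$ref,
    alt = df$alt, gene = df$gene, hgvs_c = df$hgvs_c, hgvs_p = df$hgvs_p,
    consequence = map_consequence(df$consequence), vaf = vaf, depth = depth,
    alt_reads = as.integer(round(vaf * depth)),
    caller = ifelse(max_allele_len(df$ref, df$alt) > 25, "structural",
                    "small_variant"),
    stringsAsFactors = FALSE)
  validate_calls(calls)
  calls
}

#' Annotation fixture for the reviewed variant occurrences
#'
#' One record per unique variant key of [mpn_table2_calls()]: region class,
#' population MAFs (all absent — these variants survived the 1% MAF
#' filter), dbSNP membership with exact-allele flags, ClinVar assertions and
#' COSMIC ids as printed.
#'
#' @return annotation data.frame (see [read_annotation_table()]).
#' @export
mpn_table2_annotations <- function() {
  read_annotation_table(fixture_path("table2_annotations.tsv"))
}

#' Cohort demographics summary
#'
#' @param demographics data.frame from [mpn_table1()] (needs columns
#'   `age, sex, subtype`).
#' @return list with `n`, `median_age`, `age_range`, `sex` (counts),
#'   `subtype` (counts).
#' @export
demographics_summary <- function(demographics = mpn_table1()) {
  list(n = nrow(demographics),
       median_age = median(demographics$age),
       age_range = range(demographics$age),
       sex = as.list(table(demographics$sex)),
       subtype = as.list(table(demographics$subtype)))
}

#' Synthetic coverage table reproducing the assay's per-amplicon QC counts
#'
#' The assay's original per-amplicon depth table is not redistributed;
#' this deterministic stand-in (labelled synthetic) reproduces its QC
#' structure exactly: 219 amplicons of which 216 have pooled mean depth
#' above 1000x, two sit in the warn band, and the high-GC MPL-exon-10
#' analogue falls below 100x. Built from [generate_panel()] +
#' [simulate_coverage()] with zero depth dispersion (depths equal the
#' GC-dropout expectation).
#'
#' @param config a [sim_config()].
#' @return long-format coverage data.frame.
#' @export
synthetic_coverage_fixture <- function(config = sim_config()) {
  cfg <- config
  cfg$depth_dispersion <- 0
  panel_obj <- generate_panel(cfg)
  simulate_coverage(panel_obj, cfg)
}
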