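# The somatic variant triage cascade.
#
# Order of stages (each applied to the survivors of the previous one):
#   1. region filter        — keep exonic variants only
#   2. population filter    — drop variants with any population MAF >= 1%
#   3. artifact filter      — drop VAF < 5% and cohort-recurrent variants
#                             (recurrence exempts variants with database
#                             pathogenicity evidence)
#   4. pathogenic rescue    — re-admit artifact-stage exclusions with VAF in
#                             [1%, 5%) and ClinVar P/LP or COSMIC-pathogenic
#                             evidence
# Retained and rescued variants are then classified for novelty against the
# dbSNP/ClinVar/COSMIC annotation columns and flagged for Sanger
# confirmability (>= 15% VAF). Every input occurrence receives exactly one
# status with an audit reason.

#' Default triage thresholds
#'
#' @param vaf_retain VAF below which a variant is an artifact candidate
#'   (exclusion tests `vaf < vaf_retain`; exactly 5% is kept). Default 0.05.
#' @param rescue_window VAF window `[low, high)` inspected for pathogenic
#'   rescue. Default `c(0.01, 0.05)` (the 1% analysis floor up to the
#'   retention threshold).
#' @param maf_cutoff population MAF at or above which a variant is excluded
#'   as a common polymorphism (any of the four databases). Default 0.01.
#' @param recurrence_fraction fraction of cohort samples above which a
#'   recurrent key is treated as a systematic artifact ("majority" =
#'   strictly more than 0.5). Default 0.5.
#' @param sanger_vaf Sanger confirmability floor (inclusive). Default 0.15.
#' @return named list of thresholds.
#' @export
triage_config <- function(vaf_retain = 0.05, rescue_window = c(0.01, 0.05),
                          maf_cutoff = 0.01, recurrence_fraction = 0.5,
                          sanger_vaf = 0.15) {
  list(vaf_retain = vaf_retain, rescue_window = rescue_window,
       maf_cutoff = maf_cutoff, recurrence_fraction = recurrence_fraction,
       sanger_vaf = sanger_vaf)
}

# pathogenicity evidence used by the recurrence exemption: ClinVar P/LP or
# any COSMIC entry
has_pathogenicity_evidence <- function(ann) {
  ann$clinvar_assertion %in% c("pathogenic", "likely_pathogenic") |
    ann$cosmic_pathogenic | nzchar(ann$cosmic_ids)
}

# database pathogenicity assertions used by the rescue lane (stricter: an
# unannotated COSMIC id is not an assertion of pathogenicity)
is_asserted_pathogenic <- function(ann) {
  ann$clinvar_assertion %in% c("pathogenic", "likely_pathogenic") |
    ann$cosmic_pathogenic
}

#' Region filter: keep exonic variants only
#'
#' @param calls call-set data.frame (cohort or single sample).
#' @param annotations annotation data.frame covering every call.
#' @return list with data.frames `kept` and `excluded` (annotated calls).
#' @export
filter_region <- function(calls, annotations) {
  ann <- annotate_calls(calls, annotations)
  keep <- ann$region_class == "exonic"
  list(kept = ann[keep, , drop = FALSE],
       excluded = ann[!keep, , drop = FALSE])
}

#' Population filter: drop common polymorphisms
#'
#' A variant is excluded iff any *present* MAF among 1000 Genomes, ExAC,
#' ESP6500 and gnomAD is at or above the cutoff. Variants with no frequency
#' data in any database are kept (absence is not evidence of rarity, but it
#' must not trigger the exclusion either).
#'
#' @inheritParams filter_region
#' @param maf_cutoff exclusion threshold, default 0.01.
#' @return list with data.frames `kept` and `excluded`.
#' @export
filter_population <- function(calls, annotations, maf_cutoff = 0.01) {
  ann <- annotate_calls(calls, annotations)
  mafs <- as.matrix(ann[, c("maf_1000g", "maf_exac", "maf_esp6500",
                            "maf_gnomad"), drop = FALSE])
  common <- apply(mafs, 1, function(v) any(!is.na(v) & v >= maf_cutoff))
  if (nrow(ann) == 0) common <- logical(0)
  list(kept = ann[!common, , drop = FALSE],
       excluded = ann[common, , drop = FALSE])
}

#' Artifact filter: low-VAF and cohort-recurrent variants
#'
#' A call is excluded iff its VAF is below `vaf_retain` *or* its normalized
#' key occurs in strictly more than `recurrence_fraction` of the cohort's
#' samples without database pathogenicity evidence (ClinVar
#' pathogenic/likely-pathogenic or any COSMIC entry). The exemption keeps
#' bona fide recurrent drivers (e.g. JAK2 V617F in 7/10 samples) out of the
#' artifact bin.
#'
#' @param calls annotated cohort call-set (output of the previous stages).
#' @param annotations annotation data.frame (only consulted when `calls`
#'   lacks annotation columns).
#' @param n_samples cohort size used for the recurrence denominator; default
#'   the number of distinct sample ids in `calls`.
#' @param vaf_retain,recurrence_fraction thresholds (see [triage_config()]).
#' @return list with data.frames `kept` and `excluded`; `excluded` carries a
#'   `reason` column distinguishing the two clauses.
#' @export
filter_artifacts <- function(calls, annotations = NULL, n_samples = NULL,
                             vaf_retain = 0.05, recurrence_fraction = 0.5) {
  if (nrow(calls) == 0) stop_fmt("empty cohort in filter_artifacts")
  ann <- if (!is.null(annotations) && !"region_class" %in% names(calls))
    annotate_calls(calls, annotations) else calls
  if (is.null(n_samples)) n_samples <- length(unique(ann$sample_id))
  key <- variant_id(ann$chrom, ann$pos, ann$ref, ann$alt)
  carriers <- tapply(ann$sample_id, key, function(s) length(unique(s)))
  recurrent <- as.vector(carriers[key]) > recurrence_fraction * n_samples
  low_vaf <- ann$vaf < vaf_retain
  exempt <- has_pathogenicity_evidence(ann)
  excluded <- low_vaf | (recurrent & !exempt)
  reason <- ifelse(low_vaf,
                   sprintf("VAF %.4f < %.2f", ann$vaf, vaf_retain),
                   sprintf("key in %d/%d samples (> %d%%) without pathogenicity evidence",
                           as.vector(carriers[key]), n_samples,
                           round(100 * recurrence_fraction)))
  ex <- ann[excluded, , drop = FALSE]
  ex$reason <- reason[excluded]
  list(kept = ann[!excluded, , drop = FALSE], excluded = ex)
}

#' Pathogenic rescue lane
#'
#' Re-admits artifact-stage exclusions with VAF in the rescue window
#' (default `[0.01, 0.05)`: the panel's 1% detection floor up to the 5%
#' retention threshold) and an explicit database pathogenicity assertion
#' (ClinVar pathogenic/likely-pathogenic, or COSMIC-listed-as-pathogenic).
#'
#' @param excluded annotated data.frame of artifact-stage exclusions.
#' @param rescue_window numeric `c(low, high)`; low inclusive, high
#'   exclusive.
#' @return the rescued subset (data.frame).
#' @export
rescue_pathogenic <- function(excluded, rescue_window = c(0.01, 0.05)) {
  if (nrow(excluded) == 0) return(excluded)
  in_window <- excluded$vaf >= rescue_window[1] &
    excluded$vaf < rescue_window[2]
  excluded[in_window & is_asserted_pathogenic(excluded), , drop = FALSE]
}

#' Novelty classification
#'
#' A retained/rescued variant is putatively novel iff its exact allele is
#' absent from dbSNP (`dbsnp_exact_allele_match` FALSE — membership of an
#' rsID *cluster* with a different allele does not defeat novelty), it has
#' no ClinVar assertion, and no COSMIC id.
#'
#' @param ann annotated call rows.
#' @return character vector: `"putative_novel"` or `"reported"`.
#' @export
classify_novelty <- function(ann) {
  novel <- !ann$dbsnp_exact_allele_match &
    ann$clinvar_assertion == "absent" & !nzchar(ann$cosmic_ids)
  ifelse(novel, "putative_novel", "reported")
}

#' Sanger confirmability flag
#'
#' Sanger sequencing reliably detects alleles down to roughly 15-20% VAF;
#' the flag marks calls at or above the floor. It is an eligibility flag,
#' not a gate: confirmation outcomes are user data.
#'
#' @param vaf numeric vector of VAF fractions.
#' @param threshold inclusive floor, default 0.15.
#' @return logical vector.
#' @export
flag_sanger <- function(vaf, threshold = 0.15) {
  vaf >= threshold
}

#' Run the full triage cascade on a cohort
#'
#' Applies [filter_region()], [filter_population()], [filter_artifacts()]
#' and [rescue_pathogenic()] in order, then annotates survivors with novelty
#' and Sanger flags. The decisions partition the input: every
#' (sample, normalized key) occurrence receives exactly one status.
#'
#' @param calls cohort call-set data.frame (typically merged call sets for
#'   all samples; keys are normalized internally). Duplicate
#'   (sample, key) occurrences are collapsed to the first.
#' @param annotations annotation data.frame covering every call (keys
#'   normalized internally).
#' @param config thresholds from [triage_config()].
#' @param n_samples cohort size for the recurrence rule; default the number
#'   of distinct sample ids in `calls`.
#' @return list of class `triage_result`:
#'   * `decisions`: one row per (sample_id, key) with `status`
#'     (`retained`, `rescued_pathogenic`, `excluded_region`,
#'     `excluded_common`, `excluded_artifact`), `reason`, `novelty`
#'     (`putative_novel` / `reported` / `not_assessed`), `sanger_eligible`.
#'   * `summary`: unique-variant counts (`n_input_unique`,
#'     `n_after_region_and_maf`, `n_retained`, `n_rescued`) plus
#'     `per_sample` counts of retained+rescued occurrences.
#' @export
run_triage <- function(calls, annotations, config = triage_config(),
                       n_samples = NULL) {
  if (nrow(calls) == 0) stop_fmt("empty cohort in run_triage")
  calls <- normalize_keys(calls)
  annotations <- normalize_keys(annotations)
  annotations <- annotations[!duplicated(variant_id(
    annotations$chrom, annotations$pos, annotations$ref, annotations$alt)), ,
    drop = FALSE]
  occ <- variant_id(calls$chrom, calls$pos, calls$ref, calls$alt)
  calls <- calls[!duplicated(paste(calls$sample_id, occ)), , drop = FALSE]
  if (is.null(n_samples)) n_samples <- length(unique(calls$sample_id))

  s1 <- filter_region(calls, annotations)
  s2 <- filter_population(s1$kept, annotations, config$maf_cutoff)
  if (nrow(s2$kept) > 0) {
    s3 <- filter_artifacts(s2$kept, n_samples = n_samples,
                           vaf_retain = config$vaf_retain,
                           recurrence_fraction = config$recurrence_fraction)
  } else {
    ex0 <- s2$kept
    ex0$reason <- character(0)
    s3 <- list(kept = s2$kept, excluded = ex0)
  }
  rescued <- rescue_pathogenic(s3$excluded, config$rescue_window)

  decision_row <- function(df, status, reason, assess) {
    if (nrow(df) == 0) {
      return(data.frame(sample_id = character(), chrom = character(),
                        pos = integer(), ref = character(), alt = character(),
                        gene = character(), consequence = character(),
                        vaf = numeric(), status = character(),
                        reason = character(), novelty = character(),
                        sanger_eligible = logical(),
                        stringsAsFactors = FALSE))
    }
    data.frame(
      sample_id = df$sample_id, chrom = df$chrom, pos = df$pos,
      ref = df$ref, alt = df$alt, gene = df$gene,
      consequence = df$consequence, vaf = df$vaf, status = status,
      reason = reason,
      novelty = if (assess) classify_novelty(df) else "not_assessed",
      sanger_eligible = if (assess)
        flag_sanger(df$vaf, config$sanger_vaf) else FALSE,
      stringsAsFactors = FALSE)
  }
  rescue_key <- variant_id(rescued$sample_id, rescued$pos, rescued$ref,
                           rescued$alt)
  s3ex_key <- variant_id(s3$excluded$sample_id, s3$excluded$pos,
                         s3$excluded$ref, s3$excluded$alt)
  still_excluded <- s3$excluded[!(s3ex_key %in% rescue_key), , drop = FALSE]

  decisions <- rbind(
    decision_row(s1$excluded, "excluded_region",
                 "region_class not exonic (criterion 1)", FALSE),
    decision_row(s2$excluded, "excluded_common",
                 sprintf("population MAF >= %g in >= 1 database (criterion 2)",
                         config$maf_cutoff), FALSE),
    decision_row(still_excluded, "excluded_artifact",
                 still_excluded$reason, FALSE),
    decision_row(rescued, "rescued_pathogenic",
                 sprintf("VAF in [%g, %g) with pathogenic/likely-pathogenic assertion",
                         config$rescue_window[1], config$rescue_window[2]),
                 TRUE),
    decision_row(s3$kept, "retained",
                 sprintf("exonic, rare, VAF >= %g, not recurrent artifact",
                         config$vaf_retain), TRUE))
  decisions <- decisions[order(decisions$chrom, decisions$pos, decisions$alt,
                               decisions$sample_id), , drop = FALSE]
  rownames(decisions) <- NULL

  ukey <- function(df) unique(variant_id(df$chrom, df$pos, df$ref, df$alt))
  after12 <- s2$kept
  kept_occ <- decisions$status %in% c("retained", "rescued_pathogenic")
  per_sample <- table(factor(decisions$sample_id[kept_occ],
                             levels = sort(unique(calls$sample_id))))
  summary <- list(
    n_input_unique = length(ukey(calls)),
    n_after_region_and_maf = length(ukey(after12)),
    n_retained = length(ukey(s3$kept)),
    n_rescued = length(ukey(rescued)),
    n_samples = n_samples,
    per_sample = as.list(per_sample))
  structure(list(decisions = decisions, summary = summary),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<triage_result> %d unique variants in -> %d after region+MAF -> %d retained + %d rescued\n",
    s$n_input_unique, s$n_after_region_and_maf, s$n_retained, s$n_rescued))
  invisible(x)
}

#' Write triage decisions as TSV
#'
#' @param result a `triage_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_triage_decisions <- function(result, path) {
  write.table(result$decisions, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
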