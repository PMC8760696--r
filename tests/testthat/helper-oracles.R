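# Independent brute-force oracles. These re-implement the specified rules
# as single-pass predicates, deliberately sharing no code with the package
# internals they check.

oracle_triage <- function(calls, ann, vaf_retain = 0.05,
                          maf_cutoff = 0.01, rescue_low = 0.01) {
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  ck <- key(calls)
  ak <- key(ann)
  n_samples <- length(unique(calls$sample_id))
  # survivors of region+MAF, for the recurrence count
  surv <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    a <- ann[ak == ck[i], ][1, ]
    mafs <- c(a$maf_1000g, a$maf_exac, a$maf_esp6500, a$maf_gnomad)
    surv[i] <- a$region_class == "exonic" &&
      !any(!is.na(mafs) & mafs >= maf_cutoff)
  }
  carriers <- table(ck[surv])
  status <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    a <- ann[ak == ck[i], ][1, ]
    mafs <- c(a$maf_1000g, a$maf_exac, a$maf_esp6500, a$maf_gnomad)
    evid <- a$clinvar_assertion %in% c("pathogenic", "likely_pathogenic") ||
      a$cosmic_pathogenic || nzchar(a$cosmic_ids)
    asserted <- a$clinvar_assertion %in%
      c("pathogenic", "likely_pathogenic") || a$cosmic_pathogenic
    v <- calls$vaf[i]
    if (a$region_class != "exonic") {
      status[i] <- "excluded_region"
    } else if (any(!is.na(mafs) & mafs >= maf_cutoff)) {
      status[i] <- "excluded_common"
    } else {
      recurrent <- carriers[[ck[i]]] > 0.5 * n_samples
      artifact <- v < vaf_retain || (recurrent && !evid)
      if (!artifact) {
        status[i] <- "retained"
      } else if (v >= rescue_low && v < vaf_retain && asserted) {
        status[i] <- "rescued_pathogenic"
      } else {
        status[i] <- "excluded_artifact"
      }
    }
  }
  data.frame(sample_id = calls$sample_id, key = ck, status = status,
             stringsAsFactors = FALSE)
}

# brute-force confusion from a known detection plan
oracle_confusion <- function(truth, plan) {
  # plan: list per replicate: list(standard_id, detected = keys, n_off)
  tkey <- paste(truth$chrom, truth$pos, truth$ref, truth$alt)
  all_unique <- unique(tkey)
  tp <- 0L; fn <- 0L; fp <- 0L; tn <- 0L
  for (p in plan) {
    own <- tkey[truth$standard_id == p$standard_id]
    tp <- tp + length(p$detected)
    fn <- fn + length(own) - length(p$detected)
    fp <- fp + p$n_off
    tn <- tn + length(setdiff(all_unique, own))
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}
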