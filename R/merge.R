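# Reconciliation of the small-variant and structural call sets for one
# sample. The two callers are complementary: the small-variant caller sees
# SNVs and small indels but misses large duplications; the structural caller
# sees frameshifts and large duplications but no SNVs. The merge is a union
# over normalized keys; when both callers report the same key the retained
# VAF/depth come from the caller suited to the event size.

#' Merge the two callers' call sets for one sample
#'
#' Both call sets are key-normalized ([normalize_keys()]) and unioned. When
#' both callers report the same normalized key, the retained VAF/depth come
#' from the small-variant caller for events with
#' `max(nchar(ref), nchar(alt)) <= large_threshold` and from the structural
#' caller for larger events; provenance records both contributors.
#'
#' @param small call-set data.frame from the small-variant caller.
#' @param structural call-set data.frame from the structural caller.
#' @param large_threshold allele-length cutoff (bases) above which the
#'   structural caller's measurement is preferred. Default 25.
#' @return list of class `merged_callset` with elements
#'   * `sample_id`: the sample.
#'   * `calls`: data.frame of unique normalized calls with a `callers` column
#'     (comma-joined provenance set) replacing `caller`.
#'   * `merge_log`: one row per key: contributing caller(s) and whose
#'     VAF was kept.
#' @export
merge_callsets <- function(small, structural, large_threshold = 25) {
  for (cs in list(small, structural)) validate_calls(cs, check_gene = FALSE)
  ids <- unique(c(small$sample_id, structural$sample_id))
  if (length(ids) > 1)
    stop_fmt("calls from different samples in one merge: %s",
             paste(ids, collapse = ", "))
  sample_id <- if (length(ids) == 1) ids else NA_character_
  small <- normalize_keys(small)
  structural <- normalize_keys(structural)
  key_of <- function(d) variant_id(d$chrom, d$pos, d$ref, d$alt)
  # within-caller duplicates after normalization: keep the first occurrence
  small <- small[!duplicated(key_of(small)), , drop = FALSE]
  structural <- structural[!duplicated(key_of(structural)), , drop = FALSE]
  ks <- key_of(small); kp <- key_of(structural)
  all_keys <- sort(unique(c(ks, kp)))

  rows <- vector("list", length(all_keys))
  log <- vector("list", length(all_keys))
  for (i in seq_along(all_keys)) {
    k <- all_keys[i]
    in_s <- k %in% ks; in_p <- k %in% kp
    rs <- if (in_s) small[ks == k, , drop = FALSE][1, ] else NULL
    rp <- if (in_p) structural[kp == k, , drop = FALSE][1, ] else NULL
    if (in_s && in_p) {
      big <- max_allele_len(rs$ref, rs$alt) > large_threshold
      keep <- if (big) rp else rs
      kept_from <- if (big) "structural" else "small_variant"
      callers <- "small_variant,structural"
    } else if (in_s) {
      keep <- rs; kept_from <- "small_variant"; callers <- "small_variant"
    } else {
      keep <- rp; kept_from <- "structural"; callers <- "structural"
    }
    keep$caller <- NULL
    keep$callers <- callers
    rows[[i]] <- keep
    log[[i]] <- data.frame(key = k, callers = callers, vaf_from = kept_from,
                           stringsAsFactors = FALSE)
  }
  calls <- if (length(rows) > 0) do.call(rbind, rows) else
    cbind(empty_calls()[, setdiff(call_columns(), "caller")],
          callers = character())
  rownames(calls) <- NULL
  structure(list(sample_id = sample_id, calls = calls,
                 merge_log = do.call(rbind, c(log, list(NULL)))),
            class = "merged_callset")
}

#' @export
print.merged_callset <- function(x, ...) {
  cat(sprintf("<merged_callset> sample %s: %d unique variants (%d from both callers)\n",
              x$sample_id, nrow(x$calls),
              sum(x$calls$callers == "small_variant,structural")))
  invisible(x)
}

#' Flatten merged call sets back into one cohort call-set data.frame
#'
#' @param merged list of `merged_callset` objects (one per sample).
#' @return data.frame of calls with the `callers` provenance column.
#' @export
merged_cohort_calls <- function(merged) {
  do.call(rbind, c(lapply(merged, function(m) m$calls), list(NULL)))
}

#' Write a merge log as TSV
#'
#' @param merged a `merged_callset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_merge_log <- function(merged, path) {
  write.table(merged$merge_log, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
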