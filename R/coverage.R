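# Per-amplicon coverage QC and GC-content window analysis.

#' Summarize per-amplicon coverage with alert flags
#'
#' Depth records are pooled over all (sample, run) observations per
#' amplicon; each amplicon gets a flag: `critical_below_100` (< `critical`),
#' `warn_below_1000` (< `warn`), else `ok`.
#'
#' @param records long-format coverage data.frame (`amplicon_id, sample_id,
#'   run_id, mean_depth`).
#' @param warn,critical flag thresholds (x coverage), defaults 1000 / 100.
#' @return list with `rows` (data.frame `amplicon_id, mean_depth_overall,
#'   flag`, sorted by amplicon id) and `fraction_above_warn` (fraction of
#'   amplicons with pooled mean > `warn`).
#' @export
summarize_amplicon_coverage <- function(records, warn = 1000,
                                        critical = 100) {
  if (is.null(records) || nrow(records) == 0)
    stop_fmt("empty coverage input")
  if (any(records$mean_depth < 0)) stop_fmt("negative depth")
  mean_by <- tapply(records$mean_depth, records$amplicon_id, mean)
  rows <- data.frame(amplicon_id = names(mean_by),
                     mean_depth_overall = as.vector(mean_by),
                     stringsAsFactors = FALSE)
  rows <- rows[order(rows$amplicon_id), , drop = FALSE]
  rows$flag <- ifelse(rows$mean_depth_overall < critical,
                      "critical_below_100",
                      ifelse(rows$mean_depth_overall < warn,
                             "warn_below_1000", "ok"))
  rownames(rows) <- NULL
  list(rows = rows,
       fraction_above_warn = mean(rows$mean_depth_overall > warn))
}

#' On-target read rate
#'
#' @param on_target_reads reads aligned within panel target regions.
#' @param aligned_reads total aligned reads (> 0).
#' @return fraction in \[0, 1\].
#' @export
on_target_rate <- function(on_target_reads, aligned_reads) {
  if (aligned_reads <= 0) stop_fmt("aligned_reads must be > 0")
  if (on_target_reads > aligned_reads)
    stop_fmt("on_target_reads exceeds aligned_reads")
  if (on_target_reads < 0) stop_fmt("negative read count")
  on_target_reads / aligned_reads
}

#' GC-content window profile of a sequence
#'
#' Non-overlapping windows tiled from position 1; a final partial window is
#' kept iff it spans at least `window / 2` bases. N bases are excluded from
#' both the numerator and the denominator of the per-window GC fraction;
#' overall GC is computed on the full sequence.
#'
#' @param sequence nucleotide string over \{A,C,G,T,N\} (character or
#'   [Biostrings::DNAString]).
#' @param window window size in bases, default 30.
#' @param high_gc per-window GC fraction above which a window counts as
#'   high-GC, default 0.60.
#' @param amplicon_id optional label carried into the profile.
#' @return list of class `gc_profile`: `amplicon_id`, `overall_gc`,
#'   `windows` (data.frame `start, width, gc`), `high_gc_window_fraction`.
#' @export
gc_windows <- function(sequence, window = 30, high_gc = 0.60,
                       amplicon_id = NA_character_) {
  seq <- toupper(as.character(sequence))
  n <- nchar(seq)
  if (n == 0) stop_fmt("empty sequence")
  if (window < 1) stop_fmt("window must be >= 1")
  if (grepl("[^ACGTN]", seq)) stop_fmt("sequence must be over {A,C,G,T,N}")
  dna <- Biostrings::DNAString(seq)
  starts <- seq.int(1L, n, by = window)
  ends <- pmin(starts + window - 1L, n)
  widths <- ends - starts + 1L
  keep <- widths >= window / 2
  # the first window is always kept (short sequences are one partial window)
  keep[1] <- TRUE
  starts <- starts[keep]; ends <- ends[keep]; widths <- widths[keep]
  gc <- vapply(seq_along(starts), function(i) {
    w <- Biostrings::subseq(dna, starts[i], ends[i])
    counts <- Biostrings::letterFrequency(w, c("G", "C", "N"))
    denom <- widths[i] - counts[["N"]]
    if (denom == 0) return(NA_real_)
    (counts[["G"]] + counts[["C"]]) / denom
  }, numeric(1))
  counts_all <- Biostrings::letterFrequency(dna, c("G", "C", "N"))
  denom_all <- n - counts_all[["N"]]
  overall <- if (denom_all == 0) NA_real_ else
    (counts_all[["G"]] + counts_all[["C"]]) / denom_all
  structure(list(
    amplicon_id = amplicon_id, overall_gc = overall,
    windows = data.frame(start = starts, width = widths, gc = gc),
    high_gc_window_fraction = mean(gc > high_gc, na.rm = TRUE)),
    class = "gc_profile")
}

#' Associate GC content with coverage dropout
#'
#' Joins per-amplicon QC rows with GC profiles and reports the Spearman
#' rank correlation between overall GC and pooled mean depth. Amplicons
#' present on only one side are listed, not fatal.
#'
#' @param qc_rows data.frame from [summarize_amplicon_coverage()]`$rows`.
#' @param gc either a named numeric vector of overall GC fractions
#'   (names = amplicon ids) or a list of `gc_profile`s.
#' @return list with `table` (joined, sorted by mean depth ascending),
#'   `spearman_rho` (0 with a `note` when undefined), `note`,
#'   `unmatched_ids`.
#' @export
gc_dropout_association <- function(qc_rows, gc) {
  if (is.list(gc) && !is.numeric(gc)) {
    ids <- vapply(gc, `[[`, "", "amplicon_id")
    gc <- setNames(vapply(gc, `[[`, 0, "overall_gc"), ids)
  }
  unmatched <- union(setdiff(qc_rows$amplicon_id, names(gc)),
                     setdiff(names(gc), qc_rows$amplicon_id))
  common <- intersect(qc_rows$amplicon_id, names(gc))
  tab <- qc_rows[match(common, qc_rows$amplicon_id), , drop = FALSE]
  tab$overall_gc <- as.vector(gc[common])
  tab <- tab[order(tab$mean_depth_overall), ,
             drop = FALSE][, c("amplicon_id", "overall_gc",
                               "mean_depth_overall", "flag")]
  rownames(tab) <- NULL
  note <- NA_character_
  rho <- NA_real_
  if (nrow(tab) >= 2 &&
      length(unique(tab$overall_gc)) > 1 &&
      length(unique(tab$mean_depth_overall)) > 1) {
    rho <- cor(tab$overall_gc, tab$mean_depth_overall, method = "spearman")
  } else if (nrow(tab) >= 2) {
    rho <- 0
    note <- "correlation undefined (constant ranks); reported as 0"
  } else {
    note <- "fewer than two matched amplicons; correlation not computed"
  }
  list(table = tab, spearman_rho = rho, note = note,
       unmatched_ids = unmatched)
}
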