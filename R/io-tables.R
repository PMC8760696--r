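# Tabular I/O: amplicon manifests (BED4), annotation tables, coverage tables,
# truth-set tables. All writers emit deterministic row and column order.

#' Read an amplicon manifest (BED4)
#'
#' BED intervals (0-based half-open) are converted to the internal 1-based
#' inclusive convention on read; parsing is delegated to
#' [rtracklayer::import()].
#'
#' @param path path to a BED file with at least 4 columns
#'   (chrom, start, end, amplicon id); optional columns 5-6 are ignored and a
#'   7th/8th column may carry gene symbol and exon label (as written by
#'   [write_amplicon_manifest()], which appends them after score/strand).
#' @return data.frame with columns `amplicon_id, chrom, start, end, gene,
#'   exon_label` (1-based inclusive coordinates).
#' @export
read_amplicon_manifest <- function(path) {
  if (!file.exists(path)) stop_fmt("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(amplicon_id = character(), chrom = character(),
                      start = integer(), end = integer(), gene = character(),
                      exon_label = character(), stringsAsFactors = FALSE))
  }
  raw <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(raw))
  if (ncol_min < 4) stop_fmt("BED manifest needs >= 4 columns")
  bad <- which(vapply(raw, function(f)
    as.numeric(f[2]) >= as.numeric(f[3]), logical(1)))
  if (length(bad) > 0)
    stop_fmt("degenerate interval (start >= end) at BED line %d", bad[1])
  # rtracklayer parses strict BED; the optional gene/exon columns of the
  # extended dialect are taken from the raw lines instead
  bed4 <- tempfile(fileext = ".bed")
  on.exit(unlink(bed4))
  writeLines(vapply(raw, function(f)
    paste(f[1:4], collapse = "\t"), character(1)), bed4)
  gr <- rtracklayer::import(bed4, format = "BED")
  ids <- S4Vectors::mcols(gr)$name
  if (anyDuplicated(ids))
    stop_fmt("duplicate amplicon_id in manifest: %s",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gene <- vapply(raw, function(f) if (length(f) >= 7) f[7] else NA_character_,
                 character(1))
  exon <- vapply(raw, function(f) if (length(f) >= 8) f[8] else NA_character_,
                 character(1))
  out <- data.frame(
    amplicon_id = ids,
    chrom = normalize_chrom(as.character(GenomicRanges::seqnames(gr))),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    gene = gene, exon_label = exon, stringsAsFactors = FALSE)
  len <- out$end - out$start + 1
  if (any(len < 50 | len > 1000))
    stop_fmt("amplicon length outside [50, 1000]: %s",
             paste(out$amplicon_id[len < 50 | len > 1000], collapse = ", "))
  out
}

#' Write an amplicon manifest as BED4(+)
#'
#' Internal 1-based inclusive intervals are converted back to 0-based
#' half-open BED; the conversion is the exact inverse of
#' [read_amplicon_manifest()].
#'
#' @param panel data.frame with columns `amplicon_id, chrom, start, end` and
#'   optionally `gene, exon_label`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_amplicon_manifest <- function(panel, path) {
  require_columns(panel, c("amplicon_id", "chrom", "start", "end"),
                  "amplicon manifest")
  panel <- panel[order(panel$chrom, panel$start, panel$amplicon_id), ,
                 drop = FALSE]
  extra <- NULL
  if (!is.null(panel$gene)) {
    exon <- if (is.null(panel$exon_label)) "." else panel$exon_label
    extra <- paste("0", "+", panel$gene, exon, sep = "\t")
  }
  lines <- paste(panel$chrom, panel$start - 1L, panel$end, panel$amplicon_id,
                 sep = "\t")
  if (!is.null(extra)) lines <- paste(lines, extra, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

parse_maf <- function(x, col, path) {
  x <- trimws(as.character(x))
  absent <- is.na(x) | x == "" | x == "."
  v <- suppressWarnings(as.numeric(x))
  bad <- !absent & is.na(v)
  if (any(bad))
    stop_fmt("unparseable MAF in column %s of %s: '%s'", col, path,
             x[bad][1])
  v[absent] <- NA_real_
  v
}

map_clinvar <- function(x) {
  key <- gsub("[^a-z]", "", tolower(trimws(as.character(x))))
  lut <- c(pathogenic = "pathogenic", likelypathogenic = "likely_pathogenic",
           vus = "VUS", uncertainsignificance = "VUS",
           vusuncertainsignificance = "VUS",
           likelybenign = "likely_benign", benign = "benign",
           absent = "absent", na = "absent")
  out <- unname(lut[key])
  out[key == "" | is.na(key)] <- "absent"
  if (anyNA(out))
    stop_fmt("unknown ClinVar assertion: %s",
             paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Read a wANNOVAR-style annotation table (TSV)
#'
#' One record per variant key. Missing values encoded as `"."` or empty are
#' read as absent (`NA`), never zero-filled; ClinVar assertions are mapped
#' case/space-insensitively onto the fixed vocabulary.
#'
#' @param path path to a TSV with header columns `chrom, pos, ref, alt,
#'   region_class, maf_1000g, maf_exac, maf_esp6500, maf_gnomad, dbsnp_id,
#'   dbsnp_exact_allele_match, clinvar_assertion, cosmic_ids,
#'   cosmic_pathogenic`.
#' @return validated annotation data.frame (see [validate_annotations()]).
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop_fmt("annotation table not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  require_columns(df, annotation_columns(), "annotation table")
  df$chrom <- normalize_chrom(df$chrom)
  df$pos <- as.integer(df$pos)
  for (m in c("maf_1000g", "maf_exac", "maf_esp6500", "maf_gnomad"))
    df[[m]] <- parse_maf(df[[m]], m, path)
  df$dbsnp_id <- ifelse(df$dbsnp_id %in% c("", "."), NA_character_,
                        df$dbsnp_id)
  df$dbsnp_exact_allele_match <- as.logical(df$dbsnp_exact_allele_match)
  df$clinvar_assertion <- map_clinvar(df$clinvar_assertion)
  df$cosmic_ids <- ifelse(df$cosmic_ids %in% c("."), "", df$cosmic_ids)
  df$cosmic_pathogenic <- as.logical(df$cosmic_pathogenic)
  id <- variant_id(df$chrom, df$pos, df$ref, df$alt)
  if (anyDuplicated(id)) {
    dup <- id[duplicated(id)]
    rows <- df[id %in% dup, , drop = FALSE]
    if (nrow(unique(rows)) != length(unique(dup)))
      stop_fmt("duplicated annotation key(s) with conflicting values: %s",
               paste(unique(dup), collapse = ", "))
    df <- df[!duplicated(id), , drop = FALSE]
  }
  rownames(df) <- NULL
  validate_annotations(df)
  df
}

#' Write an annotation table as TSV
#'
#' @param ann annotation data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(ann, path) {
  validate_annotations(ann)
  ann <- ann[order(ann$chrom, ann$pos, ann$alt), , drop = FALSE]
  out <- ann
  for (m in c("maf_1000g", "maf_exac", "maf_esp6500", "maf_gnomad"))
    out[[m]] <- ifelse(is.na(ann[[m]]), ".",
                       formatC(ann[[m]], format = "g", digits = 12))
  out$dbsnp_id <- ifelse(is.na(ann$dbsnp_id), ".", ann$dbsnp_id)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a wide per-amplicon coverage table (TSV)
#'
#' Dialect: amplicons as rows, one column `amplicon_id`, remaining columns
#' one per sample (column name = sample id, optionally suffixed
#' `"|<run_id>"`); cells are mean depths.
#'
#' @param path path to the TSV.
#' @return long-format data.frame with columns `amplicon_id, sample_id,
#'   run_id, mean_depth` (run_id `NA` when not encoded).
#' @export
read_coverage_table <- function(path) {
  if (!file.exists(path)) stop_fmt("coverage table not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  require_columns(df, "amplicon_id", "coverage table")
  samples <- setdiff(names(df), "amplicon_id")
  if (length(samples) == 0) stop_fmt("coverage table has no sample columns")
  recs <- lapply(samples, function(s) {
    v <- suppressWarnings(as.numeric(df[[s]]))
    bad <- which(is.na(v) & !is.na(df[[s]]))
    if (length(bad) > 0)
      stop_fmt("non-numeric depth at amplicon '%s', column '%s'",
               df$amplicon_id[bad[1]], s)
    parts <- strsplit(s, "|", fixed = TRUE)[[1]]
    data.frame(amplicon_id = df$amplicon_id,
               sample_id = parts[1],
               run_id = if (length(parts) > 1) parts[2] else NA_character_,
               mean_depth = v, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (any(out$mean_depth < 0)) stop_fmt("negative depth in coverage table")
  rownames(out) <- NULL
  out
}

#' Write coverage records as a wide per-amplicon TSV
#'
#' @param records long-format coverage data.frame (`amplicon_id, sample_id,
#'   run_id, mean_depth`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage_table <- function(records, path) {
  require_columns(records, c("amplicon_id", "sample_id", "mean_depth"),
                  "coverage records")
  run <- if (is.null(records$run_id)) NA_character_ else records$run_id
  col <- ifelse(is.na(run), records$sample_id,
                paste(records$sample_id, run, sep = "|"))
  amps <- sort(unique(records$amplicon_id))
  cols <- sort(unique(col))
  wide <- data.frame(amplicon_id = amps, stringsAsFactors = FALSE)
  for (cl in cols) {
    sel <- records[col == cl, , drop = FALSE]
    wide[[cl]] <- sel$mean_depth[match(amps, sel$amplicon_id)]
  }
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference-standard truth-set table (TSV)
#'
#' @param path TSV with header `standard_id, chrom, pos, ref, alt, gene,
#'   hgvs_p, expected_vaf` (expected_vaf `"."` or empty for absent).
#' @return data.frame of truth variants; `expected_vaf` is a fraction or `NA`.
#' @export
read_truth_sets <- function(path) {
  if (!file.exists(path)) stop_fmt("truth-set table not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  require_columns(df, c("standard_id", "chrom", "pos", "ref", "alt", "gene",
                        "hgvs_p", "expected_vaf"), "truth-set table")
  df$chrom <- normalize_chrom(df$chrom)
  df$pos <- as.integer(df$pos)
  df$expected_vaf <- parse_maf(df$expected_vaf, "expected_vaf", path)
  if (any(!is.na(df$expected_vaf) &
          (df$expected_vaf <= 0 | df$expected_vaf > 1)))
    stop_fmt("expected_vaf must lie in (0, 1]")
  validate_keys(df)
  df
}

#' Write a truth-set table as TSV
#'
#' @param truth truth-set data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_sets <- function(truth, path) {
  truth <- truth[order(truth$standard_id, truth$chrom, truth$pos, truth$alt), ,
                 drop = FALSE]
  out <- truth
  out$expected_vaf <- ifelse(is.na(truth$expected_vaf), ".",
                             formatC(truth$expected_vaf, format = "g",
                                     digits = 12))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
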