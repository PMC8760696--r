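# VCF reading (VariantAnnotation-backed) and a small deterministic VCF writer.
#
# Internal coordinates are 1-based inclusive, i.e. VCF-native: variant keys
# taken from a VCF record are used verbatim.

# Structural pre-scan so malformed records can be reported with their line
# number (the full parse is delegated to VariantAnnotation afterwards).
scan_vcf_structure <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8)
      stop_fmt("malformed VCF record at line %d: expected >= 8 tab-separated fields, got %d",
               i, length(f))
    if (is.na(suppressWarnings(as.integer(f[2]))))
      stop_fmt("malformed VCF record at line %d: POS '%s' is not an integer",
               i, f[2])
    if (!nzchar(f[4]) || !nzchar(f[5]))
      stop_fmt("malformed VCF record at line %d: empty REF/ALT", i)
  }
  invisible(length(body))
}

#' Read a caller's VCF into a call-set data.frame
#'
#' Parses a VCF v4.x file and returns one call per sample-allele.
#' Multi-allelic records are split into one call per alternate allele. VAF is
#' taken from `FORMAT/AF` when present, otherwise derived as `AD/DP`; records
#' offering neither are an error. Optional `INFO` keys `GENE`, `HGVSC`,
#' `HGVSP`, `CSQ` and `FORMAT/CL` (caller of origin), as emitted by
#' [write_callset()], are picked up when present.
#'
#' @param path path to a VCF file.
#' @param caller_label `"small_variant"` or `"structural"`; used for calls
#'   whose records carry no `FORMAT/CL` field.
#' @param check_gene passed to [validate_calls()].
#' @return data.frame with columns `sample_id, chrom, pos, ref, alt, gene,
#'   hgvs_c, hgvs_p, consequence, vaf, depth, alt_reads, caller`, sorted by
#'   chrom, pos, alt, sample_id.
#' @export
read_callset <- function(path, caller_label = c("small_variant", "structural"),
                         check_gene = TRUE) {
  caller_label <- match.arg(caller_label)
  if (!file.exists(path)) stop_fmt("VCF file not found: %s", path)
  scan_vcf_structure(path)
  vcf <- VariantAnnotation::readVcf(path, genome = "GRCh37")
  if (length(vcf) == 0) return(empty_calls())
  vcf <- VariantAnnotation::expand(vcf)
  n <- length(vcf)

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- normalize_chrom(as.character(GenomicRanges::seqnames(rr)))
  pos <- GenomicRanges::start(rr)
  refA <- as.character(VariantAnnotation::ref(vcf))
  altA <- as.character(VariantAnnotation::alt(vcf))

  info <- VariantAnnotation::info(vcf)
  get_info <- function(key) {
    if (key %in% names(info)) {
      v <- as.character(info[[key]])
      ifelse(is.na(v) | v == ".", NA_character_, v)
    } else rep(NA_character_, n)
  }
  gene <- get_info("GENE")
  hgvs_c <- get_info("HGVSC")
  hgvs_p <- get_info("HGVSP")
  csq <- get_info("CSQ")
  csq <- ifelse(is.na(csq), NA_character_, gsub("_", " ", csq, fixed = TRUE))

  g <- VariantAnnotation::geno(vcf)
  if (!any(c("AF", "AD", "DP") %in% names(g)))
    stop_fmt("%s: records carry neither FORMAT/AF nor FORMAT/AD+DP; VAF underivable",
             path)
  samples <- colnames(vcf)
  get_num <- function(field, i, s) {
    if (!(field %in% names(g))) return(NA_real_)
    x <- g[[field]]
    v <- if (length(dim(x)) == 3) x[i, s, 1] else x[i, s]
    if (is.list(v)) v <- v[[1]][1]
    suppressWarnings(as.numeric(v))
  }
  get_ad_alt <- function(i, s) {
    if (!("AD" %in% names(g))) return(NA_real_)
    x <- g[["AD"]]
    v <- if (length(dim(x)) == 3) x[i, s, ] else x[i, s][[1]]
    if (is.list(v)) v <- v[[1]]
    if (length(v) < 2) return(NA_real_)
    suppressWarnings(as.numeric(v[2]))  # after expand(): c(ref, alt)
  }
  get_cl <- function(i, s) {
    if (!("CL" %in% names(g))) return(NA_character_)
    v <- g[["CL"]][i, s]
    if (is.list(v)) v <- v[[1]][1]
    as.character(v)
  }

  out <- vector("list", n * length(samples))
  k <- 0L
  usable <- logical(n)
  for (s in samples) {
    for (i in seq_len(n)) {
      dp <- get_num("DP", i, s)
      af <- get_num("AF", i, s)
      ad_alt <- get_ad_alt(i, s)
      if (is.na(af) && is.na(ad_alt) && is.na(dp)) next  # sample w/o this call
      usable[i] <- TRUE
      if (is.na(af) && (is.na(ad_alt) || is.na(dp)))
        stop_fmt("record %s:%d %s>%s sample %s: no FORMAT/AF and no usable AD/DP",
                 chrom[i], pos[i], refA[i], altA[i], s)
      if (is.na(dp))
        stop_fmt("record %s:%d sample %s: FORMAT/DP missing", chrom[i], pos[i], s)
      vaf <- if (!is.na(af)) af else ad_alt / dp
      alt_reads <- if (!is.na(ad_alt)) ad_alt else round(vaf * dp)
      cl <- get_cl(i, s)
      k <- k + 1L
      out[[k]] <- data.frame(
        sample_id = s, chrom = chrom[i], pos = pos[i], ref = refA[i],
        alt = altA[i], gene = gene[i], hgvs_c = hgvs_c[i], hgvs_p = hgvs_p[i],
        consequence = csq[i], vaf = vaf, depth = as.integer(dp),
        alt_reads = as.integer(alt_reads),
        caller = if (is.na(cl) || cl == ".") caller_label else cl,
        stringsAsFactors = FALSE)
    }
  }
  if (any(!usable))
    stop_fmt("record %s:%d %s>%s: no sample carries FORMAT/AF or AD/DP; VAF underivable",
             chrom[which(!usable)[1]], pos[which(!usable)[1]],
             refA[which(!usable)[1]], altA[which(!usable)[1]])
  if (k == 0) return(empty_calls())
  calls <- order_calls(do.call(rbind, out[seq_len(k)]))
  rownames(calls) <- NULL
  validate_calls(calls, check_gene = check_gene && !anyNA(calls$gene))
  calls
}

#' Write a call set as a deterministic VCF v4.2 file
#'
#' One record per (key, sample-pattern) with per-sample `GT:AD:DP:AF:CL`
#' genotype fields and `INFO` keys `GENE/HGVSC/HGVSP/CSQ` (spaces in
#' consequence terms encoded as underscores). Records are sorted by chrom,
#' pos, alt; sample columns are sorted sample ids. Output is byte-identical
#' across runs on identical input.
#'
#' @param calls call-set data.frame (see [read_callset()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_callset <- function(calls, path) {
  validate_calls(calls, check_gene = FALSE)
  samples <- sort(unique(calls$sample_id))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mpnpanel",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Panel gene symbol\">",
    "##INFO=<ID=HGVSC,Number=1,Type=String,Description=\"Transcript notation\">",
    "##INFO=<ID=HGVSP,Number=1,Type=String,Description=\"Protein notation\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class (spaces as underscores)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Variant allele fraction\">",
    "##FORMAT=<ID=CL,Number=1,Type=String,Description=\"Caller of origin\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  if (nrow(calls) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  calls <- order_calls(calls)
  id <- variant_id(calls$chrom, calls$pos, calls$ref, calls$alt)
  recs <- character(0)
  for (key in unique(id)) {
    rows <- calls[id == key, , drop = FALSE]
    first <- rows[1, ]
    enc <- function(x) if (is.na(x) || !nzchar(x)) "." else x
    info <- paste0("GENE=", enc(first$gene), ";HGVSC=", enc(first$hgvs_c),
                   ";HGVSP=", enc(first$hgvs_p), ";CSQ=",
                   enc(if (is.na(first$consequence)) NA_character_
                       else gsub(" ", "_", first$consequence, fixed = TRUE)))
    cells <- vapply(samples, function(s) {
      r <- rows[rows$sample_id == s, , drop = FALSE]
      if (nrow(r) == 0) return("./.:.:.:.:.")
      r <- r[1, ]
      sprintf("0/1:%d,%d:%d:%s:%s", r$depth - r$alt_reads, r$alt_reads,
              r$depth, formatC(r$vaf, format = "g", digits = 12), r$caller)
    }, character(1))
    recs <- c(recs, paste(c(first$chrom, first$pos, ".", first$ref, first$alt,
                            ".", "PASS", info, "GT:AD:DP:AF:CL", cells),
                          collapse = "\t"))
  }
  writeLines(c(header, recs), path)
  invisible(path)
}
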