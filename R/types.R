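# Shared vocabularies, key helpers and data.frame validators.
#
# Call sets, annotations, truth sets and coverage tables are plain data.frames
# with fixed column sets (the tables a targeted-panel lab actually exchanges);
# validators below enforce the invariants at module boundaries.

#' The 22 panel genes
#'
#' Gene symbols targeted by the myeloid amplicon panel.
#'
#' @return Character vector of 22 gene symbols.
#' @export
panel_genes <- function() {
  c("ABL1", "ASXL1", "CALR", "CBL", "CEBPA", "CSF3R", "DNMT3A", "EZH2",
    "FLT3", "IDH1", "IDH2", "JAK2", "KIT", "MPL", "NPM1", "PDGFRA",
    "RUNX1", "SF3B1", "SRSF2", "TET2", "TP53", "U2AF1")
}

# fixed consequence vocabulary; unknown terms are preserved but treated as
# non-SNV by SNV-specific rules
consequence_levels <- function() {
  c("nSNV", "sSNV", "frameshift insertion", "frameshift deletion",
    "nonframeshift indel", "stopgain", "duplication")
}

region_levels <- function() {
  c("exonic", "splicing", "intronic", "UTR3", "UTR5", "intergenic")
}

clinvar_levels <- function() {
  c("pathogenic", "likely_pathogenic", "VUS", "likely_benign", "benign",
    "absent")
}

#' Map free-text consequence annotation onto the fixed vocabulary
#'
#' Case- and punctuation-insensitive mapping of annotation-style consequence
#' strings (e.g. `"Fs del"`, `"nonsynonymous SNV"`) onto the seven canonical
#' terms. Unrecognised terms are returned unchanged.
#'
#' @param x character vector of consequence strings.
#' @return character vector over the canonical vocabulary (or the input where
#'   unmapped).
#' @export
map_consequence <- function(x) {
  key <- gsub("[^a-z]", "", tolower(x))
  lut <- c(
    nsnv = "nSNV", nonsynonymoussnv = "nSNV",
    ssnv = "sSNV", synonymoussnv = "sSNV",
    frameshiftinsertion = "frameshift insertion", fsins = "frameshift insertion",
    frameshiftdeletion = "frameshift deletion", fsdel = "frameshift deletion",
    nonframeshiftindel = "nonframeshift indel",
    nonframeshiftinsertion = "nonframeshift indel",
    nonframeshiftdeletion = "nonframeshift indel",
    stopgain = "stopgain",
    duplication = "duplication", dup = "duplication"
  )
  out <- unname(lut[key])
  ifelse(is.na(out), x, out)
}

#' Normalize chromosome names to the internal "chrN" convention
#'
#' @param chrom character vector; bare names ("9", "X") are accepted.
#' @return character vector with a "chr" prefix.
#' @export
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

#' Compact string id for a variant key
#'
#' @param chrom,pos,ref,alt components of the variant key (vectors recycled
#'   by data.frame rules).
#' @return character vector "chrom:pos:ref:alt".
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# --- validators ---------------------------------------------------------

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop_fmt("%s is missing required column(s): %s", what,
             paste(missing, collapse = ", "))
  invisible(df)
}

#' Validate a variant key table
#'
#' Checks the key invariants: positive positions, non-empty ACGT alleles,
#' ref != alt.
#'
#' @param keys data.frame with columns chrom, pos, ref, alt.
#' @return the input, invisibly; errors on violation.
#' @export
validate_keys <- function(keys) {
  require_columns(keys, c("chrom", "pos", "ref", "alt"), "variant key table")
  if (nrow(keys) == 0) return(invisible(keys))
  if (any(keys$pos < 1)) stop_fmt("variant key with pos < 1")
  bad <- !grepl("^[ACGT]+$", keys$ref) | !grepl("^[ACGT]+$", keys$alt)
  if (any(bad))
    stop_fmt("allele strings must be non-empty over {A,C,G,T}: %s",
             paste(variant_id(keys$chrom, keys$pos, keys$ref, keys$alt)[bad],
                   collapse = ", "))
  same <- keys$ref == keys$alt
  if (any(same))
    stop_fmt("ref == alt (not a variant) at %s",
             paste(variant_id(keys$chrom, keys$pos, keys$ref, keys$alt)[same],
                   collapse = ", "))
  invisible(keys)
}

call_columns <- function() {
  c("sample_id", "chrom", "pos", "ref", "alt", "gene", "hgvs_c", "hgvs_p",
    "consequence", "vaf", "depth", "alt_reads", "caller")
}

#' Validate a call-set data.frame
#'
#' Enforces the VariantCall invariants: VAF in \[0,1\], alt_reads <= depth,
#' VAF consistent with alt_reads/depth to 0.005, gene in the panel list,
#' caller in \{small_variant, structural\}.
#'
#' @param calls data.frame of calls (see [call_columns][read_callset]).
#' @param check_gene logical; set `FALSE` for synthetic panels with
#'   non-canonical gene labels.
#' @return the input, invisibly.
#' @export
validate_calls <- function(calls, check_gene = TRUE) {
  require_columns(calls, call_columns(), "call set")
  if (nrow(calls) == 0) return(invisible(calls))
  validate_keys(calls)
  if (any(calls$vaf < 0 | calls$vaf > 1)) stop_fmt("vaf outside [0,1]")
  if (any(calls$depth < 0)) stop_fmt("negative depth")
  if (any(calls$alt_reads > calls$depth)) stop_fmt("alt_reads > depth")
  pos_depth <- calls$depth > 0
  dev <- abs(calls$vaf[pos_depth] -
             calls$alt_reads[pos_depth] / calls$depth[pos_depth])
  if (any(dev > 0.005 + 1e-12))
    stop_fmt("vaf inconsistent with alt_reads/depth (tolerance 0.005)")
  if (check_gene && !all(calls$gene %in% panel_genes()))
    stop_fmt("gene(s) outside the 22-gene panel: %s",
             paste(unique(setdiff(calls$gene, panel_genes())), collapse = ", "))
  if (!all(calls$caller %in% c("small_variant", "structural")))
    stop_fmt("caller must be 'small_variant' or 'structural'")
  invisible(calls)
}

annotation_columns <- function() {
  c("chrom", "pos", "ref", "alt", "region_class", "maf_1000g", "maf_exac",
    "maf_esp6500", "maf_gnomad", "dbsnp_id", "dbsnp_exact_allele_match",
    "clinvar_assertion", "cosmic_ids", "cosmic_pathogenic")
}

#' Validate an annotation table
#'
#' @param ann data.frame of annotation records keyed by chrom/pos/ref/alt.
#'   Absent MAFs are `NA` (never zero-filled); `cosmic_ids` is a
#'   comma-separated string, `""` for none.
#' @return the input, invisibly.
#' @export
validate_annotations <- function(ann) {
  require_columns(ann, annotation_columns(), "annotation table")
  if (nrow(ann) == 0) return(invisible(ann))
  validate_keys(ann)
  for (m in c("maf_1000g", "maf_exac", "maf_esp6500", "maf_gnomad")) {
    v <- ann[[m]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop_fmt("%s outside [0,1]", m)
  }
  if (!all(ann$region_class %in% region_levels()))
    stop_fmt("unknown region_class: %s",
             paste(setdiff(unique(ann$region_class), region_levels()),
                   collapse = ", "))
  if (!all(ann$clinvar_assertion %in% clinvar_levels()))
    stop_fmt("unknown clinvar_assertion: %s",
             paste(setdiff(unique(ann$clinvar_assertion), clinvar_levels()),
                   collapse = ", "))
  bad <- ann$cosmic_pathogenic & !nzchar(ann$cosmic_ids)
  if (any(bad))
    stop_fmt("cosmic_pathogenic implies non-empty cosmic_ids")
  invisible(ann)
}

#' Join calls with their annotation records
#'
#' Left join on the variant key; errors if any call lacks an annotation.
#'
#' @param calls call-set data.frame.
#' @param annotations annotation data.frame.
#' @return data.frame of calls with annotation columns appended.
#' @export
annotate_calls <- function(calls, annotations) {
  validate_annotations(annotations)
  cid <- variant_id(calls$chrom, calls$pos, calls$ref, calls$alt)
  aid <- variant_id(annotations$chrom, annotations$pos,
                    annotations$ref, annotations$alt)
  idx <- match(cid, aid)
  if (anyNA(idx))
    stop_fmt("call(s) with no annotation record: %s",
             paste(unique(cid[is.na(idx)]), collapse = ", "))
  ann_cols <- setdiff(annotation_columns(), c("chrom", "pos", "ref", "alt"))
  cbind(calls, annotations[idx, ann_cols, drop = FALSE],
        row.names = NULL)
}

# deterministic call-set ordering used by every writer
order_calls <- function(calls) {
  calls[order(calls$chrom, calls$pos, calls$alt, calls$sample_id), ,
        drop = FALSE]
}

empty_calls <- function() {
  data.frame(sample_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), gene = character(),
             hgvs_c = character(), hgvs_p = character(),
             consequence = character(), vaf = numeric(), depth = integer(),
             alt_reads = integer(), caller = character(),
             stringsAsFactors = FALSE)
}
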