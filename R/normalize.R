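# Trim-based variant normalization.
#
# The two callers emit indels in different paddings (extra shared context on
# either side). Normalization trims shared leading context first (advancing
# the position, always retaining at least one base per allele — the indel
# anchor), then shared trailing context. The fixed point is a right-shifted,
# minimally padded representation; it is idempotent and maps every padding of
# the same event within the padded window to one key. No reference genome is
# consulted, so representations are matched only as far as their own shared
# context allows (full left-alignment would need a FASTA).

#' Normalize a single variant key
#'
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @param ref,alt allele strings over \{A,C,G,T\}.
#' @return list with elements `chrom, pos, ref, alt`.
#' @export
normalize_variant <- function(chrom, pos, ref, alt) {
  out <- normalize_keys(data.frame(chrom = chrom, pos = pos, ref = ref,
                                   alt = alt, stringsAsFactors = FALSE))
  as.list(out[1, c("chrom", "pos", "ref", "alt")])
}

#' Normalize the variant keys of a table
#'
#' Vectorized over rows: trims shared leading context (keeping one anchor
#' base), then shared trailing context. SNVs embedded in padded alleles
#' reduce to the bare substitution; alleles that reduce to identical strings
#' are an error (not a variant).
#'
#' @param df data.frame with columns `chrom, pos, ref, alt` (other columns
#'   are passed through untouched).
#' @return `df` with normalized `pos, ref, alt`.
#' @export
normalize_keys <- function(df) {
  validate_keys(df)
  if (nrow(df) == 0) return(df)
  pos <- as.integer(df$pos)
  ref <- df$ref
  alt <- df$alt
  for (i in seq_len(nrow(df))) {
    r <- strsplit(ref[i], "", fixed = TRUE)[[1]]
    a <- strsplit(alt[i], "", fixed = TRUE)[[1]]
    p <- pos[i]
    # leading shared context; keep >= 1 base in each allele
    while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]; a <- a[-1]; p <- p + 1L
    }
    # trailing shared context; keep >= 1 base in each allele
    while (length(r) > 1 && length(a) > 1 &&
           r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]; a <- a[-length(a)]
    }
    rs <- paste(r, collapse = ""); as <- paste(a, collapse = "")
    if (rs == as)
      stop_fmt("alleles reduce to identical strings at %s:%d %s>%s (not a variant)",
               df$chrom[i], df$pos[i], df$ref[i], df$alt[i])
    pos[i] <- p; ref[i] <- rs; alt[i] <- as
  }
  df$pos <- pos; df$ref <- ref; df$alt <- alt
  df
}

# variant class helpers on (already normalized) keys
is_snv <- function(ref, alt) nchar(ref) == 1 & nchar(alt) == 1
is_insertion <- function(ref, alt) nchar(alt) > nchar(ref)
max_allele_len <- function(ref, alt) pmax(nchar(ref), nchar(alt))
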