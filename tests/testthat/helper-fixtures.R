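# In-code fixtures shared across test files.

# minimal VCF writer for reader tests (independent of write_callset)
tiny_vcf <- function(records, samples = "S1",
                     format_ids = c("GT", "AD", "DP")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  path <- tempfile(fileext = ".vcf")
  writeLines(c(header, records), path)
  path
}

make_call <- function(sample_id = "S1", chrom = "chr1", pos = 100L,
                      ref = "A", alt = "T", gene = "JAK2", vaf = 0.5,
                      depth = 1000L, caller = "small_variant",
                      consequence = "nSNV") {
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, gene = gene, hgvs_c = NA_character_,
             hgvs_p = NA_character_, consequence = consequence, vaf = vaf,
             depth = depth, alt_reads = as.integer(round(vaf * depth)),
             caller = caller, stringsAsFactors = FALSE)
}

make_annotation <- function(chrom = "chr1", pos = 100L, ref = "A",
                            alt = "T", region = "exonic",
                            maf_1000g = NA_real_, maf_exac = NA_real_,
                            maf_esp6500 = NA_real_, maf_gnomad = NA_real_,
                            dbsnp = NA_character_, exact = FALSE,
                            clinvar = "absent", cosmic = "",
                            cosmic_path = FALSE) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             region_class = region, maf_1000g = maf_1000g,
             maf_exac = maf_exac, maf_esp6500 = maf_esp6500,
             maf_gnomad = maf_gnomad, dbsnp_id = dbsnp,
             dbsnp_exact_allele_match = exact, clinvar_assertion = clinvar,
             cosmic_ids = cosmic, cosmic_pathogenic = cosmic_path,
             stringsAsFactors = FALSE)
}

# random cohort of SNV occurrences with annotations, for property tests;
# keys are pre-normalized SNVs so oracles stay simple
random_cohort <- function(seed, max_occurrences = 100) {
  set.seed(seed)
  n_samples <- sample(3:8, 1)
  samples <- sprintf("P%02d", seq_len(n_samples))
  n_keys <- sample(5:30, 1)
  pos <- sample(1000:99999, n_keys)
  ref <- c("A", "C", "G", "T")[(pos %% 4) + 1]
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  maf_draw <- function(n) ifelse(runif(n) < 0.35, runif(n, 0, 0.05),
                                 NA_real_)
  ann <- data.frame(
    chrom = "chr7", pos = pos, ref = ref, alt = alt,
    region_class = sample(c("exonic", "intronic", "splicing", "UTR3"),
                          n_keys, replace = TRUE,
                          prob = c(0.6, 0.2, 0.1, 0.1)),
    maf_1000g = maf_draw(n_keys), maf_exac = maf_draw(n_keys),
    maf_esp6500 = maf_draw(n_keys), maf_gnomad = maf_draw(n_keys),
    dbsnp_id = NA_character_,
    dbsnp_exact_allele_match = runif(n_keys) < 0.4,
    clinvar_assertion = sample(c("absent", "pathogenic",
                                 "likely_pathogenic", "benign", "VUS"),
                               n_keys, replace = TRUE,
                               prob = c(0.6, 0.1, 0.1, 0.1, 0.1)),
    cosmic_ids = ifelse(runif(n_keys) < 0.3,
                        sprintf("COSMT%05d", seq_len(n_keys)), ""),
    stringsAsFactors = FALSE)
  ann$cosmic_pathogenic <- nzchar(ann$cosmic_ids) & runif(n_keys) < 0.5
  calls <- list()
  for (i in seq_len(n_keys)) {
    carriers <- sample(samples, sample(seq_len(n_samples), 1))
    for (s in carriers) {
      calls[[length(calls) + 1]] <- make_call(
        sample_id = s, chrom = "chr7", pos = pos[i], ref = ref[i],
        alt = alt[i], gene = "EZH2", vaf = round(runif(1, 0.005, 0.9), 4),
        depth = 5000L)
    }
  }
  calls <- do.call(rbind, calls)
  if (nrow(calls) > max_occurrences)
    calls <- calls[seq_len(max_occurrences), , drop = FALSE]
  list(calls = calls, annotations = ann, n_samples = n_samples,
       samples = samples)
}
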