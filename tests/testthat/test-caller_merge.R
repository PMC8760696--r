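test_that("normalization reduces padded representations to one fixed point", {
  # embedded SNV
  expect_equal(normalize_variant("chr4", 100, "ATG", "ACG"),
               list(chrom = "chr4", pos = 101L, ref = "T", alt = "C"))
  # non-variant
  expect_error(normalize_variant("chr9", 200, "C", "C"), "not a variant")
  # two paddings of the same 2-base insertion agree
  a <- normalize_variant("chr20", 300, "GAA", "GAAAA")
  b <- normalize_variant("chr20", 302, "A", "AAA")
  expect_equal(a, b)
})

test_that("paddings of a 2-base insertion reduce to a single fixed point", {
  # event: insertion of "AA" after the G A A run ending at position 302.
  # left-context paddings (the representations two callers produce when
  # they anchor the same event at different upstream bases) must unify
  base_ref <- "A"; base_alt <- "AAA"; base_pos <- 302L
  left_pads <- list()
  for (l in c("", "A", "GA", "CGA")) {
    left_pads[[length(left_pads) + 1]] <- normalize_variant(
      "chr20", base_pos - nchar(l), paste0(l, base_ref),
      paste0(l, base_alt))
  }
  for (r in left_pads) expect_equal(r, left_pads[[1]])
  expect_equal(left_pads[[1]],
               list(chrom = "chr20", pos = 302L, ref = "A", alt = "AAA"))

  # trailing-context paddings right-shift further (trim-only normalization
  # cannot re-anchor them without a reference); they still reach one fixed
  # point among themselves, idempotent, with the inserted length preserved
  right_pads <- list()
  for (l in c("", "A", "GA")) {
    right_pads[[length(right_pads) + 1]] <- normalize_variant(
      "chr20", base_pos - nchar(l), paste0(l, base_ref, "TT"),
      paste0(l, base_alt, "TT"))
  }
  for (r in right_pads) {
    expect_equal(r, right_pads[[1]])
    expect_equal(nchar(r$alt) - nchar(r$ref), 2)
    expect_equal(r, do.call(normalize_variant, r))  # idempotent
  }
})

test_that("normalization is idempotent on random padded indels", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  for (i in 1:1000) {
    core_ins <- paste(sample(bases, sample(1:6, 1), replace = TRUE),
                      collapse = "")
    anchor <- sample(bases, 1)
    left <- paste(sample(bases, sample(0:3, 1), replace = TRUE),
                  collapse = "")
    right <- paste(sample(bases, sample(0:3, 1), replace = TRUE),
                   collapse = "")
    ref <- paste0(left, anchor, right)
    alt <- paste0(left, anchor, core_ins, right)
    n1 <- normalize_variant("chr1", 5000L, ref, alt)
    n2 <- normalize_variant(n1$chrom, n1$pos, n1$ref, n1$alt)
    expect_identical(n1, n2)
    # insertion length is invariant under normalization
    expect_equal(nchar(n1$alt) - nchar(n1$ref), nchar(core_ins))
  }
})

test_that("merge unions by normalized key with size-aware VAF precedence", {
  snv <- make_call("S1", "chr9", 5073770L, "G", "T", gene = "JAK2",
                   vaf = 0.88, depth = 5000L)
  merged <- merge_callsets(snv, snv[0, ])
  expect_equal(nrow(merged$calls), 1)
  expect_equal(merged$calls$callers, "small_variant")

  big_dup <- make_call("S1", "chr13", 28608249L, "C",
                       paste0("C", strrep("TG", 21)), gene = "FLT3",
                       vaf = 0.3, depth = 4000L, caller = "structural",
                       consequence = "duplication")
  merged <- merge_callsets(big_dup[0, ], big_dup)
  expect_equal(nrow(merged$calls), 1)
  expect_equal(merged$calls$callers, "structural")

  # 52-base deletion seen by both callers: structural VAF wins (> 25 bases)
  del <- paste0("A", strrep("CT", 26))
  both_s <- make_call("S1", "chr19", 13054555L, del, "A", gene = "CALR",
                      vaf = 0.10, depth = 5000L,
                      consequence = "frameshift deletion")
  both_p <- both_s; both_p$vaf <- 0.11
  both_p$alt_reads <- as.integer(0.11 * 5000); both_p$caller <- "structural"
  merged <- merge_callsets(both_s, both_p)
  expect_equal(nrow(merged$calls), 1)
  expect_equal(merged$calls$vaf, 0.11)
  expect_equal(merged$calls$callers, "small_variant,structural")
  expect_equal(merged$merge_log$vaf_from, "structural")

  # small indel seen by both: small-variant VAF wins
  small_both <- merge_callsets(
    make_call("S1", "chr2", 100L, "A", "AT", vaf = 0.2, depth = 1000L),
    make_call("S1", "chr2", 100L, "A", "AT", vaf = 0.25, depth = 1000L,
              caller = "structural"))
  expect_equal(small_both$calls$vaf, 0.2)

  expect_error(merge_callsets(make_call("S1"), make_call("S2", pos = 200L)),
               "different samples")
})

test_that("merged key set equals the brute-force union of normalized keys", {
  set.seed(23)
  bases <- c("A", "C", "G", "T")
  for (trial in 1:100) {
    n_small <- sample(0:20, 1); n_str <- sample(0:20, 1)
    mk <- function(n, caller) {
      if (n == 0) return(make_call()[0, ])
      do.call(rbind, lapply(seq_len(n), function(i) {
        pos <- sample(100:2000, 1)
        if (runif(1) < 0.5) {
          ref <- sample(bases, 1)
          alt <- sample(setdiff(bases, ref), 1)
        } else {
          anchor <- sample(bases, 1)
          ref <- anchor
          alt <- paste0(anchor, paste(sample(bases, sample(1:30, 1),
                                             replace = TRUE),
                                      collapse = ""))
        }
        make_call("SX", "chr5", pos, ref, alt, vaf = round(runif(1), 3),
                  depth = 1000L, caller = caller)
      }))
    }
    small <- mk(n_small, "small_variant")
    str <- mk(n_str, "structural")
    merged <- merge_callsets(small, str)
    norm_union <- unique(c(
      if (nrow(small)) with(normalize_keys(small),
                            paste(chrom, pos, ref, alt)),
      if (nrow(str)) with(normalize_keys(str),
                          paste(chrom, pos, ref, alt))))
    got <- with(merged$calls, paste(chrom, pos, ref, alt))
    expect_setequal(got, norm_union)
    # content-commutativity: input row order changes nothing
    shuf <- merge_callsets(small[sample(nrow(small)), , drop = FALSE],
                           str[sample(nrow(str)), , drop = FALSE])
    expect_identical(merged$calls, shuf$calls)
  }
})
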