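test_that("call/truth matching tolerates shifted insertion anchors", {
  snv <- list(chrom = "chr9", pos = 5073770L, ref = "G", alt = "T")
  expect_true(match_call_to_truth(snv, snv))
  expect_false(match_call_to_truth(snv, list(chrom = "chr9", pos = 5073771L,
                                             ref = "G", alt = "T")))
  # 42-base duplication represented at shifted anchors: exhaustive 0-10
  ins <- paste0("C", strrep("AG", 21))
  truth <- list(chrom = "chr13", pos = 28608249L, ref = "C", alt = ins)
  for (shift in 0:10) {
    call <- list(chrom = "chr13", pos = 28608249L - shift, ref = "A",
                 alt = paste0("A", strrep("GA", 21)))
    expect_equal(match_call_to_truth(call, truth), shift <= 5,
                 info = paste("shift", shift))
  }
  # SNV at a truth indel locus is never a match
  expect_false(match_call_to_truth(
    list(chrom = "chr13", pos = 28608249L, ref = "C", alt = "T"), truth))
  # deletions do not use the anchor tolerance
  expect_false(match_call_to_truth(
    list(chrom = "chr13", pos = 28608248L, ref = "CA", alt = "C"),
    list(chrom = "chr13", pos = 28608249L, ref = "AG", alt = "A")))
})

truth_calls <- function(tv, sample_id, drop_hgvs = NULL) {
  tv <- tv[!(tv$hgvs_p %in% drop_hgvs), , drop = FALSE]
  if (nrow(tv) == 0) return(make_call()[0, ])
  do.call(rbind, lapply(seq_len(nrow(tv)), function(i)
    make_call(sample_id, tv$chrom[i], tv$pos[i], tv$ref[i], tv$alt[i],
              gene = tv$gene[i], vaf = tv$expected_vaf[i], depth = 5000L)))
}

test_that("detection matrices mark truth cells and collect off-truth calls", {
  std <- generate_reference_standards(sim_config())
  sera <- std$truth[std$truth$standard_id == "SeraseqMyeloid", ]
  reps <- list(
    r1 = list(standard_id = "SeraseqMyeloid", run_id = "run1",
              calls = truth_calls(sera, "r1", drop_hgvs = "p.W515L")),
    r2 = list(standard_id = "TruQ0", run_id = "run1",
              calls = make_call("r2", "chr17", 7577050L, "A", "G",
                                gene = "TP53", vaf = 0.02, depth = 5000L)),
    r3 = list(standard_id = "TruQ7", run_id = "run1",
              calls = make_call()[0, ]))
  m <- build_detection_matrix(std$truth, reps, standards = std$standards)
  r1 <- m$cells[m$cells$replicate_id == "r1", ]
  expect_equal(sum(r1$detected), 19)          # 19/20, W515L missed
  expect_false(r1$detected[r1$hgvs_p == "p.W515L"])
  expect_equal(nrow(m$cells[m$cells$replicate_id == "r2", ]), 0)
  expect_equal(nrow(m$off_truth), 1)          # the TruQ0 false positive
  r3 <- m$cells[m$cells$replicate_id == "r3", ]
  expect_equal(nrow(r3), 9)                   # empty callset: 9 misses
  expect_false(any(r3$detected))

  bad <- list(x = list(standard_id = "NotAStandard", run_id = "run1",
                       calls = make_call()[0, ]))
  expect_error(build_detection_matrix(std$truth, bad,
                                      standards = std$standards),
               "unknown standard")
})

test_that("confusion counts follow the cross-standard negative-site convention", {
  std <- generate_reference_standards(sim_config())
  reps <- list(
    r1 = list(standard_id = "TruQ1", run_id = "run1",
              calls = truth_calls(std$truth[std$truth$standard_id ==
                                            "TruQ1", ], "r1")))
  m <- build_detection_matrix(std$truth, reps, standards = std$standards)
  conf <- compute_confusion(m)
  expect_equal(conf$tp, 3)
  expect_equal(conf$fn, 0)
  expect_equal(conf$fp, 0)
  expect_equal(conf$tn, 23)  # 26-variant union minus TruQ1's own 3
  expect_equal(conf$sensitivity, 1)
  expect_equal(conf$ppv, 1)
  # an off-truth call landing on a negative site converts a tn into an fp
  reps$r1$calls <- rbind(reps$r1$calls, truth_calls(
    std$truth[std$truth$hgvs_p == "p.D816V", ], "r1"))
  m2 <- build_detection_matrix(std$truth, reps, standards = std$standards)
  conf2 <- compute_confusion(m2)
  expect_equal(conf2$fp, 1)
  expect_equal(conf2$tn, 22)
})

test_that("per-app counting respects caller eligibility", {
  tv <- data.frame(standard_id = "STD", chrom = "chr1",
                   pos = c(100L, 200L, 300L),
                   ref = c("A", "C", "G"),
                   alt = c("T", paste0("C", "AT"),
                           paste0("G", strrep("TA", 15))),
                   gene = "MPL", hgvs_p = c("snv", "small_ins", "big_ins"),
                   expected_vaf = 0.1, stringsAsFactors = FALSE)
  calls <- rbind(
    make_call("r1", "chr1", 100L, "A", "T", gene = "MPL", vaf = 0.1,
              depth = 1000L),
    make_call("r1", "chr1", 200L, "C", "CAT", gene = "MPL", vaf = 0.1,
              depth = 1000L),
    make_call("r1", "chr1", 300L, "G", paste0("G", strrep("TA", 15)),
              gene = "MPL", vaf = 0.1, depth = 1000L,
              caller = "structural"))
  merged <- merge_callsets(calls[calls$caller == "small_variant", ],
                           calls[calls$caller == "structural", ])
  # the small insertion was only seen by the small caller
  reps <- list(r1 = list(standard_id = "STD", run_id = "run1",
                         calls = merged$calls))
  m <- build_detection_matrix(tv, reps)
  merged_conf <- compute_confusion(m, counting = "merged")
  expect_equal(c(merged_conf$tp, merged_conf$fn), c(3, 0))
  app_conf <- compute_confusion(m, counting = "per_app")
  # opportunities: snv 1 (small), small_ins 2 (both), big_ins 1 (structural)
  # detected: snv by small, small_ins by small only, big_ins by structural
  expect_equal(app_conf$tp, 3)
  expect_equal(app_conf$fn, 1)
})

test_that("concordance is a bounded symmetric Jaccard with empty-set identity", {
  expect_equal(concordance(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(concordance(character(0), character(0)), 1.0)
  expect_equal(concordance(c("a"), c("b")), 0.0)
  expect_equal(concordance(letters[1:20], letters[1:21]), 20 / 21)
  set.seed(5)
  for (i in 1:50) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(0:10, 1))
    j <- concordance(a, b)
    expect_identical(j, concordance(b, a))
    expect_gte(j, 0); expect_lte(j, 1)
    expect_identical(j == 1, setequal(a, b))
  }
  expect_equal(concordance(c("a"), c("a", "b"), method = "both_detected",
                           n_truth = 4), 0.25)
  expect_error(concordance("a", "a", method = "both_detected"), "n_truth")
})

test_that("limit of detection reports the lowest fully detected tier", {
  mk_matrix <- function(detect_13) {
    std <- generate_reference_standards(sim_config())
    tq7 <- std$truth[std$truth$standard_id == "TruQ7", ]
    tq1 <- std$truth[std$truth$standard_id == "TruQ1", ]
    reps <- list(
      q7 = list(standard_id = "TruQ7", run_id = "run1",
                calls = truth_calls(tq7, "q7",
                                    drop_hgvs = if (detect_13) NULL
                                                else "p.D816V")),
      q1 = list(standard_id = "TruQ1", run_id = "run1",
                calls = truth_calls(tq1, "q1")))
    build_detection_matrix(std$truth, reps, standards = std$standards)
  }
  lod_all <- limit_of_detection(mk_matrix(TRUE))
  expect_equal(lod_all$lod_vaf, 0.013)
  expect_equal(lod_all$analysis_floor, 0.01)
  lod_miss <- limit_of_detection(mk_matrix(FALSE))
  expect_equal(lod_miss$lod_vaf, 0.05)   # 1.3% tier incomplete
  # no tiers at all
  m <- mk_matrix(TRUE); m$cells$expected_vaf <- NA_real_
  expect_error(limit_of_detection(m), "no expected_vaf tiers")
})

test_that("removing a detected cell strictly lowers sensitivity, never raises a metric", {
  std <- generate_reference_standards(sim_config())
  sera <- std$truth[std$truth$standard_id == "SeraseqMyeloid", ]
  full <- list(r1 = list(standard_id = "SeraseqMyeloid", run_id = "run1",
                         calls = truth_calls(sera, "r1")))
  m_full <- build_detection_matrix(std$truth, full,
                                   standards = std$standards)
  c_full <- compute_confusion(m_full)
  drop1 <- list(r1 = list(standard_id = "SeraseqMyeloid", run_id = "run1",
                          calls = truth_calls(sera, "r1",
                                              drop_hgvs = "p.T315I")))
  m_drop <- build_detection_matrix(std$truth, drop1,
                                   standards = std$standards)
  c_drop <- compute_confusion(m_drop)
  expect_lt(c_drop$sensitivity, c_full$sensitivity)
  expect_lte(c_drop$specificity, c_full$specificity)
  expect_lte(c_drop$ppv, c_full$ppv)
})
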