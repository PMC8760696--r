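test_that("region filter keeps exonic variants only", {
  calls <- rbind(make_call("S1", pos = 100L),
                 make_call("S1", pos = 200L, ref = "C", alt = "G"),
                 make_call("S1", pos = 300L, ref = "G", alt = "A"))
  ann <- rbind(make_annotation(pos = 100L),
               make_annotation(pos = 200L, ref = "C", alt = "G",
                               region = "intronic"),
               make_annotation(pos = 300L, ref = "G", alt = "A",
                               region = "splicing"))
  out <- filter_region(calls, ann)
  expect_equal(out$kept$pos, 100)
  expect_setequal(out$excluded$pos, c(200, 300))  # splicing excluded too
  expect_error(filter_region(make_call("S1", pos = 999L), ann),
               "no annotation")
})

test_that("population filter excludes on any database at >= 1%", {
  calls <- rbind(make_call("S1", pos = 1L, ref = "A", alt = "C"),
                 make_call("S1", pos = 2L, ref = "A", alt = "C"),
                 make_call("S1", pos = 3L, ref = "A", alt = "C"))
  ann <- rbind(
    make_annotation(pos = 1L, ref = "A", alt = "C", maf_gnomad = 0.034),
    make_annotation(pos = 2L, ref = "A", alt = "C"),  # all absent
    make_annotation(pos = 3L, ref = "A", alt = "C", maf_1000g = 0.009,
                    maf_exac = 0.012))
  out <- filter_population(calls, ann)
  expect_setequal(out$excluded$pos, c(1, 3))  # any-database rule
  expect_equal(out$kept$pos, 2)               # absence never excludes
  # boundary: exactly 1% is excluded
  b <- filter_population(make_call("S1", pos = 4L),
                         make_annotation(pos = 4L, maf_exac = 0.01))
  expect_equal(nrow(b$excluded), 1)
})

test_that("artifact filter applies VAF and recurrence clauses with the pathogenicity exemption", {
  samples <- sprintf("S%d", 1:10)
  # recurrent driver with COSMIC evidence in 7/10 samples
  driver <- do.call(rbind, lapply(samples[1:7], function(s)
    make_call(s, pos = 10L, vaf = 0.5, depth = 5000L)))
  # recurrent systematic artifact in 8/10 samples, no evidence
  sys <- do.call(rbind, lapply(samples[1:8], function(s)
    make_call(s, pos = 20L, ref = "C", alt = "T", vaf = 0.08,
              depth = 5000L)))
  singles <- rbind(
    make_call("S1", pos = 30L, ref = "G", alt = "C", vaf = 0.098,
              depth = 5000L),
    make_call("S2", pos = 40L, ref = "T", alt = "A", vaf = 0.014,
              depth = 5000L))
  ann <- rbind(
    make_annotation(pos = 10L, clinvar = "pathogenic",
                    cosmic = "COSM12600", cosmic_path = TRUE),
    make_annotation(pos = 20L, ref = "C", alt = "T"),
    make_annotation(pos = 30L, ref = "G", alt = "C"),
    make_annotation(pos = 40L, ref = "T", alt = "A", cosmic = "COSM97191",
                    cosmic_path = TRUE))
  calls <- rbind(driver, sys, singles)
  out <- filter_artifacts(calls, ann, n_samples = 10)
  expect_equal(sum(out$kept$pos == 10), 7)     # exempted despite 7/10
  expect_equal(sum(out$excluded$pos == 20), 8) # recurrent, no evidence
  expect_true(30 %in% out$kept$pos)            # 9.8%, not recurrent
  expect_true(40 %in% out$excluded$pos)        # VAF 1.4% < 5%
  expect_error(filter_artifacts(calls[0, ], ann), "empty cohort")
})

test_that("rescue lane admits only asserted-pathogenic calls in [1%, 5%)", {
  ex <- rbind(
    cbind(make_call("S1", pos = 1L, vaf = 0.014, depth = 5000L),
          make_annotation(pos = 1L, cosmic = "COSM97191",
                          cosmic_path = TRUE)[, -(1:4)]),
    cbind(make_call("S1", pos = 2L, ref = "C", alt = "A", vaf = 0.02,
                    depth = 5000L),
          make_annotation(pos = 2L, ref = "C", alt = "A")[, -(1:4)]),
    cbind(make_call("S1", pos = 3L, ref = "G", alt = "A", vaf = 0.006,
                    depth = 5000L),
          make_annotation(pos = 3L, ref = "G", alt = "A",
                          clinvar = "pathogenic")[, -(1:4)]))
  rescued <- rescue_pathogenic(ex)
  expect_equal(rescued$pos, 1)   # 2: no evidence; 3: below the 1% floor
  # boundary: exactly 5% is outside the rescue window
  ex5 <- ex[1, ]; ex5$vaf <- 0.05
  expect_equal(nrow(rescue_pathogenic(ex5)), 0)
})

test_that("novelty requires exact-allele absence from all three databases", {
  ann <- rbind(
    make_annotation(pos = 1L),                                  # nothing
    make_annotation(pos = 2L, dbsnp = "rs750318549", exact = FALSE),
    make_annotation(pos = 3L, dbsnp = "rs371246226", exact = TRUE,
                    clinvar = "likely_pathogenic", cosmic = "COSM211534"),
    make_annotation(pos = 4L, cosmic = "COSM5985669"))
  expect_equal(classify_novelty(ann),
               c("putative_novel", "putative_novel", "reported",
                 "reported"))
})

test_that("Sanger flag is inclusive at the 15% boundary", {
  expect_equal(flag_sanger(c(0.159, 0.121, 0.15, 0.149)),
               c(TRUE, FALSE, TRUE, FALSE))
})

test_that("run_triage partitions every occurrence exactly once", {
  for (seed in c(101, 202, 303)) {
    rc <- random_cohort(seed)
    res <- run_triage(rc$calls, rc$annotations)
    dec <- res$decisions
    expect_equal(nrow(dec), nrow(rc$calls))
    occ <- paste(dec$sample_id, dec$chrom, dec$pos, dec$ref, dec$alt)
    expect_false(any(duplicated(occ)))
    expect_true(all(dec$status %in% c(
      "retained", "rescued_pathogenic", "excluded_region",
      "excluded_common", "excluded_artifact")))
    # novelty assessed only for retained/rescued
    assessed <- dec$status %in% c("retained", "rescued_pathogenic")
    expect_true(all(dec$novelty[!assessed] == "not_assessed"))
    expect_true(all(dec$novelty[assessed] != "not_assessed"))
    # sanger_eligible implies VAF >= 0.15
    expect_true(all(dec$vaf[dec$sanger_eligible] >= 0.15))
    # summary consistency
    s <- res$summary
    expect_lte(s$n_retained + s$n_rescued, s$n_after_region_and_maf)
    expect_lte(s$n_after_region_and_maf, s$n_input_unique)
  }
})

test_that("rescued variants always carry window VAF and pathogenic assertion", {
  for (seed in 1:20) {
    rc <- random_cohort(seed)
    res <- run_triage(rc$calls, rc$annotations)
    resc <- res$decisions[res$decisions$status == "rescued_pathogenic", ,
                          drop = FALSE]
    if (nrow(resc) == 0) next
    expect_true(all(resc$vaf >= 0.01 & resc$vaf < 0.05))
    aid <- with(rc$annotations, paste(chrom, pos, ref, alt))
    a <- rc$annotations[match(paste(resc$chrom, resc$pos, resc$ref,
                                    resc$alt), aid), ]
    expect_true(all(a$clinvar_assertion %in%
                    c("pathogenic", "likely_pathogenic") |
                    a$cosmic_pathogenic))
  }
})

test_that("adding an unrelated variant never changes other statuses", {
  rc <- random_cohort(77)
  res1 <- run_triage(rc$calls, rc$annotations)
  extra_call <- make_call(rc$calls$sample_id[1], "chr7", 999999L, "A", "G",
                          gene = "EZH2", vaf = 0.4, depth = 5000L)
  extra_ann <- make_annotation("chr7", 999999L, "A", "G")
  res2 <- run_triage(rbind(rc$calls, extra_call),
                     rbind(rc$annotations, extra_ann))
  d1 <- res1$decisions
  d2 <- res2$decisions[!(res2$decisions$pos == 999999), ]
  k1 <- paste(d1$sample_id, d1$pos, d1$alt)
  k2 <- paste(d2$sample_id, d2$pos, d2$alt)
  expect_identical(d1$status, d2$status[match(k1, k2)])
})
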