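# Synthetic-data generation: panels, reference-standard truth sets,
# GC-dependent coverage, binomially sampled call sets, and an MPN-like
# clinical cohort with known ground truth. Everything is deterministic given
# the config seed.

#' Simulation configuration
#'
#' Defaults encode the assay being emulated: a 22-gene, 219-amplicon panel
#' sequenced to a 5000x target depth with a 1% somatic VAF analysis floor,
#' validated on four reference standards, and a 10-sample MPN cohort with 7
#' JAK2-like SNV drivers and 3 CALR-like frameshift drivers.
#'
#' @param seed integer seed; identical configs give byte-identical outputs.
#' @param n_samples cohort size (default 10).
#' @param driver_mix named counts `c(jak2_snv = 7, calr_fs = 3)`.
#' @param target_depth per-amplicon depth target (default 5000).
#' @param depth_dispersion lognormal sigma of depth noise (default 0.3).
#' @param gc_midpoint,gc_width logistic GC-dropout parameters: the depth
#'   multiplier is `plogis((gc_midpoint - gc) / gc_width)` rescaled so a
#'   0.45-GC amplicon sits at ~1. Width default 0.006 (a 0.61-GC amplicon
#'   drops to ~33x while amplicons at or below 0.57 GC stay above ~4000x).
#' @param error_artifact_rate per-sample Poisson mean of random low-VAF
#'   error calls (default 3).
#' @param artifact_vaf_beta Beta(a, b) shape of artifact VAFs,
#'   default `c(1.2, 60)`.
#' @param artifact_vaf_max noise-floor truncation of artifact VAFs
#'   (rejection sampling), default 0.04 — artifacts live strictly below the
#'   5% somatic retention threshold.
#' @param n_systematic_artifacts number of cohort-recurrent artifact keys
#'   (default 2).
#' @param systematic_artifact_fraction fraction of samples carrying each
#'   systematic artifact (default 0.8).
#' @param germline_het_count germline heterozygous polymorphisms per sample
#'   (default 15).
#' @param min_alt_reads caller detection floor in alternate reads
#'   (default 4: at 5000x the 1% VAF floor is the binding constraint).
#' @param vaf_floor somatic VAF detection limit (default 0.01).
#' @return named list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_samples = 10L,
                       driver_mix = c(jak2_snv = 7L, calr_fs = 3L),
                       target_depth = 5000, depth_dispersion = 0.3,
                       gc_midpoint = 0.58, gc_width = 0.006,
                       error_artifact_rate = 3,
                       artifact_vaf_beta = c(1.2, 60),
                       artifact_vaf_max = 0.04,
                       n_systematic_artifacts = 2L,
                       systematic_artifact_fraction = 0.8,
                       germline_het_count = 15L,
                       min_alt_reads = 4L, vaf_floor = 0.01) {
  stopifnot(seed == as.integer(seed), n_samples >= 1,
            all(driver_mix >= 0), sum(driver_mix) <= n_samples,
            target_depth > 0, depth_dispersion >= 0,
            gc_width > 0, error_artifact_rate >= 0,
            artifact_vaf_max > 0, artifact_vaf_max < 1,
            systematic_artifact_fraction >= 0,
            systematic_artifact_fraction <= 1,
            vaf_floor >= 0, vaf_floor <= 1)
  structure(list(
    seed = as.integer(seed), n_samples = as.integer(n_samples),
    driver_mix = driver_mix, target_depth = target_depth,
    depth_dispersion = depth_dispersion, gc_midpoint = gc_midpoint,
    gc_width = gc_width, error_artifact_rate = error_artifact_rate,
    artifact_vaf_beta = artifact_vaf_beta,
    artifact_vaf_max = artifact_vaf_max,
    n_systematic_artifacts = as.integer(n_systematic_artifacts),
    systematic_artifact_fraction = systematic_artifact_fraction,
    germline_het_count = as.integer(germline_het_count),
    min_alt_reads = as.integer(min_alt_reads), vaf_floor = vaf_floor),
    class = "sim_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)
  expr
}

# GC-dependent depth multiplier, rescaled so a 0.45-GC amplicon sits at ~1
gc_multiplier <- function(gc, midpoint = 0.58, width = 0.006) {
  stats::plogis((midpoint - gc) / width) /
    stats::plogis((midpoint - 0.45) / width)
}

# fixed gene layout: chromosome + base coordinate of each gene's first
# amplicon; JAK2/CALR/MPL/FLT3 anchored near their GRCh37 hotspots so the
# fixed hotspot keys below fall inside amplicon interiors
gene_layout <- function() {
  data.frame(
    gene = c("ABL1", "ASXL1", "CALR", "CBL", "CEBPA", "CSF3R", "DNMT3A",
             "EZH2", "FLT3", "IDH1", "IDH2", "JAK2", "KIT", "MPL", "NPM1",
             "PDGFRA", "RUNX1", "SF3B1", "SRSF2", "TET2", "TP53", "U2AF1"),
    chrom = c("chr9", "chr20", "chr19", "chr11", "chr19", "chr1", "chr2",
              "chr7", "chr13", "chr2", "chr15", "chr9", "chr4", "chr1",
              "chr5", "chr4", "chr21", "chr2", "chr17", "chr4", "chr17",
              "chr21"),
    base = as.integer(c(
      133730000, 31022000, 13054400, 119148000, 33792000, 36931000,
      25457000, 148504000, 28608100, 209113000, 90631000, 5073650,
      55593000, 43814902, 170814000, 55141000, 36206000, 198266000,
      74732000, 106155000, 7577000, 44514000)),
    stringsAsFactors = FALSE)
}

# amplicon geometry constants
.amp_spacing <- 300L

#' Generate the synthetic 22-gene, 219-amplicon panel
#'
#' Fixed geometry (gene anchors, 300-base spacing) with seeded amplicon
#' lengths (150-250) and GC contents. GC is drawn from a two-component
#' mixture: a truncated normal bulk (mean 0.48, capped at 0.56) plus a
#' small high-GC tail (8% of amplicons, uniform on 0.55-0.585, sitting on
#' the logistic dropout slope but above the 1000x warn threshold). Three
#' amplicons are forced into the dropout tail proper: one MPL-exon-10
#' analogue at GC 0.61 (critical dropout) and two warn-band analogues
#' (DNMT3A exon 17 at 0.590, TP53 exon 4/5 at 0.595).
#'
#' @param config a [sim_config()].
#' @return list with `panel` (data.frame `amplicon_id, chrom, start, end,
#'   gene, exon_label`) and `gc` (named vector of per-amplicon GC
#'   fractions).
#' @export
generate_panel <- function(config = sim_config()) {
  with_seed(config$seed + 101L, {
    layout <- gene_layout()
    n_per_gene <- c(rep(10L, 21), 9L)  # 219 amplicons
    rows <- list(); gcs <- numeric(0)
    idx <- 0L
    for (g in seq_len(nrow(layout))) {
      for (k in seq_len(n_per_gene[g])) {
        idx <- idx + 1L
        id <- sprintf("AMPL%05d", idx)
        start <- layout$base[g] + (k - 1L) * .amp_spacing
        len <- sample(150:250, 1)
        gc <- if (runif(1) < 0.08) runif(1, 0.55, 0.585) else
          min(0.56, max(0.30, rnorm(1, 0.48, 0.035)))
        exon <- sprintf("%s exon region %d", layout$gene[g], k)
        if (layout$gene[g] == "MPL" && k == 1L) {
          len <- 202L; gc <- 0.61
          exon <- "MPL exon 10 (high-GC dropout analogue)"
        } else if (layout$gene[g] == "DNMT3A" && k == 5L) {
          gc <- 0.590
          exon <- "DNMT3A exon 17 (warn-band analogue)"
        } else if (layout$gene[g] == "TP53" && k == 4L) {
          gc <- 0.595
          exon <- "TP53 exon 4/5 (warn-band analogue)"
        }
        rows[[idx]] <- data.frame(
          amplicon_id = id, chrom = layout$chrom[g], start = start,
          end = start + len - 1L, gene = layout$gene[g], exon_label = exon,
          stringsAsFactors = FALSE)
        gcs[id] <- gc
      }
    }
    list(panel = do.call(rbind, rows), gc = gcs)
  })
}

# deterministic filler sequence for synthetic indel alleles
.filler <- paste0("TTGTCAGCCATGGTACGGACTTGTCAGCCATGGTACGGAC",
                  "TATGTCCGAAGGTTCAACGGTATGTCCGAAGGTTCAACGG")
synth_seq <- function(n, offset = 0) {
  substr(strrep(.filler, ceiling((n + offset) / nchar(.filler)) + 1),
         offset + 1, offset + n)
}

#' Reference-standard truth sets
#'
#' Four standards mirroring a negative control, a 5% tier (3 variants), a
#' 1.3% tier (9 variants) and a 20-variant myeloid mix including one 42-base
#' FLT3 duplication and an MPL W515L analogue placed inside the high-GC
#' dropout amplicon. The unique cross-standard union is 26 variants.
#' Deterministic (no random draws); coordinates live inside the
#' [generate_panel()] amplicons.
#'
#' @param config a [sim_config()] (unused; accepted for interface symmetry).
#' @return list with `truth` (data.frame `standard_id, chrom, pos, ref, alt,
#'   gene, hgvs_p, expected_vaf`) and `standards` (ids incl. the negative
#'   standard `"TruQ0"`).
#' @export
generate_reference_standards <- function(config = sim_config()) {
  v <- function(std, gene, off, ref, alt, hgvs, vaf) {
    lay <- gene_layout()
    i <- match(gene, lay$gene)
    data.frame(standard_id = std, chrom = lay$chrom[i],
               pos = as.integer(lay$base[i] + off), ref = ref, alt = alt,
               gene = gene,
               hgvs_p = hgvs, expected_vaf = vaf, stringsAsFactors = FALSE)
  }
  # shared hotspot keys (offsets relative to the gene anchor; all inside
  # the first 150 bases of amplicon 1 or 2 so any seeded length covers them)
  jak2_v617f <- function(std, vaf) v(std, "JAK2", 120L, "G", "T", "p.V617F", vaf)
  flt3_di836 <- function(std, vaf)
    v(std, "FLT3", 360L, paste0("A", synth_seq(3, 8)), "A", "p.I836del", vaf)
  flt3_d835y <- function(std, vaf) v(std, "FLT3", 350L, "G", "T", "p.D835Y", vaf)
  idh1_r132c <- function(std, vaf) v(std, "IDH1", 112L, "C", "T", "p.R132C", vaf)

  truq1 <- rbind(flt3_di836("TruQ1", 0.05), idh1_r132c("TruQ1", 0.05),
                 jak2_v617f("TruQ1", 0.05))
  truq7 <- rbind(
    flt3_d835y("TruQ7", 0.013), flt3_di836("TruQ7", 0.013),
    idh1_r132c("TruQ7", 0.013),
    v("TruQ7", "IDH1", 113L, "G", "A", "p.R132H", 0.013),
    v("TruQ7", "IDH2", 140L, "G", "A", "p.R140Q", 0.013),
    v("TruQ7", "IDH2", 360L, "G", "A", "p.R172K", 0.013),
    jak2_v617f("TruQ7", 0.013),
    v("TruQ7", "KIT", 116L, "A", "T", "p.D816V", 0.013),
    v("TruQ7", "PDGFRA", 142L, "A", "T", "p.D842V", 0.013))
  sera_vaf <- 0.10
  seraseq <- rbind(
    v("SeraseqMyeloid", "ABL1", 315L, "C", "T", "p.T315I", sera_vaf),
    v("SeraseqMyeloid", "ASXL1", 63L, paste0("C", synth_seq(1, 3)), "C",
      "p.E635fs*15", sera_vaf),
    v("SeraseqMyeloid", "ASXL1", 446L, "G", "GG", "p.G646fs*12", sera_vaf),
    v("SeraseqMyeloid", "CALR", 60L, paste0("A", synth_seq(52, 0)), "A",
      "p.L367fs*46", sera_vaf),
    v("SeraseqMyeloid", "CBL", 420L, "G", "A", "p.R420Q", sera_vaf),
    v("SeraseqMyeloid", "CBL", 380L, "T", "C", "p.L380P", sera_vaf),
    v("SeraseqMyeloid", "CEBPA", 24L, paste0("G", synth_seq(1, 5)), "G",
      "p.H24fs*84", sera_vaf),
    v("SeraseqMyeloid", "CEBPA", 313L, "A", paste0("A", "AAG"),
      "p.K313_V314insK", sera_vaf),
    v("SeraseqMyeloid", "CSF3R", 618L %% 150L, "C", "T", "p.T618I", sera_vaf),
    v("SeraseqMyeloid", "FLT3", 149L, "C", paste0("C", synth_seq(42, 10)),
      "c.1759_1800dup", sera_vaf),
    flt3_d835y("SeraseqMyeloid", sera_vaf),
    idh1_r132c("SeraseqMyeloid", sera_vaf),
    jak2_v617f("SeraseqMyeloid", sera_vaf),
    v("SeraseqMyeloid", "JAK2", 360L, paste0("T", synth_seq(6, 20)), "T",
      "p.N542_E543del", sera_vaf),
    v("SeraseqMyeloid", "MPL", 107L, "G", "T", "p.W515L", sera_vaf),
    v("SeraseqMyeloid", "NPM1", 288L %% 150L, "C", paste0("C", "TCTG"),
      "p.W288fs*12", sera_vaf),
    v("SeraseqMyeloid", "SF3B1", 100L, "A", "G", "p.K700E", sera_vaf),
    v("SeraseqMyeloid", "SF3B1", 66L, "G", "T", "p.K666N", sera_vaf),
    v("SeraseqMyeloid", "SRSF2", 95L, paste0("T", synth_seq(24, 30)), "T",
      "p.P95_R102del", sera_vaf),
    v("SeraseqMyeloid", "U2AF1", 34L, "C", "T", "p.S34F", sera_vaf))
  truth <- rbind(truq1, truq7, seraseq)
  rownames(truth) <- NULL
  list(truth = truth,
       standards = c("TruQ0", "TruQ1", "TruQ7", "SeraseqMyeloid"))
}

#' Simulate per-amplicon coverage
#'
#' Depth per (amplicon, replicate) is lognormal around
#' `target_depth * m(gc)` where `m` is the logistic GC-dropout multiplier
#' ([sim_config()]); with `depth_dispersion = 0`, depth is exactly the
#' expectation.
#'
#' @param panel_obj output of [generate_panel()].
#' @param config a [sim_config()].
#' @param replicates data.frame with columns `sample_id, run_id`; default
#'   the validation layout of 8 replicates (4 standards x 2 runs).
#' @return long-format coverage data.frame (`amplicon_id, sample_id,
#'   run_id, mean_depth`).
#' @export
simulate_coverage <- function(panel_obj, config = sim_config(),
                              replicates = data.frame(
                                sample_id = rep(c("TruQ0", "TruQ1", "TruQ7",
                                                  "SeraseqMyeloid"), 2),
                                run_id = rep(c("run1", "run2"), each = 4),
                                stringsAsFactors = FALSE)) {
  with_seed(config$seed + 202L, {
    gc <- panel_obj$gc[panel_obj$panel$amplicon_id]
    m <- gc_multiplier(gc, config$gc_midpoint, config$gc_width)
    expected <- config$target_depth * m
    out <- list()
    for (r in seq_len(nrow(replicates))) {
      depth <- if (config$depth_dispersion == 0) expected else
        rlnorm(length(expected), meanlog = log(expected),
               sdlog = config$depth_dispersion)
      out[[r]] <- data.frame(
        amplicon_id = panel_obj$panel$amplicon_id,
        sample_id = replicates$sample_id[r],
        run_id = replicates$run_id[r],
        mean_depth = depth, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

# locate the amplicon containing each variant position
locate_amplicon <- function(panel, chrom, pos) {
  vapply(seq_along(chrom), function(i) {
    hit <- which(panel$chrom == chrom[i] & panel$start <= pos[i] &
                 panel$end >= pos[i])
    if (length(hit) == 0)
      stop_fmt("variant %s:%d outside every panel amplicon", chrom[i], pos[i])
    panel$amplicon_id[hit[1]]
  }, character(1))
}

classify_consequence <- function(ref, alt) {
  ifelse(is_snv(ref, alt), "nSNV",
  ifelse(nchar(alt) > nchar(ref),
         ifelse((nchar(alt) - nchar(ref)) %% 3 == 0, "nonframeshift indel",
                "frameshift insertion"),
         ifelse((nchar(ref) - nchar(alt)) %% 3 == 0, "nonframeshift indel",
                "frameshift deletion")))
}

#' Simulate the two callers' call sets for one replicate
#'
#' For each planted variant, alternate reads are drawn
#' `Binomial(depth, true_vaf)` at the depth of the amplicon containing it;
#' the variant is emitted iff `alt_reads >= min_alt_reads` and
#' `alt_reads / depth >= vaf_floor`. SNVs are routed to the small-variant
#' caller only, events larger than `large_threshold` bases to the
#' structural caller only, other indels to both. Optional random error
#' artifacts (SNVs at Beta-distributed noise-floor VAFs) are appended to
#' the small-variant call set.
#'
#' @param variants data.frame `chrom, pos, ref, alt, gene, true_vaf`
#'   (optional `hgvs_p`).
#' @param coverage coverage records for this replicate's `sample_id` (and
#'   `run_id` when given).
#' @param panel_obj output of [generate_panel()].
#' @param config a [sim_config()].
#' @param sample_id,run_id replicate labels.
#' @param with_artifacts append random error artifacts
#'   (rate `config$error_artifact_rate`)? Default FALSE.
#' @param large_threshold structural-event size cutoff (bases), default 25.
#' @param seed optional integer; when given, draws are made under this seed
#'   (restoring the RNG state afterwards).
#' @return list with `small`, `structural` (call-set data.frames) and
#'   `emitted` (the planted variants with `detected`, `observed_vaf`,
#'   `depth`).
#' @export
simulate_callset <- function(variants, coverage, panel_obj,
                             config = sim_config(), sample_id,
                             run_id = NA_character_,
                             with_artifacts = FALSE,
                             large_threshold = 25, seed = NULL) {
  run_it <- function() {
    panel <- panel_obj$panel
    cov <- coverage[coverage$sample_id == sample_id, , drop = FALSE]
    if (!is.na(run_id)) cov <- cov[cov$run_id == run_id, , drop = FALSE]
    if (nrow(cov) == 0)
      stop_fmt("no coverage records for sample %s", sample_id)
    depth_of <- setNames(cov$mean_depth, cov$amplicon_id)

    small <- list(); structural <- list(); emitted <- list()
    add_call <- function(side, row) {
      if (side == "small") small[[length(small) + 1]] <<- row
      else structural[[length(structural) + 1]] <<- row
    }
    if (nrow(variants) > 0) {
      amp <- locate_amplicon(panel, variants$chrom, variants$pos)
      for (i in seq_len(nrow(variants))) {
        depth <- as.integer(round(depth_of[[amp[i]]]))
        alt_reads <- if (depth > 0)
          rbinom(1, depth, variants$true_vaf[i]) else 0L
        vaf <- if (depth > 0) alt_reads / depth else 0
        detected <- alt_reads >= config$min_alt_reads &&
          vaf >= config$vaf_floor
        emitted[[i]] <- cbind(variants[i, , drop = FALSE],
                              data.frame(detected = detected,
                                         observed_vaf = vaf, depth = depth))
        if (!detected) next
        row <- data.frame(
          sample_id = sample_id, chrom = variants$chrom[i],
          pos = variants$pos[i], ref = variants$ref[i],
          alt = variants$alt[i], gene = variants$gene[i],
          hgvs_c = NA_character_,
          hgvs_p = if ("hgvs_p" %in% names(variants))
            variants$hgvs_p[i] else NA_character_,
          consequence = classify_consequence(variants$ref[i],
                                             variants$alt[i]),
          vaf = vaf, depth = depth, alt_reads = alt_reads,
          caller = NA_character_, stringsAsFactors = FALSE)
        snv <- is_snv(row$ref, row$alt)
        big <- max_allele_len(row$ref, row$alt) > large_threshold
        if (snv) {
          row$caller <- "small_variant"; add_call("small", row)
        } else if (big) {
          row$caller <- "structural"; add_call("structural", row)
        } else {
          row$caller <- "small_variant"; add_call("small", row)
          row$caller <- "structural"; add_call("structural", row)
        }
      }
    }
    if (with_artifacts && config$error_artifact_rate > 0) {
      n_art <- rpois(1, config$error_artifact_rate)
      for (j in seq_len(n_art)) {
        ai <- sample(nrow(panel), 1)
        len <- panel$end[ai] - panel$start[ai] + 1L
        pos <- panel$start[ai] + 2L * sample.int(len %/% 2, 1) - 1L
        ref <- c("A", "C", "G", "T")[(pos %% 4) + 1]
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        # noise-floor VAF: Beta truncated below the retention threshold
        repeat {
          tv <- rbeta(1, config$artifact_vaf_beta[1],
                      config$artifact_vaf_beta[2])
          if (tv <= config$artifact_vaf_max && tv > 0) break
        }
        depth <- as.integer(round(depth_of[[panel$amplicon_id[ai]]]))
        alt_reads <- if (depth > 0) rbinom(1, depth, tv) else 0L
        vaf <- if (depth > 0) alt_reads / depth else 0
        if (alt_reads < config$min_alt_reads || vaf < config$vaf_floor) next
        add_call("small", data.frame(
          sample_id = sample_id, chrom = panel$chrom[ai], pos = pos,
          ref = ref, alt = alt, gene = panel$gene[ai],
          hgvs_c = NA_character_, hgvs_p = NA_character_,
          consequence = "nSNV", vaf = vaf, depth = depth,
          alt_reads = alt_reads, caller = "small_variant",
          stringsAsFactors = FALSE))
      }
    }
    list(small = do.call(rbind, c(small, list(empty_calls()))),
         structural = do.call(rbind, c(structural, list(empty_calls()))),
         emitted = do.call(rbind, c(emitted, list(NULL))))
  }
  if (is.null(seed)) run_it() else with_seed(seed, run_it())
}

#' Generate an annotated MPN-like cohort with ground-truth triage labels
#'
#' Ten samples (by default) carrying a JAK2-like SNV driver (7 samples) or a
#' CALR-like 52-base frameshift deletion driver (3 samples), 0-4 somatic
#' passenger variants each (true VAF 6-55%), germline heterozygous
#' polymorphisms with population MAFs above 1% (a few at non-exonic
#' positions), random low-VAF error artifacts, cohort-recurrent systematic
#' artifacts, and one low-VAF (2.5%) COSMIC-pathogenic variant planted in
#' one sample (the rescue-lane case). Every emitted call carries a
#' ground-truth class and the triage status it is expected to receive.
#'
#' @param config a [sim_config()].
#' @return list with `panel` ([generate_panel()] output), `coverage`,
#'   `callsets` (per sample: `small`, `structural`), `annotations`,
#'   `labels` (data.frame `sample_id, chrom, pos, ref, alt, class,
#'   true_vaf, expected_status`) and `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  panel_obj <- generate_panel(config)
  panel <- panel_obj$panel
  lay <- gene_layout()
  samples <- sprintf("S%02d", seq_len(config$n_samples))
  coverage <- simulate_coverage(panel_obj, config,
                                replicates = data.frame(
                                  sample_id = samples, run_id = "run1",
                                  stringsAsFactors = FALSE))

  anchor <- function(gene) {
    i <- match(gene, lay$gene)
    list(chrom = lay$chrom[i], base = lay$base[i])
  }
  jak2 <- anchor("JAK2"); calr <- anchor("CALR"); tet2 <- anchor("TET2")
  driver_jak2 <- data.frame(chrom = jak2$chrom, pos = jak2$base + 120L,
                            ref = "G", alt = "T", gene = "JAK2",
                            hgvs_p = "p.V617F", stringsAsFactors = FALSE)
  driver_calr <- data.frame(chrom = calr$chrom, pos = calr$base + 60L,
                            ref = paste0("A", synth_seq(52, 0)), alt = "A",
                            gene = "CALR", hgvs_p = "p.L367fs*46",
                            stringsAsFactors = FALSE)
  rescue <- data.frame(chrom = tet2$chrom, pos = tet2$base + 92L,
                       ref = "T", alt = "A", gene = "TET2",
                       hgvs_p = "p.Y1631*", stringsAsFactors = FALSE)

  with_seed(config$seed + 303L, {
    # somatic passenger pool: SNVs at amplicon midpoints, genes != drivers
    pool_amps <- panel[!(panel$gene %in% c("JAK2", "CALR", "MPL")), ,
                       drop = FALSE]
    pool_amps <- pool_amps[sample(nrow(pool_amps), 30), , drop = FALSE]
    # planted variants sit at even offsets, random error artifacts at odd
    # offsets, so synthetic keys never collide across classes
    mid <- pool_amps$start + 100L
    pass_ref <- c("A", "C", "G", "T")[(mid %% 4) + 1]
    pass_alt <- vapply(pass_ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
    passengers <- data.frame(chrom = pool_amps$chrom, pos = mid,
                             ref = pass_ref, alt = pass_alt,
                             gene = pool_amps$gene,
                             hgvs_p = sprintf("p.pass%02d", seq_len(30)),
                             stringsAsFactors = FALSE)
    # germline pool: 30 exonic + 10 non-exonic positions
    germ_amps <- panel[sample(nrow(panel), 40), , drop = FALSE]
    gpos <- germ_amps$start + 20L + 2L * ((seq_len(40) * 7L) %% 35L)
    germ_ref <- c("A", "C", "G", "T")[(gpos %% 4) + 1]
    germ_alt <- vapply(germ_ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
    germline <- data.frame(chrom = germ_amps$chrom, pos = gpos,
                           ref = germ_ref, alt = germ_alt,
                           gene = germ_amps$gene,
                           hgvs_p = NA_character_,
                           region = c(rep("exonic", 30),
                                      rep(c("intronic", "UTR3"), 5)),
                           maf = round(runif(40, 0.02, 0.40), 4),
                           stringsAsFactors = FALSE)
    # systematic artifacts: fixed keys, VAF above the retention threshold
    sys_amps <- panel[sample(nrow(panel), config$n_systematic_artifacts), ,
                      drop = FALSE]
    spos <- sys_amps$start + 94L
    sys_ref <- c("A", "C", "G", "T")[(spos %% 4) + 1]
    sys_alt <- vapply(sys_ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
    systematic <- data.frame(chrom = sys_amps$chrom, pos = spos,
                             ref = sys_ref, alt = sys_alt,
                             gene = sys_amps$gene, hgvs_p = NA_character_,
                             stringsAsFactors = FALSE)
    n_sys_samples <- round(config$systematic_artifact_fraction *
                           config$n_samples)
    rescue_sample <- sample(config$n_samples, 1)

    callsets <- list(); labels <- list(); art_keys <- list()
    n_jak2 <- config$driver_mix[["jak2_snv"]]
    n_calr <- config$driver_mix[["calr_fs"]]
    for (si in seq_len(config$n_samples)) {
      s <- samples[si]
      plan <- list()
      if (si <= n_jak2) {
        d <- driver_jak2; d$true_vaf <- round(runif(1, 0.10, 0.90), 4)
        d$class <- "somatic_driver"; plan[[length(plan) + 1]] <- d
      } else if (si <= n_jak2 + n_calr) {
        d <- driver_calr; d$true_vaf <- round(runif(1, 0.10, 0.40), 4)
        d$class <- "somatic_driver"; plan[[length(plan) + 1]] <- d
      }
      np <- sample(0:4, 1)
      if (np > 0) {
        p <- passengers[sample(30, np), , drop = FALSE]
        p$true_vaf <- round(runif(np, 0.06, 0.55), 4)
        p$class <- "somatic_passenger"; plan[[length(plan) + 1]] <- p
      }
      g <- germline[sample(40, config$germline_het_count), , drop = FALSE]
      g$true_vaf <- 0.5
      g$class <- ifelse(g$region == "exonic", "germline_exonic",
                        "germline_nonexonic")
      plan[[length(plan) + 1]] <- g[, c(names(germline)[1:6], "true_vaf",
                                        "class")]
      if (si <= n_sys_samples && nrow(systematic) > 0) {
        sa <- systematic
        sa$true_vaf <- round(runif(nrow(sa), 0.05, 0.12), 4)
        sa$class <- "systematic_artifact"; plan[[length(plan) + 1]] <- sa
      }
      if (si == rescue_sample) {
        r <- rescue; r$true_vaf <- 0.025; r$class <- "rescue_pathogenic"
        plan[[length(plan) + 1]] <- r
      }
      plan <- do.call(rbind, lapply(plan, function(d)
        d[, c("chrom", "pos", "ref", "alt", "gene", "hgvs_p", "true_vaf",
              "class")]))
      sim <- simulate_callset(plan, coverage, panel_obj, config,
                              sample_id = s, run_id = "run1",
                              with_artifacts = TRUE)
      callsets[[s]] <- sim[c("small", "structural")]
      em <- sim$emitted[sim$emitted$detected, , drop = FALSE]
      if (nrow(em) > 0) {
        em$sample_id <- s
        em$expected_status <- c(
          somatic_driver = "retained", somatic_passenger = "retained",
          germline_exonic = "excluded_common",
          germline_nonexonic = "excluded_region",
          systematic_artifact = "excluded_artifact",
          rescue_pathogenic = "rescued_pathogenic")[em$class]
        labels[[length(labels) + 1]] <-
          em[, c("sample_id", "chrom", "pos", "ref", "alt", "class",
                 "true_vaf", "expected_status")]
      }
      # random artifacts emitted for this sample (small caller, no plan row)
      art <- sim$small
      planned <- variant_id(plan$chrom, plan$pos, plan$ref, plan$alt)
      is_art <- !(variant_id(art$chrom, art$pos, art$ref, art$alt) %in%
                  planned)
      if (any(is_art)) {
        a <- art[is_art, , drop = FALSE]
        art_keys[[length(art_keys) + 1]] <- a
        labels[[length(labels) + 1]] <- data.frame(
          sample_id = s, chrom = a$chrom, pos = a$pos, ref = a$ref,
          alt = a$alt, class = "error_artifact", true_vaf = NA_real_,
          expected_status = "excluded_artifact", stringsAsFactors = FALSE)
      }
    }
    labels <- do.call(rbind, labels)

    ann_row <- function(chrom, pos, ref, alt, region = "exonic",
                        maf_gnomad = NA_real_, dbsnp = NA_character_,
                        exact = FALSE, clinvar = "absent", cosmic = "",
                        cosmic_path = FALSE) {
      data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 region_class = region, maf_1000g = NA_real_,
                 maf_exac = NA_real_, maf_esp6500 = NA_real_,
                 maf_gnomad = maf_gnomad, dbsnp_id = dbsnp,
                 dbsnp_exact_allele_match = exact,
                 clinvar_assertion = clinvar, cosmic_ids = cosmic,
                 cosmic_pathogenic = cosmic_path, stringsAsFactors = FALSE)
    }
    ann <- list(
      ann_row(driver_jak2$chrom, driver_jak2$pos, driver_jak2$ref,
              driver_jak2$alt, dbsnp = "rs77375493", exact = TRUE,
              clinvar = "pathogenic", cosmic = "COSM12600",
              cosmic_path = TRUE),
      ann_row(driver_calr$chrom, driver_calr$pos, driver_calr$ref,
              driver_calr$alt, cosmic = "COSM1738055", cosmic_path = TRUE),
      ann_row(rescue$chrom, rescue$pos, rescue$ref, rescue$alt,
              cosmic = "COSM97191", cosmic_path = TRUE))
    for (i in seq_len(30)) {
      ann[[length(ann) + 1]] <- ann_row(
        passengers$chrom[i], passengers$pos[i], passengers$ref[i],
        passengers$alt[i],
        cosmic = if (i %% 2 == 0) sprintf("COSMSYN%03d", i) else "")
    }
    for (i in seq_len(40)) {
      ann[[length(ann) + 1]] <- ann_row(
        germline$chrom[i], germline$pos[i], germline$ref[i],
        germline$alt[i], region = germline$region[i],
        maf_gnomad = germline$maf[i],
        dbsnp = sprintf("rsSYN%05d", i), exact = TRUE)
    }
    for (i in seq_len(nrow(systematic))) {
      ann[[length(ann) + 1]] <- ann_row(
        systematic$chrom[i], systematic$pos[i], systematic$ref[i],
        systematic$alt[i])
    }
    for (a in art_keys) {
      for (i in seq_len(nrow(a))) {
        ann[[length(ann) + 1]] <- ann_row(a$chrom[i], a$pos[i], a$ref[i],
                                          a$alt[i])
      }
    }
    annotations <- do.call(rbind, ann)
    annotations <- annotations[!duplicated(variant_id(
      annotations$chrom, annotations$pos, annotations$ref,
      annotations$alt)), , drop = FALSE]
    rownames(annotations) <- NULL

    list(panel = panel_obj, coverage = coverage, callsets = callsets,
         annotations = annotations, labels = labels, config = config)
  })
}
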