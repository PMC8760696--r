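# Reference-standard scoring: detection matrices, confusion counts,
# replicate concordance and limit of detection.

#' Match one call against one truth variant
#'
#' Keys are compared after normalization: a match is an exact normalized key,
#' or — to absorb residual representation differences between callers for
#' duplications — two insertions on the same chromosome whose anchors lie
#' within `anchor_tolerance` bases of each other with identical inserted
#' length.
#'
#' @param call list/row with `chrom, pos, ref, alt` (normalized).
#' @param truth list/row with `chrom, pos, ref, alt` (normalized).
#' @param anchor_tolerance bases of anchor slack for insertions. Default 5.
#' @return logical scalar.
#' @export
match_call_to_truth <- function(call, truth, anchor_tolerance = 5) {
  if (call$chrom != truth$chrom) return(FALSE)
  if (call$pos == truth$pos && call$ref == truth$ref &&
      call$alt == truth$alt) return(TRUE)
  ins_c <- nchar(call$alt) > nchar(call$ref)
  ins_t <- nchar(truth$alt) > nchar(truth$ref)
  if (!ins_c || !ins_t) return(FALSE)
  len_c <- nchar(call$alt) - nchar(call$ref)
  len_t <- nchar(truth$alt) - nchar(truth$ref)
  len_c == len_t && abs(call$pos - truth$pos) <= anchor_tolerance
}

#' Build the detection matrix for a set of replicates
#'
#' @param truth truth-set data.frame (`standard_id, chrom, pos, ref, alt,
#'   gene, hgvs_p, expected_vaf`); standards with zero rows (wild-type
#'   negatives) are declared via `standards`.
#' @param replicates named list: one element per replicate, each a list with
#'   `standard_id`, `run_id` and `calls` (a merged call-set data.frame).
#' @param standards character vector of all sequenced standard ids (defaults
#'   to the union of ids in `truth` and `replicates`).
#' @param anchor_tolerance passed to [match_call_to_truth()].
#' @return list of class `detection_matrix`:
#'   * `cells`: one row per (replicate, truth variant of its standard) with
#'     `detected`, `observed_vaf` and `detected_by` (comma-joined caller
#'     provenance of the matching call, `""` if none).
#'   * `off_truth`: calls in a replicate matching no truth variant of its
#'     standard, with full call fields.
#'   * `replicates`: metadata of every scored replicate (all-negative
#'     replicates with zero calls still count towards tn).
#'   * `truth`, `standards`: the inputs (truth keys normalized).
#' @export
build_detection_matrix <- function(truth, replicates,
                                   standards = NULL,
                                   anchor_tolerance = 5) {
  truth <- normalize_keys(truth)
  if (is.null(standards))
    standards <- sort(unique(c(truth$standard_id,
                               vapply(replicates, `[[`, "", "standard_id"))))
  unknown <- setdiff(vapply(replicates, `[[`, "", "standard_id"), standards)
  if (length(unknown) > 0)
    stop_fmt("replicate references unknown standard(s): %s",
             paste(unique(unknown), collapse = ", "))
  if (is.null(names(replicates)) || any(!nzchar(names(replicates))))
    names(replicates) <- sprintf("replicate%02d", seq_along(replicates))

  cells <- list(); off <- list()
  for (rn in names(replicates)) {
    rep <- replicates[[rn]]
    tv <- truth[truth$standard_id == rep$standard_id, , drop = FALSE]
    calls <- rep$calls
    if (nrow(calls) > 0) calls <- normalize_keys(calls)
    matched_call <- rep(FALSE, nrow(calls))
    if (nrow(tv) > 0) {
      for (i in seq_len(nrow(tv))) {
        hit <- integer(0)
        if (nrow(calls) > 0) {
          hit <- which(vapply(seq_len(nrow(calls)), function(j)
            match_call_to_truth(calls[j, ], tv[i, ], anchor_tolerance),
            logical(1)))
        }
        matched_call[hit] <- TRUE
        cells[[length(cells) + 1]] <- data.frame(
          replicate_id = rn, standard_id = rep$standard_id,
          run_id = rep$run_id,
          chrom = tv$chrom[i], pos = tv$pos[i], ref = tv$ref[i],
          alt = tv$alt[i], gene = tv$gene[i], hgvs_p = tv$hgvs_p[i],
          expected_vaf = tv$expected_vaf[i],
          detected = length(hit) > 0,
          observed_vaf = if (length(hit) > 0) calls$vaf[hit[1]] else NA_real_,
          detected_by = if (length(hit) > 0) {
            cl <- calls$callers
            if (is.null(cl)) cl <- calls$caller
            cl[hit[1]]
          } else "",
          stringsAsFactors = FALSE)
      }
    }
    if (any(!matched_call)) {
      o <- calls[!matched_call, , drop = FALSE]
      o$replicate_id <- rn; o$standard_id <- rep$standard_id
      o$run_id <- rep$run_id
      off[[length(off) + 1]] <- o
    }
  }
  meta <- data.frame(
    replicate_id = names(replicates),
    standard_id = vapply(replicates, `[[`, "", "standard_id"),
    run_id = vapply(replicates, `[[`, "", "run_id"),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(
    cells = do.call(rbind, c(cells, list(NULL))),
    off_truth = do.call(rbind, c(off, list(NULL))),
    replicates = meta,
    truth = truth, standards = standards), class = "detection_matrix")
}

# unique label for a truth variant
truth_label <- function(df) variant_id(df$chrom, df$pos, df$ref, df$alt)

#' Confusion counts over a detection matrix
#'
#' `tp` = detected truth cells, `fn` = undetected truth cells, `fp` =
#' off-truth calls. Negative evaluable sites are defined per replicate as
#' the cross-standard truth-variant union minus the replicate's own
#' standard's truth set; `tn` is their count summed over replicates, minus
#' off-truth calls landing on such sites.
#'
#' With `counting = "per_app"`, truth cells are counted once per eligible
#' caller (SNVs: small-variant caller only; events > `large_threshold`
#' bases: structural caller only; other indels: both), a cell counting as
#' detected for a caller iff that caller contributed the matching call.
#'
#' @param matrix a `detection_matrix`.
#' @param counting `"merged"` (default) or `"per_app"`.
#' @param large_threshold event-size cutoff used by `per_app` eligibility.
#' @param anchor_tolerance passed to [match_call_to_truth()] when checking
#'   whether an off-truth call lands on a negative site.
#' @return list with `tp, fp, fn, tn, sensitivity, specificity, ppv`
#'   (metrics `NA` when their denominator is zero).
#' @export
compute_confusion <- function(matrix, counting = c("merged", "per_app"),
                              large_threshold = 25, anchor_tolerance = 5) {
  counting <- match.arg(counting)
  cells <- matrix$cells
  det <- if (is.null(cells)) logical(0) else cells$detected
  if (counting == "merged") {
    tp <- sum(det)
    fn <- sum(!det)
  } else {
    tp <- 0L; fn <- 0L
    if (!is.null(cells)) for (i in seq_len(nrow(cells))) {
      snv <- is_snv(cells$ref[i], cells$alt[i])
      big <- max_allele_len(cells$ref[i], cells$alt[i]) > large_threshold
      apps <- if (snv) "small_variant"
              else if (big) "structural"
              else c("small_variant", "structural")
      by <- strsplit(cells$detected_by[i], ",", fixed = TRUE)[[1]]
      for (a in apps) {
        if (cells$detected[i] && a %in% by) tp <- tp + 1L else fn <- fn + 1L
      }
    }
  }
  fp <- if (is.null(matrix$off_truth)) 0L else nrow(matrix$off_truth)

  # negative evaluable sites per replicate (every sequenced replicate
  # contributes, including all-negative replicates with zero calls)
  all_truth <- matrix$truth[!duplicated(truth_label(matrix$truth)), ,
                            drop = FALSE]
  tn <- 0L
  for (rn in matrix$replicates$replicate_id) {
    std <- matrix$replicates$standard_id[
      matrix$replicates$replicate_id == rn]
    own <- truth_label(matrix$truth[matrix$truth$standard_id == std, ,
                                    drop = FALSE])
    neg <- all_truth[!(truth_label(all_truth) %in% own), , drop = FALSE]
    n_neg <- nrow(neg)
    fp_at_neg <- 0L
    offr <- matrix$off_truth[matrix$off_truth$replicate_id == rn, ,
                             drop = FALSE]
    if (!is.null(offr) && nrow(offr) > 0 && n_neg > 0) {
      for (j in seq_len(nrow(offr))) {
        if (any(vapply(seq_len(n_neg), function(i)
          match_call_to_truth(offr[j, ], neg[i, ], anchor_tolerance),
          logical(1))))
          fp_at_neg <- fp_at_neg + 1L
      }
    }
    tn <- tn + n_neg - fp_at_neg
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' Concordance between two replicate detections
#'
#' @param setA,setB character vectors of detected truth-variant labels from
#'   two replicates of the same standard.
#' @param method `"jaccard"` (default): `|A n B| / |A u B|`, 1.0 when both
#'   empty; `"both_detected"`: fraction of the standard's truth variants
#'   detected in both replicates (requires `n_truth`).
#' @param n_truth total truth variants of the standard (for
#'   `"both_detected"`).
#' @return fraction in \[0, 1\].
#' @export
concordance <- function(setA, setB, method = c("jaccard", "both_detected"),
                        n_truth = NULL) {
  method <- match.arg(method)
  setA <- unique(setA); setB <- unique(setB)
  if (method == "jaccard") {
    u <- union(setA, setB)
    if (length(u) == 0) return(1.0)
    length(intersect(setA, setB)) / length(u)
  } else {
    if (is.null(n_truth)) stop_fmt("both_detected concordance needs n_truth")
    if (n_truth == 0) return(1.0)
    length(intersect(setA, setB)) / n_truth
  }
}

# all replicate pairs of the same standard, optionally restricted to
# same-run (intra) or cross-run (inter) pairs
replicate_pairs <- function(cells, scope = c("intra", "inter")) {
  scope <- match.arg(scope)
  meta <- unique(cells[, c("replicate_id", "standard_id", "run_id")])
  pairs <- list()
  for (std in unique(meta$standard_id)) {
    m <- meta[meta$standard_id == std, , drop = FALSE]
    if (nrow(m) < 2) next
    idx <- utils::combn(nrow(m), 2)
    for (k in seq_len(ncol(idx))) {
      a <- m[idx[1, k], ]; b <- m[idx[2, k], ]
      same_run <- identical(a$run_id, b$run_id)
      if ((scope == "intra") == same_run)
        pairs[[length(pairs) + 1]] <- c(a$replicate_id, b$replicate_id)
    }
  }
  pairs
}

#' Intra- and inter-run concordance summary
#'
#' Compares detected truth-variant sets between replicate pairs of the same
#' standard: pairs within a run (intra) and across runs (inter).
#'
#' @param matrix a `detection_matrix`.
#' @param method passed to [concordance()].
#' @return list with `intra` and `inter`, each `list(mean, range, n_pairs)`
#'   (`NA` when no pairs exist).
#' @export
concordance_summary <- function(matrix, method = "jaccard") {
  cells <- matrix$cells
  if (is.null(cells) || nrow(cells) == 0) {
    none <- list(mean = NA_real_, range = c(NA_real_, NA_real_),
                 n_pairs = 0L)
    return(list(intra = none, inter = none))
  }
  det_set <- function(rn) {
    c <- cells[cells$replicate_id == rn & cells$detected, , drop = FALSE]
    truth_label(c)
  }
  one <- function(scope) {
    pairs <- replicate_pairs(cells, scope)
    if (length(pairs) == 0)
      return(list(mean = NA_real_, range = c(NA_real_, NA_real_),
                  n_pairs = 0L))
    vals <- vapply(pairs, function(p) {
      std <- cells$standard_id[cells$replicate_id == p[1]][1]
      n_truth <- sum(matrix$truth$standard_id == std)
      concordance(det_set(p[1]), det_set(p[2]), method = method,
                  n_truth = n_truth)
    }, numeric(1))
    list(mean = mean(vals), range = range(vals), n_pairs = length(vals))
  }
  list(intra = one("intra"), inter = one("inter"))
}

#' Limit of detection over expected-VAF tiers
#'
#' The lowest expected-VAF tier at which every truth variant of that tier is
#' detected in every replicate of a standard containing it. The panel's
#' analysis floor (the configured 1% somatic VAF detection limit) is
#' reported alongside: the headline "1%" limit is the floor, not a tested
#' tier.
#'
#' @param matrix a `detection_matrix` whose truth variants carry
#'   `expected_vaf` tiers.
#' @param analysis_floor reported floor, default 0.01.
#' @return list with `lod_vaf` (lowest fully detected tier, `NA` if none),
#'   `analysis_floor`, and `tiers` (per-tier detection fractions).
#' @export
limit_of_detection <- function(matrix, analysis_floor = 0.01) {
  cells <- matrix$cells
  cells <- cells[!is.na(cells$expected_vaf), , drop = FALSE]
  if (is.null(cells) || nrow(cells) == 0)
    stop_fmt("no expected_vaf tiers present in detection matrix")
  tiers <- sort(unique(cells$expected_vaf))
  frac <- vapply(tiers, function(t)
    mean(cells$detected[cells$expected_vaf == t]), numeric(1))
  complete <- tiers[frac == 1]
  list(lod_vaf = if (length(complete) > 0) min(complete) else NA_real_,
       analysis_floor = analysis_floor,
       tiers = data.frame(expected_vaf = tiers, detected_fraction = frac))
}

#' Full validation report
#'
#' @param matrix a `detection_matrix`.
#' @param counting passed to [compute_confusion()].
#' @param concordance_method passed to [concordance_summary()].
#' @param analysis_floor passed to [limit_of_detection()].
#' @return list of class `validation_report` with `confusion`,
#'   `concordance`, `lod` and the cell counts.
#' @export
validation_report <- function(matrix, counting = "merged",
                              concordance_method = "jaccard",
                              analysis_floor = 0.01) {
  conf <- compute_confusion(matrix, counting = counting)
  conc <- concordance_summary(matrix, method = concordance_method)
  lod <- tryCatch(limit_of_detection(matrix, analysis_floor),
                  error = function(e) NULL)
  structure(list(confusion = conf, concordance = conc, lod = lod,
                 n_truth_cells = nrow(matrix$cells),
                 n_off_truth = if (is.null(matrix$off_truth)) 0L
                               else nrow(matrix$off_truth)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  c <- x$confusion
  cat(sprintf(
    "<validation_report> tp=%d fp=%d fn=%d tn=%d | sens=%.3f spec=%.3f ppv=%.3f\n",
    c$tp, c$fp, c$fn, c$tn, c$sensitivity, c$specificity, c$ppv))
  if (!is.null(x$lod))
    cat(sprintf("  LoD tier: %g (analysis floor %g)\n", x$lod$lod_vaf,
                x$lod$analysis_floor))
  invisible(x)
}
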