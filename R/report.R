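# Human-readable reporting: deterministic markdown + JSON-able summaries.
# The renderer does no arithmetic beyond percent formatting: every number
# is traceable to a stage summary field.

fmt_pct <- function(x, digits = 1) sprintf(paste0("%.", digits, "f%%"),
                                           100 * x)

#' Render stage summaries as markdown and a JSON-able list
#'
#' @param triage optional `triage_result` from [run_triage()].
#' @param validation optional `validation_report` from
#'   [validation_report()].
#' @param coverage optional output of [summarize_amplicon_coverage()].
#' @param demographics optional output of [demographics_summary()].
#' @return list with `markdown` (character vector of lines) and `json`
#'   (nested list ready for [jsonlite::write_json()]). Byte-identical
#'   across repeated calls on identical inputs.
#' @export
render_report <- function(triage = NULL, validation = NULL, coverage = NULL,
                          demographics = NULL) {
  if (is.null(triage) && is.null(validation) && is.null(coverage) &&
      is.null(demographics))
    stop_fmt("render_report needs at least one stage summary")
  md <- c("# Panel analysis report", "")
  json <- list()

  if (!is.null(demographics)) {
    d <- demographics
    md <- c(md, "## Cohort",
            sprintf("- %d samples; median diagnosis age %g (range %g-%g)",
                    d$n, d$median_age, d$age_range[1], d$age_range[2]), "")
    json$demographics <- d
  }

  if (!is.null(triage)) {
    s <- triage$summary
    md <- c(md, "## Variant triage",
            sprintf("- %d unique variants in; %d after region and MAF filters; %d retained (VAF > 5%%) + %d rescued (pathogenic, 1-5%% VAF)",
                    s$n_input_unique, s$n_after_region_and_maf,
                    s$n_retained, s$n_rescued), "")
    kept <- triage$decisions[triage$decisions$status %in%
                             c("retained", "rescued_pathogenic"), ,
                             drop = FALSE]
    if (nrow(kept) > 0) {
      kept <- kept[order(kept$gene, kept$pos, kept$sample_id), ,
                   drop = FALSE]
      md <- c(md,
              "| Gene | Variant | Consequence | Sample | VAF (%) | Status | Novelty | Sanger-eligible |",
              "|---|---|---|---|---|---|---|---|",
              sprintf("| %s | %s:%d %s>%s | %s | %s | %.1f | %s | %s | %s |",
                      kept$gene, kept$chrom, kept$pos, kept$ref, kept$alt,
                      kept$consequence, kept$sample_id, 100 * kept$vaf,
                      kept$status, kept$novelty,
                      ifelse(kept$sanger_eligible, "yes", "no")), "")
    } else {
      md <- c(md, "Zero variants retained.", "")
    }
    json$triage <- list(summary = s, decisions = triage$decisions)
  }

  if (!is.null(validation)) {
    cf <- validation$confusion
    md <- c(md, "## Panel validation",
            sprintf("- TP %d, FP %d, FN %d, TN %d (denominators: sensitivity %d, specificity %d, PPV %d)",
                    cf$tp, cf$fp, cf$fn, cf$tn, cf$tp + cf$fn,
                    cf$tn + cf$fp, cf$tp + cf$fp),
            sprintf("- Sensitivity %s, specificity %s, PPV %s",
                    fmt_pct(cf$sensitivity), fmt_pct(cf$specificity),
                    fmt_pct(cf$ppv)))
    cc <- validation$concordance
    fmt_conc <- function(x, label) {
      if (x$n_pairs == 0) sprintf("- %s concordance: no pairs", label)
      else sprintf("- %s concordance %s [range %s-%s] over %d pairs", label,
                   fmt_pct(x$mean), fmt_pct(x$range[1]),
                   fmt_pct(x$range[2]), x$n_pairs)
    }
    md <- c(md, fmt_conc(cc$intra, "Intra-run"),
            fmt_conc(cc$inter, "Inter-run"))
    if (!is.null(validation$lod))
      md <- c(md, sprintf("- LoD: lowest fully detected tier %s; analysis floor %s",
                          fmt_pct(validation$lod$lod_vaf),
                          fmt_pct(validation$lod$analysis_floor)))
    md <- c(md, "")
    json$validation <- unclass(validation)
  }

  if (!is.null(coverage)) {
    rows <- coverage$rows
    md <- c(md, "## Amplicon coverage QC",
            sprintf("- %d amplicons; %s with mean depth above the warn threshold",
                    nrow(rows), fmt_pct(coverage$fraction_above_warn)),
            sprintf("- warn: %d, critical: %d",
                    sum(rows$flag == "warn_below_1000"),
                    sum(rows$flag == "critical_below_100")), "")
    flagged <- rows[rows$flag != "ok", , drop = FALSE]
    if (nrow(flagged) > 0)
      md <- c(md, sprintf("  - %s: %.0fx (%s)", flagged$amplicon_id,
                          flagged$mean_depth_overall, flagged$flag), "")
    json$coverage <- coverage
  }
  list(markdown = md, json = json)
}

#' Write a rendered report to disk
#'
#' @param report output of [render_report()].
#' @param md_path,json_path output paths (either may be `NULL`).
#' @return invisibly, a character vector of the paths written.
#' @export
write_report <- function(report, md_path = NULL, json_path = NULL) {
  written <- character(0)
  if (!is.null(md_path)) {
    writeLines(report$markdown, md_path)
    written <- c(written, md_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(report$json, json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE,
                         dataframe = "rows")
    written <- c(written, json_path)
  }
  invisible(written)
}
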