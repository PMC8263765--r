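#' Run the full study pipeline
#'
#' Orchestrates read -> validate -> quantify -> classify -> evaluate on one
#' cohort, in either of the two study designs: `mode = "prospective"`
#' evaluates the assay (and cytology, and their OR-combination) against
#' histology; `mode = "pilot"` evaluates the assay against cytology, the
#' only reference available when no core biopsy is taken, excluding
#' cytology-indeterminate samples from that comparison. A filter ledger
#' records every exclusion so that input = evaluated + inadequate
#' (+ indeterminate, for cytology-truth analyses).
#'
#' @param ct long Ct table (data.frame or CSV path; see [read_ct_table()]).
#' @param metadata per-sample metadata with at least `sample_id` and the
#'   truth column(s) (`histology` and/or `cytology`).
#' @param curves named list of `calibration_curve` per panel gene.
#' @param panel panel definition.
#' @param mode "prospective" (truth = histology) or "pilot" (truth = cytology).
#' @param threshold CM classification threshold (default 8.5).
#' @param actb_max_ct ACTB adequacy cutoff in cycles (default 40).
#' @param ci_level confidence level for all intervals (default 0.95).
#' @return object of class `study_report`: list with `mode`, `ledger`,
#'   `calls` (per-sample data.frame), `assay` (DiagnosticReport-style
#'   list: counts, metrics, auc), and for prospective mode also
#'   `cytology` and `combined` reports.
#' @export
run_study <- function(ct, metadata, curves, panel = default_panel(),
                      mode = c("prospective", "pilot"), threshold = 8.5,
                      actb_max_ct = 40, ci_level = 0.95) {
  mode <- match.arg(mode)
  truth_col <- if (mode == "prospective") "histology" else "cytology"
  if (!truth_col %in% names(metadata))
    stop("metadata lacks the '", truth_col, "' truth column for mode ", mode,
         call. = FALSE)

  records <- read_ct_table(ct, panel)
  profiles <- quantify_cohort(records, curves, panel, actb_max_ct)
  df <- merge(profiles, metadata, by = "sample_id", sort = FALSE)
  if (nrow(df) != nrow(profiles))
    stop("metadata missing for some samples in the Ct table", call. = FALSE)
  df <- df[match(profiles$sample_id, df$sample_id), ]

  n_input <- nrow(df)
  n_inadequate <- sum(!df$valid)
  ev <- df[df$valid, , drop = FALSE]
  ev$call <- classify_cm(ev$cm, threshold)

  evaluate <- function(calls, truth, scores = NULL) {
    cc <- confusion_counts(calls, truth)
    rep <- list(counts = cc,
                metrics = diagnostic_metrics(cc, ci_level),
                n = length(calls))
    if (!is.null(scores))
      rep$auc <- roc_auc(scores, truth, ci_level)
    rep
  }

  out <- list(mode = mode, threshold = threshold, calls = ev)
  if (mode == "prospective") {
    out$assay <- evaluate(ev$call, ev$histology, ev$cm)
    has_cyt <- "cytology" %in% names(ev)
    n_indet <- if (has_cyt) sum(ev$cytology == "indeterminate") else 0L
    if (has_cyt) {
      det <- ev[ev$cytology != "indeterminate", , drop = FALSE]
      out$cytology <- evaluate(det$cytology, det$histology)
      out$cytology$n_excluded_indeterminate <- n_indet
      out$combined <- evaluate(combine_calls(ev$call, ev$cytology),
                               ev$histology)
    }
    out$ledger <- list(n_input = n_input, n_inadequate = n_inadequate,
                       n_evaluated = nrow(ev),
                       n_indeterminate_excluded_cytology_analysis = n_indet)
  } else {
    det <- ev[ev$cytology != "indeterminate", , drop = FALSE]
    out$assay <- evaluate(det$call, det$cytology, det$cm)
    out$ledger <- list(n_input = n_input, n_inadequate = n_inadequate,
                       n_evaluated = nrow(det),
                       n_indeterminate_excluded = nrow(ev) - nrow(det))
  }
  structure(out, class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> mode=%s threshold=%.1f CM\n", x$mode, x$threshold))
  cat(sprintf("  samples: %d in, %d inadequate, %d evaluated\n",
              x$ledger$n_input, x$ledger$n_inadequate, x$ledger$n_evaluated))
  show <- function(name, rep) {
    m <- rep$metrics
    g <- function(k) m$estimate[m$metric == k]
    cat(sprintf("  %-9s sens %.1f%%  spec %.1f%%  ppv %.1f%%  npv %.1f%%",
                name, g("sensitivity"), g("specificity"), g("ppv"), g("npv")))
    if (!is.null(rep$auc))
      cat(sprintf("  AUC %.3f (%.3f-%.3f)", rep$auc$auc, rep$auc$lower,
                  rep$auc$upper))
    cat("\n")
  }
  show("assay", x$assay)
  if (!is.null(x$cytology)) show("cytology", x$cytology)
  if (!is.null(x$combined)) show("combined", x$combined)
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' Percents are rendered to one decimal place, AUCs to three.
#'
#' @param report a `study_report`.
#' @param path output JSON path.
#' @export
write_report_json <- function(report, path) {
  fmt <- function(rep) {
    m <- rep$metrics
    out <- list(counts = rep$counts, n = rep$n,
                metrics = lapply(stats::setNames(seq_len(nrow(m)), m$metric),
                                 function(i) list(estimate = round(m$estimate[i], 1),
                                                  lower = round(m$lower[i], 1),
                                                  upper = round(m$upper[i], 1))))
    if (!is.null(rep$auc))
      out$auc <- lapply(rep$auc[c("auc", "lower", "upper")], round, 3)
    if (!is.null(rep$n_excluded_indeterminate))
      out$n_excluded_indeterminate <- rep$n_excluded_indeterminate
    out
  }
  obj <- list(mode = report$mode, threshold = report$threshold,
              ledger = report$ledger, assay = fmt(report$assay))
  if (!is.null(report$cytology)) obj$cytology <- fmt(report$cytology)
  if (!is.null(report$combined)) obj$combined <- fmt(report$combined)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the per-sample call matrix
#'
#' TSV mirroring the study's call heatmap: sample, CM (one decimal), assay
#' call, cytology and truth columns where present.
#'
#' @param report a `study_report`.
#' @param path output TSV path.
#' @export
write_calls_tsv <- function(report, path) {
  df <- report$calls
  keep <- intersect(c("sample_id", "cm", "call", "cytology", "histology"),
                    names(df))
  out <- df[, keep, drop = FALSE]
  out$cm <- round(out$cm, 1)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
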