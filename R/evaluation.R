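#' Confusion counts against a gold standard
#'
#' @param calls character vector, "malignant"/"benign".
#' @param truth truth labels ("malignant"/"benign" or logical).
#' @return list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(calls, truth) {
  if (length(calls) != length(truth))
    stop("calls and truth must have equal length", call. = FALSE)
  pos <- as_positive(truth)
  called <- calls == "malignant"
  list(tp = sum(called & pos), fp = sum(called & !pos),
       fn = sum(!called & pos), tn = sum(!called & !pos))
}

#' Diagnostic accuracy metrics with exact confidence intervals
#'
#' Sensitivity, specificity, PPV and NPV as percents, each with a
#' Clopper-Pearson exact binomial confidence interval. A metric whose
#' denominator is empty is returned as `NA` (undefined) without failing
#' the others.
#'
#' @param counts list with tp, fp, fn, tn (see [confusion_counts()]).
#' @param ci_level confidence level, default 0.95.
#' @return data.frame with columns `metric`, `estimate`, `lower`, `upper`
#'   (percent scale) and `x`, `n` (the underlying counts).
#' @examples
#' diagnostic_metrics(list(tp = 98, fp = 1, fn = 10, tn = 109))
#' @export
diagnostic_metrics <- function(counts, ci_level = 0.95) {
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(counts)))
  with(counts, {
    spec_tab <- list(
      sensitivity = c(tp, tp + fn),
      specificity = c(tn, tn + fp),
      ppv         = c(tp, tp + fp),
      npv         = c(tn, tn + fn))
    rows <- lapply(names(spec_tab), function(m) {
      x <- spec_tab[[m]][1L]; n <- spec_tab[[m]][2L]
      if (n == 0L)
        return(data.frame(metric = m, estimate = NA_real_, lower = NA_real_,
                          upper = NA_real_, x = x, n = n))
      ci <- stats::binom.test(x, n, conf.level = ci_level)$conf.int
      data.frame(metric = m, estimate = 100 * x / n,
                 lower = 100 * ci[1L], upper = 100 * ci[2L], x = x, n = n)
    })
    do.call(rbind, rows)
  })
}

#' Empirical ROC-AUC with confidence interval
#'
#' The AUC is the empirical probability that a randomly chosen positive
#' score exceeds a randomly chosen negative score, with ties counting
#' one half. The confidence interval uses the DeLong variance method by
#' default, with a stratified bootstrap available behind `ci_method`.
#'
#' @param scores numeric scores (higher = more malignant).
#' @param truth truth labels.
#' @param ci_level confidence level, default 0.95.
#' @param ci_method "delong" (default) or "bootstrap".
#' @return list with `auc`, `lower`, `upper`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, truth, ci_level = 0.95, ci_method = c("delong", "bootstrap")) {
  ci_method <- match.arg(ci_method)
  pos <- as_positive(truth)
  if (!any(pos) || all(pos))
    stop("degenerate input: both classes required for ROC analysis", call. = FALSE)
  r <- pROC::roc(response = pos, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- pROC::ci.auc(r, conf.level = ci_level,
                     method = if (ci_method == "delong") "delong" else "bootstrap")
  list(auc = as.numeric(pROC::auc(r)), lower = ci[1L], upper = ci[3L],
       n_pos = sum(pos), n_neg = sum(!pos))
}

#' Spearman rank concordance between two score vectors
#'
#' Cross-platform agreement between cumulative methylation measured on two
#' assays, as a Spearman correlation with average ranks for ties.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return list with `spearman_r` and `n`; `spearman_r` is `NA` when
#'   either vector is constant (undefined correlation).
#' @export
spearman_concordance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(spearman_r = NA_real_, n = length(x)))
  r <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(spearman_r = unname(r$estimate), n = length(x))
}
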