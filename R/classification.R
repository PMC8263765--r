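#' Classify CM scores against a threshold
#'
#' A sample is called malignant when its cumulative methylation score
#' strictly exceeds the threshold; the threshold itself is read as
#' "threshold for benign", so a score exactly at the cutoff stays benign.
#' The default of 8.5 CM units is the laboratory threshold established in
#' the prospective study.
#'
#' @param cm numeric vector of CM scores (>= 0).
#' @param threshold CM units, default 8.5.
#' @return character vector, "malignant" or "benign".
#' @examples
#' classify_cm(c(0, 8.5, 8.6))
#' @export
classify_cm <- function(cm, threshold = 8.5) {
  if (any(!is.na(cm) & cm < 0)) stop("invalid score: cm must be >= 0", call. = FALSE)
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  ifelse(cm > threshold, "malignant", "benign")
}

#' Select a CM threshold from labeled scores
#'
#' Scans all candidate cutpoints (midpoints between adjacent sorted unique
#' scores, plus -Inf/+Inf sentinels) and returns the one maximizing
#' sensitivity subject to a specificity floor; ties broken by higher
#' specificity, then by lower threshold. This mirrors the laboratory rule
#' of choosing the ROC operating point with optimal sensitivity while
#' retaining at least 90% specificity.
#'
#' @param scores numeric CM (or other) scores.
#' @param truth logical or character truth; `TRUE`/"malignant" = positive.
#' @param min_specificity specificity floor in (0, 1), default 0.90.
#' @return list with `threshold`, `sensitivity`, `specificity`.
#' @export
select_threshold <- function(scores, truth, min_specificity = 0.90) {
  pos <- as_positive(truth)
  if (!any(pos) || all(pos))
    stop("both classes must be present to select a threshold", call. = FALSE)
  stopifnot(min_specificity > 0, min_specificity < 1)
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, Inf)
  sens <- vapply(cand, function(t) mean(scores[pos] > t), numeric(1L))
  spec <- vapply(cand, function(t) mean(scores[!pos] <= t), numeric(1L))
  feas <- spec >= min_specificity
  if (!any(feas)) stop("no feasible threshold meets the specificity floor",
                       call. = FALSE)
  ord <- order(-sens[feas], -spec[feas], cand[feas])
  i <- which(feas)[ord[1L]]
  list(threshold = cand[i], sensitivity = sens[i], specificity = spec[i])
}

#' Combine molecular and cytology calls
#'
#' Either-positive rule: the combined call is malignant if the molecular
#' assay or cytology calls malignant; an indeterminate cytology read is
#' non-informative and leaves the molecular call unchanged. This rule can
#' only raise sensitivity and lower specificity relative to the molecular
#' assay alone.
#'
#' @param assay_call character vector, "malignant"/"benign".
#' @param cytology character vector, "malignant"/"benign"/"indeterminate".
#' @return combined character calls.
#' @examples
#' combine_calls(c("benign", "benign"), c("malignant", "indeterminate"))
#' @export
combine_calls <- function(assay_call, cytology) {
  stopifnot(length(assay_call) == length(cytology),
            all(assay_call %in% c("malignant", "benign")),
            all(cytology %in% c("malignant", "benign", "indeterminate")))
  ifelse(assay_call == "malignant" | cytology == "malignant",
         "malignant", "benign")
}

#' @keywords internal
as_positive <- function(truth) {
  if (is.logical(truth)) return(truth)
  if (is.numeric(truth)) return(truth != 0)
  truth <- as.character(truth)
  bad <- !truth %in% c("malignant", "benign")
  if (any(bad)) stop("truth labels must be 'malignant' or 'benign'", call. = FALSE)
  truth == "malignant"
}
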