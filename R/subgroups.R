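#' Nonparametric group comparison of CM scores
#'
#' Two groups are compared with the two-sided Mann-Whitney (Wilcoxon
#' rank-sum) test, more than two with the Kruskal-Wallis test. The
#' two-group asymptotic p-value uses the tie-corrected normal
#' approximation without continuity correction, which coincides with the
#' Kruskal-Wallis chi-square formulation; exact enumeration is used when
#' both groups have fewer than 8 members and the data are tie-free.
#'
#' @param values numeric vector (e.g. CM scores).
#' @param groups group labels, same length.
#' @return list with `method`, `statistic`, `p_value`, `n_groups`.
#' @export
compare_groups <- function(values, groups) {
  if (length(values) != length(groups))
    stop("values and groups must have equal length", call. = FALSE)
  g <- split(values, factor(groups))
  if (length(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(g, length, integer(1L)) == 0L))
    stop("every group must be nonempty", call. = FALSE)
  if (length(g) == 2L) {
    exact <- all(lengths(g) < 8L) && !anyDuplicated(values)
    ht <- stats::wilcox.test(g[[1L]], g[[2L]], exact = exact, correct = FALSE)
    list(method = "mann-whitney", statistic = unname(ht$statistic),
         p_value = ht$p.value, n_groups = 2L)
  } else {
    ht <- stats::kruskal.test(values, factor(groups))
    list(method = "kruskal-wallis", statistic = unname(ht$statistic),
         p_value = ht$p.value, n_groups = length(g))
  }
}

#' Call-rate contingency table with exact test
#'
#' Tabulates positive/negative assay calls by stratum (e.g. IHC subtype)
#' and tests homogeneity of call rates with Fisher's exact test:
#' hypergeometric for a 2x2 table, seeded Monte-Carlo (>= 1e5 draws) for
#' wider tables. Empty strata are dropped with a warning.
#'
#' @param calls character "malignant"/"benign" calls.
#' @param strata stratum labels, same length.
#' @param b Monte-Carlo draws for tables wider than 2x2.
#' @param seed RNG seed for the Monte-Carlo p-value.
#' @return list with `table` (2 x k), `p_value`, `method`.
#' @export
call_rate_table <- function(calls, strata, b = 1e5, seed = 1L) {
  if (length(calls) != length(strata))
    stop("calls and strata must have equal length", call. = FALSE)
  f <- if (is.factor(strata)) strata else factor(strata)
  empty <- !levels(f) %in% unique(as.character(f))
  if (any(empty)) {
    warning("dropping empty strata: ", paste(levels(f)[empty], collapse = ", "))
    f <- droplevels(f)
  }
  if (nlevels(f) < 2L) stop("need >= 2 nonempty strata", call. = FALSE)
  tab <- table(factor(calls, levels = c("malignant", "benign")), f)
  if (nlevels(f) == 2L) {
    p <- stats::fisher.test(tab)$p.value
    method <- "fisher-exact"
  } else {
    set.seed(seed)
    p <- stats::fisher.test(tab, simulate.p.value = TRUE, B = b)$p.value
    method <- sprintf("fisher-monte-carlo (B=%g)", b)
  }
  list(table = tab, p_value = p, method = method)
}

#' Linear age trend in cumulative methylation
#'
#' Ordinary least-squares regression of CM on age; the slope's two-sided
#' p-value is reported with the Pearson correlation alongside (the two
#' carry the same t statistic but different scales, so both are kept).
#'
#' @param cm numeric CM scores.
#' @param age numeric ages (years), same length, n >= 3 for a p-value.
#' @return list with `slope`, `intercept`, `correlation`, `p_value`, `n`;
#'   `p_value` is `NA` with two points (zero residual df).
#' @export
age_trend <- function(cm, age) {
  if (length(cm) != length(age) || length(cm) < 2L)
    stop("need equal-length vectors with n >= 2", call. = FALSE)
  if (length(unique(age)) == 1L)
    stop("undefined slope: age is constant", call. = FALSE)
  fit <- stats::lm(cm ~ age)
  co <- stats::coef(fit)
  p <- if (stats::df.residual(fit) > 0L && length(cm) > 2L)
    summary(fit)$coefficients["age", "Pr(>|t|)"] else NA_real_
  list(slope = unname(co["age"]), intercept = unname(co["(Intercept)"]),
       correlation = stats::cor(cm, age), p_value = p, n = length(cm))
}

#' Misclassification risk versus age across CM thresholds
#'
#' For each candidate threshold, fits a logistic regression of the
#' misclassification indicator on age, separately per class: among benign
#' samples the event is a false-positive call (CM > threshold); among
#' malignant samples a false-negative call (CM <= threshold). A fit that
#' does not converge or separates completely is flagged rather than
#' reported.
#'
#' @param cm numeric CM scores.
#' @param age numeric ages.
#' @param truth truth labels.
#' @param thresholds numeric vector of CM thresholds to scan.
#' @return data.frame: `threshold`, `class` ("benign"/"malignant"),
#'   `coef_age` (log-odds per year), `se`, `p_value`, `n_events`,
#'   `converged`.
#' @export
misclassification_vs_age <- function(cm, age, truth, thresholds) {
  pos <- as_positive(truth)
  if (!any(pos) || all(pos))
    stop("both truth classes must be present", call. = FALSE)
  one <- function(thr, cls) {
    sel <- if (cls == "benign") !pos else pos
    y <- if (cls == "benign") cm[sel] > thr else cm[sel] <= thr
    a <- age[sel]
    n_ev <- sum(y)
    if (n_ev == 0L || n_ev == length(y))
      return(data.frame(threshold = thr, class = cls, coef_age = NA_real_,
                        se = NA_real_, p_value = NA_real_,
                        n_events = n_ev, converged = FALSE))
    fit <- suppressWarnings(stats::glm(y ~ a, family = stats::binomial()))
    sm <- summary(fit)$coefficients
    sep <- !fit$converged || any(abs(stats::coef(fit)) > 20)
    data.frame(threshold = thr, class = cls,
               coef_age = if (sep) NA_real_ else unname(stats::coef(fit)["a"]),
               se = if (sep) NA_real_ else sm["a", "Std. Error"],
               p_value = if (sep) NA_real_ else sm["a", "Pr(>|z|)"],
               n_events = n_ev, converged = !sep)
  }
  do.call(rbind, lapply(thresholds, function(thr)
    rbind(one(thr, "benign"), one(thr, "malignant"))))
}
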