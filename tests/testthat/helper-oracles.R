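# Independent oracles used against the package implementations. These are
# deliberately naive (normal equations, exhaustive enumeration, manual
# IRLS) so they share no code path with the functions they check.

# closed-form least squares of y on a single regressor x
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  list(slope = slope, intercept = intercept)
}

# empirical AUC by exhaustive positive/negative pair comparison, ties = 1/2
auc_pairs_oracle <- function(scores, positive) {
  s1 <- scores[positive]; s0 <- scores[!positive]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# exhaustive threshold search mirroring the laboratory rule by plain loops
select_threshold_oracle <- function(scores, positive, floor) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2, Inf)
  best <- NULL
  for (t in cand) {
    sens <- mean(scores[positive] > t)
    spec <- mean(scores[!positive] <= t)
    if (spec < floor) next
    if (is.null(best) || sens > best$sens + 1e-12 ||
        (abs(sens - best$sens) < 1e-12 && spec > best$spec + 1e-12) ||
        (abs(sens - best$sens) < 1e-12 && abs(spec - best$spec) < 1e-12 &&
         t < best$t)) {
      best <- list(t = t, sens = sens, spec = spec)
    }
  }
  best
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_enumeration_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pool <- c(x, y)
  ustat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- ustat(x, y)
  mu <- n1 * (n - n1) / 2
  idx <- utils::combn(n, n1)
  us <- apply(idx, 2, function(i) ustat(pool[i], pool[-i]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# logistic regression of y on x by manual iteratively-reweighted least squares
irls_oracle <- function(x, y, iter = 50) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (i in seq_len(iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta <- solve(t(X) %*% (w * X), t(X) %*% (w * z))
  }
  drop(beta)
}

# build a long Ct table for hand-specified delta-Ct values: gene Ct is
# actb_ct + dct; NA dct encodes an undetected target
make_ct_table <- function(sample_id, dct, panel = default_panel(), actb_ct = 28) {
  rows <- lapply(1:2, function(s) {
    genes <- panel$gene[panel$marker_set == s]
    data.frame(sample_id = sample_id, marker_set = s,
               gene = c("ACTB", genes),
               ct = c(actb_ct, actb_ct + dct[genes]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

unit_curves <- function(panel = default_panel()) default_curves(panel)

small_cohort_config <- function(...) {
  cohort_config(n_malignant = 60L, n_benign = 60L, ...)
}
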