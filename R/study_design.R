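#' Bootstrap confidence-interval half-width simulation
#'
#' Sample-size design by CI-width control: per replicate, draw `n`
#' Bernoulli outcomes at the assumed true rate, form a nonparametric
#' percentile bootstrap confidence interval for the proportion, and record
#' its half-width; summaries are taken over replicates. Resampling `n`
#' Bernoulli outcomes with replacement makes each bootstrap proportion an
#' exact Binomial(n, phat)/n draw, which is used directly for speed; the
#' distribution is identical to index resampling.
#'
#' @param true_rate assumed true proportion in (0, 1) (e.g. sensitivity 0.90).
#' @param n subjects per group.
#' @param ci_level bootstrap CI level, default 0.90.
#' @param n_boot bootstrap resamples per replicate, default 1000.
#' @param reps simulation replicates, default 2000.
#' @param seed RNG seed.
#' @return list with `mean`, `median`, `q90` of the CI half-widths, plus
#'   the simulation settings.
#' @examples
#' ci_halfwidth_simulation(0.9, 100, reps = 200, n_boot = 200, seed = 1)$mean
#' @export
ci_halfwidth_simulation <- function(true_rate, n, ci_level = 0.90,
                                    n_boot = 1000, reps = 2000, seed = 1L) {
  stopifnot(true_rate > 0, true_rate < 1, n >= 1, n_boot >= 1, reps >= 1)
  set.seed(seed)
  alpha <- (1 - ci_level) / 2
  hw <- vapply(seq_len(reps), function(i) {
    phat <- stats::rbinom(1L, n, true_rate) / n
    boot <- stats::rbinom(n_boot, n, phat) / n
    q <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE, type = 7)
    (q[2L] - q[1L]) / 2
  }, numeric(1L))
  list(mean = mean(hw), median = stats::median(hw),
       q90 = unname(stats::quantile(hw, 0.90)),
       true_rate = true_rate, n = n, ci_level = ci_level,
       n_boot = n_boot, reps = reps)
}

#' Exact enrollment probability for a two-arm diagnostic study
#'
#' Probability that enrolling `total` subjects at the given disease
#' prevalence yields at least `min_per_arm` subjects in both arms, by the
#' exact Binomial sum over admissible positive counts.
#'
#' @param total number enrolled.
#' @param prevalence probability a subject is in the positive arm, (0, 1).
#' @param min_per_arm required minimum per arm.
#' @return probability in \[0, 1\]; 0 when 2 * min_per_arm > total.
#' @examples
#' enrollment_probability(230, 0.5, 100)  # >= 0.95
#' @export
enrollment_probability <- function(total, prevalence, min_per_arm) {
  stopifnot(prevalence > 0, prevalence < 1, min_per_arm >= 0,
            min_per_arm <= total)
  if (2 * min_per_arm > total) return(0)
  if (min_per_arm == 0) return(1)
  stats::pbinom(total - min_per_arm, total, prevalence) -
    stats::pbinom(min_per_arm - 1L, total, prevalence)
}
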