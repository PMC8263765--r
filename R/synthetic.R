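#' Synthetic cohort generator configuration
#'
#' Defaults emulate the statistical structure of the prospective
#' lymph-node study: a roughly 50% prevalence cohort of 230 aspirates
#' (110 malignant, 120 benign before exclusions), benign cumulative
#' methylation concentrated near zero (median about 1.9 CM units from
#' per-gene exponential noise), malignant CM broadly elevated through a
#' two-part per-gene model (a detectability spike times a scaled-Beta
#' methylation level), a cytology caller with 92.5% sensitivity / 95.3%
#' specificity and a small indeterminate rate (6/218), and an
#' inadequate-DNA rate of 12/230.
#'
#' @param ... overrides for any default field.
#' @return list of class `cohort_config`.
#' @section Fields:
#' * `panel`: ten-gene panel data.frame.
#' * `n_malignant`, `n_benign`: arm sizes (110 / 120).
#' * `detectable_frac`: probability a malignant aspirate carries enough
#'   tumor DNA to methylate above background (0.91).
#' * `per_gene_positive_prob`: per-gene probability a detectable malignant
#'   sample is methylated at that gene (0.5 each).
#' * `malignant_shape1`, `malignant_shape2`: Beta shape parameters of the
#'   per-gene methylated fraction in positive genes (2, 4).
#' * `benign_scale`: mean (percent) of the per-gene exponential background
#'   (0.2, giving benign median CM about 1.9).
#' * `age_coef`: benign log-scale CM drift per year of age (0.008).
#' * `cytology_sensitivity`, `cytology_specificity`: 0.925 / 0.953.
#' * `indeterminate_rate`: 6/218; `inadequate_rate`: 12/230.
#' * `slope`, `intercept`: shared calibration curve coefficients (-1, 5).
#' * `ct_noise_sd`: Gaussian Ct noise in cycles (0.2).
#' * `actb_ct_mean`, `actb_ct_sd`: ACTB reference Ct distribution (28, 1).
#' * `detection_floor_percent`: percent below which a target fails to
#'   amplify and is reported undetected (0.01).
#' * `seed`: RNG seed for the whole cohort draw.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    panel = default_panel(),
    n_malignant = 110L,
    n_benign = 120L,
    detectable_frac = 0.91,
    per_gene_positive_prob = stats::setNames(rep(0.5, 10L), default_panel()$gene),
    malignant_shape1 = 2,
    malignant_shape2 = 4,
    benign_scale = 0.2,
    age_coef = 0.008,
    cytology_sensitivity = 0.925,
    cytology_specificity = 0.953,
    indeterminate_rate = 6 / 218,
    inadequate_rate = 12 / 230,
    slope = -1,
    intercept = 5,
    ct_noise_sd = 0.2,
    actb_ct_mean = 28,
    actb_ct_sd = 1,
    detection_floor_percent = 0.01,
    age_mean_malignant = 51, age_mean_benign = 52, age_sd = 10,
    region_prob_china = 0.85,
    subtype_probs = c("ER/PR+HER2-" = 0.40, "ER/PR+HER2+" = 0.20,
                      "ER/PR-HER2+" = 0.14, "ER/PR-HER2-" = 0.12,
                      "unknown" = 0.14),
    stage_probs = c(I = 0.15, II = 0.45, III = 0.30, IV = 0.01,
                    unknown = 0.09),
    nac_frac = 0.464,
    miller_payne_probs = c(0.15, 0.20, 0.30, 0.20, 0.15),
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = "cohort_config")
}

# draw the n x 10 per-gene percent matrix for one arm; RNG state is the
# caller's. Benign background is exponential with optional age drift;
# malignant samples add a two-part spike-times-Beta signal when the
# aspirate carries detectable tumor DNA.
draw_percent_matrix <- function(n, malignant, ages, cfg) {
  k <- nrow(cfg$panel)
  if (n == 0L) return(matrix(numeric(0), 0L, k, dimnames = list(NULL, cfg$panel$gene)))
  bg <- matrix(stats::rexp(n * k, rate = 1 / cfg$benign_scale), n, k)
  if (!malignant) bg <- bg * exp(cfg$age_coef * (ages - 50))
  pct <- bg
  if (malignant) {
    detect <- stats::rbinom(n, 1L, cfg$detectable_frac)
    p <- rep(cfg$per_gene_positive_prob[cfg$panel$gene], each = n)
    on <- matrix(stats::rbinom(n * k, 1L, p), n, k)
    level <- matrix(100 * stats::rbeta(n * k, cfg$malignant_shape1,
                                       cfg$malignant_shape2), n, k)
    pct <- bg + detect * on * level
  }
  pct <- pmin(pct, 100)
  colnames(pct) <- cfg$panel$gene
  pct
}

rtruncage <- function(n, mean, sd) pmin(pmax(stats::rnorm(n, mean, sd), 25), 85)

#' Implied operating characteristics of the generator
#'
#' The generator's truth is defined by its percent-methylation model, not
#' by the Ct round trip; this evaluates that truth at a CM threshold by a
#' large seeded Monte-Carlo draw from the percent model directly.
#'
#' @param config a `cohort_config`.
#' @param threshold CM threshold (default 8.5).
#' @param n draws per arm (default 1e5).
#' @param seed RNG seed for the reference draw.
#' @return list with `sensitivity`, `specificity`, `auc` (proportions).
#' @export
operating_characteristics <- function(config = cohort_config(), threshold = 8.5,
                                      n = 1e5, seed = 999L) {
  set.seed(seed)
  age_m <- rtruncage(n, config$age_mean_malignant, config$age_sd)
  age_b <- rtruncage(n, config$age_mean_benign, config$age_sd)
  cm_m <- rowSums(draw_percent_matrix(n, TRUE, age_m, config))
  cm_b <- rowSums(draw_percent_matrix(n, FALSE, age_b, config))
  rk <- rank(c(cm_m, cm_b))
  auc <- (sum(rk[seq_len(n)]) - n * (n + 1) / 2) / (as.numeric(n) * n)
  list(sensitivity = mean(cm_m > threshold),
       specificity = mean(cm_b <= threshold),
       auc = auc)
}

#' Generate a synthetic calibration plate
#'
#' One six-point two-fold dilution series (100% down to 3.12%) per panel
#' gene, with delta-Ct = slope * log2(fraction) + intercept plus Gaussian
#' noise, emitted in the plate CSV layout read by
#' [read_calibration_plate()].
#'
#' @param config a `cohort_config` (uses `slope`, `intercept`,
#'   `ct_noise_sd`, `actb_ct_mean`, `seed`).
#' @return data.frame with columns gene, methylated_percent, ct_gene, ct_actb.
#' @export
generate_calibration_plate <- function(config = cohort_config()) {
  set.seed(config$seed)
  pcts <- dilution_series()
  rows <- lapply(config$panel$gene, function(g) {
    actb <- rep(config$actb_ct_mean, length(pcts))
    dct <- config$intercept + config$slope * log2(pcts / 100) +
      stats::rnorm(length(pcts), 0, config$ct_noise_sd)
    data.frame(gene = g, methylated_percent = pcts,
               ct_gene = actb + dct, ct_actb = actb,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a synthetic Ct-level cohort
#'
#' Draws truth labels and per-gene percent methylation from the configured
#' model, inverts the calibration curve to delta-Ct, adds Ct noise, and
#' emits gene Ct = ACTB Ct + delta-Ct in the long Ct-table layout read by
#' [read_ct_table()]. A fixed number of samples, `round(inadequate_rate *
#' n)`, is masked as inadequate DNA (ACTB undetected in one marker set);
#' cytology calls follow the configured error model with an independent
#' indeterminate rate; patient metadata (age, region, IHC subtype, stage,
#' positive nodes, Miller-Payne grade) come from configurable categorical
#' distributions. Fully reproducible from `config$seed`.
#'
#' @param config a `cohort_config`.
#' @return list with `ct` (long Ct data.frame), `metadata` (one row per
#'   sample: histology, cytology, age, region, subtype, stage,
#'   positive_nodes, miller_payne, nac_responder, inadequate), and
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_malignant + cfg$n_benign
  panel <- cfg$panel

  histology <- sample(rep(c("malignant", "benign"),
                          c(cfg$n_malignant, cfg$n_benign)))
  sample_id <- sprintf("S%04d", seq_len(n))
  pos <- histology == "malignant"
  age <- numeric(n)
  age[pos] <- rtruncage(sum(pos), cfg$age_mean_malignant, cfg$age_sd)
  age[!pos] <- rtruncage(sum(!pos), cfg$age_mean_benign, cfg$age_sd)

  pct <- matrix(NA_real_, n, nrow(panel), dimnames = list(NULL, panel$gene))
  pct[pos, ] <- draw_percent_matrix(sum(pos), TRUE, age[pos], cfg)
  pct[!pos, ] <- draw_percent_matrix(sum(!pos), FALSE, age[!pos], cfg)

  # cytology error model: independent indeterminate rate, then a flip
  # with the configured sensitivity/specificity
  indet <- stats::runif(n) < cfg$indeterminate_rate
  correct_p <- ifelse(pos, cfg$cytology_sensitivity, cfg$cytology_specificity)
  correct <- stats::runif(n) < correct_p
  cytology <- ifelse(correct, histology,
                     ifelse(pos, "benign", "malignant"))
  cytology[indet] <- "indeterminate"

  n_inadequate <- round(cfg$inadequate_rate * n)
  inadequate <- rep(FALSE, n)
  if (n_inadequate > 0L) inadequate[sample.int(n, n_inadequate)] <- TRUE

  region <- ifelse(stats::runif(n) < cfg$region_prob_china, "China", "US")
  subtype <- if (n) sample(names(cfg$subtype_probs), n, TRUE, cfg$subtype_probs) else character(0)
  stage <- if (n) sample(names(cfg$stage_probs), n, TRUE, cfg$stage_probs) else character(0)
  positive_nodes <- ifelse(pos, sample(1:8, n, TRUE,
                                       c(.25, .2, .15, .12, .1, .08, .06, .04)), NA)
  nac <- pos & stats::runif(n) < cfg$nac_frac
  miller_payne <- rep(NA_integer_, n)
  if (any(nac)) miller_payne[nac] <- sample(1:5, sum(nac), TRUE,
                                            cfg$miller_payne_probs)

  # Ct emission: per marker set an ACTB reference Ct, per gene
  # Ct = ACTB Ct + delta-Ct(percent) + noise; percent below the detection
  # floor never amplifies
  actb <- matrix(stats::rnorm(n * 2L, cfg$actb_ct_mean, cfg$actb_ct_sd), n, 2L)
  ct_rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- lapply(1:2, function(s) {
      genes <- panel$gene[panel$marker_set == s]
      p <- pct[i, genes]
      detected <- p >= cfg$detection_floor_percent
      dct <- ifelse(detected,
                    cfg$intercept + cfg$slope * log2(p / 100) +
                      stats::rnorm(length(genes), 0, cfg$ct_noise_sd),
                    NA_real_)
      actb_ct <- if (inadequate[i] && s == 1L) NA_real_ else actb[i, s]
      data.frame(sample_id = sample_id[i], marker_set = s,
                 gene = c(ACTB, genes),
                 ct = c(actb_ct, actb[i, s] + dct),
                 stringsAsFactors = FALSE)
    })
    ct_rows[[i]] <- do.call(rbind, rows)
  }
  ct <- if (n) do.call(rbind, ct_rows) else
    data.frame(sample_id = character(0), marker_set = integer(0),
               gene = character(0), ct = numeric(0))
  rownames(ct) <- NULL

  metadata <- data.frame(
    sample_id = sample_id, histology = histology, cytology = cytology,
    age = age, region = region, subtype = subtype, stage = stage,
    positive_nodes = positive_nodes, miller_payne = miller_payne,
    nac_responder = ifelse(is.na(miller_payne), NA, miller_payne >= 4L),
    inadequate = inadequate, stringsAsFactors = FALSE)

  list(ct = ct, metadata = metadata, config = cfg)
}

#' Write a complete demo study to disk
#'
#' Emits the calibration plate CSV, cohort Ct CSV, metadata CSV and the
#' generator configuration (JSON) in the dialects read by the pipeline.
#'
#' @param dir output directory (created if needed).
#' @param config a `cohort_config`.
#' @return invisibly, the named vector of file paths.
#' @export
write_demo_study <- function(dir, config = cohort_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(plate = file.path(dir, "calibration_plate.csv"),
             ct = file.path(dir, "ct_table.csv"),
             metadata = file.path(dir, "metadata.csv"),
             config = file.path(dir, "generator_config.json"))
  plate <- generate_calibration_plate(config)
  cohort <- generate_cohort(config)
  utils::write.csv(plate, paths["plate"], row.names = FALSE)
  utils::write.csv(cohort$ct, paths["ct"], row.names = FALSE)
  utils::write.csv(cohort$metadata, paths["metadata"], row.names = FALSE)
  cfg <- unclass(config)
  cfg$panel <- NULL
  cfg$genes <- config$panel$gene
  jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
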