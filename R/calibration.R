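#' Two-fold dilution series of methylated DNA
#'
#' Calibration plates use mixtures of fully methylated and unmethylated DNA
#' in a geometric dilution series; the standard design starts at 100%
#' methylation and halves six times down to 3.12% (as displayed at two
#' decimals).
#'
#' @param start_percent highest methylated percent (> 0).
#' @param n_points number of dilution points (>= 2).
#' @param fold dilution factor between consecutive points (> 1).
#' @return numeric vector of methylated percents, descending.
#' @examples
#' dilution_series()           # 100, 50, 25, 12.5, 6.25, 3.125
#' round(min(dilution_series()), 2)  # displayed low endpoint 3.12
#' @export
dilution_series <- function(start_percent = 100, n_points = 6, fold = 2) {
  if (!is.numeric(start_percent) || length(start_percent) != 1L || start_percent <= 0)
    stop("start_percent must be a single positive number", call. = FALSE)
  if (!is.numeric(n_points) || n_points < 2 || n_points != round(n_points))
    stop("n_points must be an integer >= 2", call. = FALSE)
  if (!is.numeric(fold) || fold <= 1)
    stop("fold must be > 1", call. = FALSE)
  start_percent / fold^(seq_len(n_points) - 1L)
}

#' Fit a per-gene standard curve
#'
#' Ordinary least squares of the observed delta-Ct (Ct of the methylated
#' target minus Ct of the ACTB reference) on log2 of the methylated-DNA
#' fraction. The two-fold dilution design makes log2 the natural scale; a
#' perfectly efficient PCR gives a slope of -1 cycle per two-fold dilution.
#'
#' @param fractions methylated fractions in (0, 1], one per calibration well.
#' @param delta_ct observed delta-Ct values (cycles), same length.
#' @param gene gene symbol attached to the curve.
#' @return object of class `calibration_curve`: list with `gene`, `slope`
#'   (cycles per log2 fraction, negative), `intercept` (delta-Ct at
#'   fraction 1), `residual_rms` (cycles) and the calibration `points`.
#' @examples
#' f <- dilution_series() / 100
#' fit_standard_curve(f, -log2(f) + 5, gene = "APC")
#' @export
fit_standard_curve <- function(fractions, delta_ct, gene = "gene") {
  if (length(fractions) != length(delta_ct))
    stop("fractions and delta_ct must have equal length", call. = FALSE)
  ok <- is.finite(fractions) & is.finite(delta_ct)
  if (!all(ok)) stop("calibration points must be finite", call. = FALSE)
  if (any(fractions <= 0 | fractions > 1))
    stop("methylated fractions must lie in (0, 1]", call. = FALSE)
  if (length(unique(fractions)) < 3L)
    stop("insufficient calibration: need >= 3 points with distinct fractions",
         call. = FALSE)
  x <- log2(fractions)
  fit <- stats::lm.fit(cbind(1, x), delta_ct)
  curve <- structure(list(
    gene = gene,
    slope = unname(fit$coefficients[2L]),
    intercept = unname(fit$coefficients[1L]),
    residual_rms = sqrt(mean(fit$residuals^2)),
    points = data.frame(methylated_fraction = fractions, delta_ct = delta_ct)
  ), class = "calibration_curve")
  curve
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: slope %.4f cycles/log2, intercept %.4f, rms %.4f (%d points)\n",
              x$gene, x$slope, x$intercept, x$residual_rms, nrow(x$points)))
  invisible(x)
}

#' Invert a standard curve to percent methylation
#'
#' Maps a sample's delta-Ct through the fitted curve:
#' fraction = 2^((delta_ct - intercept) / slope), reported as a percent
#' clamped to \[0, 100\]. A target that never amplified (`NA` delta-Ct) is
#' read as absence of methylated template and returns 0.
#'
#' @param curve a `calibration_curve`.
#' @param delta_ct numeric vector of delta-Ct values; `NA` marks an
#'   undetected target.
#' @return percent methylation in \[0, 100\], same length as `delta_ct`.
#' @examples
#' cv <- fit_standard_curve(c(1, .5, .25, .125), -log2(c(1, .5, .25, .125)) + 5)
#' percent_methylation(cv, c(5, 8, NA))  # 100, 12.5, 0
#' @export
percent_methylation <- function(curve, delta_ct) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(!is.na(delta_ct) & !is.finite(delta_ct)))
    stop("invalid measurement: delta_ct must be finite or NA (undetected)",
         call. = FALSE)
  frac <- 2^((delta_ct - curve$intercept) / curve$slope)
  frac[is.na(delta_ct)] <- 0
  pmin(pmax(frac, 0), 1) * 100
}

#' Default curve set for synthetic work
#'
#' When per-gene calibration plates are not supplied, every panel gene
#' shares an ideal-efficiency curve (slope -1) with a common intercept.
#'
#' @param panel panel data.frame (see [default_panel()]).
#' @param slope,intercept shared curve coefficients.
#' @return named list of `calibration_curve` objects, one per panel gene.
#' @export
default_curves <- function(panel = default_panel(), slope = -1, intercept = 5) {
  check_panel(panel)
  f <- dilution_series() / 100
  curves <- lapply(panel$gene, function(g)
    fit_standard_curve(f, intercept + slope * log2(f), gene = g))
  names(curves) <- panel$gene
  curves
}

#' Read a calibration plate and fit one curve per gene
#'
#' The plate file is a CSV with columns `gene`, `methylated_percent`,
#' `ct_gene`, `ct_actb` (one row per well); delta-Ct is formed per well as
#' `ct_gene - ct_actb` and each gene's wells are fitted with
#' [fit_standard_curve()].
#'
#' @param path CSV file path.
#' @return named list of `calibration_curve` objects.
#' @export
read_calibration_plate <- function(path) {
  plate <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "methylated_percent", "ct_gene", "ct_actb")
  if (!all(need %in% names(plate)))
    stop("calibration plate must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  curves <- lapply(split(plate, plate$gene), function(d)
    fit_standard_curve(d$methylated_percent / 100, d$ct_gene - d$ct_actb,
                       gene = d$gene[1L]))
  curves[unique(plate$gene)]
}

#' Serialize / restore a curve store
#'
#' Curves are stored as JSON keyed by gene, holding slope, intercept,
#' residual RMS and the calibration points.
#'
#' @param curves named list of `calibration_curve` objects.
#' @param path JSON file path.
#' @return `read_curve_store()` returns the named curve list.
#' @export
write_curve_store <- function(curves, path) {
  obj <- lapply(curves, function(cv) list(
    gene = cv$gene, slope = cv$slope, intercept = cv$intercept,
    residual_rms = cv$residual_rms, points = cv$points))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_curve_store
#' @export
read_curve_store <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  curves <- lapply(obj, function(o) structure(list(
    gene = o$gene, slope = o$slope, intercept = o$intercept,
    residual_rms = o$residual_rms,
    points = as.data.frame(o$points)), class = "calibration_curve"))
  curves
}
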