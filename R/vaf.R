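#' Detection-limit filter on a frequency spectrum
#'
#' Drops mutations whose cell fraction is below the detection limit
#' (inclusive at the limit): at standard sequencing depth, mutations
#' below about 1% frequency are effectively invisible, so the default
#' limit is 0.01.
#'
#' @param spectrum A `frequency_spectrum` (cell-fraction convention).
#' @param limit Minimum detectable cell fraction, in (0, 1).  `limit = 0`
#'   is allowed and is the identity.
#' @return The filtered `frequency_spectrum`.
#' @export
detection_filter <- function(spectrum, limit = 0.01) {
  stopifnot(inherits(spectrum, "frequency_spectrum"),
            limit >= 0, limit < 1)
  out <- spectrum[spectrum$cell_fraction >= limit, , drop = FALSE]
  attributes(out) <- c(attributes(out)[c("names", "row.names", "class")],
                       attributes(spectrum)[c("universe_size",
                                              "convention")])
  out
}

#' Cumulative variant-allele-frequency curve
#'
#' Builds the cumulative mutation count \eqn{M(v)} = number of mutations
#' with frequency at least \eqn{v}, evaluated at the distinct observed
#' frequencies, as points \eqn{(1/v, M(v))}.  Under neutral exponential
#' growth the curve is linear,
#' \eqn{M(v) = (\mu/\beta)(1/v - 1/v_{max})}, and its slope is the
#' effective mutation rate.
#'
#' The native convention is the diploid heterozygous VAF
#' \eqn{v = f_c / 2} with \eqn{v_{max} = 1/2}: with one Poisson
#' (\eqn{\lambda}) draw per daughter, the expected slope then equals
#' \eqn{\lambda} exactly.  The raw cell-fraction convention
#' (\eqn{v = f_c}, \eqn{v_{max} = 1}, expected slope \eqn{2\lambda}) is
#' available as an option.
#'
#' @param spectrum A (typically detection-filtered) `frequency_spectrum`.
#' @param convention `"diploid_vaf"` (default) or `"cell_fraction"`.
#' @return A `cumulative_curve`: data frame with columns `freq`,
#'   `inv_freq`, `cumulative_count`, ordered by increasing `inv_freq`,
#'   with attributes `f_max`, `convention`, `truncated`.
#' @export
cumulative_vaf <- function(spectrum,
                           convention = c("diploid_vaf",
                                          "cell_fraction")) {
  stopifnot(inherits(spectrum, "frequency_spectrum"))
  convention <- match.arg(convention)
  if (nrow(spectrum) == 0L)
    stop("empty frequency spectrum", call. = FALSE)
  v <- spectrum$cell_fraction
  if (convention == "diploid_vaf") v <- v / 2
  vs <- sort(unique(v), decreasing = TRUE)
  m <- cumsum(tabulate(match(v, vs), length(vs)))
  structure(data.frame(freq = vs, inv_freq = 1 / vs,
                       cumulative_count = m),
            f_max = if (convention == "diploid_vaf") 0.5 else 1,
            convention = convention, truncated = FALSE,
            class = c("cumulative_curve", "data.frame"))
}

#' Drop the lowest-frequency points of a cumulative curve
#'
#' Removes the `n_points` points with the largest \eqn{1/v} (the lowest
#' frequencies) before regression.  The points nearest the detection
#' limit are depleted by the limit itself and would otherwise bias the
#' fit, hence the convention of discarding the last few dots (three by
#' default) of the cumulative curve.
#'
#' @param curve A `cumulative_curve`.
#' @param n_points Number of points to drop; 0 is the identity.
#' @return The truncated `cumulative_curve` (attribute `truncated` set).
#' @export
truncate_low_frequency <- function(curve, n_points = 3) {
  stopifnot(inherits(curve, "cumulative_curve"), n_points >= 0)
  if (n_points == 0) return(curve)
  if (nrow(curve) <= n_points)
    stop("curve has too few points to truncate", call. = FALSE)
  keep <- order(curve$inv_freq)[seq_len(nrow(curve) - n_points)]
  out <- curve[sort(keep), , drop = FALSE]
  attributes(out) <- c(attributes(out)[c("names", "row.names", "class")],
                       attributes(curve)[c("f_max", "convention")],
                       list(truncated = TRUE))
  out
}

#' Kolmogorov-Smirnov-style distance of a curve from a fitted line
#'
#' Both the observed cumulative counts and the fitted line are normalised
#' by the maximum observed count over the fitted points; the distance is
#' the maximum absolute difference between the two normalised curves,
#' clipped to \[0, 1\].  0 means the curve lies exactly on the line;
#' values near 1 mean gross deviation from linearity (as under surface
#' growth).
#'
#' @param curve A `cumulative_curve`.
#' @param slope,intercept Coefficients of the fitted line
#'   `M = intercept + slope / v`.
#' @return The distance `D` in \[0, 1\].
#' @export
ks_distance <- function(curve, slope, intercept) {
  stopifnot(inherits(curve, "cumulative_curve"))
  mx <- max(curve$cumulative_count)
  if (mx <= 0) stop("degenerate curve", call. = FALSE)
  fitted <- intercept + slope * curve$inv_freq
  d <- max(abs(curve$cumulative_count - fitted)) / mx
  min(max(d, 0), 1)
}

#' Fit the effective mutation rate from a cumulative VAF curve
#'
#' Ordinary least squares of the cumulative count against \eqn{1/v} with
#' a free intercept.  The slope estimates the effective mutation rate
#' \eqn{\mu/\beta} (mutations per division scaled by the birth/death
#' structure; equal to the per-division rate in this pure-birth model).
#' The free intercept absorbs detection-limit truncation effects rather
#' than forcing the theoretical \eqn{-(\mu/\beta)/v_{max}}.
#'
#' @param curve A (typically truncated) `cumulative_curve` with at least
#'   two points.
#' @return A `vaf_fit`: list with `slope`, `intercept`, `ks_distance`,
#'   `n_points`, `convention`.
#' @export
fit_effective_mutation_rate <- function(curve) {
  stopifnot(inherits(curve, "cumulative_curve"))
  if (nrow(curve) < 2L)
    stop("need at least 2 points to fit", call. = FALSE)
  if (stats::sd(curve$inv_freq) == 0)
    stop("zero variance in 1/v; cannot fit", call. = FALSE)
  fit <- lm(cumulative_count ~ inv_freq, data = curve)
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  structure(list(slope = slope, intercept = intercept,
                 ks_distance = ks_distance(curve, slope, intercept),
                 n_points = nrow(curve),
                 convention = attr(curve, "convention")),
            class = "vaf_fit")
}

#' @export
print.vaf_fit <- function(x, ...) {
  cat(sprintf(
    "<vaf_fit> mu/beta = %.3f (intercept %.2f, KS distance %.4f, %d points, %s)\n",
    x$slope, x$intercept, x$ks_distance, x$n_points, x$convention))
  invisible(x)
}

#' One-call mutation-rate inference
#'
#' Convenience pipeline: frequency spectrum over a cell universe,
#' detection filter, cumulative curve, low-frequency truncation, least
#' squares.  Defaults for the detection limit and the number of truncated
#' points come from the tumour's configuration.
#'
#' @param tumour A `tumour` object.
#' @param cells Cell universe (default: all alive cells).  Pass the
#'   member cells of a spatial sample for within-sample inference; sample
#'   frequencies are re-normalised to the sample.
#' @param detection_limit,truncation_points Override the configured
#'   values.
#' @param convention Frequency convention for [cumulative_vaf()].
#' @return A `vaf_fit`.
#' @export
infer_mutation_rate <- function(tumour, cells = NULL,
                                detection_limit = NULL,
                                truncation_points = NULL,
                                convention = "diploid_vaf") {
  stopifnot(inherits(tumour, "tumour"))
  if (is.null(detection_limit))
    detection_limit <- tumour$config$detection_limit
  if (is.null(truncation_points))
    truncation_points <- tumour$config$truncation_points
  spec <- mutation_frequencies(tumour, cells)
  spec <- detection_filter(spec, detection_limit)
  curve <- cumulative_vaf(spec, convention)
  curve <- truncate_low_frequency(curve, truncation_points)
  fit_effective_mutation_rate(curve)
}
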