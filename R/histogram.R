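#' Intensity histogram of a volume
#'
#' Equal-width bins spanning the `[min, max]` range of the selected voxels.
#' Bins are left-closed and right-open except the final bin, which is
#' right-closed so the maximum value is counted.
#'
#' @param vol an [`mri_volume`][volume].
#' @param n_bins number of bins (>= 2). The default 256 is a conventional
#'   gray-level resolution; results are insensitive to it at realistic noise
#'   levels.
#' @param foreground_only count only foreground voxels (see
#'   [foreground_mask()]).
#' @return An `intensity_histogram`: list with `bin_edges` (length
#'   `n_bins + 1`, strictly increasing), `counts` (length `n_bins`), and
#'   `n_voxels = sum(counts)`.
#' @export
compute_histogram <- function(vol, n_bins = 256, foreground_only = TRUE) {
  stopifnot(inherits(vol, "mri_volume"))
  vals <- if (foreground_only) foreground_values(vol) else as.numeric(vol$data)
  if (length(vals) == 0L)
    stop("empty foreground: the mask (or positive-intensity rule) selects no voxels")
  .make_histogram(vals, n_bins)
}

.make_histogram <- function(vals, n_bins, rng = range(vals)) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L)
    stop("n_bins must be an integer >= 2")
  if (rng[1] == rng[2])
    stop("degenerate constant image: histogram range is empty")
  w <- (rng[2] - rng[1]) / n_bins
  idx <- pmin(floor((vals - rng[1]) / w) + 1L, n_bins)  # last bin right-closed
  structure(list(bin_edges = seq(rng[1], rng[2], length.out = n_bins + 1L),
                 counts = tabulate(idx, nbins = n_bins),
                 n_voxels = length(vals)),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat("intensity_histogram: ", length(x$counts), " bins over [",
      signif(x$bin_edges[1], 6), ", ", signif(max(x$bin_edges), 6), "], ",
      x$n_voxels, " voxels\n", sep = "")
  invisible(x)
}

#' Mode of an intensity histogram
#'
#' Center of the bin with the highest count; ties are broken toward the
#' lowest-intensity bin.
#'
#' @param h an `intensity_histogram` from [compute_histogram()].
#' @return The modal intensity (a bin center).
#' @export
histogram_mode <- function(h) {
  stopifnot(inherits(h, "intensity_histogram"))
  i <- which.max(h$counts)  # first maximum = lowest bin on ties
  (h$bin_edges[i] + h$bin_edges[i + 1L]) / 2
}

#' Order-statistic percentile of a volume's intensities
#'
#' Linear interpolation between adjacent order statistics (the convention of
#' [stats::quantile()] type 7).
#'
#' @inheritParams compute_histogram
#' @param q fraction in \[0, 1\]; `q = 0` is the minimum, `q = 1` the maximum.
#' @return The interpolated intensity.
#' @export
intensity_percentile <- function(vol, q, foreground_only = TRUE) {
  stopifnot(inherits(vol, "mri_volume"))
  if (!is.numeric(q) || any(q < 0) || any(q > 1))
    stop("q must lie in [0, 1]")
  vals <- if (foreground_only) foreground_values(vol) else as.numeric(vol$data)
  if (length(vals) == 0L)
    stop("empty foreground: the mask (or positive-intensity rule) selects no voxels")
  stats::quantile(vals, q, type = 7, names = FALSE)
}

#' Construct a landmark set
#'
#' The triple (low, mean, high) plus observed extrema that parameterizes the
#' piecewise-linear intensity mapping for one image: the minimum-decile and
#' maximum-decile intensities bounding the intensity of interest (IOI), the
#' mean intensity inside it, and the observed foreground minimum/maximum to
#' which the mapping's tails extend.
#'
#' @param low,mean_val,high IOI landmarks, strictly increasing.
#' @param obs_min,obs_max observed foreground extrema, with
#'   `obs_min <= low` and `high <= obs_max`.
#' @return An object of class `landmark_set`.
#' @seealso [compute_landmarks()]
#' @export
landmark_set <- function(low, mean_val, high, obs_min, obs_max) {
  v <- c(obs_min = obs_min, low = low, mean_val = mean_val,
         high = high, obs_max = obs_max)
  if (any(!is.finite(v)))
    stop("landmarks must all be finite")
  if (!(obs_min <= low && low < mean_val && mean_val < high && high <= obs_max))
    stop("landmarks violate ordering obs_min <= low < mean < high <= obs_max (",
         paste(signif(v, 6), collapse = ", "), ")")
  structure(list(low = low, mean_val = mean_val, high = high,
                 obs_min = obs_min, obs_max = obs_max),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set: low ", signif(x$low, 6), ", mean ", signif(x$mean_val, 6),
      ", high ", signif(x$high, 6), " (observed range [",
      signif(x$obs_min, 6), ", ", signif(x$obs_max, 6), "])\n", sep = "")
  invisible(x)
}

#' @export
as.list.landmark_set <- function(x, ...) unclass(x)

#' Extract the three-landmark set of a volume
#'
#' Trims background and outliers by restricting to the foreground and to the
#' intensity of interest bounded by the `low_q` and `high_q` quantiles; the
#' landmarks are the two quantiles, the mean of the IOI-trimmed foreground
#' intensities, and the observed foreground extrema.
#'
#' @param vol an [`mri_volume`][volume] with a non-empty foreground.
#' @param low_q,high_q trimming quantiles; the defaults read the minimum /
#'   maximum decile as the 10th / 90th percentile.
#' @return A [landmark_set()].
#' @export
compute_landmarks <- function(vol, low_q = 0.10, high_q = 0.90) {
  stopifnot(inherits(vol, "mri_volume"))
  if (!(is.numeric(low_q) && is.numeric(high_q) &&
        low_q >= 0 && low_q < high_q && high_q <= 1))
    stop("quantiles must satisfy 0 <= low_q < high_q <= 1")
  vals <- foreground_values(vol)
  if (length(vals) == 0L)
    stop("empty foreground: the mask (or positive-intensity rule) selects no voxels")
  qs <- stats::quantile(vals, c(low_q, high_q), type = 7, names = FALSE)
  low <- qs[1]; high <- qs[2]
  mu <- mean(vals[vals >= low & vals <= high])
  if (!(low < mu && mu < high))
    stop("landmarks are not strictly ordered (low = ", signif(low, 6),
         ", mean = ", signif(mu, 6), ", high = ", signif(high, 6),
         "); the image may be nearly binary - try different quantiles")
  landmark_set(low, mu, high, min(vals), max(vals))
}
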