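#' Rescale a reference volume over its decile-trimmed intensity range
#'
#' The intensity scaling (IS) step applied to the reference image: every
#' foreground voxel is mapped by `f' = (f - LIR) / (HIR - LIR)`, where LIR
#' and HIR are the minimum-decile and maximum-decile landmarks, so the
#' reference IOI lands on \[0, 1\]. Values below LIR map below 0 and above
#' HIR above 1 — the tails are not clipped; the normalization step handles
#' them by linear extension. Background voxels are never transformed: on a
#' skull-stripped scan they are exactly 0 and stay 0.
#'
#' @param ref the reference [`mri_volume`][volume].
#' @param landmarks a [landmark_set()] for `ref`; computed with the default
#'   quantiles when omitted.
#' @return The rescaled [`mri_volume`][volume].
#' @export
scale_reference <- function(ref, landmarks = NULL) {
  stopifnot(inherits(ref, "mri_volume"))
  if (is.null(landmarks)) landmarks <- compute_landmarks(ref)
  stopifnot(inherits(landmarks, "landmark_set"))
  if (landmarks$high == landmarks$low)
    stop("degenerate image: HIR equals LIR")
  fg <- foreground_mask(ref)
  out <- ref$data          # background voxels pass through untransformed
  out[fg] <- (ref$data[fg] - landmarks$low) / (landmarks$high - landmarks$low)
  volume(out, spacing = ref$spacing, mask = ref$mask, header = ref$header)
}

# Rescale every landmark of a set by the set's own IS transform.
.unit_scale_landmarks <- function(l) {
  s <- function(v) (v - l$low) / (l$high - l$low)
  landmark_set(s(l$low), s(l$mean_val), s(l$high), s(l$obs_min), s(l$obs_max))
}

#' Construct a piecewise-linear normalization map from landmark sets
#'
#' The fitted transfer function from input gray levels to the reference
#' scale. With `segments = 2` it is the mean-anchored two-segment map:
#' `[low_in, mean_in]` is sent linearly to `[low_ref, mean_ref]` and
#' `[mean_in, high_in]` to `[mean_ref, high_ref]`, with each segment's line
#' continued over the adjacent tail down to the observed input extrema.
#' `segments = 1` is the single linear stretch sending
#' `[low_in, high_in]` to `[low_ref, high_ref]` — the degenerate special
#' case in which the mean is not anchored.
#'
#' @param input_landmarks,reference_landmarks [landmark_set()] objects for
#'   the input image and for the reference scale.
#' @param segments 2 (mean-anchored, the method) or 1 (plain stretch).
#' @param apply_ceiling quantize mapped values with the ceiling operator, for
#'   integer gray-level output on the reference scale.
#' @param scale_mode bookkeeping tag: `"reference_scale"` when the reference
#'   landmarks are raw gray values, `"unit_scale"` when they have been sent
#'   through the IS rescale (see [fit_map()]).
#' @return An object of class `normalization_map`.
#' @export
normalization_map <- function(input_landmarks, reference_landmarks,
                              segments = 2, apply_ceiling = TRUE,
                              scale_mode = "reference_scale") {
  stopifnot(inherits(input_landmarks, "landmark_set"),
            inherits(reference_landmarks, "landmark_set"))
  segments <- as.integer(segments)
  if (!segments %in% c(1L, 2L)) stop("segments must be 1 or 2")
  structure(list(input_landmarks = input_landmarks,
                 reference_landmarks = reference_landmarks,
                 segments = segments,
                 apply_ceiling = isTRUE(apply_ceiling),
                 scale_mode = scale_mode),
            class = "normalization_map")
}

#' @export
print.normalization_map <- function(x, ...) {
  il <- x$input_landmarks; rl <- x$reference_landmarks
  cat("normalization_map (", x$segments, " segment(s), ceiling ",
      if (x$apply_ceiling) "on" else "off", ", ", x$scale_mode, ")\n", sep = "")
  cat("  input:     "); print(il)
  cat("  reference: "); print(rl)
  if (x$segments == 2L) {
    cat("  slopes: ",
        signif((rl$low - rl$mean_val) / (il$low - il$mean_val), 6), " / ",
        signif((rl$high - rl$mean_val) / (il$high - il$mean_val), 6), "\n",
        sep = "")
  }
  invisible(x)
}

#' Fit the normalization map between an input and a reference volume
#'
#' Extracts the three-landmark sets of both volumes and assembles the
#' piecewise-linear map. In `"reference_scale"` mode (default) the target
#' landmarks are the reference's own gray values, so the normalized output is
#' directly comparable to the reference image and ceiling quantization is
#' meaningful. In `"unit_scale"` mode the reference landmarks are first sent
#' through the IS rescale ([scale_reference()]), the output lives on the
#' unit-interval reference scale, and ceiling is disabled (gray levels are
#' fractional there).
#'
#' @param input_vol,ref_vol [`mri_volume`][volume] objects.
#' @param low_q,high_q landmark quantiles, see [compute_landmarks()].
#' @param segments,apply_ceiling see [normalization_map()].
#' @param scale_mode `"reference_scale"` or `"unit_scale"`.
#' @return A [normalization_map()]; fully determined, no optimization.
#' @export
fit_map <- function(input_vol, ref_vol, low_q = 0.10, high_q = 0.90,
                    segments = 2, apply_ceiling = TRUE,
                    scale_mode = c("reference_scale", "unit_scale")) {
  scale_mode <- match.arg(scale_mode)
  il <- tryCatch(compute_landmarks(input_vol, low_q, high_q),
                 error = function(e) stop("input image: ", conditionMessage(e),
                                          call. = FALSE))
  rl <- tryCatch(compute_landmarks(ref_vol, low_q, high_q),
                 error = function(e) stop("reference image: ", conditionMessage(e),
                                          call. = FALSE))
  if (scale_mode == "unit_scale") {
    rl <- .unit_scale_landmarks(rl)
    apply_ceiling <- FALSE
  }
  normalization_map(il, rl, segments, apply_ceiling, scale_mode)
}

#' Apply a fitted normalization map
#'
#' For gray values between the input's observed extrema the two-segment map
#' is, writing `(S1, mu_i, S2)` for the input landmarks and
#' `(LIR, mu_s, HIR)` for the reference targets,
#' \deqn{N(g) = \lceil \mu_s + (g - \mu_i)(LIR - \mu_s)/(S_1 - \mu_i) \rceil}
#' when `g <= mu_i` and
#' \deqn{N(g) = \lceil \mu_s + (g - \mu_i)(HIR - \mu_s)/(S_2 - \mu_i) \rceil}
#' when `g >= mu_i`; the same two lines extend over the tails
#' `[obs_min, S1]` and `[S2, obs_max]`, and the ceiling is applied only when
#' the map says so. Values outside the observed input range are clamped to
#' the nearest extremum and the event is counted, not raised.
#'
#' @param map a [normalization_map()].
#' @param g a numeric vector of gray values, or an [`mri_volume`][volume]
#'   (mapped voxelwise on the foreground; background voxels are never
#'   transformed — exactly 0 on skull-stripped scans, passed through
#'   otherwise).
#' @return Same type as `g`, with an attribute `clamp` = named counts
#'   `c(below, above)` of out-of-range inputs.
#' @export
apply_map <- function(map, g) {
  stopifnot(inherits(map, "normalization_map"))
  if (inherits(g, "mri_volume")) {
    fg <- foreground_mask(g)
    mapped <- .map_values(map, g$data[fg])
    out <- g$data          # background voxels pass through untransformed
    out[fg] <- mapped
    res <- volume(out, spacing = g$spacing, mask = g$mask, header = g$header)
    attr(res, "clamp") <- attr(mapped, "clamp")
    res
  } else {
    .map_values(map, as.numeric(g))
  }
}

.map_values <- function(map, g) {
  il <- map$input_landmarks
  rl <- map$reference_landmarks
  n_below <- sum(g < il$obs_min)
  n_above <- sum(g > il$obs_max)
  g <- pmin(pmax(g, il$obs_min), il$obs_max)
  if (map$segments == 2L) {
    lo <- rl$mean_val + (g - il$mean_val) * (rl$low  - rl$mean_val) / (il$low  - il$mean_val)
    hi <- rl$mean_val + (g - il$mean_val) * (rl$high - rl$mean_val) / (il$high - il$mean_val)
    y <- ifelse(g <= il$mean_val, lo, hi)
  } else {
    y <- rl$low + (g - il$low) * (rl$high - rl$low) / (il$high - il$low)
  }
  if (map$apply_ceiling) y <- ceiling(y)
  attr(y, "clamp") <- c(below = n_below, above = n_above)
  y
}

#' Exact first Wasserstein distance between two empirical distributions
#'
#' The area between the two empirical CDFs — the standard scalar summary of
#' how far apart two intensity histograms are, used by the normalization
#' report to quantify the pre/post distance to the reference.
#'
#' @param x,y numeric samples (e.g. foreground intensities of two volumes).
#' @return Non-negative scalar, in intensity units.
#' @export
wasserstein1 <- function(x, y) {
  x <- sort(as.numeric(x)); y <- sort(as.numeric(y))
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  z <- sort(c(x, y))
  zu <- z[-length(z)]
  dz <- diff(z)
  Fx <- findInterval(zu, x) / length(x)
  Fy <- findInterval(zu, y) / length(y)
  sum(abs(Fx - Fy) * dz)
}

#' Normalize an input volume onto a reference volume's intensity scale
#'
#' The end-to-end two-step method: landmark extraction on both images,
#' piecewise-linear map fitting ([fit_map()]), and voxelwise application
#' ([apply_map()]). The report records both landmark sets, tail-clamp
#' counts, and the Wasserstein-1 distance between foreground histograms
#' before and after normalization (against the reference on the target
#' scale).
#'
#' @param input_vol,ref_vol [`mri_volume`][volume] objects.
#' @param config a [run_config()].
#' @return A `normalization_result`: list with `volume` (the normalized
#'   input), `map` (the fitted [normalization_map()]), and `report`.
#' @export
normalize_volume <- function(input_vol, ref_vol, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  map <- fit_map(input_vol, ref_vol,
                 low_q = config$low_q, high_q = config$high_q,
                 segments = config$segments, apply_ceiling = config$ceiling,
                 scale_mode = config$scale_mode)
  out <- apply_map(map, input_vol)
  target <- if (config$scale_mode == "unit_scale")
    scale_reference(ref_vol, compute_landmarks(ref_vol, config$low_q, config$high_q))
  else ref_vol
  in_fg  <- foreground_values(input_vol)
  ref_fg <- foreground_values(target)
  out_fg <- out$data[foreground_mask(input_vol)]
  report <- list(
    input_landmarks = as.list(map$input_landmarks),
    reference_landmarks = as.list(map$reference_landmarks),
    clamp = as.list(attr(out, "clamp")),
    w1_to_reference_before = wasserstein1(in_fg, ref_fg),
    w1_to_reference_after = wasserstein1(out_fg, ref_fg),
    config = unclass(config))
  structure(list(volume = out, map = map, report = report),
            class = "normalization_result")
}

#' @export
print.normalization_result <- function(x, ...) {
  r <- x$report
  cat("normalization_result\n")
  cat("  W1 distance to reference: ", signif(r$w1_to_reference_before, 6),
      " -> ", signif(r$w1_to_reference_after, 6), "\n", sep = "")
  cat("  clamped voxels: ", r$clamp$below, " below, ", r$clamp$above,
      " above\n", sep = "")
  print(x$map)
  invisible(x)
}
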