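#' Specification of a two-scanner brain phantom pair
#'
#' Describes paired synthetic scans of one anatomy acquired on two virtual
#' scanners that differ in a monotone intensity transfer and in background
#' noise level — the statistical structure the normalization method assumes:
#' ordered tissue intensities (CSF < GM < WM, as in T1 weighting), Gaussian
#' within-tissue noise, and Rayleigh-distributed background intensities.
#'
#' The defaults emulate a realistic study condition: class means 40/110/160
#' with within-tissue SD 10 (well-separated but overlapping tissue peaks),
#' scanner A background sigma 3 versus scanner B sigma 12 (a four-fold noise
#' gap, so A is the reference-grade scan), and a scanner-B transfer
#' `1.6 * v^0.9 + 20` — a mildly compressive gamma with gain and offset, as
#' produced by different field strengths and acquisition parameters.
#'
#' @param shape grid dimensions (default `c(96, 96, 96)`).
#' @param class_means intensities for (CSF, GM, WM), strictly increasing.
#' @param tissue_sigma within-class Gaussian noise SD (both scanners).
#' @param background_sigma_a,background_sigma_b Rayleigh background scale per
#'   scanner.
#' @param transfer_b list with `gain > 0`, `offset >= 0`, `gamma > 0`: the
#'   monotone map `gain * v^gamma + offset` scanner B applies to the
#'   noiseless anatomy.
#' @param seed integer RNG seed; the pair is fully deterministic given it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 96),
                         class_means = c(csf = 40, gm = 110, wm = 160),
                         tissue_sigma = 10,
                         background_sigma_a = 3,
                         background_sigma_b = 12,
                         transfer_b = list(gain = 1.6, offset = 20, gamma = 0.9),
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("shape must be 3 positive integers")
  class_means <- as.numeric(class_means)
  if (length(class_means) != 3L || any(diff(class_means) <= 0))
    stop("class_means must be 3 strictly increasing intensities (CSF, GM, WM)")
  if (tissue_sigma < 0 || background_sigma_a < 0 || background_sigma_b < 0)
    stop("noise SDs must be >= 0")
  if (!all(c("gain", "offset", "gamma") %in% names(transfer_b)) ||
      transfer_b$gain <= 0 || transfer_b$gamma <= 0 || transfer_b$offset < 0)
    stop("transfer_b needs gain > 0, offset >= 0, gamma > 0")
  structure(list(shape = shape, class_means = class_means,
                 tissue_sigma = tissue_sigma,
                 background_sigma_a = background_sigma_a,
                 background_sigma_b = background_sigma_b,
                 transfer_b = transfer_b, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Ellipsoid semi-axes, as fractions of the grid dimensions. Nested: a WM
# core inside a GM brain shell, with a CSF "ventricle" inside the WM. The
# fractions give roughly brain-like tissue proportions (GM ~58%, WM ~34%,
# CSF ~8% of brain volume).
.PHANTOM_FRACS <- list(brain = c(0.42, 0.38, 0.40),
                       wm    = c(0.32, 0.28, 0.30),
                       vent  = c(0.18, 0.16, 0.17))

#' Analytic geometry of the phantom's nested ellipsoids
#'
#' Semi-axes (in voxels) of the brain, white-matter core and ventricle
#' ellipsoids for a given grid shape — useful for comparing voxel counts with
#' analytic ellipsoid volumes.
#'
#' @param shape grid dimensions.
#' @return List of length-3 numeric semi-axes: `brain`, `wm`, `vent`.
#' @export
phantom_geometry <- function(shape) {
  lapply(.PHANTOM_FRACS, function(f) f * shape)
}

# Ground-truth labels from nested ellipsoids centred in the grid.
.phantom_labels <- function(shape) {
  geom <- phantom_geometry(shape)
  if (any(shape < 25L))
    stop("ellipsoids do not fit: phantom shape must be at least 25 voxels per axis")
  ctr <- (shape + 1) / 2
  axd <- function(i, r) ((seq_len(shape[i]) - ctr[i]) / r[i])^2
  inside <- function(r) {
    q <- outer(outer(axd(1, r), axd(2, r), "+"), axd(3, r), "+")
    q <= 1
  }
  brain <- inside(geom$brain)
  wm <- inside(geom$wm)
  vent <- inside(geom$vent)
  lab <- array(0L, shape)
  lab[brain] <- 2L   # GM shell
  lab[wm] <- 3L      # WM core
  lab[vent] <- 1L    # CSF ventricle
  lab
}

#' Monotone scanner intensity transfer
#'
#' `gain * v^gamma + offset`, strictly increasing in `v` for `v >= 0`.
#'
#' @param v non-negative intensity (vectorized).
#' @param gain,offset,gamma transfer parameters, `gain > 0`, `gamma > 0`.
#' @return Transformed intensity.
#' @export
apply_scanner_transfer <- function(v, gain, offset, gamma) {
  if (any(v < 0)) stop("scanner transfer is defined for non-negative intensities")
  if (gain <= 0 || gamma <= 0) stop("gain and gamma must be positive")
  gain * v^gamma + offset
}

# Rayleigh(sigma) draws; mode of the density equals sigma.
.rrayleigh <- function(n, sigma) {
  if (sigma == 0) return(numeric(n))
  sigma * sqrt(-2 * log(1 - stats::runif(n)))
}

#' Simulate a co-registered two-scanner phantom pair
#'
#' Builds the ground-truth anatomy (nested ellipsoids), then renders it on
#' both virtual scanners: scanner A adds Gaussian within-tissue noise to the
#' class means and Rayleigh(`background_sigma_a`) background; scanner B first
#' passes the noiseless anatomy through its monotone transfer, then adds its
#' own noise draws and Rayleigh(`background_sigma_b`) background. Foreground
#' intensities are clamped at 0 (magnitude images are non-negative). Both
#' volumes carry the ground-truth foreground as their mask, so the
#' registration between them is the identity by construction.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_pair`: list with `vol_a`, `vol_b`
#'   ([`mri_volume`][volume]), `truth` ([label_volume()]), and `spec`.
#' @export
simulate_pair <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  lab <- .phantom_labels(spec$shape)
  fg <- lab > 0L
  n_fg <- sum(fg); n_bg <- sum(!fg)
  clean <- array(0, spec$shape)
  clean[fg] <- spec$class_means[lab[fg]]

  a <- array(0, spec$shape)
  a[fg] <- pmax(clean[fg] + stats::rnorm(n_fg, 0, spec$tissue_sigma), 0)
  a[!fg] <- .rrayleigh(n_bg, spec$background_sigma_a)

  tb <- spec$transfer_b
  clean_b <- apply_scanner_transfer(clean[fg], tb$gain, tb$offset, tb$gamma)
  b <- array(0, spec$shape)
  b[fg] <- pmax(clean_b + stats::rnorm(n_fg, 0, spec$tissue_sigma), 0)
  b[!fg] <- .rrayleigh(n_bg, spec$background_sigma_b)

  structure(list(vol_a = volume(a, mask = fg),
                 vol_b = volume(b, mask = fg),
                 truth = label_volume(lab),
                 spec = spec),
            class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat("phantom_pair ", paste(x$spec$shape, collapse = " x "),
      ", seed ", x$spec$seed, "\n", sep = "")
  cat("  scanner A background sigma ", x$spec$background_sigma_a,
      ", scanner B sigma ", x$spec$background_sigma_b, ", transfer ",
      x$spec$transfer_b$gain, " * v^", x$spec$transfer_b$gamma, " + ",
      x$spec$transfer_b$offset, "\n", sep = "")
  invisible(x)
}
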