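#' Construct a label volume
#'
#' Integer tissue labels on the same grid as a source volume:
#' 0 = background, 1 = CSF, 2 = gray matter, 3 = white matter.
#'
#' @param labels 3D integer array with values in `0:3`.
#' @param spacing voxel size in mm per axis.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  if (any(is.na(labels)) || any(labels != as.integer(labels)) ||
      any(labels < 0L) || any(labels > 3L))
    stop("labels must be integers in {0 = background, 1 = CSF, 2 = GM, 3 = WM}")
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive voxel sizes in mm")
  structure(list(labels = labels, spacing = spacing), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume ", paste(dim(x$labels), collapse = " x "), " voxels: ",
      paste(sprintf("%s=%d", c("bg", "csf", "gm", "wm"),
                    tabulate(x$labels + 1L, 4L)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Mean squared error between two volumes
#'
#' `(1/n) * sum((a - b)^2)` over a region. The default region is the union
#' of the two foregrounds, so identically-zero backgrounds do not dilute the
#' score.
#'
#' @param a,b [`mri_volume`][volume] objects of identical shape.
#' @param region optional logical array selecting the voxels to compare.
#' @return Non-negative scalar.
#' @export
mse <- function(a, b, region = NULL) {
  stopifnot(inherits(a, "mri_volume"), inherits(b, "mri_volume"))
  if (!identical(dim(a$data), dim(b$data)))
    stop("shape mismatch: ", paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"))
  if (is.null(region)) {
    region <- foreground_mask(a) | foreground_mask(b)
  } else if (!identical(dim(region), dim(a$data))) {
    stop("region shape differs from the volumes")
  }
  if (sum(region) == 0L) stop("empty comparison region")
  mean((a$data[region] - b$data[region])^2)
}

#' Dice similarity coefficient for one tissue class
#'
#' `2 |X intersect Y| / (|X| + |Y|)` where X and Y are the binarizations of
#' the two label volumes at class `cls`. When both classes are empty the
#' coefficient is defined as 1 (perfect agreement on absence).
#'
#' @param a,b [label_volume()] objects of identical shape.
#' @param cls the tissue label (1 = CSF, 2 = GM, 3 = WM; 0 compares
#'   backgrounds).
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(a, b, cls) {
  stopifnot(inherits(a, "label_volume"), inherits(b, "label_volume"))
  if (!identical(dim(a$labels), dim(b$labels)))
    stop("shape mismatch: ", paste(dim(a$labels), collapse = "x"), " vs ",
         paste(dim(b$labels), collapse = "x"))
  x <- a$labels == cls
  y <- b$labels == cls
  nx <- sum(x); ny <- sum(y)
  if (nx + ny == 0L) return(1)
  2 * sum(x & y) / (nx + ny)
}

#' Three-class k-means tissue segmentation
#'
#' A simple intensity-only segmenter used to exercise the evaluation metrics
#' on phantoms: k-means with k = 3 on the foreground intensities, clusters
#' relabeled by ascending centroid so that CSF < GM < WM by construction
#' (T1-weighted ordering). Deterministic given the seed.
#'
#' @param vol an [`mri_volume`][volume] with a non-empty foreground.
#' @param seed RNG seed for the k-means initialization.
#' @return A [label_volume()] on the volume's grid.
#' @export
segment_three_class <- function(vol, seed = 1L) {
  stopifnot(inherits(vol, "mri_volume"))
  fg <- foreground_mask(vol)
  vals <- vol$data[fg]
  if (length(vals) < 3L || length(unique(vals)) < 3L)
    stop("fewer than 3 distinct foreground intensities; cannot fit 3 classes")
  set.seed(as.integer(seed))
  km <- stats::kmeans(vals, centers = 3, nstart = 5, iter.max = 100)
  rnk <- integer(3)
  rnk[order(km$centers)] <- 1:3
  labels <- array(0L, dim(vol$data))
  labels[fg] <- rnk[km$cluster]
  label_volume(labels, vol$spacing)
}

#' Per-class tissue volumes in cubic millimetres
#'
#' Voxel count per class times the voxel volume implied by the spacing.
#'
#' @param lab a [label_volume()].
#' @return Named numeric vector `c(background, csf, gm, wm)` in mm^3; the
#'   values sum to the total grid volume.
#' @export
tissue_volumes <- function(lab) {
  stopifnot(inherits(lab, "label_volume"))
  vox <- prod(lab$spacing)
  counts <- tabulate(lab$labels + 1L, nbins = 4L)
  stats::setNames(counts * vox, c("background", "csf", "gm", "wm"))
}
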