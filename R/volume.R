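#' Construct an in-memory MR volume
#'
#' The unit every operation in this package consumes: a 3D scalar intensity
#' grid with per-axis voxel spacing and an optional binary foreground mask.
#' All data are held in double precision regardless of on-disk storage, so
#' that fractional mapping slopes never lose precision.
#'
#' @param data 3D numeric array of voxel intensities. Skull-stripped scans
#'   have an exactly-zero background.
#' @param spacing numeric length-3, voxel size in mm per axis.
#' @param mask optional array of the same shape; nonzero/`TRUE` marks
#'   foreground. Coerced to logical.
#' @param header optional NIfTI header (as returned by
#'   [RNifti::niftiHeader()]) carried through untouched on save, so the
#'   orientation/affine of a loaded scan survives a round trip. The method is
#'   voxelwise and never reasons about world coordinates.
#'
#' @return An object of class `mri_volume`: a list with elements `data`,
#'   `spacing`, `mask`, `header`.
#' @seealso [load_volume()], [save_volume()], [foreground_mask()]
#' @export
volume <- function(data, spacing = c(1, 1, 1), mask = NULL, header = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array (got ",
         if (is.array(data)) length(dim(data)) else 0L, " axes)")
  if (any(dim(data) < 1L))
    stop("every volume dimension must be >= 1")
  storage.mode(data) <- "double"
  n_bad <- sum(!is.finite(data))
  if (n_bad > 0L)
    stop("volume contains ", n_bad, " non-finite (NaN/Inf) voxel(s)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive voxel sizes in mm")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(data)))
      stop("mask shape (", paste(dim(mask), collapse = "x"),
           ") differs from data shape (", paste(dim(data), collapse = "x"), ")")
    mask <- array(as.vector(mask) != 0, dim(data))
  }
  structure(list(data = data, spacing = spacing, mask = mask, header = header),
            class = "mri_volume")
}

#' @export
print.mri_volume <- function(x, ...) {
  cat("mri_volume ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  cat("  intensity range [", signif(min(x$data), 6), ", ",
      signif(max(x$data), 6), "]",
      if (!is.null(x$mask)) paste0(", mask: ", sum(x$mask), " foreground voxels"),
      "\n", sep = "")
  invisible(x)
}

#' Foreground selection of a volume
#'
#' A voxel is foreground iff the mask is `TRUE` when a mask is supplied,
#' else iff its intensity is strictly positive — skull-stripped images have
#' an exactly-zero background.
#'
#' @param vol an [`mri_volume`][volume].
#' @return `foreground_mask`: logical array of the volume's shape.
#' @export
foreground_mask <- function(vol) {
  stopifnot(inherits(vol, "mri_volume"))
  if (!is.null(vol$mask)) vol$mask else vol$data > 0
}

#' @rdname foreground_mask
#' @return `foreground_values`: numeric vector of foreground intensities.
#' @export
foreground_values <- function(vol) {
  vol$data[foreground_mask(vol)]
}

# Normalize to exactly 3 axes: drop trailing singleton axes (a 3D scan
# stored as X x Y x Z x 1) and restore those the NIfTI dim convention
# dropped (an X x 1 x 1 image reads back as 1D).
.squeeze3d <- function(arr, path) {
  d <- dim(arr)
  if (is.null(d)) d <- length(arr)
  while (length(d) > 3L && d[length(d)] == 1L) d <- d[-length(d)]
  if (length(d) < 3L) d <- c(d, rep(1L, 3L - length(d)))
  if (length(d) != 3L)
    stop(path, ": expected a 3D volume, found ", length(d),
         " axes after squeezing")
  array(arr, d)
}

#' Read a NIfTI volume (and optional mask) from disk
#'
#' @param path path to a NIfTI-1 file (`.nii` or `.nii.gz`) holding a 3D
#'   image (a trailing singleton 4th dimension is squeezed away).
#' @param mask_path optional path to a mask volume of the same shape;
#'   nonzero voxels become foreground.
#' @return An [`mri_volume`][volume] with data cast to double, header
#'   spacing preserved, and the full NIfTI header retained for round trips.
#' @export
load_volume <- function(path, mask_path = NULL) {
  if (!file.exists(path))
    stop("cannot read NIfTI file: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop("cannot read NIfTI file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  arr <- .squeeze3d(as.array(img), path)
  n_bad <- sum(!is.finite(arr))
  if (n_bad > 0L)
    stop(path, ": ", n_bad, " non-finite (NaN/Inf) voxel(s)")
  spc <- RNifti::pixdim(img)
  spc <- c(spc, rep(1, 3))[1:3]
  spc[spc <= 0 | !is.finite(spc)] <- 1
  mask <- NULL
  if (!is.null(mask_path)) {
    if (!file.exists(mask_path))
      stop("cannot read mask file: ", mask_path)
    mask <- .squeeze3d(as.array(RNifti::readNifti(mask_path)), mask_path)
    if (!identical(dim(mask), dim(arr)))
      stop("mask ", mask_path, " shape differs from image ", path)
  }
  volume(arr, spacing = spc, mask = mask, header = RNifti::niftiHeader(img))
}

#' Write a volume to a NIfTI-1 file
#'
#' @param vol an [`mri_volume`][volume].
#' @param path output path (`.nii` or `.nii.gz`); the parent directory must
#'   exist.
#' @param dtype_policy `"float32"` stores values unmodified in 32-bit float;
#'   `"match_input_int"` rounds and clips to the integer range of
#'   `int_type`, for interoperability with integer-typed source scans.
#' @param int_type target integer type under `match_input_int`.
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path,
                        dtype_policy = c("float32", "match_input_int"),
                        int_type = c("uint8", "int16", "uint16", "int32")) {
  stopifnot(inherits(vol, "mri_volume"))
  dtype_policy <- match.arg(dtype_policy)
  if (!dir.exists(dirname(path)))
    stop("cannot write ", path, ": directory does not exist")
  dat <- vol$data
  if (dtype_policy == "match_input_int") {
    int_type <- match.arg(int_type)
    rng <- switch(int_type,
                  uint8  = c(0, 255),
                  int16  = c(-32768, 32767),
                  uint16 = c(0, 65535),
                  int32  = c(-2147483648, 2147483647))
    dat <- pmin(pmax(round(dat), rng[1]), rng[2])
    datatype <- int_type
  } else {
    datatype <- "float"
  }
  ref <- vol$header
  if (!is.null(ref) && !identical(dim(vol$data), .hdr_dim(ref))) ref <- NULL
  img <- RNifti::asNifti(array(dat, dim(vol$data)), reference = ref)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

.hdr_dim <- function(hdr) {
  d <- hdr$dim
  nd <- d[1]
  if (nd < 3) return(NULL)
  d[2:(1 + nd)][1:3]
}
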