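#' Core image and landmark containers
#'
#' `image_slice()` wraps a 2D matrix of intensities with the physical
#' metadata the registration pipeline needs: pixel spacing in mm, the
#' physical coordinate of pixel (1,1) and a modality tag.  The coordinate
#' convention used throughout the package is: pixel index `(row, col)`
#' (1-based) maps to physical position
#' `(y_mm, x_mm) = origin + (index - 1) * spacing`, i.e. pixel centres.
#'
#' @param pixels numeric matrix of intensities (finite, rectangular).
#' @param spacing length-2 positive numeric, physical pixel size
#'   `(row_mm, col_mm)`.
#' @param modality one of `"MR"`, `"US"`, `"REGISTERED"`, `"LABEL"`.
#' @param origin length-2 numeric, physical `(y_mm, x_mm)` of pixel (1,1).
#' @return An object of class `"image_slice"`.
#' @export
image_slice <- function(pixels, spacing = c(1, 1), modality = "MR",
                        origin = c(0, 0)) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels)))
    stop("image_slice: pixels must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("image_slice: spacing must be two strictly positive numbers")
  modality <- match.arg(modality, c("MR", "US", "REGISTERED", "LABEL"))
  origin <- as.numeric(origin)
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("image_slice: origin must be two finite numbers")
  structure(list(pixels = pixels, spacing = spacing, modality = modality,
                 origin = origin),
            class = "image_slice")
}

#' @export
print.image_slice <- function(x, ...) {
  cat(sprintf("<image_slice> %s  %d x %d px  spacing %.4g x %.4g mm  range [%.4g, %.4g]\n",
              x$modality, nrow(x$pixels), ncol(x$pixels),
              x$spacing[1], x$spacing[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.image_slice <- function(x) dim(x$pixels)

is_image_slice <- function(x) inherits(x, "image_slice")

#' Physical coordinates of every pixel centre of a slice grid
#' @noRd
slice_grid_mm <- function(img) {
  h <- nrow(img$pixels); w <- ncol(img$pixels)
  list(y = img$origin[1] + (seq_len(h) - 1) * img$spacing[1],
       x = img$origin[2] + (seq_len(w) - 1) * img$spacing[2])
}

#' A co-gridded fixed/moving slice pair
#'
#' The unit of training and registration: an intraoperative ultrasound slice
#' (fixed) and a pre-operative MR slice (moving) resampled onto the same
#' pixel grid.
#'
#' @param fixed `image_slice` with modality `"US"`.
#' @param moving `image_slice` with modality `"MR"`.
#' @param case_id text label.
#' @param slice_index integer slice index within the source volume.
#' @return An object of class `"slice_pair"`.
#' @export
slice_pair <- function(fixed, moving, case_id = "case", slice_index = 1L) {
  if (!is_image_slice(fixed) || !is_image_slice(moving))
    stop("slice_pair: fixed and moving must be image_slice objects")
  if (!identical(dim(fixed$pixels), dim(moving$pixels)))
    stop("slice_pair: fixed and moving must share the same pixel grid")
  if (max(abs(fixed$spacing - moving$spacing)) > 1e-9)
    stop("slice_pair: fixed and moving must share the same spacing")
  if (fixed$modality != "US")
    stop("slice_pair: fixed image must be tagged US")
  if (moving$modality != "MR")
    stop("slice_pair: moving image must be tagged MR")
  structure(list(fixed = fixed, moving = moving,
                 case_id = as.character(case_id),
                 slice_index = as.integer(slice_index)),
            class = "slice_pair")
}

#' @export
print.slice_pair <- function(x, ...) {
  cat(sprintf("<slice_pair> %s[%d]  %d x %d px  spacing %.4g x %.4g mm\n",
              x$case_id, x$slice_index,
              nrow(x$fixed$pixels), ncol(x$fixed$pixels),
              x$fixed$spacing[1], x$fixed$spacing[2]))
  invisible(x)
}

#' Paired anatomical landmarks in physical space
#'
#' Index `i` of `fixed_points` and `moving_points` refers to the same
#' anatomy, located in the fixed (ultrasound) and moving (MR) physical
#' frames respectively.  Coordinates are `(y_mm, x_mm)`.
#'
#' @param fixed_points,moving_points n x 2 numeric matrices (or coercible)
#'   of `(y_mm, x_mm)` coordinates.
#' @param case_id text label.
#' @return An object of class `"landmark_set"`.
#' @export
landmark_set <- function(fixed_points, moving_points, case_id = "case") {
  fp <- matrix(as.numeric(as.matrix(fixed_points)), ncol = 2)
  mp <- matrix(as.numeric(as.matrix(moving_points)), ncol = 2)
  if (nrow(fp) != nrow(mp))
    stop("landmark_set: fixed and moving point counts differ (pairing error)")
  if (nrow(fp) < 1L)
    stop("landmark_set: at least one landmark pair is required")
  if (!all(is.finite(fp)) || !all(is.finite(mp)))
    stop("landmark_set: all coordinates must be finite")
  colnames(fp) <- colnames(mp) <- c("y_mm", "x_mm")
  structure(list(fixed_points = fp, moving_points = mp,
                 case_id = as.character(case_id)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %s  %d pairs\n", x$case_id,
              nrow(x$fixed_points)))
  invisible(x)
}

#' @export
length.landmark_set <- function(x) nrow(x$fixed_points)

#' A 3D image volume in (z, y, x) axis order
#'
#' Carrier for NIfTI/MetaImage content before slice extraction.  Voxels are
#' stored with the slowest-varying axis first, i.e. `voxels[z, y, x]`;
#' `spacing` and `origin` follow the same order, in mm.
#'
#' @param voxels numeric 3D array `(z, y, x)`.
#' @param spacing length-3 positive numeric (mm).
#' @param origin length-3 numeric (mm), physical position of voxel (1,1,1).
#' @return An object of class `"volume"`.
#' @export
volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("volume: voxels must be a 3D array")
  storage.mode(voxels) <- "double"
  if (!all(is.finite(voxels)))
    stop("volume: voxels must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0) || any(!is.finite(spacing)))
    stop("volume: spacing must be three strictly positive numbers")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("volume: origin must be three finite numbers")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume> %d x %d x %d (z,y,x)  spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Percentile-based intensity normalization to [0, 1]
#'
#' Clips intensities at the given percentiles and maps the clipped range
#' affinely onto `[0, 1]`.  The joint-histogram losses require a bounded,
#' common intensity range, so this is applied at data-loading time.  A
#' constant image maps to all zeros.  The mapping is invariant to positive
#' affine rescaling of the input.
#'
#' @param img an `image_slice`.
#' @param lo_pct,hi_pct lower/upper clipping percentiles in `[0, 100]`.
#' @return An `image_slice` with values in `[0, 1]`.
#' @export
normalize_intensity <- function(img, lo_pct = 1, hi_pct = 99) {
  stopifnot(is_image_slice(img))
  if (lo_pct >= hi_pct)
    stop("normalize_intensity: lo_pct must be strictly below hi_pct")
  v <- img$pixels
  q <- stats::quantile(v, c(lo_pct, hi_pct) / 100, names = FALSE)
  if (q[2] - q[1] <= 0) {
    out <- v * 0
  } else {
    out <- (pmin(pmax(v, q[1]), q[2]) - q[1]) / (q[2] - q[1])
  }
  image_slice(out, spacing = img$spacing, modality = img$modality,
              origin = img$origin)
}
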