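#' Dense displacement field on the fixed grid
#'
#' The transform the registration produces: a per-pixel 2-vector `u(x)` in
#' mm, defined on the fixed (ultrasound) grid, pull-back convention — the
#' warped moving image at pixel `x` samples the moving image at physical
#' position `x + u(x)`.  The identity transform is the all-zero field.
#'
#' @param u numeric array `(H, W, 2)`; `u[,,1]` is the y-component and
#'   `u[,,2]` the x-component, in mm.
#' @param spacing length-2 positive numeric, grid spacing in mm.
#' @param origin length-2 numeric, physical position of pixel (1,1).
#' @return An object of class `"displacement_field"`.
#' @export
displacement_field <- function(u, spacing = c(1, 1), origin = c(0, 0)) {
  u <- as.array(u)
  if (length(dim(u)) != 3L || dim(u)[3] != 2L)
    stop("displacement_field: u must be an (H, W, 2) array")
  storage.mode(u) <- "double"
  if (!all(is.finite(u)))
    stop("displacement_field: all components must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(spacing <= 0))
    stop("displacement_field: spacing must be two strictly positive numbers")
  origin <- as.numeric(origin)
  structure(list(u = u, spacing = spacing, origin = origin),
            class = "displacement_field")
}

#' @rdname displacement_field
#' @param shape length-2 integer `(H, W)`.
#' @export
zero_field <- function(shape, spacing = c(1, 1), origin = c(0, 0)) {
  displacement_field(array(0, c(shape[1], shape[2], 2)), spacing, origin)
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$u[, , 1]^2 + x$u[, , 2]^2)
  cat(sprintf("<displacement_field> %d x %d  |u| max %.4g mm, mean %.4g mm\n",
              dim(x$u)[1], dim(x$u)[2], max(mag), mean(mag)))
  invisible(x)
}

#' Warp a moving image through a displacement field
#'
#' Pull-back resampling: `out(x) = moving(x + u(x))`, with `x` ranging over
#' the fixed grid carried by `field`.  Sampling is bilinear (differentiable
#' with respect to both the field and the moving image) or nearest
#' neighbour; positions outside the moving image's extent contribute 0
#' (zero-padded extension, matching the dark ultrasound background).
#'
#' @param moving an `image_slice`.
#' @param field a [displacement_field()] on the fixed grid, same shape as
#'   `moving`.
#' @param interp `"bilinear"` or `"nearest"`.
#' @return An `image_slice` with modality `"REGISTERED"` on the fixed grid.
#' @export
apply_displacement <- function(moving, field, interp = c("bilinear", "nearest")) {
  stopifnot(is_image_slice(moving), inherits(field, "displacement_field"))
  interp <- match.arg(interp)
  h <- dim(field$u)[1]; w <- dim(field$u)[2]
  if (!identical(dim(moving$pixels), c(h, w)))
    stop("apply_displacement: moving image and field shapes differ")
  q <- warp_sample_coords(moving, field)
  px <- if (interp == "bilinear") bilinear_gather(moving$pixels, q$qr, q$qc)$value
        else nearest_gather(moving$pixels, q$qr, q$qc)
  image_slice(matrix(px, h, w), spacing = field$spacing,
              modality = "REGISTERED", origin = field$origin)
}

# pixel-space sample coordinates in the moving image for every fixed pixel
warp_sample_coords <- function(moving, field) {
  h <- dim(field$u)[1]; w <- dim(field$u)[2]
  y <- field$origin[1] + (seq_len(h) - 1) * field$spacing[1]
  x <- field$origin[2] + (seq_len(w) - 1) * field$spacing[2]
  Y <- matrix(y, h, w) + field$u[, , 1]
  X <- matrix(x, h, w, byrow = TRUE) + field$u[, , 2]
  list(qr = (Y - moving$origin[1]) / moving$spacing[1] + 1,
       qc = (X - moving$origin[2]) / moving$spacing[2] + 1)
}

# Bilinear gather with zero-padded extension; also returns the pieces the
# backward pass needs.  qr, qc are matrices of fractional pixel indices.
bilinear_gather <- function(mat, qr, qc) {
  h <- nrow(mat); w <- ncol(mat)
  r0 <- floor(qr); c0 <- floor(qc)
  fr <- qr - r0; fc <- qc - c0
  get0 <- function(ri, ci) {
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    v <- numeric(length(ri))
    idx <- (pmin(pmax(ci, 1), w) - 1) * h + pmin(pmax(ri, 1), h)
    v[ok] <- mat[idx[ok]]
    list(v = v, ok = ok, idx = idx)
  }
  n00 <- get0(r0,     c0)
  n01 <- get0(r0,     c0 + 1)
  n10 <- get0(r0 + 1, c0)
  n11 <- get0(r0 + 1, c0 + 1)
  w00 <- (1 - fr) * (1 - fc); w01 <- (1 - fr) * fc
  w10 <- fr * (1 - fc);       w11 <- fr * fc
  value <- w00 * n00$v + w01 * n01$v + w10 * n10$v + w11 * n11$v
  list(value = value, fr = fr, fc = fc,
       n = list(n00, n01, n10, n11),
       wts = list(w00, w01, w10, w11))
}

nearest_gather <- function(mat, qr, qc) {
  h <- nrow(mat); w <- ncol(mat)
  ri <- round(qr); ci <- round(qc)
  ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
  v <- numeric(length(ri))
  idx <- (pmin(pmax(ci, 1), w) - 1) * h + pmin(pmax(ri, 1), h)
  v[ok] <- mat[idx[ok]]
  v
}

# Backward pass of apply_displacement (bilinear): given the upstream
# gradient d_out (H x W matrix), return gradients with respect to the
# moving image and to the field components (mm).
warp_backward <- function(moving, field, d_out) {
  h <- dim(field$u)[1]; w <- dim(field$u)[2]
  q <- warp_sample_coords(moving, field)
  g <- bilinear_gather(moving$pixels, q$qr, q$qc)
  d <- as.vector(d_out)
  # gradient wrt moving: scatter-add weight * d_out at each neighbour
  d_mov <- numeric(h * w)
  for (k in 1:4) {
    nk <- g$n[[k]]; wk <- as.vector(g$wts[[k]])
    sel <- nk$ok
    if (any(sel)) {
      contrib <- rowsum((wk * d)[sel], group = nk$idx[sel])
      ii <- as.integer(rownames(contrib))
      d_mov[ii] <- d_mov[ii] + contrib[, 1]
    }
  }
  # gradient wrt sample coordinates
  v <- lapply(g$n, `[[`, "v")
  fr <- as.vector(g$fr); fc <- as.vector(g$fc)
  dval_dqr <- -(1 - fc) * v[[1]] - fc * v[[2]] + (1 - fc) * v[[3]] + fc * v[[4]]
  dval_dqc <- -(1 - fr) * v[[1]] + (1 - fr) * v[[2]] - fr * v[[3]] + fr * v[[4]]
  du <- array(0, c(h, w, 2))
  du[, , 1] <- matrix(d * dval_dqr / moving$spacing[1], h, w)
  du[, , 2] <- matrix(d * dval_dqc / moving$spacing[2], h, w)
  list(d_moving = matrix(d_mov, h, w), d_field = du)
}

#' Map fixed-space landmarks through a displacement field
#'
#' Each fixed landmark `x'` is mapped to `x' + u(x')`, with `u` evaluated by
#' bilinear interpolation of the field at the landmark's physical position.
#' Under the pull-back convention this is the predicted location of the
#' corresponding anatomy in the moving (MR) frame, so the per-landmark
#' registration error is the distance between the mapped point and the
#' paired moving landmark.
#'
#' @param lm a [landmark_set()].
#' @param field a [displacement_field()].
#' @return n x 2 matrix of mapped `(y_mm, x_mm)` points.  If any landmark
#'   fell outside the field's extent it was clamped to the border and the
#'   attribute `"clamped"` counts how many.
#' @export
transform_landmarks <- function(lm, field) {
  stopifnot(inherits(lm, "landmark_set"), inherits(field, "displacement_field"))
  if (nrow(lm$fixed_points) == 0L)
    stop("transform_landmarks: empty landmark set")
  u <- sample_field_at(field, lm$fixed_points)
  mapped <- lm$fixed_points + u$values
  attr(mapped, "clamped") <- u$clamped
  mapped
}

# bilinear field sampling at physical points (n x 2), clamped to the grid
sample_field_at <- function(field, pts) {
  h <- dim(field$u)[1]; w <- dim(field$u)[2]
  qr <- (pts[, 1] - field$origin[1]) / field$spacing[1] + 1
  qc <- (pts[, 2] - field$origin[2]) / field$spacing[2] + 1
  clamped <- sum(qr < 1 | qr > h | qc < 1 | qc > w)
  qr <- pmin(pmax(qr, 1), h)
  qc <- pmin(pmax(qc, 1), w)
  r0 <- pmin(pmax(floor(qr), 1), max(h - 1, 1))
  c0 <- pmin(pmax(floor(qc), 1), max(w - 1, 1))
  fr <- qr - r0; fc <- qc - c0
  vals <- matrix(0, nrow(pts), 2)
  for (comp in 1:2) {
    m <- field$u[, , comp]
    v00 <- m[(c0 - 1) * h + r0]
    v01 <- m[(pmin(c0 + 1, w) - 1) * h + r0]
    v10 <- m[(c0 - 1) * h + pmin(r0 + 1, h)]
    v11 <- m[(pmin(c0 + 1, w) - 1) * h + pmin(r0 + 1, h)]
    vals[, comp] <- (1 - fr) * (1 - fc) * v00 + (1 - fr) * fc * v01 +
      fr * (1 - fc) * v10 + fr * fc * v11
  }
  list(values = vals, clamped = clamped)
}

#' Read/write a displacement field as a 2-channel NIfTI
#'
#' The field is stored as an `(H, W, 2)` array in mm (third axis = y then x
#' component) with the grid spacing in the header.
#'
#' @param field a [displacement_field()].
#' @param path file path (`.nii` / `.nii.gz`).
#' @return `write_field` returns `path` invisibly; `read_field` the field.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  vol <- volume(aperm(field$u, c(3, 1, 2)),
                spacing = c(1, field$spacing),
                origin = c(0, field$origin))
  write_volume(vol, path)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  vol <- read_volume(path)
  d <- dim(vol$voxels)
  if (d[1] != 2L)
    stop(sprintf("read_field: %s does not hold a 2-channel field", path))
  displacement_field(aperm(vol$voxels, c(2, 3, 1)),
                     spacing = vol$spacing[2:3], origin = vol$origin[2:3])
}
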