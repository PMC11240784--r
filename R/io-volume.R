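#' Read a 3D volume from NIfTI or MetaImage
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) through RNifti and uncompressed
#' MetaImage (`.mha` with local data, or `.mhd` + raw file).  The voxel
#' array is returned in `(z, y, x)` axis order with spacing and origin read
#' from the header.
#'
#' @param path path to the volume file.
#' @return A [volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_volume: file not found: %s", path))
  ext <- volume_ext(path)
  if (ext %in% c("nii", "nii.gz")) {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e)
                      stop(sprintf("read_volume: unreadable NIfTI file %s (%s)",
                                   path, conditionMessage(e))))
    arr <- as.array(img)
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 3L)
      stop(sprintf("read_volume: %s is not a 3D volume", path))
    xf <- RNifti::xform(img)
    sp_xyz <- abs(diag(xf)[1:3])
    if (any(sp_xyz == 0)) sp_xyz <- RNifti::pixdim(img)[1:3]
    or_xyz <- xf[1:3, 4]
    # NIfTI stores x fastest; flip to (z, y, x)
    volume(aperm(arr, c(3, 2, 1)), spacing = rev(sp_xyz),
           origin = rev(or_xyz))
  } else if (ext %in% c("mha", "mhd")) {
    read_metaimage(path)
  } else {
    stop(sprintf("read_volume: unsupported extension '.%s' (expected .nii, .nii.gz, .mha or .mhd): %s",
                 ext, path))
  }
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' @param vol a [volume()].
#' @param path output path; format chosen by extension (`.nii`, `.nii.gz`,
#'   `.mha`, `.mhd`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume"))
  ext <- volume_ext(path)
  if (ext %in% c("nii", "nii.gz")) {
    arr <- aperm(vol$voxels, c(3, 2, 1))         # back to x-fastest
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rev(vol$spacing)
    m <- diag(c(rev(vol$spacing), 1))
    m[1:3, 4] <- rev(vol$origin)
    img <- RNifti::`sform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path)
  } else if (ext %in% c("mha", "mhd")) {
    write_metaimage(vol, path)
  } else {
    stop(sprintf("write_volume: unsupported extension '.%s': %s", ext, path))
  }
  invisible(path)
}

volume_ext <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii\\.gz$", low)) return("nii.gz")
  tolower(tools::file_ext(low))
}

# --- MetaImage (ITK MetaIO) ----------------------------------------------
# Minimal reader/writer for the uncompressed local/raw form used by common
# MR/US datasets.  Header is "Key = Value" lines; data is raw, x fastest.

metaio_types <- c(MET_UCHAR = "uchar", MET_CHAR = "char", MET_SHORT = "short",
                  MET_USHORT = "ushort", MET_INT = "int", MET_UINT = "uint",
                  MET_FLOAT = "float", MET_DOUBLE = "double")

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop(sprintf("read_volume: malformed MetaImage header (no ElementDataFile): %s", path))
    kv <- regmatches(line, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L)
      stop(sprintf("read_volume: malformed MetaImage header line '%s' in %s", line, path))
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  ndims <- as.integer(hdr[["NDims"]] %||% "3")
  if (is.na(ndims) || !(ndims %in% c(2L, 3L)))
    stop(sprintf("read_volume: unsupported NDims in %s", path))
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr[["ElementSpacing"]] %||%
                              paste(rep("1", ndims), collapse = " "), "\\s+")[[1]])
  off <- as.numeric(strsplit(hdr[["Offset"]] %||% hdr[["Position"]] %||%
                               paste(rep("0", ndims), collapse = " "), "\\s+")[[1]])
  etype <- hdr[["ElementType"]] %||% "MET_FLOAT"
  if (!etype %in% names(metaio_types))
    stop(sprintf("read_volume: unsupported MetaImage ElementType %s in %s", etype, path))
  msb <- identical(hdr[["ElementByteOrderMSB"]], "True") ||
    identical(hdr[["BinaryDataByteOrderMSB"]], "True")
  comp <- hdr[["CompressedData"]]
  if (identical(comp, "True"))
    stop(sprintf("read_volume: compressed MetaImage data is not supported: %s", path))
  n <- prod(dims)
  datafile <- hdr[["ElementDataFile"]]
  if (identical(datafile, "LOCAL")) {
    raw_con <- con
  } else {
    raw_path <- file.path(dirname(path), datafile)
    if (!file.exists(raw_path))
      stop(sprintf("read_volume: MetaImage data file not found: %s", raw_path))
    raw_con <- file(raw_path, "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  endian <- if (msb) "big" else "little"
  vals <- switch(etype,
    MET_UCHAR  = as.numeric(readBin(raw_con, "integer", n, size = 1, signed = FALSE)),
    MET_CHAR   = as.numeric(readBin(raw_con, "integer", n, size = 1, signed = TRUE)),
    MET_SHORT  = as.numeric(readBin(raw_con, "integer", n, size = 2, signed = TRUE, endian = endian)),
    MET_USHORT = as.numeric(readBin(raw_con, "integer", n, size = 2, signed = FALSE, endian = endian)),
    MET_INT    = as.numeric(readBin(raw_con, "integer", n, size = 4, endian = endian)),
    MET_UINT   = as.numeric(readBin(raw_con, "integer", n, size = 4, endian = endian)),
    MET_FLOAT  = readBin(raw_con, "double", n, size = 4, endian = endian),
    MET_DOUBLE = readBin(raw_con, "double", n, size = 8, endian = endian))
  if (length(vals) != n)
    stop(sprintf("read_volume: truncated MetaImage data in %s", path))
  if (ndims == 2L) { dims <- c(dims, 1L); sp <- c(sp, 1); off <- c(off, 0) }
  arr <- array(vals, dim = dims)                 # x fastest
  volume(aperm(arr, c(3, 2, 1)), spacing = rev(sp), origin = rev(off))
}

write_metaimage <- function(vol, path) {
  dims <- rev(dim(vol$voxels))                   # (x, y, z)
  ext <- volume_ext(path)
  local_data <- ext == "mha"
  raw_name <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste("DimSize =", paste(dims, collapse = " ")),
           paste("ElementSpacing =", paste(format(rev(vol$spacing), scientific = FALSE),
                                           collapse = " ")),
           paste("Offset =", paste(format(rev(vol$origin), scientific = FALSE),
                                   collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", if (local_data) "LOCAL" else raw_name))
  data <- as.vector(aperm(vol$voxels, c(3, 2, 1)))
  if (local_data) {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeLines(hdr, con)
    writeBin(data, con, size = 8, endian = "little")
  } else {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(con), add = TRUE)
    writeBin(data, con, size = 8, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract a co-gridded fixed/moving slice pair from two volumes
#'
#' Takes the fixed (ultrasound) volume's slice along the requested axis and
#' resamples the moving (MR) volume onto that slice's pixel grid by
#' interpolation in physical space (trilinear across the volume, which
#' reduces to bilinear when the two volumes share planes).  Moving samples
#' outside the moving volume's physical extent are set to 0.
#'
#' @param vol_fixed,vol_moving [volume()] objects (axis-aligned frames).
#' @param axis slicing axis: `"axial"` (fix z), `"sagittal"` (fix x) or
#'   `"coronal"` (fix y).
#' @param index 1-based slice index along the axis of the fixed volume.
#' @param case_id label stored in the returned pair.
#' @return A [slice_pair()]; fixed is tagged `US`, moving `MR`.
#' @export
extract_slice_pair <- function(vol_fixed, vol_moving,
                               axis = c("axial", "sagittal", "coronal"),
                               index, case_id = "case") {
  stopifnot(inherits(vol_fixed, "volume"), inherits(vol_moving, "volume"))
  axis <- match.arg(axis)
  d <- dim(vol_fixed$voxels)
  ax <- switch(axis, axial = 1L, coronal = 2L, sagittal = 3L)  # (z,y,x)
  if (index < 1L || index > d[ax])
    stop(sprintf("extract_slice_pair: index %d out of range 1..%d along %s axis",
                 index, d[ax], axis))
  inplane <- setdiff(1:3, ax)
  fixed_px <- switch(axis,
                     axial    = vol_fixed$voxels[index, , ],
                     coronal  = vol_fixed$voxels[, index, ],
                     sagittal = vol_fixed$voxels[, , index])
  sp2 <- vol_fixed$spacing[inplane]
  or2 <- vol_fixed$origin[inplane]
  # physical coordinates of every fixed-slice pixel, full 3D
  h <- dim(fixed_px)[1]; w <- dim(fixed_px)[2]
  coord_ax <- vol_fixed$origin[ax] + (index - 1) * vol_fixed$spacing[ax]
  rr <- or2[1] + (seq_len(h) - 1) * sp2[1]
  cc <- or2[2] + (seq_len(w) - 1) * sp2[2]
  pts <- matrix(0, h * w, 3)
  pts[, ax] <- coord_ax
  pts[, inplane[1]] <- rep(rr, times = w)
  pts[, inplane[2]] <- rep(cc, each = h)
  mov_vals <- sample_volume_trilinear(vol_moving, pts)
  if (all(is.na(mov_vals)))
    stop("extract_slice_pair: fixed and moving volumes have no overlapping physical extent")
  mov_vals[is.na(mov_vals)] <- 0
  moving_px <- matrix(mov_vals, h, w)
  fixed <- image_slice(fixed_px, spacing = sp2, modality = "US", origin = or2)
  moving <- image_slice(moving_px, spacing = sp2, modality = "MR", origin = or2)
  slice_pair(fixed, moving, case_id = case_id, slice_index = as.integer(index))
}

# Trilinear sampling of a volume at physical (z,y,x) points; NA outside the
# grid's convex hull of voxel centres extended half a voxel is not applied:
# strictly outside [first, last] voxel centre coordinates returns NA.
sample_volume_trilinear <- function(vol, pts) {
  d <- dim(vol$voxels)
  q <- sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
  out <- rep(NA_real_, nrow(pts))
  inside <- q[, 1] >= 1 & q[, 1] <= d[1] &
            q[, 2] >= 1 & q[, 2] <= d[2] &
            q[, 3] >= 1 & q[, 3] <= d[3]
  if (!any(inside)) return(out)
  qi <- q[inside, , drop = FALSE]
  f0 <- pmin(floor(qi), matrix(rep(d - 1L, each = nrow(qi)), ncol = 3))
  f0 <- pmax(f0, 1)
  fr <- qi - f0
  acc <- numeric(nrow(qi))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    wz <- if (dz == 0) 1 - fr[, 1] else fr[, 1]
    wy <- if (dy == 0) 1 - fr[, 2] else fr[, 2]
    wx <- if (dx == 0) 1 - fr[, 3] else fr[, 3]
    # clamp the upper neighbour for degenerate (size-1) axes; its weight is 0
    idx <- cbind(pmin(f0[, 1] + dz, d[1]), pmin(f0[, 2] + dy, d[2]),
                 pmin(f0[, 3] + dx, d[3]))
    acc <- acc + wz * wy * wx * vol$voxels[idx]
  }
  out[inside] <- acc
  out
}
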