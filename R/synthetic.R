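# Synthetic co-registered pseudo-MR / pseudo-ultrasound slice pairs with
# known ground-truth deformations and paired landmarks.  The simulator is
# phenomenological: it reproduces the statistical structure the
# registration losses rely on (shared anatomy rendered through disjoint
# intensity mappings, edge-dominated speckled ultrasound), not acoustic or
# biomechanical physics.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# separable Gaussian blur with normalized (edge-corrected) convolution
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  blur1 <- function(m, along_rows) {
    acc <- m * 0; wacc <- m * 0
    n <- if (along_rows) nrow(m) else ncol(m)
    for (o in -r:r) {
      wo <- k[o + r + 1L]
      src <- seq_len(n) + o
      ok <- src >= 1L & src <= n
      if (along_rows) {
        acc[ok, ] <- acc[ok, ] + wo * m[src[ok], ]
        wacc[ok, ] <- wacc[ok, ] + wo
      } else {
        acc[, ok] <- acc[, ok] + wo * m[, src[ok]]
        wacc[, ok] <- wacc[, ok] + wo
      }
    }
    acc / wacc
  }
  blur1(blur1(mat, TRUE), FALSE)
}

ellipse_mask <- function(h, w, cy, cx, a, b, theta = 0) {
  dy <- matrix(seq_len(h) - cy, h, w)
  dx <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  ct <- cos(theta); st <- sin(theta)
  ((dy * ct + dx * st) / a)^2 + ((-dy * st + dx * ct) / b)^2 <= 1
}

#' Synthetic dataset configuration
#'
#' Study conditions of the simulator.  The defaults emulate moderate brain
#' shift on a desk-scale grid: smooth elastic displacements of up to 3 mm
#' with an 8 mm correlation length on 1 mm pixels, ten expert-like
#' landmarks per case, 12-look speckle and 2\% additive MR noise.
#'
#' @param size `(H, W)` in pixels, multiples of 32.
#' @param n_cases number of cases.
#' @param seed base RNG seed; every case derives its own sub-seed from it.
#' @param deform_amplitude maximum elastic displacement magnitude, mm.
#' @param deform_smoothness Gaussian correlation length of the field, mm.
#' @param rigid length-3 numeric `(rotation_deg, ty_mm, tx_mm)` rigid part.
#' @param n_landmarks landmarks per case (>= 3).
#' @param speckle_looks gamma-speckle shape parameter (larger = smoother
#'   ultrasound).
#' @param noise_sigma additive Gaussian noise sd of the MR rendering.
#' @param spacing pixel spacing in mm.
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(size = c(64L, 64L), n_cases = 10L, seed = 1L,
                         deform_amplitude = 3, deform_smoothness = 8,
                         rigid = c(0, 0, 0), n_landmarks = 10L,
                         speckle_looks = 12, noise_sigma = 0.02,
                         spacing = c(1, 1)) {
  if (deform_amplitude < 0) stop("synth_config: deform_amplitude must be >= 0")
  if (deform_smoothness <= 0) stop("synth_config: deform_smoothness must be > 0")
  if (n_landmarks < 3L) stop("synth_config: n_landmarks must be >= 3")
  if (any(size < 32L))
    stop("synth_config: size components must be at least 32")
  structure(list(size = as.integer(size), n_cases = as.integer(n_cases),
                 seed = as.integer(seed),
                 deform_amplitude = deform_amplitude,
                 deform_smoothness = deform_smoothness,
                 rigid = as.numeric(rigid),
                 n_landmarks = as.integer(n_landmarks),
                 speckle_looks = speckle_looks, noise_sigma = noise_sigma,
                 spacing = as.numeric(spacing)),
            class = "synth_config")
}

#' Generate a cartoon anatomy label map
#'
#' Deterministic per seed: background (0), a cortex ellipse (1), two to
#' five smooth internal structures and one tumour disk drawn last, at the
#' scale of a low-grade-glioma slice.
#'
#' @param seed RNG seed.
#' @param size `(H, W)` pixels.
#' @param spacing pixel spacing in mm.
#' @return An `image_slice` with modality `"LABEL"`; attributes
#'   `"tumor_radius_px"` and `"tumor_center"` describe the tumour disk.
#' @export
generate_anatomy <- function(seed, size = c(64L, 64L), spacing = c(1, 1)) {
  h <- size[1]; w <- size[2]
  with_seed(seed, {
    lab <- matrix(0, h, w)
    cy <- h / 2 + stats::runif(1, -h / 20, h / 20)
    cx <- w / 2 + stats::runif(1, -w / 20, w / 20)
    a <- h * stats::runif(1, 0.34, 0.42)
    b <- w * stats::runif(1, 0.36, 0.44)
    th <- stats::runif(1, -0.3, 0.3)
    cortex <- ellipse_mask(h, w, cy, cx, a, b, th)
    lab[cortex] <- 1
    n_struct <- sample(2:5, 1)
    for (s in seq_len(n_struct)) {
      sy <- cy + stats::runif(1, -0.45, 0.45) * a
      sx <- cx + stats::runif(1, -0.45, 0.45) * b
      sa <- stats::runif(1, 0.06, 0.16) * h
      sb <- stats::runif(1, 0.06, 0.16) * w
      m <- ellipse_mask(h, w, sy, sx, sa, sb, stats::runif(1, 0, pi)) & cortex
      lab[m] <- 1 + s
    }
    r_t <- stats::runif(1, 0.07, 0.11) * min(h, w)
    ty <- cy + stats::runif(1, -0.35, 0.35) * a
    tx <- cx + stats::runif(1, -0.35, 0.35) * b
    ty <- min(max(ty, r_t + 1), h - r_t - 1)
    tx <- min(max(tx, r_t + 1), w - r_t - 1)
    tum <- ellipse_mask(h, w, ty, tx, r_t, r_t)
    lab[tum] <- n_struct + 2
    out <- image_slice(lab, spacing = spacing, modality = "LABEL")
    attr(out, "tumor_radius_px") <- r_t
    attr(out, "tumor_center") <- c(ty, tx)
    out
  })
}

#' Render an MR-like slice from a label map
#'
#' Per-class mean intensities, a smooth low-order multiplicative bias field
#' and additive Gaussian noise, clamped to `[0, 1]`.  With zero noise and
#' zero bias amplitude the output is exactly piecewise constant at the
#' class means.
#'
#' @param labels label `image_slice` from [generate_anatomy()].
#' @param seed RNG seed (intensity assignment, bias, noise).
#' @param noise_sigma additive noise sd.
#' @param bias_amplitude relative amplitude of the bias field (0 = flat).
#' @return An `image_slice` with modality `"MR"`, values in `[0, 1]`;
#'   attribute `"class_means"` holds the per-class intensities.
#' @export
render_mr <- function(labels, seed, noise_sigma = 0.02,
                      bias_amplitude = 0.15) {
  stopifnot(is_image_slice(labels))
  lab <- labels$pixels
  h <- nrow(lab); w <- ncol(lab)
  classes <- sort(unique(as.vector(lab)))
  with_seed(seed + 1L, {
    means <- stats::setNames(numeric(length(classes)), classes)
    means[1] <- 0.05                      # background stays dark
    if (length(classes) > 1)
      means[-1] <- stats::runif(length(classes) - 1, 0.3, 0.85)
    img <- matrix(means[as.character(lab)], h, w)
    if (bias_amplitude > 0) {
      yn <- matrix(seq_len(h) / h - 0.5, h, w)
      xn <- matrix(seq_len(w) / w - 0.5, h, w, byrow = TRUE)
      co <- stats::runif(4, -bias_amplitude, bias_amplitude)
      bias <- 1 + co[1] * yn + co[2] * xn + co[3] * yn * xn +
        co[4] * (yn^2 - xn^2)
      img <- img * bias
    }
    if (noise_sigma > 0)
      img <- img + matrix(stats::rnorm(h * w, sd = noise_sigma), h, w)
    out <- image_slice(pmin(pmax(img, 0), 1), spacing = labels$spacing,
                       modality = "MR", origin = labels$origin)
    attr(out, "class_means") <- means
    out
  })
}

#' Render a B-mode-ultrasound-like slice from a label map
#'
#' Edge-dominated echogenicity (tissue boundaries emphasized via the
#' label-gradient magnitude), class-dependent base echo, multiplicative
#' mean-one gamma speckle, exponential depth attenuation and a fan-shaped
#' field of view outside which pixels are exactly zero.
#'
#' @param labels label `image_slice`.
#' @param seed RNG seed (echo assignment, speckle).
#' @param speckle_looks gamma shape (number of looks); speckle variance
#'   scales as `1/looks`.
#' @param attenuation depth-attenuation coefficient (per normalized depth).
#' @param fov `"fan"` or `"full"`.
#' @return An `image_slice` with modality `"US"`, values in `[0, 1]`;
#'   attribute `"fov_mask"` is the logical field-of-view mask.
#' @export
render_us <- function(labels, seed, speckle_looks = 12, attenuation = 0.3,
                      fov = c("fan", "full")) {
  stopifnot(is_image_slice(labels))
  fov <- match.arg(fov)
  lab <- labels$pixels
  h <- nrow(lab); w <- ncol(lab)
  with_seed(seed + 2L, {
    sm <- gaussian_blur(lab, 1.0)
    gy <- rbind(sm[2:h, ] - sm[1:(h - 1), ], matrix(0, 1, w))
    gx <- cbind(sm[, 2:w] - sm[, 1:(w - 1)], matrix(0, h, 1))
    edges <- gaussian_blur(sqrt(gy^2 + gx^2), 0.8)
    if (max(edges) > 0) edges <- edges / max(edges)
    classes <- sort(unique(as.vector(lab)))
    echo <- stats::setNames(stats::runif(length(classes), 0.1, 0.8),
                            classes)
    echo[1] <- 0.03
    img <- 0.8 * matrix(echo[as.character(lab)], h, w) + 0.35 * edges
    spk <- matrix(stats::rgamma(h * w, shape = speckle_looks,
                                rate = speckle_looks), h, w)
    img <- img * spk
    depth <- matrix((seq_len(h) - 1) / (h - 1), h, w)
    img <- img * exp(-attenuation * depth)
    mask <- if (fov == "fan") fan_mask(h, w) else matrix(TRUE, h, w)
    img[!mask] <- 0
    if (max(img) > 0) img <- img / max(img)
    out <- image_slice(pmin(pmax(img, 0), 1), spacing = labels$spacing,
                       modality = "US", origin = labels$origin)
    attr(out, "fov_mask") <- mask
    out
  })
}

# fan-shaped field of view: apex above the top edge, half-angle 40 degrees
fan_mask <- function(h, w) {
  ay <- -0.15 * h; ax <- (w + 1) / 2
  dy <- matrix(seq_len(h) - ay, h, w)
  dx <- matrix(seq_len(w) - ax, h, w, byrow = TRUE)
  ang <- atan2(dx, dy)
  rad <- sqrt(dy^2 + dx^2)
  abs(ang) <= 40 * pi / 180 & rad <= 1.12 * h & rad >= 0.08 * h
}

#' Sample a smooth random displacement field
#'
#' Per-component Gaussian-filtered white noise rescaled so the maximum
#' displacement magnitude equals `amplitude`, plus an optional rigid part
#' (rotation about the grid centre and translation).  Zero amplitude with
#' no rigid part gives the identity field.
#'
#' @param seed RNG seed.
#' @param size `(H, W)` pixels.
#' @param amplitude maximum elastic displacement magnitude, mm.
#' @param smoothness Gaussian correlation length, mm.
#' @param spacing pixel spacing, mm.
#' @param rigid `(rotation_deg, ty_mm, tx_mm)` or `NULL`.
#' @return A [displacement_field()].
#' @export
sample_smooth_field <- function(seed, size, amplitude, smoothness,
                                spacing = c(1, 1), rigid = NULL) {
  h <- size[1]; w <- size[2]
  u <- array(0, c(h, w, 2))
  if (amplitude > 0) {
    u[, , 1] <- with_seed(seed + 3L,
                          gaussian_blur(matrix(stats::rnorm(h * w), h, w),
                                        smoothness / spacing[1]))
    u[, , 2] <- with_seed(seed + 4L,
                          gaussian_blur(matrix(stats::rnorm(h * w), h, w),
                                        smoothness / spacing[2]))
    mag <- sqrt(u[, , 1]^2 + u[, , 2]^2)
    m <- max(mag)
    if (m > 0) u <- u * (amplitude / m)
  }
  if (!is.null(rigid) && any(rigid != 0)) {
    th <- rigid[1] * pi / 180
    cy <- (1 + h) / 2 * spacing[1]; cx <- (1 + w) / 2 * spacing[2]
    py <- matrix((seq_len(h) - 1) * spacing[1], h, w)
    px <- matrix((seq_len(w) - 1) * spacing[2], h, w, byrow = TRUE)
    dy <- py - cy; dx <- px - cx
    u[, , 1] <- u[, , 1] + (cos(th) - 1) * dy - sin(th) * dx + rigid[2]
    u[, , 2] <- u[, , 2] + sin(th) * dy + (cos(th) - 1) * dx + rigid[3]
  }
  displacement_field(u, spacing = spacing)
}

# Approximate inverse of a pull-back field by fixed-point iteration:
# returns the field v with moving = warp(aligned, v) consistent with
# aligned = warp(moving, u).  Exact for pure translations.
invert_field <- function(field, iterations = 10L) {
  h <- dim(field$u)[1]; w <- dim(field$u)[2]
  py <- field$origin[1] + (seq_len(h) - 1) * field$spacing[1]
  px <- field$origin[2] + (seq_len(w) - 1) * field$spacing[2]
  P <- cbind(rep(py, times = w), rep(px, each = h))
  X <- P
  for (it in seq_len(iterations)) {
    uX <- sample_field_at(field, X)$values
    X <- P - uX
  }
  v <- X - P
  displacement_field(array(c(v[, 1], v[, 2]), c(h, w, 2)),
                     spacing = field$spacing, origin = field$origin)
}

#' Generate one synthetic registration case
#'
#' Renders MR and ultrasound from the same anatomy, samples a ground-truth
#' pull-back field `u`, constructs the misaligned moving MR by warping the
#' aligned MR through the (approximately) inverted field — so that warping
#' the moving image through `u` re-aligns it — and places paired landmarks
#' at high-gradient anatomy points.  Landmark consistency is exact by
#' construction: moving landmark = fixed landmark + `u`(fixed landmark).
#'
#' @param cfg a [synth_config()].
#' @param case_index 1-based case number (drives the per-case seed).
#' @return A list of class `"synth_case"`: `pair` (misaligned
#'   [slice_pair()]), `true_field` ([displacement_field()]), `landmarks`
#'   ([landmark_set()]), `labels` (`image_slice`), `case_id`, `seed`.
#' @export
generate_case <- function(cfg, case_index = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  # double arithmetic: exact below 2^53, and the modulus keeps the derived
  # seed inside the 32-bit range set.seed accepts
  seed <- (as.numeric(cfg$seed) * 10007 + as.numeric(case_index) * 97) %%
    2147483647
  labels <- generate_anatomy(seed, cfg$size, cfg$spacing)
  mr0 <- render_mr(labels, seed, noise_sigma = cfg$noise_sigma)
  us <- render_us(labels, seed, speckle_looks = cfg$speckle_looks)
  u <- sample_smooth_field(seed, cfg$size, cfg$deform_amplitude,
                           cfg$deform_smoothness, cfg$spacing,
                           rigid = cfg$rigid)
  if (max(abs(u$u)) > 0) {
    vinv <- invert_field(u)
    moving <- apply_displacement(mr0, vinv)
  } else {
    moving <- mr0
  }
  moving <- image_slice(moving$pixels, spacing = cfg$spacing,
                        modality = "MR", origin = labels$origin)
  case_id <- sprintf("case_%03d", case_index)
  pair <- slice_pair(us, moving, case_id = case_id, slice_index = 1L)
  fixed_pts <- place_landmarks(labels, attr(us, "fov_mask"),
                               cfg$n_landmarks, seed)
  upts <- sample_field_at(u, fixed_pts)$values
  lm <- landmark_set(fixed_pts, fixed_pts + upts, case_id = case_id)
  structure(list(pair = pair, true_field = u, landmarks = lm,
                 labels = labels, case_id = case_id, seed = seed),
            class = "synth_case")
}

# landmarks at local maxima of the label-gradient magnitude, greedy
# farthest-point thinning with a minimum separation
place_landmarks <- function(labels, mask, n, seed) {
  lab <- labels$pixels
  h <- nrow(lab); w <- ncol(lab)
  sm <- gaussian_blur(lab, 1.0)
  gy <- rbind(sm[2:h, ] - sm[1:(h - 1), ], matrix(0, 1, w))
  gx <- cbind(sm[, 2:w] - sm[, 1:(w - 1)], matrix(0, h, 1))
  g <- sqrt(gy^2 + gx^2)
  margin <- 4L
  ok <- matrix(FALSE, h, w)
  ok[(margin + 1):(h - margin), (margin + 1):(w - margin)] <- TRUE
  if (!is.null(mask)) ok <- ok & mask
  g[!ok] <- 0
  cand <- order(g, decreasing = TRUE)[seq_len(min(500L, sum(g > 0)))]
  cy <- (cand - 1) %% h + 1
  cx <- (cand - 1) %/% h + 1
  min_sep <- max(4, min(h, w) / 12)
  sel <- integer(0)
  for (i in seq_along(cand)) {
    if (length(sel) >= n) break
    if (!length(sel)) { sel <- i; next }
    dd <- sqrt((cy[i] - cy[sel])^2 + (cx[i] - cx[sel])^2)
    if (min(dd) >= min_sep) sel <- c(sel, i)
  }
  # relax separation if the gradient map was too sparse
  while (length(sel) < n && min_sep > 1) {
    min_sep <- min_sep / 2
    for (i in seq_along(cand)) {
      if (length(sel) >= n) break
      dd <- sqrt((cy[i] - cy[sel])^2 + (cx[i] - cx[sel])^2)
      if (min(dd) >= min_sep) sel <- c(sel, i)
    }
  }
  pts_px <- cbind(cy[sel[seq_len(n)]], cx[sel[seq_len(n)]])
  cbind(labels$origin[1] + (pts_px[, 1] - 1) * labels$spacing[1],
        labels$origin[2] + (pts_px[, 2] - 1) * labels$spacing[2])
}

#' Write a synthetic dataset to disk
#'
#' One directory per case holding the ultrasound, moving MR and label
#' images plus the ground-truth field (NIfTI) and the landmark CSV, and a
#' `manifest.csv` at the root from which the whole dataset is reproducible.
#'
#' @param cfg a [synth_config()].
#' @param out_dir output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
make_dataset <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop(sprintf("make_dataset: cannot create directory %s", out_dir))
  rows <- vector("list", cfg$n_cases)
  for (i in seq_len(cfg$n_cases)) {
    cs <- generate_case(cfg, i)
    cdir <- file.path(out_dir, cs$case_id)
    dir.create(cdir, showWarnings = FALSE)
    write_slice_nifti(cs$pair$fixed, file.path(cdir, "us.nii.gz"))
    write_slice_nifti(cs$pair$moving, file.path(cdir, "mr.nii.gz"))
    write_slice_nifti(cs$labels, file.path(cdir, "labels.nii.gz"))
    write_field(cs$true_field, file.path(cdir, "true_field.nii.gz"))
    write_landmarks(cs$landmarks, file.path(cdir, "landmarks.csv"))
    rows[[i]] <- data.frame(case_id = cs$case_id, case_index = i,
                            seed = cs$seed, h = cfg$size[1], w = cfg$size[2],
                            deform_amplitude = cfg$deform_amplitude,
                            deform_smoothness = cfg$deform_smoothness,
                            rigid_rot = cfg$rigid[1], rigid_ty = cfg$rigid[2],
                            rigid_tx = cfg$rigid[3],
                            n_landmarks = cfg$n_landmarks,
                            speckle_looks = cfg$speckle_looks,
                            noise_sigma = cfg$noise_sigma)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

write_slice_nifti <- function(img, path) {
  write_volume(volume(array(img$pixels, c(1, dim(img$pixels))),
                      spacing = c(1, img$spacing),
                      origin = c(0, img$origin)), path)
}

read_slice_nifti <- function(path, modality) {
  vol <- read_volume(path)
  image_slice(matrix(vol$voxels[1, , ], dim(vol$voxels)[2],
                     dim(vol$voxels)[3]),
              spacing = vol$spacing[2:3], modality = modality,
              origin = vol$origin[2:3])
}

#' Read a synthetic dataset back from disk
#'
#' @param dir dataset directory written by [make_dataset()].
#' @return List of cases, each with `pair`, `true_field`, `landmarks`,
#'   `labels`, `case_id`.
#' @export
load_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath))
    stop(sprintf("load_dataset: no manifest.csv in %s", dir))
  manifest <- utils::read.csv(mpath)
  lapply(seq_len(nrow(manifest)), function(i) {
    cdir <- file.path(dir, manifest$case_id[i])
    us <- read_slice_nifti(file.path(cdir, "us.nii.gz"), "US")
    mr <- read_slice_nifti(file.path(cdir, "mr.nii.gz"), "MR")
    labels <- read_slice_nifti(file.path(cdir, "labels.nii.gz"), "LABEL")
    fpath <- file.path(cdir, "true_field.nii.gz")
    fld <- if (file.exists(fpath)) read_field(fpath)
    lpath <- file.path(cdir, "landmarks.csv")
    lm <- if (file.exists(lpath))
      read_landmarks(lpath, format = "csv",
                     case_id = manifest$case_id[i])
    list(pair = slice_pair(us, mr, case_id = manifest$case_id[i]),
         true_field = fld, landmarks = lm, labels = labels,
         case_id = manifest$case_id[i])
  })
}
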