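# The synthetic MR/ultrasound simulator and its statistical properties.

test_that("anatomy generation is deterministic with bounded class counts", {
  a1 <- generate_anatomy(5, c(64, 64))
  a2 <- generate_anatomy(5, c(64, 64))
  expect_identical(a1$pixels, a2$pixels)
  for (seed in 1:25) {
    lab <- generate_anatomy(seed, c(64, 64))
    k <- length(unique(as.vector(lab$pixels)))
    expect_gte(k, 3); expect_lte(k, 8)
  }
})

test_that("the tumour disk area matches the analytic value", {
  for (seed in c(2, 9, 14)) {
    lab <- generate_anatomy(seed, c(96, 96))
    r <- attr(lab, "tumor_radius_px")
    tumor_label <- max(lab$pixels)
    area <- sum(lab$pixels == tumor_label)
    # discretization error of a rasterized disk is O(perimeter)
    expect_lt(abs(area - pi * r^2), 2 * pi * r + 8)
  }
})

test_that("noise-free flat-bias MR rendering is exactly piecewise constant", {
  lab <- generate_anatomy(3, c(64, 64))
  mr <- render_mr(lab, 3, noise_sigma = 0, bias_amplitude = 0)
  means <- attr(mr, "class_means")
  expect_identical(sort(unique(as.vector(mr$pixels))),
                   sort(unname(means)))
  expect_identical(render_mr(lab, 3)$pixels, render_mr(lab, 3)$pixels)
})

test_that("within-class MR variance matches the configured noise", {
  lab <- generate_anatomy(4, c(128, 128))
  sigma <- 0.03
  mr <- render_mr(lab, 4, noise_sigma = sigma, bias_amplitude = 0)
  inside <- lab$pixels == 1
  expect_gt(sum(inside), 2000)
  expect_lt(abs(stats::var(mr$pixels[inside]) - sigma^2), 0.1 * sigma^2)
})

test_that("ultrasound pixels outside the field of view are exactly zero", {
  lab <- generate_anatomy(6, c(64, 64))
  us <- render_us(lab, 6)
  mask <- attr(us, "fov_mask")
  expect_true(any(!mask))
  expect_true(all(us$pixels[!mask] == 0))
  expect_true(all(us$pixels >= 0 & us$pixels <= 1))
})

test_that("speckle variance scales as one over the number of looks", {
  lab <- generate_anatomy(7, c(128, 128))
  # divide out the deterministic echo structure with a near-noiseless
  # rendering, leaving the multiplicative speckle whose relative variance
  # is 1/looks (gamma with shape = looks); the ratio is normalization-free
  ref <- render_us(lab, 7, speckle_looks = 1e8)
  sel <- attr(ref, "fov_mask") & ref$pixels > 0.05
  relvar_speckle <- function(looks) {
    r <- render_us(lab, 7, speckle_looks = looks)$pixels[sel] /
      ref$pixels[sel]
    stats::var(r) / mean(r)^2
  }
  ratio <- relvar_speckle(4) / relvar_speckle(400)
  expect_gt(ratio, 50); expect_lt(ratio, 200)
})

test_that("same-anatomy MR and US are far more dependent than mismatched pairs", {
  margins <- sapply(1:3, function(k) {
    la <- generate_anatomy(300 + k, c(128, 128))
    lb <- generate_anatomy(800 + k, c(128, 128))
    usa <- render_us(la, 300 + k)
    nmi(usa, render_mr(la, 300 + k), bins = 16) -
      nmi(usa, render_mr(lb, 800 + k), bins = 16)
  })
  expect_gt(min(margins), 0.05)
})

test_that("sampled fields respect amplitude and grow smoother with the length scale", {
  z <- sample_smooth_field(1, c(64, 64), amplitude = 0, smoothness = 8)
  expect_true(all(z$u == 0))
  f <- sample_smooth_field(1, c(64, 64), amplitude = 2.5, smoothness = 8)
  mag <- sqrt(f$u[, , 1]^2 + f$u[, , 2]^2)
  expect_lt(abs(max(mag) - 2.5), 1e-6)

  # lag-2 autocorrelation of the y-component rises monotonically with the
  # correlation length, averaged over seeds
  acf2 <- function(sm) {
    mean(sapply(1:8, function(s) {
      u <- sample_smooth_field(s, c(64, 64), 1, sm)$u[, , 1]
      u <- u - mean(u)
      sum(u[1:62, ] * u[3:64, ]) / sum(u^2)
    }))
  }
  a <- acf2(2); b <- acf2(8); c3 <- acf2(32)
  expect_lt(a, b); expect_lt(b, c3)
})

test_that("generated cases are landmark-consistent by construction", {
  for (seed in 1:4) {
    cs <- generate_case(synth_config(size = c(64, 64), seed = seed), 1)
    mapped <- transform_landmarks(cs$landmarks, cs$true_field)
    err <- sqrt(rowSums((mapped - cs$landmarks$moving_points)^2))
    expect_lt(max(err), 0.01)
    expect_lte(as.numeric(mtre(cs$landmarks)),
               cs$true_field$spacing[1] * 0 + 3 + 1e-9)  # <= amplitude
  }
})

test_that("an aligned case has zero initial mTRE and a 3-4-5 shift gives 5", {
  cs0 <- generate_case(synth_config(size = c(32, 32), seed = 5,
                                    deform_amplitude = 0), 1)
  expect_equal(as.numeric(mtre(cs0$landmarks)), 0)
  cs <- generate_case(synth_config(size = c(32, 32), seed = 5,
                                   deform_amplitude = 0,
                                   rigid = c(0, 3, 4)), 1)
  expect_equal(as.numeric(mtre(cs$landmarks)), 5, tolerance = 1e-9)
})

test_that("warping the misaligned MR through the true field re-aligns it", {
  cfg <- synth_config(size = c(64, 64), seed = 8, deform_amplitude = 2,
                      deform_smoothness = 10)
  cs <- generate_case(cfg, 1)
  aligned <- render_mr(cs$labels, cs$seed, noise_sigma = cfg$noise_sigma)
  back <- apply_displacement(cs$pair$moving, cs$true_field)
  inner <- 12:52
  expect_lt(mean(abs(back$pixels[inner, inner] - aligned$pixels[inner, inner])),
            0.03)
})

test_that("datasets round-trip through disk byte-identically", {
  cfg <- synth_config(size = c(32, 32), n_cases = 2, seed = 12)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  manifest <- make_dataset(cfg, d1)
  expect_identical(nrow(manifest), 2L)
  make_dataset(cfg, d2)
  for (f in c("case_001/us.nii.gz", "case_001/landmarks.csv",
              "case_002/true_field.nii.gz", "manifest.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  cases <- load_dataset(d1)
  mem <- generate_case(cfg, 1)
  expect_equal(cases[[1]]$pair$moving$pixels, mem$pair$moving$pixels,
               tolerance = 1e-6)
  expect_equal(cases[[1]]$true_field$u, mem$true_field$u, tolerance = 1e-6)
  expect_equal(cases[[1]]$landmarks$fixed_points, mem$landmarks$fixed_points,
               tolerance = 1e-6)
})
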