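# Training schedule, determinism, gradient isolation and validation.

small_control <- function(...) {
  defaults <- list(epochs = 2L, batch_size = 2L, seed = 11L,
                   enc_channels = c(8L, 8L, 16L, 16L, 32L),
                   dec_channels = c(16L, 16L, 8L, 8L, 8L),
                   disc_channels = c(8L, 8L, 16L, 16L))
  args <- utils::modifyList(defaults, list(...))
  do.call(ganreg_control, args)
}

test_that("the learning-rate schedule decays exponentially from 1e-5", {
  ctl <- ganreg_control()
  expect_equal(lr_schedule(0, ctl), 1e-5)
  expect_equal(lr_schedule(1, ctl), 8.5e-6)
  expect_equal(lr_schedule(2, ctl), 7.225e-6)
  for (e in c(5, 50, 199))
    expect_equal(lr_schedule(e, ctl), 1e-5 * 0.85^e, tolerance = 1e-12)
})

test_that("control validates its hyperparameters", {
  expect_error(ganreg_control(epochs = 0), "epochs")
  expect_error(ganreg_control(lr0 = 0), "lr0")
  expect_error(ganreg_control(lr_decay = 1.2), "lr_decay")
  expect_error(ganreg_control(lambda_b = -1), "nonnegative")
})

test_that("training is bit-reproducible under a fixed seed", {
  pairs <- lapply(1:4, function(i) rand_pair(32, seed = 80 + i))
  m1 <- ganreg(pairs, small_control())
  m2 <- ganreg(pairs, small_control())
  expect_identical(m1$history[, setdiff(names(m1$history), "seconds")],
                   m2$history[, setdiff(names(m2$history), "seconds")])
  expect_identical(ganreg:::net_parameters(m1$generator),
                   ganreg:::net_parameters(m2$generator))
})

test_that("zero weights remove the similarity terms from the totals", {
  pairs <- lapply(1:2, function(i) rand_pair(32, seed = 85 + i))
  m <- ganreg(pairs, small_control(lambda_b = 0, lambda_mi = 0))
  h <- m$history
  expect_equal(h$l_g_total, h$l_g)
  expect_equal(h$l_d1_total, h$l_d1)
  expect_equal(h$l_d2_total, h$l_d2)
  # components are still measured and logged
  expect_true(all(h$l_b >= 0 & h$l_b <= 1))
  expect_true(all(is.finite(h$l_mi_d1)))
})

test_that("each update touches only its own network's parameters", {
  pairs <- lapply(1:2, function(i) rand_pair(32, seed = 87 + i))
  st <- ganreg:::stack_pairs(pairs)
  ctl <- small_control()
  set.seed(ctl$seed)
  gen <- build_generator(generator_config(enc_channels = ctl$enc_channels,
                                          dec_channels = ctl$dec_channels))
  d1 <- build_discriminator(discriminator_config(
    conv_channels = ctl$disc_channels, input_size = c(32L, 32L)))
  d2 <- build_discriminator(discriminator_config(
    conv_channels = ctl$disc_channels, input_size = c(32L, 32L)))
  snap <- function(net) ganreg:::net_parameters(net)
  g0 <- snap(gen); d10 <- snap(d1); d20 <- snap(d2)
  x <- array(0, c(32, 32, 2, 2))
  x[, , , 1] <- st$fixed; x[, , , 2] <- st$moving
  gfw <- ganreg:::generator_forward(gen, x, train = TRUE)

  # one D1 adversarial update
  fr <- ganreg:::discriminator_forward(d1, st$fixed, train = TRUE)
  grads <- ganreg:::backward_network(d1, fr$caches, rep(-0.5, 2))$grads
  ganreg:::adam_step(d1, grads, 1e-3)
  expect_false(identical(snap(d1), d10))
  expect_identical(snap(gen), g0)
  expect_identical(snap(d2), d20)

  # one generator update
  d11 <- snap(d1)
  ggr <- ganreg:::backward_network(gen, gfw$caches,
                                   array(1e-3, c(32, 32, 2, 2)))$grads
  ganreg:::adam_step(gen, ggr, 1e-3)
  expect_false(identical(snap(gen), g0))
  expect_identical(snap(d1), d11)
  expect_identical(snap(d2), d20)
})

test_that("training rejects unnormalized input and empty pair lists", {
  bad <- rand_pair(32, seed = 90)
  bad$moving$pixels <- bad$moving$pixels * 4 - 1
  expect_error(ganreg(list(bad), small_control()), "normalize_intensity")
  expect_error(ganreg(list(), small_control()), "non-empty")
})

test_that("validation is deterministic and needs a non-empty set", {
  pairs <- lapply(1:3, function(i) rand_pair(32, seed = 91 + i))
  m <- ganreg(pairs[1:2], small_control(epochs = 1L))
  v1 <- validate_pairs(pairs[3], m)
  v2 <- validate_pairs(pairs[3], m)
  expect_identical(v1, v2)
  expect_named(v1, c("l_g", "l_d1", "l_d2", "l_b", "l_mi_d1", "l_mi_d2"))
  expect_error(validate_pairs(list(), m), "empty")
})

test_that("per-epoch validation is recorded in the history", {
  pairs <- lapply(1:3, function(i) rand_pair(32, seed = 95 + i))
  m <- ganreg(pairs[1:2], small_control(), validation = pairs[3])
  expect_true(all(c("val_l_g", "val_l_d1", "val_l_d2") %in% names(m$history)))
  expect_true(all(is.finite(m$history$val_l_g)))
})

test_that("training resumes from a fitted model with continued numbering", {
  pairs <- lapply(1:2, function(i) rand_pair(32, seed = 120 + i))
  m1 <- ganreg(pairs, small_control(epochs = 1L))
  m2 <- ganreg(pairs, small_control(epochs = 2L), init = m1)
  expect_identical(m2$history$epoch, 1:3)
  # the schedule keeps decaying across the resume boundary
  expect_equal(m2$history$lr, small_control()$lr0 * 0.85^(0:2),
               tolerance = 1e-12)
  expect_false(identical(ganreg:::net_parameters(m1$generator),
                         ganreg:::net_parameters(m2$generator)))
  expect_error(ganreg(lapply(1:2, function(i) rand_pair(64, seed = i)),
                      small_control(epochs = 1L), init = m1),
               "different grid")
})

test_that("checkpoints round-trip the whole model", {
  pairs <- lapply(1:2, function(i) rand_pair(32, seed = 98 + i))
  m <- ganreg(pairs, small_control(epochs = 1L))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(ganreg:::net_parameters(back$generator),
                   ganreg:::net_parameters(m$generator))
  expect_identical(back$control, m$control)
  r1 <- predict(m, pairs[[1]])
  r2 <- predict(back, pairs[[1]])
  expect_identical(r1$registered$pixels, r2$registered$pixels)

  corrupt <- tempfile(fileext = ".rds")
  saveRDS(list(1, 2), corrupt)
  expect_error(load_checkpoint(corrupt), "not a ganreg checkpoint")
})

test_that("fitted model methods print, summarize and predict", {
  pairs <- lapply(1:2, function(i) rand_pair(32, seed = 101 + i))
  m <- ganreg(pairs, small_control(epochs = 1L))
  expect_output(print(m), "Adversarial deformable registration")
  expect_output(summary(m), "Loss trajectory")
  res <- predict(m, pairs)
  expect_length(res, 2)
  expect_s3_class(res[[1]]$field, "displacement_field")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
})
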