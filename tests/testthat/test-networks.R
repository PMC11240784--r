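# Generator / discriminator architectures and the registration wrapper.

test_that("generator output matches input size across valid sizes", {
  set.seed(51)
  gen <- build_generator(generator_config())
  for (hw in list(c(32L, 32L), c(64L, 32L), c(96L, 64L))) {
    x <- array(runif(prod(hw) * 2), c(hw[1], hw[2], 1L, 2L))
    out <- ganreg:::generator_forward(gen, x, train = FALSE)$out
    expect_identical(dim(out), c(hw, 1L, 2L))
  }
  expect_error(ganreg:::generator_forward(gen, array(0, c(50, 50, 1, 2))),
               "multiple-of-32")
})

test_that("a fresh field-mode generator starts at the identity transform", {
  set.seed(52)
  gen <- build_generator(generator_config())
  x <- array(runif(64 * 64 * 2), c(64, 64, 1, 2))
  out <- ganreg:::generator_forward(gen, x, train = FALSE)$out
  expect_lt(max(abs(out)), 0.5)
})

test_that("parameter counts match the configured channel plan", {
  set.seed(53)
  gen <- build_generator(generator_config())
  enc <- c(16, 32, 64, 128, 256)
  dec <- c(128, 64, 32, 16, 16)
  conv_p <- function(ci, co) 9 * ci * co + co
  bn_p <- function(c) 2 * c
  want <- 0
  ci <- 2
  for (co in enc) { want <- want + conv_p(ci, co) + bn_p(co); ci <- co }
  for (co in dec) { want <- want + conv_p(co, ci) - ci + co + bn_p(co); ci <- co }
  want <- want + conv_p(ci, 2)              # zero-initialized head
  expect_identical(n_parameters(gen), want)

  dis <- build_discriminator(discriminator_config(input_size = c(64, 64)))
  dw <- 0; ci <- 1
  for (co in c(16, 32, 64, 128)) { dw <- dw + conv_p(ci, co) + bn_p(co); ci <- co }
  dw <- dw + 4 * 4 * 128 + 1                # dense head on the 4x4 map
  expect_identical(n_parameters(dis), dw)
})

test_that("discriminator outputs are clamped probabilities, deterministic in eval", {
  set.seed(54)
  dis <- build_discriminator(discriminator_config(input_size = c(32, 32)))
  for (mag in c(1, 1e3)) {
    x <- array(runif(32 * 32 * 3, -mag, mag), c(32, 32, 3, 1))
    p <- ganreg:::discriminator_forward(dis, x, train = FALSE)$out
    expect_length(p, 3)
    expect_true(all(p >= 1e-6 & p <= 1 - 1e-6))
  }
  one <- matrix(runif(32 * 32), 32, 32)
  x <- array(0, c(32, 32, 2, 1))
  x[, , 1, 1] <- one; x[, , 2, 1] <- one    # the same image twice in a batch
  p1 <- ganreg:::discriminator_forward(dis, x, train = FALSE)$out
  p2 <- ganreg:::discriminator_forward(dis, x, train = FALSE)$out
  expect_identical(p1, p2)
  expect_identical(p1[1], p1[2])            # identical inputs, identical outputs
})

test_that("configs validate their structural constraints", {
  expect_error(generator_config(enc_channels = c(8, 16)), "5 encoder")
  expect_error(generator_config(max_disp = 0), "max_disp")
  expect_error(discriminator_config(in_channels = 3), "1 or 2")
  expect_error(discriminator_config(input_size = c(40, 64)), "divisible")
})

test_that("register_pair starts near the identity and validates shapes", {
  set.seed(55)
  gen <- build_generator(generator_config())
  pair <- rand_pair(64, seed = 56)
  res <- register_pair(gen, pair)
  expect_s3_class(res$field, "displacement_field")
  expect_lt(max(abs(res$registered$pixels - pair$moving$pixels)), 0.05)

  gen_img <- build_generator(generator_config(mode = "image"))
  res2 <- register_pair(gen_img, pair)
  expect_null(res2$field)
  expect_true(all(res2$registered$pixels >= 0 & res2$registered$pixels <= 1))

  expect_error(register_pair(gen, rand_pair(48, seed = 57)), "multiple-of-32")
})

test_that("network layer gradients agree with numerical derivatives", {
  set.seed(58)
  checks <- list(
    list(layer = ganreg:::layer_conv(2, 3), din = c(8, 8, 2, 2),
         dout = c(4, 4, 2, 3)),
    list(layer = ganreg:::layer_tconv(3, 2), din = c(4, 4, 2, 3),
         dout = c(8, 8, 2, 2)),
    list(layer = ganreg:::layer_bn(3), din = c(4, 4, 2, 3),
         dout = c(4, 4, 2, 3)))
  for (ck in checks) {
    l <- ck$layer
    x <- array(rnorm(prod(ck$din)), ck$din)
    R <- array(rnorm(prod(ck$dout)), ck$dout)
    fw <- ganreg:::layer_forward(l, x, train = TRUE, update_stats = FALSE)
    bk <- ganreg:::layer_backward(l, fw$cache, R)
    gn <- numerical_gradient(function(xx)
      sum(ganreg:::layer_forward(l, xx, train = TRUE,
                                 update_stats = FALSE)$out * R), x)
    expect_lt(max_rel_err(bk$dx, gn), 1e-3)
    for (p in ganreg:::layer_params(l)) {
      gp <- numerical_gradient(function(w) {
        l2 <- l; l2[[p]] <- array(w, dim(l[[p]]) %||% length(l[[p]]))
        sum(ganreg:::layer_forward(l2, x, train = TRUE,
                                   update_stats = FALSE)$out * R)
      }, l[[p]])
      expect_lt(max_rel_err(bk$grads[[p]], gp), 1e-3)
    }
  }
})
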