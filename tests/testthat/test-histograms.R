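# Joint histograms, mutual information and the two similarity losses,
# checked against brute-force enumerations.

test_that("hard joint histogram matches the enumerated 2x2 example", {
  a <- matrix(c(0, 0.6, 0.4, 1), 2, 2)      # pixels (0, .4), (.6, 1)
  b <- matrix(c(1, 0.4, 0.6, 0), 2, 2)
  h <- joint_histogram(a, b, bins = 2, mode = "hard")
  expect_equal(h$counts, matrix(c(0, 2, 2, 0), 2, 2))
})

test_that("identical images concentrate all counts on the diagonal", {
  a <- rand_image(6, seed = 31)
  h <- joint_histogram(a, a, bins = 4, mode = "hard")
  expect_equal(sum(h$counts) - sum(diag(h$counts)), 0)
  expect_equal(sum(h$counts), 36)
})

test_that("hard histograms equal a brute-force double loop on random inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:16, 1)
    bins <- sample(2:8, 1)
    a <- matrix(runif(n * n), n, n)
    b <- matrix(runif(n * n), n, n)
    h <- joint_histogram(a, b, bins = bins, mode = "hard")
    expect_identical(h$counts, brute_hist2(a, b, bins))
  }
})

test_that("soft histograms sum to the pixel count and approach hard counts", {
  set.seed(32)
  a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
  hs <- joint_histogram(a, b, bins = 6, mode = "soft")
  expect_lt(abs(sum(hs$counts) - 64), 1e-6)
  narrow <- joint_histogram(a, b, bins = 6, mode = "soft",
                            kernel_width = 1e-4)
  hard <- joint_histogram(a, b, bins = 6, mode = "hard")
  expect_lt(max(abs(narrow$counts - hard$counts)), 1e-3)
})

test_that("mutual information has its closed-form values and symmetry", {
  # independent uniform marginals: product table has zero MI
  h <- joint_histogram(matrix(rep(c(0.1, 0.6), 8), 4, 4),
                       matrix(rep(c(0.1, 0.6), each = 8), 4, 4),
                       bins = 2, mode = "hard")
  expect_equal(mutual_information(h), 0, tolerance = 1e-12)

  # identity permutation over 4 equiprobable bins: MI = log 4
  v <- matrix((0:15) / 15, 4, 4)
  hi <- joint_histogram(v, v, bins = 4, mode = "hard")
  expect_equal(mutual_information(hi), log(4), tolerance = 1e-12)

  # random tables: brute-force oracle and symmetry
  for (seed in 1:5) {
    set.seed(seed + 100)
    a <- matrix(runif(81), 9, 9); b <- matrix(runif(81), 9, 9)
    hab <- joint_histogram(a, b, bins = 3, mode = "hard")
    hba <- joint_histogram(b, a, bins = 3, mode = "hard")
    expect_lt(abs(mutual_information(hab) - brute_mi(hab$counts)), 1e-12)
    expect_lt(abs(mutual_information(hab) - mutual_information(hba)), 1e-12)
  }
})

test_that("mi_loss is 0 for identical images and ~1 for independent ones", {
  a <- rand_image(8, seed = 33)
  expect_equal(mi_loss(a, a, bins = 4), 0, tolerance = 1e-12)

  set.seed(34)
  x <- matrix(runif(64 * 64), 64, 64)
  y <- matrix(runif(64 * 64), 64, 64)
  expect_lt(abs(mi_loss(x, y, bins = 8) - 1), 0.05)

  const <- image_slice(matrix(0.5, 8, 8))
  l <- mi_loss(const, a, bins = 4)
  expect_equal(as.numeric(l), 1)
  expect_true(attr(l, "degenerate"))
})

test_that("mi_loss and bayes_loss stay within [0, 1] on random inputs", {
  set.seed(35)
  for (k in 1:200) {
    n <- sample(c(4, 6, 8), 1)
    a <- matrix(runif(n * n), n, n)
    b <- matrix(runif(n * n), n, n)
    c3 <- matrix(runif(n * n), n, n)
    mode <- if (k %% 2) "hard" else "soft"
    lm <- mi_loss(a, b, bins = 4, mode = mode)
    lb <- bayes_loss(a, b, c3, bins = 4, mode = mode)
    expect_true(lm >= 0 && lm <= 1)
    expect_true(lb >= 0 && lb <= 1)
  }
})

test_that("bayes_loss is 0 when registered is a per-bin function of a source", {
  set.seed(36)
  m <- matrix(runif(64), 8, 8)
  u <- matrix(runif(64), 8, 8)
  expect_equal(bayes_loss(m, m, u, bins = 4, mode = "hard"), 0,
               tolerance = 1e-12)
  # any per-bin injective remapping of the MR bins also scores posterior 1
  f <- (pmin(pmax(floor(m * 4) + 1, 1), 4) - 0.5) / 4
  remap <- matrix(rev(seq(0.1, 0.9, length.out = 4))[pmin(pmax(floor(m * 4) + 1, 1), 4)], 8, 8)
  expect_equal(bayes_loss(remap, m, u, bins = 4, mode = "hard"), 0,
               tolerance = 1e-12)
})

test_that("bayes_loss equals brute-force pixel enumeration on toy inputs", {
  for (seed in 1:5) {
    set.seed(seed + 200)
    r <- matrix(runif(16), 4, 4)
    m <- matrix(runif(16), 4, 4)
    u <- matrix(runif(16), 4, 4)
    expect_lt(abs(bayes_loss(r, m, u, bins = 3, mode = "hard") -
                    brute_bayes_loss(r, m, u, 3)), 1e-12)
  }
})

test_that("bayes_loss approaches 1 - 1/B for an independent registered image", {
  set.seed(37)
  n <- 128
  m <- matrix(runif(n * n), n, n)
  u <- matrix(runif(n * n), n, n)
  r <- matrix(runif(n * n), n, n)
  expect_lt(abs(bayes_loss(r, m, u, bins = 4, mode = "hard") - 0.75), 0.05)
})

test_that("soft-mode losses have exact analytic gradients", {
  set.seed(38)
  a <- matrix(runif(64), 8, 8)
  b <- matrix(runif(64), 8, 8)
  g <- ganreg:::mi_loss_grad(a, b, bins = 8)
  gn <- numerical_gradient(function(x)
    ganreg:::mi_loss_grad(matrix(x, 8, 8), b, bins = 8)$loss, a)
  expect_lt(max_rel_err(g$grad, gn), 1e-3)

  m <- matrix(runif(64), 8, 8); u <- matrix(runif(64), 8, 8)
  gb <- ganreg:::bayes_loss_grad(a, m, u, bins = 4)
  gbn <- numerical_gradient(function(x)
    ganreg:::bayes_loss_grad(matrix(x, 8, 8), m, u, bins = 4)$loss, a)
  expect_lt(max_rel_err(gb$grad, gbn), 1e-3)
  expect_true(all(is.finite(g$grad)) && all(is.finite(gb$grad)))
})

test_that("histogram inputs are validated", {
  a <- matrix(runif(16), 4, 4)
  expect_error(joint_histogram(a, matrix(0.5, 4, 5)), "shape")
  expect_error(joint_histogram(a * 2 + 1, a), "outside")
  expect_error(joint_histogram(a, a, bins = 1), "bins")
  expect_error(mutual_information(structure(
    list(counts = matrix(0, 2, 2)), class = "joint_histogram")), "all-zero")
})
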