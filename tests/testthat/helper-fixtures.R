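# Shared fixtures and numerical helpers for the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_image <- function(h, w = h, seed = NULL, modality = "MR") {
  if (!is.null(seed)) set.seed(seed)
  image_slice(matrix(stats::runif(h * w), h, w), modality = modality)
}

rand_pair <- function(h, w = h, seed = 1, case_id = "t") {
  set.seed(seed)
  slice_pair(image_slice(matrix(stats::runif(h * w), h, w), modality = "US"),
             image_slice(matrix(stats::runif(h * w), h, w), modality = "MR"),
             case_id = case_id)
}

# central-difference gradient of a scalar function of an array
numerical_gradient <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

# brute-force joint histogram by explicit double loop over bins
brute_hist2 <- function(a, b, bins) {
  va <- as.vector(a); vb <- as.vector(b)
  ia <- pmin(pmax(floor(va * bins) + 1L, 1L), bins)
  ib <- pmin(pmax(floor(vb * bins) + 1L, 1L), bins)
  counts <- matrix(0L, bins, bins)
  for (i in seq_len(bins)) for (j in seq_len(bins))
    counts[i, j] <- sum(ia == i & ib == j)
  counts
}

# brute-force mutual information from a count table
brute_mi <- function(counts) {
  p <- counts / sum(counts)
  pa <- rowSums(p); pb <- colSums(p)
  acc <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0)
      acc <- acc + p[i, j] * log(p[i, j] / (pa[i] * pb[j]))
  }
  acc
}

# brute-force Bayes posterior score by enumerating pixels
brute_bayes_loss <- function(r, m, u, bins) {
  br <- pmin(pmax(floor(as.vector(r) * bins) + 1L, 1L), bins)
  bm <- pmin(pmax(floor(as.vector(m) * bins) + 1L, 1L), bins)
  bu <- pmin(pmax(floor(as.vector(u) * bins) + 1L, 1L), bins)
  n <- length(br)
  score <- 0
  for (p in seq_len(n)) {
    joint <- sum(br == br[p] & bm == bm[p] & bu == bu[p])
    marg <- sum(bm == bm[p] & bu == bu[p])
    score <- score + joint / marg
  }
  1 - score / n
}
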