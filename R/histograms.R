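#' Joint intensity histograms over [0, 1]
#'
#' Builds the B x B (pairwise) or B x B x B (triple) co-occurrence table of
#' intensity bins from two or three images on the same grid.  Two binning
#' modes are provided:
#' \describe{
#'   \item{`hard`}{each pixel contributes a unit count to the bin containing
#'     its value; the oracle-checkable reference.}
#'   \item{`soft`}{Parzen-style Gaussian kernel weights on the bin centres,
#'     normalized per pixel so every pixel still contributes total mass 1;
#'     this is differentiable with respect to the images, which is what
#'     lets histogram losses drive a generator.}
#' }
#'
#' @param a,b images (`image_slice` or numeric matrix) with values in
#'   `[0, 1]`, same shape.
#' @param third optional third image for the triple histogram.
#' @param bins number of intensity bins B (>= 2).
#' @param mode `"hard"` or `"soft"`.
#' @param kernel_width Gaussian kernel width for soft mode, on the [0, 1]
#'   intensity scale; defaults to the bin width `1/bins`.
#' @return An object of class `"joint_histogram"` with fields `counts`
#'   (B x B or B x B x B), `breaks`, `mode`, `kernel_width`, `n` (pixels).
#' @export
joint_histogram <- function(a, b, third = NULL, bins = 32L,
                            mode = c("hard", "soft"), kernel_width = NULL) {
  mode <- match.arg(mode)
  va <- hist_values(a, "a"); vb <- hist_values(b, "b")
  if (length(va) != length(vb))
    stop("joint_histogram: images differ in shape")
  vc <- NULL
  if (!is.null(third)) {
    vc <- hist_values(third, "third")
    if (length(vc) != length(va))
      stop("joint_histogram: images differ in shape")
  }
  bins <- as.integer(bins)
  if (bins < 2L) stop("joint_histogram: bins must be at least 2")
  if (is.null(kernel_width)) kernel_width <- 1 / bins
  n <- length(va)
  if (mode == "hard") {
    ia <- hard_bin(va, bins); ib <- hard_bin(vb, bins)
    if (is.null(vc)) {
      counts <- matrix(tabulate(ia + bins * (ib - 1L), nbins = bins^2),
                       bins, bins)
    } else {
      ic <- hard_bin(vc, bins)
      counts <- array(tabulate(ia + bins * (ib - 1L) + bins^2 * (ic - 1L),
                               nbins = bins^3), c(bins, bins, bins))
    }
  } else {
    Wa <- soft_bin_weights(va, bins, kernel_width)
    Wb <- soft_bin_weights(vb, bins, kernel_width)
    if (is.null(vc)) {
      counts <- crossprod(Wa, Wb)
    } else {
      Wc <- soft_bin_weights(vc, bins, kernel_width)
      Wbc <- khatri_rao_rows(Wb, Wc)             # n x B^2, (b, c) pairs
      counts <- array(crossprod(Wa, Wbc), c(bins, bins, bins))
    }
  }
  structure(list(counts = counts, breaks = seq(0, 1, length.out = bins + 1L),
                 bins = bins, mode = mode, kernel_width = kernel_width,
                 n = n),
            class = "joint_histogram")
}

#' @export
print.joint_histogram <- function(x, ...) {
  cat(sprintf("<joint_histogram> %s  %s bins, %s mode, %d pixels\n",
              paste(dim(x$counts), collapse = " x "), x$bins, x$mode, x$n))
  invisible(x)
}

hist_values <- function(img, what) {
  v <- if (is_image_slice(img)) img$pixels else img
  v <- as.vector(v)
  if (!is.numeric(v) || !all(is.finite(v)))
    stop(sprintf("joint_histogram: image '%s' must be finite numeric", what))
  if (min(v) < 0 || max(v) > 1)
    stop(sprintf("joint_histogram: image '%s' has values outside [0, 1]; normalize first", what))
  v
}

hard_bin <- function(v, bins) pmin(pmax(floor(v * bins) + 1L, 1L), bins)

# n x B Gaussian kernel weights on bin centres, rows normalized to sum 1.
# Rows whose kernel mass underflows (very narrow kernels) fall back to a
# one-hot at the nearest centre, the exact zero-width limit.
soft_bin_weights <- function(v, bins, width) {
  centers <- (seq_len(bins) - 0.5) / bins
  G <- exp(-0.5 * (outer(v, centers, "-") / width)^2)
  S <- rowSums(G)
  dead <- S == 0
  if (any(dead)) {
    nearest <- pmin(pmax(round(v[dead] * bins + 0.5), 1), bins)
    G[dead, ] <- 0
    G[cbind(which(dead), nearest)] <- 1
    S[dead] <- 1
  }
  G / S
}

# derivative of the row-normalized weights with respect to the pixel value:
# returns list(W, dW) where dW[p, k] = d W[p, k] / d v[p]
soft_bin_weights_grad <- function(v, bins, width) {
  centers <- (seq_len(bins) - 0.5) / bins
  D <- outer(v, centers, "-")
  G <- exp(-0.5 * (D / width)^2)
  Gp <- G * (-D / width^2)                      # d g_k / d v
  S <- rowSums(G); Sp <- rowSums(Gp)
  dead <- S == 0
  if (any(dead)) {                              # one-hot limit, flat gradient
    nearest <- pmin(pmax(round(v[dead] * bins + 0.5), 1), bins)
    G[dead, ] <- 0
    G[cbind(which(dead), nearest)] <- 1
    S[dead] <- 1
    Gp[dead, ] <- 0
    Sp[dead] <- 0
  }
  W <- G / S
  dW <- (Gp - W * Sp) / S
  list(W = W, dW = dW)
}

# row-wise Khatri-Rao product: out[, (j-1)*Bc + k] = A[, j] * B[, k]
khatri_rao_rows <- function(A, B) {
  Ba <- ncol(A); Bb <- ncol(B)
  A[, rep(seq_len(Ba), each = Bb), drop = FALSE] *
    B[, rep(seq_len(Bb), times = Ba), drop = FALSE]
}

#' Mutual information of a pairwise joint histogram, in nats
#'
#' `I = sum_ij p(i,j) log( p(i,j) / (p(i) p(j)) )` over the normalized
#' table; zero-probability cells contribute 0.
#'
#' @param h a pairwise [joint_histogram()].
#' @return Nonnegative scalar (nats).
#' @export
mutual_information <- function(h) {
  stopifnot(inherits(h, "joint_histogram"))
  C <- h$counts
  if (length(dim(C)) != 2L)
    stop("mutual_information: pairwise histogram required")
  s <- sum(C)
  if (s <= 0) stop("mutual_information: all-zero histogram")
  p <- C / s
  pa <- rowSums(p); pb <- colSums(p)
  pos <- p > 0
  sum(p[pos] * (log(p[pos]) - log(outer(pa, pb))[pos]))
}

marginal_entropy <- function(p) {
  pos <- p > 0
  -sum(p[pos] * log(p[pos]))
}

#' Normalized mutual information of two images
#'
#' `NMI = 2 I(a; b) / (H(a) + H(b))`, in `[0, 1]`.
#'
#' @inheritParams joint_histogram
#' @return Scalar in `[0, 1]`; 0 if either image has zero entropy.
#' @export
nmi <- function(a, b, bins = 32L, mode = c("hard", "soft"),
                kernel_width = NULL) {
  mode <- match.arg(mode)
  h <- joint_histogram(a, b, bins = bins, mode = mode,
                       kernel_width = kernel_width)
  p <- h$counts / sum(h$counts)
  ha <- marginal_entropy(rowSums(p)); hb <- marginal_entropy(colSums(p))
  if (ha + hb <= .Machine$double.eps) return(0)
  2 * mutual_information(h) / (ha + hb)
}

#' Mutual-information similarity loss, 1 - NMI
#'
#' The discriminator-side similarity penalty: one minus the normalized
#' mutual information between the registered image and a source image,
#' bounded in `[0, 1]` (0 for perfectly dependent intensities, ~1 for
#' independent images).  A constant (zero-entropy) image is a degenerate
#' input; the loss is then defined as 1 and flagged.
#'
#' @param registered,source images in `[0, 1]` on the same grid.
#' @inheritParams joint_histogram
#' @return Scalar in `[0, 1]`; attribute `"degenerate"` is `TRUE` when an
#'   input had zero entropy.
#' @export
mi_loss <- function(registered, source, bins = 32L,
                    mode = c("hard", "soft"), kernel_width = NULL) {
  mode <- match.arg(mode)
  h <- joint_histogram(registered, source, bins = bins, mode = mode,
                       kernel_width = kernel_width)
  p <- h$counts / sum(h$counts)
  ha <- marginal_entropy(rowSums(p)); hb <- marginal_entropy(colSums(p))
  if (ha <= 1e-12 || hb <= 1e-12)
    return(structure(1, degenerate = TRUE))
  loss <- 1 - 2 * mutual_information(h) / (ha + hb)
  min(max(loss, 0), 1)
}

# Soft-mode MI loss with analytic gradient with respect to the registered
# image.  Returns list(loss, grad) where grad has the image's shape.
# `Wb` optionally supplies the source's precomputed soft-bin weights (they
# are constant across a training run).
mi_loss_grad <- function(registered, source, bins = 32L, kernel_width = NULL,
                         Wb = NULL) {
  va <- hist_values(registered, "registered")
  if (is.null(kernel_width)) kernel_width <- 1 / bins
  n <- length(va)
  sg <- soft_bin_weights_grad(va, bins, kernel_width)
  if (is.null(Wb)) {
    vb <- hist_values(source, "source")
    Wb <- soft_bin_weights(vb, bins, kernel_width)
  }
  C <- crossprod(sg$W, Wb)                       # B x B, sums to n
  p <- C / n
  pa <- rowSums(p); pb <- colSums(p)
  eps <- 1e-12
  lp <- log(pmax(p, eps)); la <- log(pmax(pa, eps)); lb <- log(pmax(pb, eps))
  I <- sum(p * (lp - outer(la, lb, "+")))
  Ha <- -sum(pa * la); Hb <- -sum(pb * lb)
  if (Ha + Hb <= 1e-12) {
    g <- matrix(0, nrow(as_mat(registered)), ncol(as_mat(registered)))
    return(list(loss = 1, grad = g))
  }
  nmi_val <- 2 * I / (Ha + Hb)
  # gradients with respect to counts; the total count is fixed at n because
  # each pixel's soft weights sum to 1, so p = C/n with constant n
  dI_dC <- (lp - outer(la, lb, "+") - 1) / n
  dHa_dC <- -outer(la + 1, rep(1 / n, length(lb)), "*")
  dHb_dC <- -outer(rep(1 / n, length(la)), lb + 1, "*")
  dNMI_dC <- (2 * dI_dC * (Ha + Hb) - 2 * I * (dHa_dC + dHb_dC)) / (Ha + Hb)^2
  dL_dC <- -dNMI_dC
  dL_dWa <- Wb %*% t(dL_dC)                      # n x B
  gvec <- rowSums(dL_dWa * sg$dW)
  m <- as_mat(registered)
  list(loss = min(max(1 - nmi_val, 0), 1),
       grad = matrix(gvec, nrow(m), ncol(m)))
}

as_mat <- function(img) if (is_image_slice(img)) img$pixels else as.matrix(img)

# soft-mode 1 - NMI against a precomputed source weight matrix (training
# fast path for the logged MR-side component)
mi_loss_soft_w <- function(registered, Wb, bins, kernel_width) {
  va <- hist_values(registered, "registered")
  Wa <- soft_bin_weights(va, bins, kernel_width)
  C <- crossprod(Wa, Wb)
  p <- C / sum(C)
  ha <- marginal_entropy(rowSums(p)); hb <- marginal_entropy(colSums(p))
  if (ha <= 1e-12 || hb <= 1e-12) return(structure(1, degenerate = TRUE))
  h <- structure(list(counts = C), class = "joint_histogram")
  min(max(1 - 2 * mutual_information(h) / (ha + hb), 0), 1)
}

#' Bayesian posterior loss of a registered image given its sources
#'
#' Builds the triple joint histogram over the intensity bins of
#' (registered, MR, US) and scores each pixel by the posterior probability
#' of its registered-image bin given its (MR, US) bin pair,
#' `q(r | m, u) = p(r, m, u) / p(m, u)` — the Bayes identity
#' `p(m, u | r) p(r) / p(m, u)` evaluated in count space.  The loss is one
#' minus the mean posterior over pixels, in `[0, 1]`: it is 0 exactly when
#' the registered intensity bin is a deterministic function of the source
#' bins, and approaches `1 - 1/B` when it is independent of them.
#'
#' @param registered,mr,us images in `[0, 1]` on the same grid.
#' @inheritParams joint_histogram
#' @return Scalar in `[0, 1]`.
#' @export
bayes_loss <- function(registered, mr, us, bins = 16L,
                       mode = c("hard", "soft"), kernel_width = NULL) {
  mode <- match.arg(mode)
  h <- joint_histogram(registered, mr, third = us, bins = bins, mode = mode,
                       kernel_width = kernel_width)
  C <- h$counts
  Cmu <- apply(C, c(2, 3), sum)                  # counts of (m, u) pairs
  pos <- Cmu > 0
  # mean posterior = (1/N) sum_{r,m,u} C^2 / Cmu ; empty (m,u) cells hold no
  # pixels (their C is identically 0) so dividing by 1 there excludes them
  sc <- sweep(C^2, c(2, 3), ifelse(pos, Cmu, 1), "/")
  score <- sum(sc) / h$n
  min(max(1 - score, 0), 1)
}

# Soft-mode Bayes loss with analytic gradient wrt the registered image.
# `Wmu` optionally supplies the precomputed row-wise Khatri-Rao product of
# the source weights (constant across a training run).
bayes_loss_grad <- function(registered, mr, us, bins = 16L,
                            kernel_width = NULL, Wmu = NULL) {
  vr <- hist_values(registered, "registered")
  if (is.null(kernel_width)) kernel_width <- 1 / bins
  n <- length(vr)
  sg <- soft_bin_weights_grad(vr, bins, kernel_width)
  if (is.null(Wmu)) {
    vm <- hist_values(mr, "mr"); vu <- hist_values(us, "us")
    Wm <- soft_bin_weights(vm, bins, kernel_width)
    Wu <- soft_bin_weights(vu, bins, kernel_width)
    Wmu <- khatri_rao_rows(Wm, Wu)               # n x B^2
  }
  C <- crossprod(sg$W, Wmu)                      # B x B^2
  Cmu <- colSums(C)                              # independent of registered
  pos <- Cmu > 0
  Cs <- sweep(C, 2, ifelse(pos, Cmu, 1), "/")
  score <- sum(C * Cs) / n
  # d score / d C[r, mu] = 2 C / (n Cmu)
  T2 <- 2 * Cs / n
  dL_dWr <- -(Wmu %*% t(T2))                     # n x B
  gvec <- rowSums(dL_dWr * sg$dW)
  m <- as_mat(registered)
  list(loss = min(max(1 - score, 0), 1),
       grad = matrix(gvec, nrow(m), ncol(m)))
}
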