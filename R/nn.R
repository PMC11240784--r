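# Minimal convolutional-network engine with manual backpropagation.
#
# Feature maps are 4D arrays (H, W, N, C) — channels last, so that the
# (pixel, sample) x channel matrix views needed by the convolutions and by
# batch normalization are plain dim<- reshapes without copying.
# Convolutions are realized as im2col gathers followed by BLAS matrix
# products; transposed convolutions are the exact adjoint of a stride-2
# convolution, so up-sampling doubles the grid.  Every layer implements an
# analytic backward pass; the pairs are verified against numerical
# derivatives in the test suite.

.conv_cache <- new.env(parent = emptyenv())

# Batch-expanded im2col index for a padded (Hp, Wp, N, C) input and a
# k x k stride-s kernel.  Rows are (output position, sample) with position
# fastest; columns are (channel, kernel offset) with channel fastest, so
# the columns belonging to one kernel offset are contiguous (cheap to
# slice during the scatter pass).
conv_index_full <- function(Hp, Wp, C, N, k, stride) {
  key <- paste(Hp, Wp, C, N, k, stride, sep = "_")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  kk <- k * k
  nr <- Ho * Wo
  M0 <- matrix(0L, nr, kk)
  t <- 0L
  for (kj in seq_len(k)) for (ki in seq_len(k)) {
    t <- t + 1L
    ihs <- (seq_len(Ho) - 1L) * stride + ki
    iws <- (seq_len(Wo) - 1L) * stride + kj
    M0[, t] <- rep(ihs, times = Wo) + Hp * rep(iws - 1L, each = Ho)
  }
  base <- M0[rep(seq_len(nr), times = N), , drop = FALSE] +
    rep(Hp * Wp * (seq_len(N) - 1L), each = nr)       # (nr*N, kk)
  idx3 <- matrix(0L, nr * N, C * kk)
  for (t in seq_len(kk))
    idx3[, (t - 1L) * C + seq_len(C)] <-
      base[, rep(t, C), drop = FALSE] +
      rep(Hp * Wp * N * (seq_len(C) - 1L), each = nr * N)
  storage.mode(idx3) <- "integer"
  out <- list(idx3 = idx3, Ho = Ho, Wo = Wo, nr = nr)
  # the cache is keyed by shape and batch size; across many configurations
  # it can grow large, so evict everything when it passes ~120 MB and let
  # the needed tables rebuild on demand
  cells <- sum(unlist(eapply(.conv_cache, function(e)
    if (is.list(e) && !is.null(e$idx3)) length(e$idx3) else 0)))
  if (cells + length(idx3) > 3e7)
    rm(list = ls(.conv_cache), envir = .conv_cache)
  assign(key, out, envir = .conv_cache)
  out
}

pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

n_of <- function(x) dim(x)[3]
c_of <- function(x) dim(x)[4]

unpad_hw <- function(x, p, H, W) {
  if (p == 0L) return(x)
  x[p + seq_len(H), p + seq_len(W), , , drop = FALSE]
}

# gather padded input into the im2col matrix (Ho*Wo*N, kk*C)
conv_gather <- function(xp, ci) {
  X <- xp[ci$idx3]
  dim(X) <- dim(ci$idx3)
  X
}

# adjoint of conv_gather: scatter-add the columns matrix back onto the
# padded (Hp, Wp, N, C) grid.  Within one kernel offset all target indices
# are distinct across positions, channels and samples, so k*k vectorized
# accumulations suffice.
conv_scatter <- function(dX, ci, Hp, Wp, k, C, N) {
  kk <- k * k
  dP <- numeric(Hp * Wp * N * C)
  for (t in seq_len(kk)) {
    cols_t <- (t - 1L) * C + seq_len(C)
    ii <- ci$idx3[, cols_t]
    dP[ii] <- dP[ii] + dX[, cols_t]
  }
  array(dP, c(Hp, Wp, N, C))
}

he_init <- function(n, fan_in) stats::rnorm(n, sd = sqrt(2 / fan_in))

layer_conv <- function(cin, cout, k = 3L, stride = 2L, pad = 1L,
                       zero_init = FALSE) {
  kk <- k * k
  W <- if (zero_init) matrix(0, kk * cin, cout)
       else matrix(he_init(kk * cin * cout, kk * cin), kk * cin, cout)
  list(type = "conv", k = k, stride = stride, pad = pad,
       cin = cin, cout = cout, W = W, b = numeric(cout))
}

layer_tconv <- function(cin, cout, k = 3L, pad = 1L) {
  kk <- k * k
  # weights of the underlying (big -> small) convolution: (kk*cout, cin)
  W <- matrix(he_init(kk * cout * cin, kk * cout), kk * cout, cin)
  list(type = "tconv", k = k, stride = 2L, pad = pad,
       cin = cin, cout = cout, W = W, b = numeric(cout))
}

layer_bn <- function(c) {
  list(type = "bn", c = c, gamma = rep(1, c), beta = numeric(c),
       running_mean = numeric(c), running_var = rep(1, c),
       eps = 1e-5, momentum = 0.1)
}

layer_relu <- function() list(type = "relu")

layer_scale_tanh <- function(scale) list(type = "scale_tanh", scale = scale)

# fixed separable Gaussian smoothing with edge normalization: the raw
# zero-padded convolution B is divided pointwise by B applied to a map of
# ones, so constant fields stay constant up to the border.  The operator is
# x -> B(x)/m with symmetric B, whose adjoint is y -> B(y/m); the backward
# pass uses exactly that.
layer_blur <- function(sigma) {
  r <- max(1L, ceiling(2.5 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  list(type = "blur", k = k / sum(k), r = r)
}

# row-normalized 1D smoothing band matrix (n x n); the zero-padded
# separable blur's edge normalization factorizes exactly into one such
# matrix per image dimension
blur_band <- function(k, r, n) {
  K <- matrix(0, n, n)
  for (o in -r:r) {
    w <- k[o + r + 1L]
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    K[cbind(which(ok), src[ok])] <- w
  }
  K / rowSums(K)
}

blur_mats <- function(layer, H, W) {
  key <- paste("blurm", layer$r, H, W, sep = "_")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- list(Kh = blur_band(layer$k, layer$r, H),
              Kw = blur_band(layer$k, layer$r, W))
  assign(key, out, envir = .conv_cache)
  out
}

# Y = Kh X Kw' per (sample, channel) slice; transpose = TRUE applies the
# adjoint Kh' X Kw instead (the backward pass)
blur_apply_mats <- function(x, Km, transpose = FALSE) {
  d <- dim(x)
  out <- array(0, d)
  Kh <- if (transpose) t(Km$Kh) else Km$Kh
  Kw <- if (transpose) Km$Kw else t(Km$Kw)
  for (n in seq_len(d[3])) for (c in seq_len(d[4]))
    out[, , n, c] <- Kh %*% x[, , n, c] %*% Kw
  out
}

layer_sigmoid <- function() list(type = "sigmoid")

layer_dense_prob <- function(in_features, eps = 1e-6) {
  list(type = "dense_prob", f = in_features,
       W = matrix(he_init(in_features, in_features), in_features, 1),
       b = 0, eps = eps)
}

layer_params <- function(layer) {
  switch(layer$type,
         conv = , tconv = c("W", "b"),
         bn = c("gamma", "beta"),
         dense_prob = c("W", "b"),
         character(0))
}

layer_forward <- function(layer, x, train = TRUE, update_stats = train) {
  switch(layer$type,
    conv = {
      xp <- pad_hw(x, layer$pad)
      d <- dim(xp)                               # (Hp, Wp, N, C)
      ci <- conv_index_full(d[1], d[2], d[4], d[3], layer$k, layer$stride)
      X <- conv_gather(xp, ci)
      Z <- X %*% layer$W
      Z <- Z + rep(layer$b, each = nrow(Z))
      out <- array(Z, c(ci$Ho, ci$Wo, d[3], layer$cout))
      list(out = out, cache = list(X = X, din = dim(x), dpad = d, ci = ci),
           layer = layer)
    },
    tconv = {
      d <- dim(x)                                # (H, W, N, cin)
      H <- d[1]; W <- d[2]; N <- d[3]
      xMat <- x
      dim(xMat) <- c(H * W * N, layer$cin)
      cols <- tcrossprod(xMat, layer$W)          # (HWN, cout*kk)
      Hb <- 2L * H; Wb <- 2L * W
      Hp <- Hb + 2L * layer$pad; Wp <- Wb + 2L * layer$pad
      ci <- conv_index_full(Hp, Wp, layer$cout, N, layer$k, layer$stride)
      stopifnot(ci$Ho == H, ci$Wo == W)
      dP <- conv_scatter(cols, ci, Hp, Wp, layer$k, layer$cout, N)
      out <- unpad_hw(dP, layer$pad, Hb, Wb)
      out <- out + rep(layer$b, each = Hb * Wb * N)
      list(out = out, cache = list(xMat = xMat, din = d, ci = ci,
                                   Hp = Hp, Wp = Wp),
           layer = layer)
    },
    bn = {
      d <- dim(x)
      C <- d[4]; M <- d[1] * d[2] * d[3]
      xm <- x
      dim(xm) <- c(M, C)
      if (train) {
        mu <- colMeans(xm)
        va <- colMeans(xm^2) - mu^2
        va <- pmax(va, 0)
        if (update_stats) {
          layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
            layer$momentum * mu
          layer$running_var <- (1 - layer$momentum) * layer$running_var +
            layer$momentum * va
        }
      } else {
        mu <- layer$running_mean
        va <- layer$running_var
      }
      invstd <- 1 / sqrt(va + layer$eps)
      xhat <- (xm - rep(mu, each = M)) * rep(invstd, each = M)
      om <- xhat * rep(layer$gamma, each = M) + rep(layer$beta, each = M)
      out <- array(om, d)
      list(out = out, cache = list(xhat = xhat, invstd = invstd, d = d,
                                   train = train),
           layer = layer)
    },
    relu = list(out = pmax(x, 0), cache = list(mask = x > 0), layer = layer),
    blur = {
      d <- dim(x)
      Km <- blur_mats(layer, d[1], d[2])
      list(out = blur_apply_mats(x, Km), cache = list(Km = Km),
           layer = layer)
    },
    scale_tanh = {
      th <- tanh(x)
      list(out = layer$scale * th, cache = list(th = th), layer = layer)
    },
    sigmoid = {
      s <- 1 / (1 + exp(-x))
      list(out = s, cache = list(s = s), layer = layer)
    },
    dense_prob = {
      d <- dim(x)                                # (H, W, N, C)
      N <- d[3]
      xm <- aperm(x, c(1, 2, 4, 3))              # features contiguous per n
      dim(xm) <- c(layer$f, N)
      z <- as.vector(crossprod(xm, layer$W)) + layer$b
      tt <- tanh(z)
      p <- (tt + 1) / 2
      pc <- pmin(pmax(p, layer$eps), 1 - layer$eps)
      list(out = pc,
           cache = list(xm = xm, t = tt, din = d,
                        mask = p > layer$eps & p < 1 - layer$eps),
           layer = layer)
    },
    stop("unknown layer type"))
}

layer_backward <- function(layer, cache, dout, want_grads = TRUE) {
  switch(layer$type,
    conv = {
      d <- dim(dout)                             # (Ho, Wo, N, cout)
      N <- d[3]
      dmat <- dout
      dim(dmat) <- c(d[1] * d[2] * N, layer$cout)
      if (want_grads) {
        dW <- crossprod(cache$X, dmat)
        db <- colSums(dmat)
      } else dW <- db <- NULL
      dXmat <- tcrossprod(dmat, layer$W)
      dP <- conv_scatter(dXmat, cache$ci, cache$dpad[1], cache$dpad[2],
                         layer$k, layer$cin, N)
      dx <- unpad_hw(dP, layer$pad, cache$din[1], cache$din[2])
      list(dx = dx, grads = list(W = dW, b = db))
    },
    tconv = {
      d <- dim(dout)                             # (2H, 2W, N, cout)
      N <- d[3]
      db_mat <- dout
      dim(db_mat) <- c(d[1] * d[2] * N, layer$cout)
      db <- colSums(db_mat)
      dop <- pad_hw(dout, layer$pad)
      Xd <- conv_gather(dop, cache$ci)           # (HWN, cout*kk)
      dxMat <- Xd %*% layer$W                    # (HWN, cin)
      H <- cache$din[1]; W <- cache$din[2]
      dx <- array(dxMat, c(H, W, N, layer$cin))
      dW <- crossprod(Xd, cache$xMat)
      list(dx = dx, grads = list(W = dW, b = db))
    },
    bn = {
      d <- cache$d
      C <- d[4]; M <- d[1] * d[2] * d[3]
      dmat <- dout
      dim(dmat) <- c(M, C)
      dgamma <- colSums(dmat * cache$xhat)
      dbeta <- colSums(dmat)
      dxhat <- dmat * rep(layer$gamma, each = M)
      if (cache$train) {
        s1 <- colSums(dxhat)
        s2 <- colSums(dxhat * cache$xhat)
        dxm <- (dxhat - rep(s1 / M, each = M) -
                  cache$xhat * rep(s2 / M, each = M)) *
          rep(cache$invstd, each = M)
      } else {
        dxm <- dxhat * rep(cache$invstd, each = M)
      }
      dx <- array(dxm, d)
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dx = dout * cache$mask, grads = NULL),
    blur = list(dx = blur_apply_mats(dout, cache$Km, transpose = TRUE),
                grads = NULL),
    scale_tanh = list(dx = dout * layer$scale * (1 - cache$th^2),
                      grads = NULL),
    sigmoid = list(dx = dout * cache$s * (1 - cache$s), grads = NULL),
    dense_prob = {
      dz <- dout * 0.5 * cache$mask * (1 - cache$t^2)
      dW <- cache$xm %*% matrix(dz, ncol = 1)
      db <- sum(dz)
      dxm <- layer$W %*% matrix(dz, nrow = 1)    # (F, N)
      di <- cache$din
      dx <- aperm(array(dxm, c(di[1], di[2], di[4], di[3])), c(1, 2, 4, 3))
      list(dx = dx, grads = list(W = dW, b = db))
    },
    stop("unknown layer type"))
}

# --- network container ----------------------------------------------------

# deep copy of a network environment (layers/opt are plain lists, so a new
# environment with the same fields is an independent copy)
clone_network <- function(net) {
  out <- make_network(net$layers, net$name)
  out$cfg <- net$cfg
  out$step <- net$step
  out$opt <- net$opt
  out
}

make_network <- function(layers, name) {
  net <- new.env(parent = emptyenv())
  net$layers <- layers
  net$name <- name
  net$step <- 0L
  net$opt <- NULL
  class(net) <- "ganreg_net"
  net
}

#' @export
print.ganreg_net <- function(x, ...) {
  cat(sprintf("<network '%s'> %d layers, %d parameters\n",
              x$name, length(x$layers), n_parameters(x)))
  invisible(x)
}

forward_network <- function(net, x, train = TRUE, update_stats = train) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    st <- layer_forward(net$layers[[i]], x, train = train,
                        update_stats = update_stats)
    net$layers[[i]] <- st$layer                  # BN running stats
    caches[[i]] <- st$cache
    x <- st$out
  }
  list(out = x, caches = caches)
}

backward_network <- function(net, caches, dout, want_grads = TRUE) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    bk <- layer_backward(net$layers[[i]], caches[[i]], dout,
                         want_grads = want_grads)
    grads[i] <- list(bk$grads)      # [[<-]] with NULL would drop the slot
    dout <- bk$dx
  }
  list(dx = dout, grads = grads)
}

#' Number of trainable parameters of a network
#' @param net an internal network object.
#' @return Integer count.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$layers, function(l) {
    sum(vapply(layer_params(l), function(p) length(l[[p]]), numeric(1)))
  }, numeric(1)))
}

net_parameters <- function(net) {
  lapply(net$layers, function(l) {
    ps <- layer_params(l)
    if (!length(ps)) return(NULL)
    stats::setNames(lapply(ps, function(p) l[[p]]), ps)
  })
}

# Adam with bias correction; one optimizer state per network
adam_step <- function(net, grads, lr, betas = c(0.5, 0.999), eps = 1e-8) {
  if (is.null(net$opt)) {
    net$opt <- lapply(net$layers, function(l) {
      ps <- layer_params(l)
      stats::setNames(lapply(ps, function(p)
        list(m = l[[p]] * 0, v = l[[p]] * 0)), ps)
    })
  }
  net$step <- net$step + 1L
  b1 <- betas[1]; b2 <- betas[2]
  bc1 <- 1 - b1^net$step
  bc2 <- 1 - b2^net$step
  for (i in seq_along(net$layers)) {
    gi <- grads[[i]]
    if (is.null(gi)) next
    for (p in names(gi)) {
      st <- net$opt[[i]][[p]]
      st$m <- b1 * st$m + (1 - b1) * gi[[p]]
      st$v <- b2 * st$v + (1 - b2) * gi[[p]]^2
      net$opt[[i]][[p]] <- st
      net$layers[[i]][[p]] <- net$layers[[i]][[p]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    }
  }
  invisible(net)
}
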