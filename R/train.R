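#' Training configuration
#'
#' Collects every hyperparameter of the adversarial registration training
#' schedule.  The defaults follow the published schedule for the full-scale
#' experiment: 200 epochs, Adam at learning rate 1e-5 multiplied by 0.85
#' after every epoch, batch size 24, and equal unit weights on the Bayesian
#' and mutual-information terms.
#'
#' @param epochs number of passes over the training pairs.
#' @param lr0 initial learning rate.
#' @param lr_decay per-epoch multiplicative decay (0.85 means the rate is
#'   multiplied by 0.85 after each epoch).
#' @param batch_size images per optimization step.
#' @param lambda_b weight of the Bayesian posterior loss in the generator
#'   objective.
#' @param lambda_mi weight of the mutual-information loss in the
#'   discriminator objectives.
#' @param bins_pair,bins_triple histogram bin counts for the pairwise (MI)
#'   and triple (Bayes) histograms.
#' @param kernel_width soft-binning kernel width; default one bin width.
#' @param seed RNG seed controlling initialization and data order; equal
#'   seeds and configuration give bit-identical runs on one platform.
#' @param betas Adam momentum parameters.
#' @param mode generator output mode, `"field"` or `"image"`.
#' @param d_steps discriminator updates per generator update.
#' @param nonsaturating use the non-saturating generator loss.
#' @param mi_to_generator also feed the mutual-information loss gradients to
#'   the generator.  The MI terms depend only on the images, so in the
#'   discriminator objectives they act as reported regularizers without a
#'   parameter gradient; enabling this flag routes their image gradient into
#'   the generator update, which is what makes them drive alignment.
#' @param max_disp field-mode maximum displacement, mm.
#' @param field_smooth standard deviation (pixels) of a fixed Gaussian
#'   smoothing stage inside the field head, a smooth-transform
#'   parameterization in the spirit of spline-based free-form deformations;
#'   0 (default) disables it.
#' @param conditional two-channel discriminators (candidate plus the
#'   other-modality source) instead of the single-channel default.
#' @param enc_channels,dec_channels,disc_channels network widths.
#' @param verbose print one line per epoch.
#' @return An object of class `"ganreg_control"`.
#' @export
ganreg_control <- function(epochs = 200L, lr0 = 1e-5, lr_decay = 0.85,
                           batch_size = 24L, lambda_b = 1, lambda_mi = 1,
                           bins_pair = 32L, bins_triple = 16L,
                           kernel_width = NULL, seed = 1L,
                           betas = c(0.5, 0.999),
                           mode = c("field", "image"), d_steps = 1L,
                           nonsaturating = FALSE, mi_to_generator = FALSE,
                           max_disp = 10, field_smooth = 0,
                           conditional = FALSE,
                           enc_channels = c(16L, 32L, 64L, 128L, 256L),
                           dec_channels = c(128L, 64L, 32L, 16L, 16L),
                           disc_channels = c(16L, 32L, 64L, 128L),
                           verbose = FALSE) {
  mode <- match.arg(mode)
  if (epochs < 1L) stop("ganreg_control: epochs must be >= 1")
  if (batch_size < 1L) stop("ganreg_control: batch_size must be >= 1")
  if (lr0 <= 0) stop("ganreg_control: lr0 must be positive")
  if (lr_decay <= 0 || lr_decay > 1)
    stop("ganreg_control: lr_decay must be in (0, 1]")
  if (lambda_b < 0 || lambda_mi < 0)
    stop("ganreg_control: loss weights must be nonnegative")
  if (d_steps < 1L) stop("ganreg_control: d_steps must be >= 1")
  structure(list(epochs = as.integer(epochs), lr0 = lr0,
                 lr_decay = lr_decay, batch_size = as.integer(batch_size),
                 lambda_b = lambda_b, lambda_mi = lambda_mi,
                 bins_pair = as.integer(bins_pair),
                 bins_triple = as.integer(bins_triple),
                 kernel_width = kernel_width, seed = as.integer(seed),
                 betas = betas, mode = mode, d_steps = as.integer(d_steps),
                 nonsaturating = nonsaturating,
                 mi_to_generator = mi_to_generator, max_disp = max_disp,
                 field_smooth = field_smooth, conditional = conditional,
                 enc_channels = enc_channels, dec_channels = dec_channels,
                 disc_channels = disc_channels, verbose = verbose),
            class = "ganreg_control")
}

#' Learning-rate schedule
#'
#' Exponential decay: `lr = lr0 * lr_decay^epoch` with `epoch` counted from
#' 0, i.e. the rate is multiplied by `lr_decay` after each epoch.
#'
#' @param epoch 0-based epoch index.
#' @param control a [ganreg_control()].
#' @return The learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, control) {
  stopifnot(epoch >= 0)
  control$lr0 * control$lr_decay^epoch
}

#' Fit the adversarial registration model
#'
#' Trains the generator and the two discriminators on a set of co-gridded
#' ultrasound/MR slice pairs.  Per batch the update order is: discriminator
#' D1 (real = ultrasound, fake = the current registered output, detached),
#' discriminator D2 (real = MR), then the generator on its adversarial loss
#' plus the weighted Bayesian posterior loss (and, optionally, the
#' mutual-information gradients).  All randomness (initialization, batch
#' order) is governed by `control$seed`.
#'
#' @param pairs list of [slice_pair()] objects, all the same shape with
#'   sides multiples of 32, intensities in `[0, 1]`
#'   (see [normalize_intensity()]).
#' @param control a [ganreg_control()].
#' @param validation optional list of held-out pairs evaluated after every
#'   epoch.
#' @param init optional fitted `"ganreg"` model to resume from: its
#'   networks and optimizer state continue training for `control$epochs`
#'   further epochs and the history is appended (epoch numbering and the
#'   learning-rate schedule continue from the stored count).
#' @return An object of class `"ganreg"`: the trained networks, the control
#'   used, and a per-epoch `history` data frame with the loss components,
#'   learning rate and wall time.
#' @seealso [predict.ganreg()], [validate_pairs()], [register_pair()]
#' @export
ganreg <- function(pairs, control = ganreg_control(), validation = NULL,
                   init = NULL) {
  stopifnot(inherits(control, "ganreg_control"))
  st <- stack_pairs(pairs)
  h <- st$h; w <- st$w; n <- st$n
  check_generator_input(h, w)
  set.seed(control$seed)
  epoch0 <- 0L
  if (!is.null(init)) {
    stopifnot(inherits(init, "ganreg"))
    if (!identical(init$dims, c(h, w)))
      stop("ganreg: the resumed model was trained on a different grid size")
    gen <- clone_network(init$generator)
    d1 <- clone_network(init$d1)
    d2 <- clone_network(init$d2)
    epoch0 <- if (is.null(init$history)) 0L else max(init$history$epoch)
  } else {
    gen <- build_generator(generator_config(
      mode = control$mode, enc_channels = control$enc_channels,
      dec_channels = control$dec_channels, max_disp = control$max_disp,
      field_smooth = control$field_smooth))
    d_in <- if (control$conditional) 2L else 1L
    d1 <- build_discriminator(discriminator_config(
      in_channels = d_in, conv_channels = control$disc_channels,
      input_size = c(h, w)))
    d2 <- build_discriminator(discriminator_config(
      in_channels = d_in, conv_channels = control$disc_channels,
      input_size = c(h, w)))
  }
  model <- structure(list(generator = gen, d1 = d1, d2 = d2,
                          control = control, dims = c(h, w), n_pairs = n,
                          spacing = st$spacing, history = NULL),
                     class = "ganreg")
  kwp <- control$kernel_width %||% (1 / control$bins_pair)
  kwt <- control$kernel_width %||% (1 / control$bins_triple)
  precomp <- lapply(seq_len(n), function(i) {
    vf <- as.vector(st$fixed[, , i, 1])
    vm <- as.vector(st$moving[, , i, 1])
    list(Wf = soft_bin_weights(vf, control$bins_pair, kwp),
         Wm = soft_bin_weights(vm, control$bins_pair, kwp),
         Wmu = khatri_rao_rows(soft_bin_weights(vm, control$bins_triple, kwt),
                               soft_bin_weights(vf, control$bins_triple, kwt)))
  })
  hist_rows <- vector("list", control$epochs)
  for (epoch in epoch0 + seq_len(control$epochs)) {
    lr <- lr_schedule(epoch - 1L, control)
    t0 <- proc.time()[3]
    order <- sample.int(n)
    comp_sums <- NULL; n_batches <- 0L
    for (start in seq(1L, n, by = control$batch_size)) {
      idx <- order[start:min(start + control$batch_size - 1L, n)]
      comps <- ganreg_train_step(gen, d1, d2,
                                 st$fixed[, , idx, , drop = FALSE],
                                 st$moving[, , idx, , drop = FALSE],
                                 lr, control, st$spacing, st$origin,
                                 precomp[idx])
      bad <- names(comps)[!is.finite(unlist(comps))]
      if (length(bad))
        stop(sprintf("ganreg: training diverged at epoch %d (non-finite %s)",
                     epoch, paste(bad, collapse = ", ")))
      comp_sums <- if (is.null(comp_sums)) comps
                   else Map(`+`, comp_sums, comps)
      n_batches <- n_batches + 1L
    }
    means <- lapply(comp_sums, function(v) v / n_batches)
    row <- data.frame(epoch = epoch, lr = lr,
                      l_g = means$l_g, l_d1 = means$l_d1, l_d2 = means$l_d2,
                      l_b = means$l_b, l_mi_d1 = means$l_mi_d1,
                      l_mi_d2 = means$l_mi_d2,
                      l_g_total = means$l_g_total,
                      l_d1_total = means$l_d1_total,
                      l_d2_total = means$l_d2_total,
                      seconds = proc.time()[3] - t0)
    if (!is.null(validation)) {
      vr <- validate_pairs(validation, model)
      row$val_l_g <- vr$l_g; row$val_l_d1 <- vr$l_d1; row$val_l_d2 <- vr$l_d2
    }
    hist_rows[[epoch - epoch0]] <- row
    if (control$verbose)
      message(sprintf("epoch %3d  lr %.3g  L_G %.4f  L_D1 %.4f  L_D2 %.4f  L_B %.4f",
                      epoch, lr, means$l_g, means$l_d1, means$l_d2, means$l_b))
  }
  model$history <- do.call(rbind, c(if (!is.null(init)) list(init$history),
                                    hist_rows))
  rownames(model$history) <- NULL
  model$rng_state <- .Random.seed
  model
}

stack_pairs <- function(pairs) {
  if (!is.list(pairs) || length(pairs) < 1L ||
      !all(vapply(pairs, inherits, logical(1), "slice_pair")))
    stop("ganreg: pairs must be a non-empty list of slice_pair objects")
  d <- dim(pairs[[1]]$fixed$pixels)
  for (p in pairs)
    if (!identical(dim(p$fixed$pixels), d))
      stop("ganreg: all pairs must share the same shape")
  n <- length(pairs)
  fixed <- array(0, c(d[1], d[2], n, 1L))       # channels-last
  moving <- array(0, c(d[1], d[2], n, 1L))
  for (i in seq_len(n)) {
    fixed[, , i, 1] <- pairs[[i]]$fixed$pixels
    moving[, , i, 1] <- pairs[[i]]$moving$pixels
  }
  if (min(fixed) < 0 || max(fixed) > 1 || min(moving) < 0 || max(moving) > 1)
    stop("ganreg: intensities must lie in [0, 1]; apply normalize_intensity first")
  list(fixed = fixed, moving = moving, h = d[1], w = d[2], n = n,
       spacing = pairs[[1]]$fixed$spacing, origin = pairs[[1]]$fixed$origin)
}

# one optimization step on one batch; mutates the three network
# environments and returns the named loss components
ganreg_train_step <- function(gen, d1, d2, xb_f, xb_m, lr, control,
                              spacing, origin, precomp = NULL) {
  h <- dim(xb_f)[1]; w <- dim(xb_f)[2]; nb <- dim(xb_f)[3]
  x <- array(0, c(h, w, nb, 2L))
  x[, , , 1] <- xb_f; x[, , , 2] <- xb_m
  gfw <- generator_forward(gen, x, train = TRUE)
  if (control$mode == "field") {
    fields <- vector("list", nb)
    reg <- array(0, c(h, w, nb, 1L))
    for (i in seq_len(nb)) {
      fields[[i]] <- displacement_field(array(gfw$out[, , i, ], c(h, w, 2)),
                                        spacing = spacing, origin = origin)
      reg[, , i, 1] <- apply_displacement(
        image_slice(matrix(xb_m[, , i, 1], h, w), spacing = spacing,
                    modality = "MR", origin = origin),
        fields[[i]])$pixels
    }
  } else {
    reg <- gfw$out
  }
  d_input <- function(cand, other) {
    if (!control$conditional) return(cand)
    out <- array(0, c(h, w, nb, 2L))
    out[, , , 1] <- cand; out[, , , 2] <- other
    out
  }
  # --- discriminator updates (generator output detached) ---
  upd_d <- function(dis, real_src, other_src) {
    l <- NA_real_
    for (s in seq_len(control$d_steps)) {
      fr <- discriminator_forward(dis, d_input(real_src, other_src),
                                  train = TRUE)
      ff <- discriminator_forward(dis, d_input(reg, other_src), train = TRUE)
      l <- adversarial_d_loss(fr$out, ff$out)
      dp_r <- -1 / (nb * fr$out)
      dp_f <- 1 / (nb * (1 - ff$out))
      gr <- backward_network(dis, fr$caches, dp_r)$grads
      gf <- backward_network(dis, ff$caches, dp_f)$grads
      adam_step(dis, add_grads(gr, gf), lr, control$betas)
    }
    l
  }
  l_d1 <- upd_d(d1, xb_f, xb_m)
  l_d2 <- upd_d(d2, xb_m, xb_f)
  # --- similarity components on the current registered batch ---
  l_mi_d1 <- 0; l_mi_d2 <- 0; l_b <- 0
  mi_grad <- if (control$mi_to_generator) array(0, c(h, w, nb, 1L)) else NULL
  bayes_grad <- array(0, c(h, w, nb, 1L))
  kwp <- control$kernel_width %||% (1 / control$bins_pair)
  for (i in seq_len(nb)) {
    ri <- matrix(reg[, , i, 1], h, w)
    fi <- matrix(xb_f[, , i, 1], h, w)
    mi <- matrix(xb_m[, , i, 1], h, w)
    pc <- if (is.null(precomp)) NULL else precomp[[i]]
    if (control$mi_to_generator) {
      # only the ultrasound-side similarity drives the generator: it is the
      # one term that couples the warped MR to the fixed image.  The
      # MR-side term compares the warped MR with its own source, so its
      # gradient points back to the identity warp (a rigidity anchor) and
      # is not routed; both values are still logged and enter the
      # discriminator totals.
      g1 <- mi_loss_grad(ri, fi, bins = control$bins_pair,
                         kernel_width = control$kernel_width,
                         Wb = pc$Wf)
      l_mi_d1 <- l_mi_d1 + g1$loss
      l_mi_d2 <- l_mi_d2 +
        if (is.null(pc)) mi_loss(ri, mi, bins = control$bins_pair,
                                 mode = "soft",
                                 kernel_width = control$kernel_width)
        else mi_loss_soft_w(ri, pc$Wm, control$bins_pair, kwp)
      mi_grad[, , i, 1] <- g1$grad / nb
    } else {
      l_mi_d1 <- l_mi_d1 +
        if (is.null(pc)) mi_loss(ri, fi, bins = control$bins_pair,
                                 mode = "soft",
                                 kernel_width = control$kernel_width)
        else mi_loss_soft_w(ri, pc$Wf, control$bins_pair, kwp)
      l_mi_d2 <- l_mi_d2 +
        if (is.null(pc)) mi_loss(ri, mi, bins = control$bins_pair,
                                 mode = "soft",
                                 kernel_width = control$kernel_width)
        else mi_loss_soft_w(ri, pc$Wm, control$bins_pair, kwp)
    }
    gb <- bayes_loss_grad(ri, mi, fi, bins = control$bins_triple,
                          kernel_width = control$kernel_width,
                          Wmu = pc$Wmu)
    l_b <- l_b + gb$loss
    bayes_grad[, , i, 1] <- gb$grad / nb
  }
  l_mi_d1 <- l_mi_d1 / nb; l_mi_d2 <- l_mi_d2 / nb; l_b <- l_b / nb
  # --- generator update ---
  f1 <- discriminator_forward(d1, d_input(reg, xb_m), train = TRUE,
                              update_stats = FALSE)
  f2 <- discriminator_forward(d2, d_input(reg, xb_f), train = TRUE,
                              update_stats = FALSE)
  l_g <- adversarial_g_loss(f1$out, f2$out,
                            nonsaturating = control$nonsaturating)
  dp1 <- if (control$nonsaturating) -1 / (nb * f1$out)
         else -1 / (nb * (1 - f1$out))
  dp2 <- if (control$nonsaturating) -1 / (nb * f2$out)
         else -1 / (nb * (1 - f2$out))
  dx1 <- backward_network(d1, f1$caches, dp1, want_grads = FALSE)$dx
  dx2 <- backward_network(d2, f2$caches, dp2, want_grads = FALSE)$dx
  dreg <- dx1[, , , 1, drop = FALSE] + dx2[, , , 1, drop = FALSE]
  dreg <- dreg + control$lambda_b * bayes_grad
  if (control$mi_to_generator)
    dreg <- dreg + control$lambda_mi * mi_grad
  if (control$mode == "field") {
    dU <- array(0, c(h, w, nb, 2L))
    for (i in seq_len(nb)) {
      wb <- warp_backward(
        image_slice(matrix(xb_m[, , i, 1], h, w), spacing = spacing,
                    modality = "MR", origin = origin),
        fields[[i]], matrix(dreg[, , i, 1], h, w))
      dU[, , i, ] <- wb$d_field
    }
    ggr <- backward_network(gen, gfw$caches, dU)$grads
  } else {
    ggr <- backward_network(gen, gfw$caches, dreg)$grads
  }
  adam_step(gen, ggr, lr, control$betas)
  tot <- total_losses(l_g, l_d1, l_d2, l_b, l_mi_d1, l_mi_d2,
                      control$lambda_b, control$lambda_mi)
  list(l_g = l_g, l_d1 = l_d1, l_d2 = l_d2, l_b = l_b,
       l_mi_d1 = l_mi_d1, l_mi_d2 = l_mi_d2,
       l_g_total = tot$g, l_d1_total = tot$d1, l_d2_total = tot$d2)
}

add_grads <- function(a, b) {
  Map(function(ga, gb) {
    if (is.null(ga)) return(NULL)
    Map(`+`, ga, gb)
  }, a, b)
}

#' Evaluate the losses on held-out pairs without updating parameters
#'
#' Runs the generator and both discriminators in evaluation mode (batch
#' norm uses running statistics) on a validation set and returns the loss
#' components.  Deterministic: repeated calls on the same weights give the
#' same record.
#'
#' @param pairs non-empty list of [slice_pair()] objects.
#' @param model a fitted [ganreg()] object.
#' @return Named list with `l_g`, `l_d1`, `l_d2`, `l_b`, `l_mi_d1`,
#'   `l_mi_d2`.
#' @export
validate_pairs <- function(pairs, model) {
  stopifnot(inherits(model, "ganreg"))
  if (!is.list(pairs) || length(pairs) < 1L)
    stop("validate_pairs: empty validation set")
  st <- stack_pairs(pairs)
  control <- model$control
  h <- st$h; w <- st$w; nb <- st$n
  x <- array(0, c(h, w, nb, 2L))
  x[, , , 1] <- st$fixed; x[, , , 2] <- st$moving
  gfw <- generator_forward(model$generator, x, train = FALSE)
  if (control$mode == "field") {
    reg <- array(0, c(h, w, nb, 1L))
    for (i in seq_len(nb)) {
      fld <- displacement_field(array(gfw$out[, , i, ], c(h, w, 2)),
                                spacing = st$spacing, origin = st$origin)
      reg[, , i, 1] <- apply_displacement(
        image_slice(matrix(st$moving[, , i, 1], h, w), spacing = st$spacing,
                    modality = "MR", origin = st$origin), fld)$pixels
    }
  } else {
    reg <- gfw$out
  }
  d_in <- function(cand, other) {
    if (!control$conditional) return(cand)
    out <- array(0, c(h, w, nb, 2L))
    out[, , , 1] <- cand; out[, , , 2] <- other
    out
  }
  p1r <- discriminator_forward(model$d1, d_in(st$fixed, st$moving),
                               train = FALSE)$out
  p1f <- discriminator_forward(model$d1, d_in(reg, st$moving),
                               train = FALSE)$out
  p2r <- discriminator_forward(model$d2, d_in(st$moving, st$fixed),
                               train = FALSE)$out
  p2f <- discriminator_forward(model$d2, d_in(reg, st$fixed),
                               train = FALSE)$out
  l_b <- 0; l1 <- 0; l2 <- 0
  for (i in seq_len(nb)) {
    ri <- matrix(reg[, , i, 1], h, w)
    fi <- matrix(st$fixed[, , i, 1], h, w)
    mi <- matrix(st$moving[, , i, 1], h, w)
    l1 <- l1 + mi_loss(ri, fi, bins = control$bins_pair, mode = "soft",
                       kernel_width = control$kernel_width)
    l2 <- l2 + mi_loss(ri, mi, bins = control$bins_pair, mode = "soft",
                       kernel_width = control$kernel_width)
    l_b <- l_b + bayes_loss(ri, mi, fi, bins = control$bins_triple,
                            mode = "soft",
                            kernel_width = control$kernel_width)
  }
  list(l_g = adversarial_g_loss(p1f, p2f,
                                nonsaturating = control$nonsaturating),
       l_d1 = adversarial_d_loss(p1r, p1f),
       l_d2 = adversarial_d_loss(p2r, p2f),
       l_b = l_b / nb, l_mi_d1 = l1 / nb, l_mi_d2 = l2 / nb)
}

# --- S3 methods of the fitted model ---------------------------------------

#' @export
print.ganreg <- function(x, ...) {
  cat(sprintf("Adversarial deformable registration model (%s mode)\n",
              x$control$mode))
  cat(sprintf("  trained on %d pairs of %d x %d px for %d epochs\n",
              x$n_pairs, x$dims[1], x$dims[2], nrow(x$history)))
  cat(sprintf("  generator: %d parameters; discriminators: %d + %d\n",
              n_parameters(x$generator), n_parameters(x$d1),
              n_parameters(x$d2)))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final losses: L_G %.4f  L_D1 %.4f  L_D2 %.4f  L_B %.4f\n",
              last$l_g, last$l_d1, last$l_d2, last$l_b))
  invisible(x)
}

#' @export
summary.ganreg <- function(object, ...) {
  print(object)
  cat("\nLoss trajectory (first / mid / last epoch):\n")
  hrows <- object$history[unique(c(1L, ceiling(nrow(object$history) / 2),
                                   nrow(object$history))), ]
  print(hrows[, c("epoch", "lr", "l_g", "l_d1", "l_d2", "l_b",
                  "l_mi_d1", "l_mi_d2")], row.names = FALSE)
  invisible(object)
}

#' Register slice pairs with a fitted model
#'
#' @param object a fitted [ganreg()] model.
#' @param pairs a [slice_pair()] or list of them.
#' @param ... unused.
#' @return For a single pair, a list with `registered` and `field`; for a
#'   list of pairs, a list of such results.
#' @export
predict.ganreg <- function(object, pairs, ...) {
  if (inherits(pairs, "slice_pair"))
    return(register_pair(object$generator, pairs))
  lapply(pairs, function(p) register_pair(object$generator, p))
}

#' Plot the training history of a fitted registration model
#'
#' @param x a fitted [ganreg()] model.
#' @param which columns of the history to draw.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ganreg <- function(x, which = c("l_g", "l_d1", "l_d2", "l_b"), ...) {
  h <- x$history
  which <- intersect(which, names(h))
  graphics::matplot(h$epoch, as.matrix(h[, which, drop = FALSE]),
                    type = "l", lty = 1, lwd = 2,
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", legend = which, lty = 1, lwd = 2,
                   col = seq_along(which), bty = "n")
  invisible(x)
}

# --- checkpointing --------------------------------------------------------

#' Save / load a fitted model
#'
#' The checkpoint holds every network's weights and batch-norm statistics,
#' the full training control (including the seed) and the training history,
#' so a run is reconstructable and resumable from its file.
#'
#' @param model a fitted [ganreg()] object.
#' @param path file path (RDS).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   the restored `"ganreg"` object.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ganreg"))
  pack_net <- function(net) list(layers = net$layers, cfg = net$cfg,
                                 step = net$step, opt = net$opt,
                                 name = net$name)
  obj <- list(generator = pack_net(model$generator),
              d1 = pack_net(model$d1), d2 = pack_net(model$d2),
              control = model$control, dims = model$dims,
              n_pairs = model$n_pairs, spacing = model$spacing,
              history = model$history, rng_state = model$rng_state,
              package_version = as.character(utils::packageVersion("ganreg")))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(suppressWarnings(readRDS(path)), error = function(e)
    stop(sprintf("load_checkpoint: cannot read %s (%s)", path,
                 conditionMessage(e))))
  need <- c("generator", "d1", "d2", "control", "dims")
  if (!is.list(obj) || !all(need %in% names(obj)))
    stop(sprintf("load_checkpoint: %s is not a ganreg checkpoint", path))
  unpack_net <- function(x) {
    net <- make_network(x$layers, x$name)
    net$cfg <- x$cfg; net$step <- x$step; net$opt <- x$opt
    net
  }
  structure(list(generator = unpack_net(obj$generator),
                 d1 = unpack_net(obj$d1), d2 = unpack_net(obj$d2),
                 control = obj$control, dims = obj$dims,
                 n_pairs = obj$n_pairs, spacing = obj$spacing,
                 history = obj$history, rng_state = obj$rng_state),
            class = "ganreg")
}
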