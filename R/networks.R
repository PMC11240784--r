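#' Generator configuration
#'
#' The generator is a convolutional autoencoder: five stride-2 encoder
#' stages and five stride-2 up-sampling decoder stages, all with 3 x 3
#' kernels, batch normalization and rectifier activations, followed by a
#' zero-initialized output stage.  Two output modes exist:
#' \describe{
#'   \item{`field`}{a 2-channel dense displacement field in mm, squashed by
#'     `max_disp * tanh(.)` so the freshly initialized network starts at
#'     the identity transform — the evaluable default, since a field can be
#'     applied to landmarks;}
#'   \item{`image`}{a 1-channel registered image in `[0, 1]` emitted
#'     directly (no transform is recoverable in this mode).}
#' }
#' Channel widths are configurable; the defaults double per stage and are
#' sized for CPU use.
#'
#' @param mode `"field"` or `"image"`.
#' @param enc_channels,dec_channels integer vectors of length 5.
#' @param in_channels input channels (fixed + moving = 2).
#' @param max_disp maximum displacement magnitude per component, mm
#'   (field mode).
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(mode = c("field", "image"),
                             enc_channels = c(16L, 32L, 64L, 128L, 256L),
                             dec_channels = c(128L, 64L, 32L, 16L, 16L),
                             in_channels = 2L, max_disp = 10,
                             field_smooth = 0) {
  mode <- match.arg(mode)
  if (field_smooth < 0)
    stop("generator_config: field_smooth must be >= 0")
  if (length(enc_channels) != 5L || length(dec_channels) != 5L)
    stop("generator_config: exactly 5 encoder and 5 decoder stages are required")
  if (any(enc_channels < 1L) || any(dec_channels < 1L))
    stop("generator_config: channel counts must be positive")
  if (max_disp <= 0) stop("generator_config: max_disp must be positive")
  structure(list(mode = mode, enc_channels = as.integer(enc_channels),
                 dec_channels = as.integer(dec_channels),
                 in_channels = as.integer(in_channels),
                 kernel = 3L, stride = 2L, max_disp = max_disp,
                 field_smooth = field_smooth),
            class = "generator_config")
}

#' Discriminator configuration
#'
#' A stack of stride-2 3 x 3 convolutions (batch norm + rectifier) followed
#' by a dense layer with a saturating tanh output mapped affinely onto
#' (0, 1) and clamped to `[eps, 1 - eps]` — the affine map is needed because
#' the adversarial objectives take logarithms of `D` and `1 - D`.  By
#' default the discriminator sees a single channel (real = the source
#' image, fake = the registered image); `conditional = TRUE` concatenates
#' the candidate with the other-modality source as a second channel.
#'
#' @param in_channels 1 or 2.
#' @param conv_channels integer vector of per-stage channel counts.
#' @param input_size `(H, W)` of the images the discriminator will judge
#'   (the dense head's size depends on it).
#' @param eps clamping margin of the probability output.
#' @return An object of class `"discriminator_config"`.
#' @export
discriminator_config <- function(in_channels = 1L,
                                 conv_channels = c(16L, 32L, 64L, 128L),
                                 input_size = c(64L, 64L), eps = 1e-6) {
  if (!in_channels %in% c(1L, 2L))
    stop("discriminator_config: in_channels must be 1 or 2")
  n <- length(conv_channels)
  if (n < 1L) stop("discriminator_config: at least one conv stage")
  if (any(input_size %% 2L^n != 0L))
    stop(sprintf("discriminator_config: input size must be divisible by 2^%d", n))
  structure(list(in_channels = as.integer(in_channels),
                 conv_channels = as.integer(conv_channels),
                 input_size = as.integer(input_size),
                 kernel = 3L, stride = 2L, eps = eps),
            class = "discriminator_config")
}

#' Build the generator network
#'
#' Uses the current RNG state for weight initialization (seed it for
#' reproducibility).  The output stage is zero-initialized, so a fresh
#' field-mode generator emits the identity (all-zero) field.
#'
#' @param cfg a [generator_config()].
#' @return A network object of class `"ganreg_net"`.
#' @export
build_generator <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  layers <- list()
  cin <- cfg$in_channels
  for (ch in cfg$enc_channels) {
    layers <- c(layers, list(layer_conv(cin, ch, k = cfg$kernel,
                                        stride = cfg$stride, pad = 1L),
                             layer_bn(ch), layer_relu()))
    cin <- ch
  }
  for (ch in cfg$dec_channels) {
    layers <- c(layers, list(layer_tconv(cin, ch, k = cfg$kernel, pad = 1L),
                             layer_bn(ch), layer_relu()))
    cin <- ch
  }
  out_ch <- if (cfg$mode == "field") 2L else 1L
  layers <- c(layers, list(layer_conv(cin, out_ch, k = 3L, stride = 1L,
                                      pad = 1L, zero_init = TRUE)))
  if (cfg$mode == "field" && cfg$field_smooth > 0)
    layers <- c(layers, list(layer_blur(cfg$field_smooth)))
  layers <- c(layers, list(if (cfg$mode == "field")
    layer_scale_tanh(cfg$max_disp) else layer_sigmoid()))
  net <- make_network(layers, sprintf("generator[%s]", cfg$mode))
  net$cfg <- cfg
  net
}

check_generator_input <- function(h, w) {
  if (h %% 32L != 0L || w %% 32L != 0L || h < 32L || w < 32L)
    stop(sprintf("generator input size %d x %d violates the multiple-of-32 constraint (5 stride-2 stages)", h, w))
}

# forward pass; x is (H, W, N, 2) channels-last
generator_forward <- function(gen, x, train = TRUE, update_stats = train) {
  d <- dim(x)
  check_generator_input(d[1], d[2])
  if (d[4] != gen$cfg$in_channels)
    stop("generator_forward: wrong channel count")
  forward_network(gen, x, train = train, update_stats = update_stats)
}

#' Build a discriminator network
#'
#' @param cfg a [discriminator_config()].
#' @return A network object of class `"ganreg_net"`.
#' @export
build_discriminator <- function(cfg = discriminator_config()) {
  stopifnot(inherits(cfg, "discriminator_config"))
  layers <- list()
  cin <- cfg$in_channels
  for (ch in cfg$conv_channels) {
    layers <- c(layers, list(layer_conv(cin, ch, k = cfg$kernel,
                                        stride = cfg$stride, pad = 1L),
                             layer_bn(ch), layer_relu()))
    cin <- ch
  }
  red <- 2L^length(cfg$conv_channels)
  feat <- prod(cfg$input_size %/% red) * cin
  layers <- c(layers, list(layer_dense_prob(feat, eps = cfg$eps)))
  net <- make_network(layers, "discriminator")
  net$cfg <- cfg
  net
}

discriminator_forward <- function(dis, x, train = TRUE,
                                  update_stats = train) {
  d <- dim(x)
  if (!identical(d[1:2], dis$cfg$input_size))
    stop(sprintf("discriminator_forward: input %d x %d does not match the configured size %d x %d",
                 d[1], d[2], dis$cfg$input_size[1], dis$cfg$input_size[2]))
  if (d[4] != dis$cfg$in_channels)
    stop("discriminator_forward: wrong channel count")
  forward_network(dis, x, train = train, update_stats = update_stats)
}

#' Register one slice pair with a generator
#'
#' Runs the generator on the stacked (fixed, moving) pair in evaluation
#' mode.  In field mode the output is scaled to mm, wrapped as a
#' displacement field and applied to the moving image; in image mode the
#' generator's output is the registered image itself and no transform is
#' available.
#'
#' @param gen a generator built by [build_generator()].
#' @param pair a [slice_pair()].
#' @return List with elements `registered` (an `image_slice`) and `field`
#'   (a [displacement_field()], or `NULL` in image mode).
#' @export
register_pair <- function(gen, pair) {
  stopifnot(inherits(gen, "ganreg_net"), inherits(pair, "slice_pair"))
  h <- nrow(pair$fixed$pixels); w <- ncol(pair$fixed$pixels)
  check_generator_input(h, w)
  x <- array(0, c(h, w, 1L, 2L))
  x[, , 1, 1] <- pair$fixed$pixels
  x[, , 1, 2] <- pair$moving$pixels
  fw <- generator_forward(gen, x, train = FALSE)
  if (gen$cfg$mode == "field") {
    u <- array(fw$out[, , 1, ], c(h, w, 2))
    field <- displacement_field(u, spacing = pair$fixed$spacing,
                                origin = pair$fixed$origin)
    registered <- apply_displacement(pair$moving, field)
    list(registered = registered, field = field)
  } else {
    registered <- image_slice(matrix(fw$out[, , 1, 1], h, w),
                              spacing = pair$fixed$spacing,
                              modality = "REGISTERED",
                              origin = pair$fixed$origin)
    list(registered = registered, field = NULL)
  }
}
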