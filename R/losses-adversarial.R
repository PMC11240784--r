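#' Adversarial generator loss
#'
#' The generator's adversarial objective over a batch: the mean of
#' `log(1 - D1(fake)) + log(1 - D2(fake))`.  Minimizing it drives both
#' discriminator outputs on generated images towards 1 (the generator
#' "deceiving" them).  This saturating form is the default; the
#' non-saturating alternative `-log D1(fake) - log D2(fake)`, the standard
#' stabilization when discriminators win early, is available behind a flag.
#'
#' @param d1_fake,d2_fake numeric vectors of discriminator outputs on
#'   generated images, strictly inside (0, 1).
#' @param nonsaturating use `-log D(fake)` instead of `log(1 - D(fake))`.
#' @return Scalar loss (batch mean).
#' @export
adversarial_g_loss <- function(d1_fake, d2_fake, nonsaturating = FALSE) {
  check_prob(d1_fake, "d1_fake"); check_prob(d2_fake, "d2_fake")
  if (nonsaturating) {
    mean(-log(d1_fake)) + mean(-log(d2_fake))
  } else {
    mean(log(1 - d1_fake)) + mean(log(1 - d2_fake))
  }
}

#' Adversarial discriminator loss
#'
#' One discriminator's objective over a batch:
#' `mean(-log D(real)) + mean(-log(1 - D(fake)))`.  It is 0 in the limit of
#' a perfect discriminator (`D(real) -> 1`, `D(fake) -> 0`) and `2 log 2`
#' at the uninformative point `D = 1/2`.
#'
#' @param d_real,d_fake numeric vectors of outputs on real and generated
#'   images, strictly inside (0, 1).
#' @return Scalar loss (batch mean).
#' @export
adversarial_d_loss <- function(d_real, d_fake) {
  check_prob(d_real, "d_real"); check_prob(d_fake, "d_fake")
  mean(-log(d_real)) + mean(-log(1 - d_fake))
}

check_prob <- function(p, what) {
  if (!is.numeric(p) || length(p) < 1L || any(!is.finite(p)) ||
      any(p <= 0) || any(p >= 1))
    stop(sprintf("%s must be probabilities strictly inside (0, 1)", what))
  invisible(TRUE)
}

#' Compose the total training objectives
#'
#' The generator total is the adversarial term plus the weighted Bayesian
#' posterior loss; each discriminator total is its adversarial term plus
#' the weighted mutual-information loss against its own modality (D1
#' against ultrasound, D2 against MR).
#'
#' @param l_g,l_d1,l_d2 adversarial components.
#' @param l_b Bayesian posterior loss of the registered batch.
#' @param l_mi_d1,l_mi_d2 mutual-information losses against US and MR.
#' @param lambda_b,lambda_mi nonnegative loss weights.
#' @return Named list `g`, `d1`, `d2` of total losses.
#' @export
total_losses <- function(l_g, l_d1, l_d2, l_b = 0, l_mi_d1 = 0, l_mi_d2 = 0,
                         lambda_b = 1, lambda_mi = 1) {
  if (lambda_b < 0 || lambda_mi < 0)
    stop("total_losses: loss weights must be nonnegative")
  list(g = l_g + lambda_b * l_b,
       d1 = l_d1 + lambda_mi * l_mi_d1,
       d2 = l_d2 + lambda_mi * l_mi_d2)
}
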