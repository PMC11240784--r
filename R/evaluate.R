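#' Mean target registration error (mTRE)
#'
#' The average Euclidean distance, in mm, between the fixed landmarks
#' mapped through the recovered transform and their paired moving
#' landmarks: `mTRE = (1/N) sum_i || T(x'_i) - x_i ||`.  With `field =
#' NULL` the identity transform is used, giving the pre-registration error.
#'
#' @param lm a [landmark_set()].
#' @param field a [displacement_field()], or `NULL` for the identity.
#' @return The mean distance in mm; attribute `"distances"` holds the
#'   per-landmark values.
#' @export
mtre <- function(lm, field = NULL) {
  stopifnot(inherits(lm, "landmark_set"))
  if (nrow(lm$fixed_points) == 0L)
    stop("mtre: empty landmark set")
  mapped <- if (is.null(field)) lm$fixed_points
            else transform_landmarks(lm, field)
  d <- sqrt(rowSums((mapped - lm$moving_points)^2))
  structure(mean(d), distances = as.vector(d))
}

#' Cohort summary statistics
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of a
#' vector of per-case registration errors.
#'
#' @param values numeric vector (mm), length >= 2.
#' @return An object of class `"cohort_stats"`: list with `mean`, `sd`,
#'   `n`.
#' @export
cohort_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("cohort_stats: at least two values are required for the sample sd")
  if (any(!is.finite(values)))
    stop("cohort_stats: values must be finite")
  structure(list(mean = mean(values), sd = stats::sd(values),
                 n = length(values)),
            class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat(sprintf("%.4f ± %.4f (n = %d)\n", x$mean, x$sd, x$n))
  invisible(x)
}

#' Percentage error reduction
#'
#' `100 * (pre - post) / pre`: the relative improvement of the
#' post-registration error over the initial error, in percent.
#'
#' @param pre_mean,post_mean cohort mean errors in mm; `pre_mean` must be
#'   positive.
#' @return The reduction in percent.
#' @export
percent_reduction <- function(pre_mean, post_mean) {
  if (pre_mean <= 0)
    stop("percent_reduction: pre_mean must be positive")
  100 * (pre_mean - post_mean) / pre_mean
}

#' Paired two-sided signed-rank test
#'
#' Wilcoxon signed-rank test on paired pre/post errors (mTRE differences
#' are typically non-normal, so a nonparametric paired test is used; the
#' exact null distribution is evaluated for n <= 25 when there are no
#' ties).  Zero differences are dropped following the standard signed-rank
#' convention; if every difference is zero the p-value is 1 by convention
#' and flagged.
#'
#' @param pre,post numeric vectors of equal length (n >= 5).
#' @return Two-sided p-value; attributes `"method"` and (if degenerate)
#'   `"all_ties"`.
#' @export
paired_test <- function(pre, post) {
  if (length(pre) != length(post))
    stop("paired_test: pre and post lengths differ")
  if (length(pre) < 5L)
    stop("paired_test: at least 5 pairs are required")
  d <- pre - post
  nz <- d[d != 0]
  if (!length(nz))
    return(structure(1, all_ties = TRUE, method = "wilcoxon signed-rank"))
  exact <- length(nz) <= 25L && !anyDuplicated(abs(nz))
  p <- suppressWarnings(stats::wilcox.test(pre, post, paired = TRUE,
                                           exact = exact,
                                           correct = TRUE)$p.value)
  structure(min(p, 1), method = "wilcoxon signed-rank", exact = exact)
}

#' Evaluate a fitted model on landmark-annotated cases
#'
#' Computes the pre- and post-registration mTRE for each case: the
#' generator proposes a displacement field for the case's slice pair, the
#' fixed landmarks are mapped through it, and Euclidean distances to the
#' paired moving landmarks are averaged.  Only field-mode models support
#' this; an image-mode generator emits no transform, so its TRE is
#' unavailable by construction.
#'
#' @param cases list of cases, each a list with elements `pair` (a
#'   [slice_pair()]) and `landmarks` (a [landmark_set()]).
#' @param model a fitted [ganreg()] model (field mode), or `NULL` to
#'   evaluate the identity transform.
#' @param fields optional list of [displacement_field()] objects overriding
#'   the model (e.g. ground-truth fields), one per case.
#' @param file optional path to write the per-case report CSV.
#' @return List with `results` (data frame: `case_id`, `n_landmarks`,
#'   `mtre_pre_mm`, `mtre_post_mm`), `pre` and `post` ([cohort_stats()]),
#'   and `p_value` (paired signed-rank, when n >= 5).
#' @export
evaluate_cases <- function(cases, model = NULL, fields = NULL, file = NULL) {
  if (!is.list(cases) || length(cases) < 1L)
    stop("evaluate_cases: empty case list")
  if (!is.null(model)) {
    stopifnot(inherits(model, "ganreg"))
    if (model$control$mode != "field")
      stop("evaluate_cases: TRE is unavailable for an image-mode model (no transform is produced)")
  }
  if (!is.null(fields) && length(fields) != length(cases))
    stop("evaluate_cases: one field per case is required")
  rows <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    if (!inherits(cs$pair, "slice_pair") ||
        !inherits(cs$landmarks, "landmark_set"))
      stop("evaluate_cases: each case needs a 'pair' and a 'landmarks' element")
    fld <- if (!is.null(fields)) fields[[i]]
           else if (!is.null(model)) register_pair(model$generator, cs$pair)$field
           else NULL
    rows[[i]] <- data.frame(case_id = cs$landmarks$case_id,
                            n_landmarks = nrow(cs$landmarks$fixed_points),
                            mtre_pre_mm = as.numeric(mtre(cs$landmarks)),
                            mtre_post_mm = as.numeric(mtre(cs$landmarks, fld)))
  }
  results <- do.call(rbind, rows)
  out <- list(results = results,
              pre = if (nrow(results) >= 2) cohort_stats(results$mtre_pre_mm),
              post = if (nrow(results) >= 2) cohort_stats(results$mtre_post_mm),
              p_value = if (nrow(results) >= 5)
                as.numeric(paired_test(results$mtre_pre_mm,
                                       results$mtre_post_mm)) else NA_real_)
  class(out) <- "ganreg_evaluation"
  if (!is.null(file)) {
    utils::write.csv(results, file, row.names = FALSE)
  }
  out
}

#' @export
print.ganreg_evaluation <- function(x, ...) {
  cat(sprintf("Landmark evaluation over %d cases (2D slice TRE)\n",
              nrow(x$results)))
  print(x$results, row.names = FALSE)
  if (!is.null(x$pre)) {
    cat("pre-registration  mTRE: "); print(x$pre)
    cat("post-registration mTRE: "); print(x$post)
  }
  if (is.finite(x$p_value))
    cat(sprintf("paired signed-rank p-value: %.6g\n", x$p_value))
  invisible(x)
}

#' Reference cohort registration errors
#'
#' Published per-case mean target registration errors for two public
#' MR/intraoperative-ultrasound brain-tumour cohorts, shipped as package
#' fixtures so the cohort statistics pipeline can be exercised and checked
#' against the published summary rows.
#'
#' `resect_mtre_table()`: 22 cases; columns `pre` (initial error, mm),
#' `post_adversarial` (registration trained with the adversarial losses
#' alone) and `post_full` (adversarial plus Bayesian/mutual-information
#' losses).  `bite_mtre_table()`: 14 cases with per-case mean and sd before
#' and after registration.
#'
#' @return A data frame.
#' @export
resect_mtre_table <- function() {
  utils::read.csv(system.file("extdata", "resect_mtre.csv",
                              package = "ganreg"))
}

#' @rdname resect_mtre_table
#' @export
bite_mtre_table <- function() {
  utils::read.csv(system.file("extdata", "bite_mtre.csv",
                              package = "ganreg"))
}
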