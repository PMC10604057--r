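#' Success rate at an error threshold
#'
#' The proportion of cases whose absolute error falls below the threshold.
#' "Below" is strict by default; set `inclusive = TRUE` for `<=`.
#'
#' @param errors Non-negative numeric vector of absolute errors.
#' @param threshold Error threshold (same units as `errors`).
#' @param inclusive Use `<=` instead of strict `<`.
#' @return Fraction in \[0, 1\].
#' @examples
#' success_rate(c(1, 2, 4, 8), 3.5)
#' @export
success_rate <- function(errors, threshold, inclusive = FALSE) {
  check_errors(errors)
  if (inclusive) mean(errors <= threshold) else mean(errors < threshold)
}

check_errors <- function(errors) {
  if (!length(errors)) abort("empty error vector")
  if (any(!is.finite(errors)) || any(errors < 0)) {
    abort("errors must be finite and non-negative")
  }
  invisible(errors)
}

#' Success-rate curve over a threshold grid
#'
#' Evaluates [success_rate()] on a grid of thresholds (default 0.5 to 10
#' degrees in 0.5 degree steps).  The curve is non-decreasing in the
#' threshold and invariant under permutation of the errors.
#'
#' @inheritParams success_rate
#' @param thresholds Numeric grid of thresholds.
#' @param parameter Optional label attached to the curve rows.
#' @return Tibble of class `success_curve` with columns `parameter`
#'   (if given), `threshold`, `rate`.
#' @export
success_curve <- function(errors, thresholds = seq(0.5, 10, by = 0.5),
                          inclusive = FALSE, parameter = NULL) {
  check_errors(errors)
  out <- tibble::tibble(
    threshold = thresholds,
    rate = vapply(thresholds, function(t) success_rate(errors, t, inclusive), 0)
  )
  if (!is.null(parameter)) out <- dplyr::bind_cols(tibble::tibble(parameter = parameter), out)
  class(out) <- c("success_curve", class(out))
  out
}

#' Smallest grid threshold reaching a target success rate
#'
#' @inheritParams success_curve
#' @param target Target rate (default 0.8).
#' @return The smallest threshold on the grid whose rate is at least
#'   `target`; `NA` if none reaches it.
#' @export
threshold_for_rate <- function(errors, target = 0.8,
                               thresholds = seq(0.5, 10, by = 0.5),
                               inclusive = FALSE) {
  sc <- success_curve(errors, thresholds, inclusive)
  hit <- sc$threshold[sc$rate >= target]
  if (length(hit)) min(hit) else NA_real_
}

#' Bland-Altman agreement analysis
#'
#' Computes the differences `x - y`, their mean and sample standard
#' deviation (n - 1 denominator), and the limits of agreement
#' `mean +/- 1.96 * SD`.
#'
#' @param x,y Paired numeric measurement vectors of equal length >= 2.
#' @return Object of class `bland_altman`: list with `summary` (one-row
#'   tibble: `mean_diff`, `sd_diff`, `loa_lower`, `loa_upper`, `n`) and
#'   `data` (tibble with `mean_xy`, `diff` per pair, for plotting).
#' @examples
#' ba <- bland_altman(c(1, 2, 3), c(2, 2, 2))
#' ba$summary
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` have different lengths")
  if (length(x) < 2) abort("Bland-Altman needs at least 2 pairs")
  d <- x - y
  m <- mean(d); s <- sd(d)
  structure(
    list(
      summary = tibble::tibble(
        mean_diff = m, sd_diff = s,
        loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
        n = length(d)
      ),
      data = tibble::tibble(mean_xy = (x + y) / 2, diff = d)
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<bland_altman> n=%d  mean diff %.3f  LoA [%.3f, %.3f]\n",
              s$n, s$mean_diff, s$loa_lower, s$loa_upper))
  invisible(x)
}

#' Agreement summary between two measurement series
#'
#' Mean and SD of the absolute differences, Pearson correlation with its
#' two-sided p-value, and the coefficient of determination `R^2 = r^2`.
#' If either series has zero variance the correlation is undefined and
#' reported as `NA` with a warning (not silently).
#'
#' @param x,y Paired numeric vectors of equal length >= 3.
#' @return One-row tibble of class `agreement_summary` with columns `mae`,
#'   `sd_ae`, `r`, `r_squared`, `p_value`, `n`.
#' @export
agreement_summary <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` have different lengths")
  if (length(x) < 3) abort("agreement summary needs at least 3 pairs")
  ae <- abs(x - y)
  if (sd(x) == 0 || sd(y) == 0) {
    warn("zero variance in one input: correlation undefined")
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- cor.test(x, y)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  out <- tibble::tibble(
    mae = mean(ae), sd_ae = sd(ae),
    r = r, r_squared = r^2, p_value = p, n = length(x)
  )
  class(out) <- c("agreement_summary", class(out))
  out
}

#' ICC(2,1): two-way random effects, absolute agreement, single measure
#'
#' Computed from the two-way ANOVA mean squares (rows = subjects, columns
#' = raters): with `MSR` the between-subject, `MSC` the between-rater and
#' `MSE` the residual mean square,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' The 95% confidence interval uses the F-based formulation of McGraw &
#' Wong (1996); the p-value tests ICC = 0 via `F = MSR / MSE`.
#'
#' @param ratings Numeric matrix or data frame, subjects in rows and
#'   raters in columns; complete, >= 2 subjects and >= 2 raters.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble of class `icc_result` with columns `icc`,
#'   `ci_lower`, `ci_upper`, `p_value`, `n_subjects`, `n_raters`, plus the
#'   mean squares `msr`, `msc`, `mse`.
#' @examples
#' icc_2_1(cbind(r1 = c(1, 2, 3), r2 = c(2, 3, 4)))
#' @export
icc_2_1 <- function(ratings, conf_level = 0.95) {
  m <- as.matrix(ratings)
  if (anyNA(m)) abort("ratings matrix must be complete (no NA)")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) abort("need at least 2 subjects and 2 raters")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom == 0) {
    abort("degenerate ratings: no variance anywhere in the matrix")
  }
  icc <- (msr - mse) / denom
  alpha <- 1 - conf_level

  if (mse == 0 && msc <= mse) {
    # perfect absolute agreement: no residual and no rater effect
    ci <- c(1, 1); p <- 0
  } else {
    fj <- if (mse > 0) msr / mse else Inf
    p <- if (is.finite(fj)) pf(fj, n - 1, (n - 1) * (k - 1), lower.tail = FALSE) else 0
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lower, upper)
  }
  out <- tibble::tibble(
    icc = icc, ci_lower = min(ci[1], icc), ci_upper = max(ci[2], icc),
    p_value = p, n_subjects = n, n_raters = k,
    msr = msr, msc = msc, mse = mse
  )
  class(out) <- c("icc_result", class(out))
  out
}

#' Derived-vs-direct agreement table for a synthetic cohort
#'
#' For every subject of a phantom cohort, measures the six test parameters
#' directly from the landmarks and derives them from the measured pelvic
#' parameters and incidence angles, then summarises agreement per
#' parameter and pooled.
#'
#' @param cohort A `phantom_cohort` from [sample_cohort()].
#' @param frame A [frame_convention()].
#' @return List with `paired` (tibble: subject, parameter, direct,
#'   derived), `by_parameter` (per-parameter [agreement_summary()] rows)
#'   and `pooled` (one [agreement_summary()] row over all parameters).
#' @export
cohort_agreement <- function(cohort, frame = frame_convention()) {
  stopifnot(inherits(cohort, "phantom_cohort"), nrow(cohort) > 0)
  paired <- purrr::map2_dfr(cohort$subject, cohort$landmarks, function(id, lms) {
    rep_ <- sagittal_report(lms, frame)
    rep_ <- rep_[rep_$group == "test", ]
    tibble::tibble(subject = id, parameter = rep_$parameter,
                   direct = rep_$direct, derived = rep_$derived)
  })
  by_par <- paired |>
    dplyr::group_by(.data$parameter) |>
    dplyr::group_modify(~ agreement_summary(.x$derived, .x$direct)) |>
    dplyr::ungroup()
  pooled <- agreement_summary(paired$derived, paired$direct)
  list(paired = paired, by_parameter = by_par, pooled = pooled)
}
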