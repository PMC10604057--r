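#' Tidy a sagittal report into long parameter rows
#'
#' @param x A [sagittal_report()].
#' @param ... Ignored.
#' @return Tibble with one row per parameter and measurement route.
#' @method tidy sagittal_report
#' @export
tidy.sagittal_report <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(unclass(x)),
                      cols = c("direct", "derived"),
                      names_to = "route", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
}

#' One-row summary of a sagittal report
#'
#' @param x A [sagittal_report()].
#' @param ... Ignored.
#' @return Tibble with parameter counts and the maximum derived-vs-direct
#'   discrepancy.
#' @method glance sagittal_report
#' @export
glance.sagittal_report <- function(x, ...) {
  tibble::tibble(
    n_parameters = nrow(x),
    n_test = sum(x$group == "test"),
    max_discrepancy = max(x$discrepancy, na.rm = TRUE)
  )
}

#' Tidy an agreement summary
#'
#' @param x An [agreement_summary()].
#' @param ... Ignored.
#' @return Long tibble of statistic/value pairs.
#' @method tidy agreement_summary
#' @export
tidy.agreement_summary <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(unclass(x)), dplyr::everything(),
                      names_to = "statistic", values_to = "value")
}

#' Tidy an ICC result
#'
#' @param x An [icc_2_1()] result.
#' @param ... Ignored.
#' @return One-row tibble with estimate, CI bounds and p-value.
#' @method tidy icc_result
#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(estimate = x$icc, conf.low = x$ci_lower,
                 conf.high = x$ci_upper, p.value = x$p_value)
}

#' Tidy a cascade model's training history
#'
#' @param x A `cascade_model`.
#' @param ... Ignored.
#' @return Tibble with `order`, `head`, `epoch`, `loss`.
#' @method tidy cascade_model
#' @export
tidy.cascade_model <- function(x, ...) {
  tibble::as_tibble(x$history)
}

#' One-row summary of a trained cascade
#'
#' @param x A `cascade_model`.
#' @param ... Ignored.
#' @return Tibble with head count, epochs, and initial/final mean training
#'   loss across heads.
#' @method glance cascade_model
#' @export
glance.cascade_model <- function(x, ...) {
  h <- x$history
  last <- max(h$epoch)
  tibble::tibble(
    n_heads = length(unique(h$head)),
    epochs = last,
    initial_loss = mean(h$loss[h$epoch == 0]),
    final_loss = mean(h$loss[h$epoch == last]),
    n_train = length(x$train_idx),
    n_validation = length(x$val_idx)
  )
}

#' Tidy a Bland-Altman result
#'
#' @param x A [bland_altman()] result.
#' @param ... Ignored.
#' @return The per-pair tibble with `mean_xy` and `diff`.
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) x$data

#' One-row summary of a Bland-Altman result
#'
#' @param x A [bland_altman()] result.
#' @param ... Ignored.
#' @return The one-row summary tibble.
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) x$summary
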