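# Permutation robustness of the selected model.

#' Permutation robustness analysis
#'
#' Assesses whether the selected model's performance could arise from chance
#' associations: each predictor column is shuffled and the model refitted on
#' the shuffled data, recording in-sample classification errors, repeated
#' `n_permutations` times. The baseline is the in-sample error count of the
#' model fitted on the unshuffled data; the quantity of interest is the
#' distribution of `permuted - baseline` error differences.
#'
#' By default every predictor column is shuffled independently (breaking
#' predictor intercorrelations as well as predictor-outcome links) and the
#' model is refitted per permutation. `shuffle = "joint"` permutes whole
#' rows of the predictor block instead; `mode = "freeze"` keeps the baseline
#' model's coefficients and only scores the shuffled inputs.
#'
#' @param data Abilities tibble (oriented raw units) with the outcome.
#' @param predictors Predictor subset of the selected model.
#' @param outcome Binary 0/1 outcome column name.
#' @param n_components Component count of the selected model.
#' @param n_permutations Number of permutations (the reference analysis uses
#'   10,000).
#' @param seed Integer seed; the permutation stream is reproducible and
#'   extending `n_permutations` leaves earlier draws unchanged.
#' @param mode `"refit"` (default) refits on shuffled data; `"freeze"`
#'   scores shuffled data with the baseline coefficients.
#' @param shuffle `"independent"` (default) or `"joint"` row shuffling.
#'
#' @return An object of class `permutation_summary`: `baseline_errors`,
#'   integer vector `permuted_errors` (`NA` where a permutation produced a
#'   degenerate fit), `differences`, `n_failed`, `min_difference`, and the
#'   call parameters. See [fraction_below()], [tidy.permutation_summary()],
#'   [glance.permutation_summary()], [autoplot.permutation_summary()].
#' @export
permutation_robustness <- function(data, predictors = NULL,
                                   outcome = "success", n_components = 1L,
                                   n_permutations = 10000L, seed = 1L,
                                   mode = c("refit", "freeze"),
                                   shuffle = c("independent", "joint")) {
  mode <- match.arg(mode)
  shuffle <- match.arg(shuffle)
  if (n_permutations < 1L) {
    abort_takeovr("`n_permutations` must be at least 1.",
                  class = "takeovr_error_validation")
  }
  predictors <- resolve_predictors(data, predictors, outcome)
  y <- check_binary_outcome(data[[outcome]], outcome)
  n <- nrow(data)
  baseline_fit <- fit_pls_logistic(data, predictors, outcome, n_components)
  baseline_errors <- sum(classify(baseline_fit$fitted) != y)

  count_errors <- function(shuffled) {
    if (mode == "refit") {
      fit <- fit_pls_logistic(shuffled, predictors, outcome, n_components)
      sum(classify(fit$fitted) != y)
    } else {
      sum(predict(baseline_fit, shuffled, type = "class") != y)
    }
  }

  set.seed(seed)
  permuted_errors <- rep(NA_integer_, n_permutations)
  for (b in seq_len(n_permutations)) {
    shuffled <- data
    if (shuffle == "independent") {
      for (nm in predictors) shuffled[[nm]] <- shuffled[[nm]][sample.int(n)]
    } else {
      ord <- sample.int(n)
      shuffled[predictors] <- shuffled[ord, predictors]
    }
    permuted_errors[b] <- tryCatch(
      count_errors(shuffled),
      takeovr_error = function(e) NA_integer_
    )
  }
  structure(
    list(
      n_permutations = as.integer(n_permutations),
      seed = as.integer(seed),
      mode = mode,
      shuffle = shuffle,
      predictors = predictors,
      n_components = as.integer(n_components),
      baseline_errors = baseline_errors,
      permuted_errors = permuted_errors,
      differences = permuted_errors - baseline_errors,
      n_failed = sum(is.na(permuted_errors)),
      min_difference = suppressWarnings(min(permuted_errors - baseline_errors,
                                            na.rm = TRUE))
    ),
    class = "permutation_summary"
  )
}

#' Share of permutations with error difference below a bound
#'
#' @param summary A `permutation_summary`.
#' @param k Difference bound (errors).
#' @return Fraction of successful permutations with
#'   `permuted - baseline < k`.
#' @export
fraction_below <- function(summary, k) {
  stopifnot(inherits(summary, "permutation_summary"))
  mean(summary$differences < k, na.rm = TRUE)
}

#' @export
print.permutation_summary <- function(x, ...) {
  ok <- x$n_permutations - x$n_failed
  cat(sprintf(
    "Permutation robustness (%s, %s shuffling): %d permutations (%d failed)\n",
    x$mode, x$shuffle, x$n_permutations, x$n_failed))
  cat(sprintf("  baseline errors: %d\n", x$baseline_errors))
  cat(sprintf("  median additional errors: %.1f; min difference: %d\n",
              stats::median(x$differences, na.rm = TRUE), x$min_difference))
  cat(sprintf("  permutations at-or-better than baseline: %d of %d\n",
              sum(x$differences <= 0, na.rm = TRUE), ok))
  invisible(x)
}

#' Tidy permutation results
#'
#' @param x A `permutation_summary`.
#' @param ... Unused.
#' @return One row per permutation: `permutation`, `errors`, `difference`.
#' @export
tidy.permutation_summary <- function(x, ...) {
  tibble::tibble(
    permutation = seq_len(x$n_permutations),
    errors = x$permuted_errors,
    difference = x$differences
  )
}

#' One-row permutation summary
#'
#' @inheritParams tidy.permutation_summary
#' @return Baseline errors, median/min difference, fraction of permutations
#'   at-or-better than baseline, and the failure count.
#' @export
glance.permutation_summary <- function(x, ...) {
  tibble::tibble(
    n_permutations = x$n_permutations,
    n_failed = x$n_failed,
    baseline_errors = x$baseline_errors,
    median_difference = stats::median(x$differences, na.rm = TRUE),
    min_difference = x$min_difference,
    fraction_at_or_better = mean(x$differences <= 0, na.rm = TRUE)
  )
}

#' Histogram of permuted-minus-baseline error differences
#'
#' @param object A `permutation_summary`.
#' @param ... Unused.
#' @return A ggplot histogram with the baseline (difference 0) marked.
#' @export
autoplot.permutation_summary <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(.data$difference)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey40", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = "additional errors vs unshuffled model",
      y = "permutations",
      title = "Permutation robustness of the selected model"
    ) +
    ggplot2::theme_minimal()
}
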