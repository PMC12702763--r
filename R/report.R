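# Univariate group comparisons, confusion-matrix metrics and the assembled
# analysis report.

#' Confusion matrix of hard classifications
#'
#' Cell conventions: `a` = actual success predicted success, `b` = actual
#' success predicted fail (false negatives), `c` = actual fail predicted
#' success (false positives), `d` = actual fail predicted fail.
#'
#' @param actual,predicted Integer 0/1 vectors of equal length.
#' @return A list of class `confusion_matrix` with counts `a`, `b`, `c`,
#'   `d` and `n`.
#' @export
confusion_matrix <- function(actual, predicted) {
  actual <- check_binary_outcome(actual, "actual")
  predicted <- check_binary_outcome(predicted, "predicted")
  stopifnot(length(actual) == length(predicted))
  confusion_counts(
    a = sum(actual == 1 & predicted == 1),
    b = sum(actual == 1 & predicted == 0),
    c = sum(actual == 0 & predicted == 1),
    d = sum(actual == 0 & predicted == 0)
  )
}

#' @rdname confusion_matrix
#' @param a,b,c,d Cell counts (see above).
#' @export
confusion_counts <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_takeovr("Confusion-matrix cells must be non-negative integers.",
                  class = "takeovr_error_validation")
  }
  structure(as.list(c(counts, n = sum(counts))), class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is `100 (a + d) / n`. Following the reference analysis's
#' terminology, the "specificity" is the success-prediction rate
#' `100 a / (a + b)` (share of actual successes predicted as successes) and
#' the "sensitivity" is the fail-prediction rate `100 d / (c + d)` —
#' note this swaps the usual epidemiological usage.
#'
#' @param cm A [confusion_matrix()].
#' @return One-row tibble: `accuracy`, `success_prediction_rate`,
#'   `fail_prediction_rate` (percent, unrounded), `false_positives`,
#'   `false_negatives`, `total_errors`, `n`.
#' @export
#' @examples
#' confusion_metrics(confusion_counts(a = 50, b = 13, c = 20, d = 30))
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$n == 0) {
    abort_takeovr("Empty confusion matrix.", class = "takeovr_error_validation")
  }
  tibble::tibble(
    accuracy = 100 * (cm$a + cm$d) / cm$n,
    success_prediction_rate = if (cm$a + cm$b > 0)
      100 * cm$a / (cm$a + cm$b) else NA_real_,
    fail_prediction_rate = if (cm$c + cm$d > 0)
      100 * cm$d / (cm$c + cm$d) else NA_real_,
    false_positives = cm$c,
    false_negatives = cm$b,
    total_errors = cm$b + cm$c,
    n = cm$n
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(actual = c("success (1)", "fail (0)"),
                              predicted = c("success (1)", "fail (0)")))
  print(m)
  met <- confusion_metrics(x)
  cat(sprintf(
    "accuracy %.2f%%; success-prediction rate %.1f%%; fail-prediction rate %.1f%%\n",
    met$accuracy, met$success_prediction_rate, met$fail_prediction_rate))
  invisible(x)
}

#' Pooled-variance two-sample t-test
#'
#' Student's independent-samples t-test with pooled variance (not Welch):
#' degrees of freedom `n1 + n2 - 2`, two-sided p-value.
#'
#' @param group_a,group_b Numeric vectors (each of length >= 2).
#' @return One-row tibble: `mean_a`, `mean_b`, `pooled_sd`, `t`, `df`,
#'   `p_value`.
#' @export
#' @examples
#' two_sample_t(c(1, 2, 3), c(2, 3, 4))
two_sample_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort_takeovr("Each group needs at least two observations.",
                  class = "takeovr_error_validation")
  }
  v1 <- stats::var(group_a)
  v2 <- stats::var(group_b)
  n1 <- length(group_a)
  n2 <- length(group_b)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  if (sp2 <= 0) {
    abort_takeovr("Pooled variance is zero; the t statistic is undefined.",
                  class = "takeovr_error_validation")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
  tibble::tibble(
    mean_a = mean(group_a),
    mean_b = mean(group_b),
    pooled_sd = sqrt(sp2),
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value
  )
}

#' Univariate group comparisons of every ability
#'
#' One pooled-variance t-test per predictor, comparing the success and fail
#' groups. These are exploratory: no multiple-testing correction is applied
#' and the p-value column is named accordingly.
#'
#' @inheritParams loo_evaluate
#' @return Tibble with one row per predictor: group means, `pooled_sd`, `t`,
#'   `df`, `p_uncorrected`.
#' @export
univariate_comparisons <- function(data, predictors = NULL,
                                   outcome = "success") {
  predictors <- resolve_predictors(data, predictors, outcome)
  y <- check_binary_outcome(data[[outcome]], outcome)
  check_both_classes(y)
  purrr::map_dfr(predictors, function(nm) {
    res <- two_sample_t(data[[nm]][y == 1], data[[nm]][y == 0])
    tibble::tibble(
      variable = nm,
      mean_success = res$mean_a,
      mean_fail = res$mean_b,
      pooled_sd = res$pooled_sd,
      t = res$t,
      df = res$df,
      p_uncorrected = res$p_value
    )
  })
}

#' Assemble the full analysis report
#'
#' Gathers the component-selection table, the subset-search summary, the
#' final model's confusion matrix and coefficient interpretation, the
#' permutation summary and the univariate comparison table into one
#' structure that serialises to JSON ([write_report()]).
#'
#' @param model The final `pls_glr` fit (on all participants).
#' @param component_selection Optional `component_selection` result.
#' @param search_result Optional `subset_search` result.
#' @param permutation_summary Optional `permutation_summary`.
#' @param univariate_table Optional output of [univariate_comparisons()];
#'   when given it must cover every model predictor.
#' @return A list of class `takeover_report`.
#' @export
final_report <- function(model, component_selection = NULL,
                         search_result = NULL, permutation_summary = NULL,
                         univariate_table = NULL) {
  stopifnot(inherits(model, "pls_glr"))
  if (!is.null(univariate_table) &&
      !all(model$predictors %in% univariate_table$variable)) {
    abort_takeovr(
      "The univariate table does not cover every model predictor; inputs appear to come from different catalogues.",
      class = "takeovr_error_validation"
    )
  }
  cm <- confusion_matrix(model$y, classify(model$fitted))
  coef_table <- tidy(model) |>
    dplyr::mutate(unit_1sd = model$std_params$sd) |>
    dplyr::select("term", "unit_1sd", "beta", "multiplier", "percent_change")
  structure(
    list(
      model = list(
        predictors = model$predictors,
        n_components = model$n_components,
        n = model$n
      ),
      component_selection = if (!is.null(component_selection))
        component_selection$candidates else NULL,
      subset_search = if (!is.null(search_result))
        as.list(search_result$selected) else NULL,
      confusion = list(a = cm$a, b = cm$b, c = cm$c, d = cm$d),
      metrics = confusion_metrics(cm),
      coefficients = coef_table,
      permutation = if (!is.null(permutation_summary))
        glance(permutation_summary) else NULL,
      univariate = univariate_table,
      p_values = "uncorrected (no multiple-testing correction applied)"
    ),
    class = "takeover_report"
  )
}

#' @export
print.takeover_report <- function(x, ...) {
  cat("== Take-over prediction report ==\n\n")
  cat(sprintf("Final model: %d component(s) on %s (n = %d)\n\n",
              x$model$n_components,
              paste(x$model$predictors, collapse = ", "), x$model$n))
  if (!is.null(x$component_selection)) {
    cat("Component-count selection:\n")
    print(x$component_selection[c("h", "fp", "fn", "max_errors",
                                  "total_errors")])
    cat("\n")
  }
  if (!is.null(x$subset_search)) {
    cat(sprintf("Selected subset (Minimax): %s  [max %d, total %d]\n\n",
                x$subset_search$subset, x$subset_search$max_errors,
                x$subset_search$total_errors))
  }
  cm <- do.call(confusion_counts, as.list(x$confusion))
  print(cm)
  cat("\nCoefficients (per 1 SD of each ability):\n")
  print(x$coefficients)
  if (is.null(x$permutation)) {
    cat("\nPermutation analysis: not run\n")
  } else {
    cat(sprintf(
      "\nPermutation analysis: min difference %d over %d permutations (%.1f%% at-or-better)\n",
      x$permutation$min_difference, x$permutation$n_permutations,
      100 * x$permutation$fraction_at_or_better))
  }
  if (!is.null(x$univariate)) {
    cat(sprintf("\nUnivariate comparisons (p-values %s):\n", x$p_values))
    print(x$univariate)
  }
  invisible(x)
}

#' Write / read a report as JSON
#'
#' @param report A `takeover_report`.
#' @param path File path.
#' @return `read_report()` returns the report list (tibbles restored as
#'   data frames).
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "takeover_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  out <- jsonlite::fromJSON(path)
  class(out) <- "takeover_report"
  out
}
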