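# Internal helpers shared across the package.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_takeovr <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "takeovr_error"), ...)
}

check_binary_outcome <- function(y, arg = "success") {
  if (length(y) == 0L || anyNA(y) || !all(y %in% c(0, 1))) {
    abort_takeovr(
      sprintf("`%s` must contain only 0 (collision) and 1 (no collision).", arg),
      class = "takeovr_error_outcome"
    )
  }
  invisible(as.integer(y))
}

check_both_classes <- function(y, context = "outcome") {
  if (length(unique(y)) < 2L) {
    abort_takeovr(
      sprintf("Both outcome classes must be present in the %s.", context),
      class = "takeovr_error_single_class"
    )
  }
  invisible(y)
}

# Resolve a character vector of predictor names against the columns of `data`,
# defaulting to every numeric column that is not the outcome or an id.
resolve_predictors <- function(data, predictors = NULL, outcome = "success") {
  if (is.null(predictors)) {
    predictors <- setdiff(names(data), c(outcome, "participant_id"))
    predictors <- predictors[vapply(data[predictors], is.numeric, logical(1))]
  }
  missing <- setdiff(predictors, names(data))
  if (length(missing) > 0L) {
    abort_takeovr(
      sprintf("Predictor column(s) not found: %s.", paste(missing, collapse = ", ")),
      class = "takeovr_error_missing_column"
    )
  }
  predictors
}

as_predictor_matrix <- function(data, predictors) {
  X <- as.matrix(data[predictors])
  if (!is.numeric(X) || anyNA(X) || any(!is.finite(X))) {
    abort_takeovr(
      "Predictor columns must be numeric and finite with no missing values.",
      class = "takeovr_error_nonfinite"
    )
  }
  storage.mode(X) <- "double"
  X
}

# Stable integer-valued bitmask (as double, safe for p <= 20) identifying a
# predictor subset by its catalogue positions.
subset_bitmask <- function(idx) sum(2^(sort(idx) - 1))
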