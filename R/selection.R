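# Leave-one-out evaluation, the Minimax selection rule, component-count
# selection and exhaustive predictor-subset search.
#
# A "false positive" is a predicted success for a participant who collided;
# a "false negative" is a predicted failure for a participant who succeeded.
# The Minimax rule picks the candidate minimising max(FP, FN), breaking ties
# by total errors, then (to make the artifact deterministic) by fewer
# predictors, smaller component count, and lowest subset bitmask.

# Precompute, for every leave-one-out fold, the training-standardized
# predictor matrix and the standardized held-out row. Standardization is
# per-column, so a column subset of the cached fold equals what fold-local
# standardization of that subset would give — results are identical to the
# naive loop, only cheaper.
loo_cache_build <- function(X, y) {
  n <- nrow(X)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    mu <- colMeans(Xtr)
    sd_ <- sqrt(colSums(sweep(Xtr, 2, mu, "-")^2) / (nrow(Xtr) - 1))
    Xs <- sweep(sweep(Xtr, 2, mu, "-"), 2, sd_, "/")
    folds[[i]] <- list(Xs = Xs, xh = (X[i, ] - mu) / sd_, sd = sd_,
                       ytr = y[-i])
  }
  list(folds = folds, y = y, n = n, p = ncol(X))
}

loo_evaluate_cached <- function(cache, subset_idx, H) {
  fp <- 0L
  fn <- 0L
  H_eff <- min(H, length(subset_idx))
  for (i in seq_len(cache$n)) {
    f <- cache$folds[[i]]
    if (any(f$sd[subset_idx] == 0)) {
      abort_takeovr(
        sprintf("Zero-variance predictor in training fold %d.", i),
        class = "takeovr_error_zero_variance"
      )
    }
    if (length(unique(f$ytr)) < 2L) {
      abort_takeovr(
        sprintf("Training fold %d contains a single outcome class.", i),
        class = "takeovr_error_single_class"
      )
    }
    core <- pls_glr_core(f$Xs[, subset_idx, drop = FALSE], f$ytr, H_eff)
    eta <- core$gamma0 + sum(f$xh[subset_idx] * core$beta)
    pred <- as.integer(stats::plogis(eta) >= 0.5)
    truth <- cache$y[i]
    if (pred == 1L && truth == 0L) fp <- fp + 1L
    if (pred == 0L && truth == 1L) fn <- fn + 1L
  }
  list(fp = fp, fn = fn, h = H_eff)
}

#' Leave-one-out evaluation of one candidate model
#'
#' For each participant in turn: the PLS logistic model is fitted on the
#' other `n - 1` rows (standardization recomputed on the training fold), the
#' held-out row is standardized with the fold's parameters, predicted, and
#' classified at 0.5. False positives and false negatives are tallied over
#' all `n` folds.
#'
#' @param data Abilities tibble (oriented raw units) with the outcome column.
#' @param predictors Character vector naming the candidate predictor subset.
#' @param outcome Binary 0/1 outcome column name.
#' @param n_components Component count `H` (capped at the subset size).
#' @param catalogue_names Optional full predictor catalogue order used to
#'   compute the subset bitmask; defaults to `predictors`.
#'
#' @return One-row tibble: `subset` (comma-joined names), `bitmask`,
#'   `n_predictors`, `h`, `fp`, `fn`, `max_errors`, `total_errors`.
#' @export
loo_evaluate <- function(data, predictors = NULL, outcome = "success",
                         n_components = 1L, catalogue_names = NULL) {
  predictors <- resolve_predictors(data, predictors, outcome)
  y <- check_binary_outcome(data[[outcome]], outcome)
  X <- as_predictor_matrix(data, predictors)
  cache <- loo_cache_build(X, y)
  res <- loo_evaluate_cached(cache, seq_along(predictors), n_components)
  catalogue_names <- catalogue_names %||% predictors
  idx <- match(predictors, catalogue_names)
  loo_row(predictors, idx, res)
}

loo_row <- function(names_, idx, res) {
  tibble::tibble(
    subset = paste(names_, collapse = ","),
    bitmask = subset_bitmask(idx),
    n_predictors = length(names_),
    h = res$h,
    fp = res$fp,
    fn = res$fn,
    max_errors = max(res$fp, res$fn),
    total_errors = res$fp + res$fn
  )
}

#' Minimax selection among leave-one-out evaluations
#'
#' Selects the candidate minimising `max(FP, FN)`; ties are broken by lower
#' total errors, then fewer predictors, then smaller component count, then
#' lowest bitmask, giving a deterministic total order. The criteria actually
#' consulted are recorded in the `tie_break_trail` attribute.
#'
#' @param candidates Tibble with at least `max_errors` and `total_errors`
#'   columns (as produced by [loo_evaluate()]); optional `n_predictors`,
#'   `h`, `bitmask` columns join the tie-break cascade; an optional logical
#'   `eligible` column excludes failed evaluations.
#' @return The selected one-row tibble, with attribute `tie_break_trail`.
#' @export
minimax_select <- function(candidates) {
  if (!is.data.frame(candidates) || nrow(candidates) == 0L) {
    abort_takeovr("`candidates` must be a non-empty data frame.",
                  class = "takeovr_error_validation")
  }
  pool <- candidates
  if ("eligible" %in% names(pool)) pool <- pool[isTRUE_vec(pool$eligible), ]
  if (nrow(pool) == 0L) {
    abort_takeovr("No eligible candidate remains.",
                  class = "takeovr_error_validation")
  }
  trail <- character(0)
  stages <- list(
    max_errors = "minimax: min max(FP, FN)",
    total_errors = "tie-break: min total errors",
    n_predictors = "tie-break: fewer predictors",
    h = "tie-break: smaller component count",
    bitmask = "tie-break: lowest bitmask"
  )
  for (col in names(stages)) {
    if (nrow(pool) == 1L) break
    if (!col %in% names(pool)) next
    trail <- c(trail, stages[[col]])
    pool <- pool[pool[[col]] == min(pool[[col]]), , drop = FALSE]
  }
  selected <- pool[1L, , drop = FALSE]
  attr(selected, "tie_break_trail") <- trail
  selected
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Select the number of PLS components by leave-one-out Minimax
#'
#' Evaluates the full predictor set for `H = 1, ..., h_max` and applies
#' [minimax_select()]: the component count with the smallest worst error
#' type wins, ties going to the smaller total error count (and then to the
#' smaller `H`).
#'
#' @inheritParams loo_evaluate
#' @param h_max Largest component count to consider (at most the number of
#'   predictors).
#' @return A list of class `component_selection`: `selected_h`, `selected`
#'   (one-row tibble) and `candidates` (one row per `H`).
#' @export
select_n_components <- function(data, predictors = NULL, outcome = "success",
                                h_max = NULL) {
  predictors <- resolve_predictors(data, predictors, outcome)
  h_max <- as.integer(h_max %||% length(predictors))
  if (h_max > length(predictors)) {
    abort_takeovr("`h_max` cannot exceed the number of predictors.",
                  class = "takeovr_error_validation")
  }
  y <- check_binary_outcome(data[[outcome]], outcome)
  X <- as_predictor_matrix(data, predictors)
  cache <- loo_cache_build(X, y)
  rows <- purrr::map(seq_len(h_max), function(h) {
    res <- loo_evaluate_cached(cache, seq_along(predictors), h)
    loo_row(predictors, seq_along(predictors), res)
  })
  candidates <- dplyr::bind_rows(rows)
  selected <- minimax_select(candidates)
  structure(
    list(selected_h = selected$h, selected = selected,
         candidates = candidates),
    class = "component_selection"
  )
}

#' @export
print.component_selection <- function(x, ...) {
  cat(sprintf("Component-count selection (leave-one-out Minimax): H = %d\n",
              x$selected_h))
  print(x$candidates[c("h", "fp", "fn", "max_errors", "total_errors")], ...)
  invisible(x)
}

#' Exhaustive predictor-subset search
#'
#' Enumerates every non-empty subset of the candidate predictors
#' (`2^p - 1` models), evaluates each by leave-one-out ([loo_evaluate()])
#' at the given component count (capped at the subset size), and selects by
#' [minimax_select()]. Subsets whose evaluation fails (e.g. a single-class
#' training fold) are kept in the table but marked ineligible.
#'
#' @inheritParams loo_evaluate
#' @param n_components Component count applied to every subset (capped at
#'   the subset size).
#' @param max_predictors Enumeration cap; searching more than this many
#'   predictors requires raising the cap explicitly.
#' @param progress Print a progress line every 500 subsets.
#'
#' @return A list of class `subset_search`: `selected` (one-row tibble with
#'   tie-break trail), `evaluations` (all `2^p - 1` rows, ranked), and the
#'   call parameters.
#' @export
exhaustive_subset_search <- function(data, predictors = NULL,
                                     outcome = "success", n_components = 1L,
                                     max_predictors = 20L, progress = FALSE) {
  predictors <- resolve_predictors(data, predictors, outcome)
  p <- length(predictors)
  if (p > max_predictors) {
    abort_takeovr(
      sprintf(paste0("Refusing to enumerate 2^%d - 1 subsets; raise ",
                     "`max_predictors` (currently %d) to override."),
              p, max_predictors),
      class = "takeovr_error_cap"
    )
  }
  y <- check_binary_outcome(data[[outcome]], outcome)
  X <- as_predictor_matrix(data, predictors)
  cache <- loo_cache_build(X, y)
  n_subsets <- 2^p - 1
  rows <- vector("list", n_subsets)
  for (m in seq_len(n_subsets)) {
    idx <- which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0)
    res <- tryCatch(
      loo_evaluate_cached(cache, idx, n_components),
      takeovr_error = function(e) NULL
    )
    if (is.null(res)) {
      row <- loo_row(predictors[idx], idx,
                     list(fp = NA_integer_, fn = NA_integer_,
                          h = min(n_components, length(idx))))
      row$max_errors <- NA_integer_
      row$total_errors <- NA_integer_
      row$eligible <- FALSE
    } else {
      row <- loo_row(predictors[idx], idx, res)
      row$eligible <- TRUE
    }
    rows[[m]] <- row
    if (progress && m %% 500L == 0L) {
      message(sprintf("  evaluated %d / %d subsets", m, n_subsets))
    }
  }
  evaluations <- dplyr::bind_rows(rows)
  selected <- minimax_select(evaluations)
  ranked <- dplyr::arrange(
    evaluations, dplyr::desc(.data$eligible), .data$max_errors,
    .data$total_errors, .data$n_predictors, .data$h, .data$bitmask
  )
  structure(
    list(selected = selected, evaluations = ranked,
         n_components = n_components, predictors = predictors),
    class = "subset_search"
  )
}

#' @export
print.subset_search <- function(x, ...) {
  cat(sprintf(
    "Exhaustive subset search: %d candidate models over %d predictors (H = %d)\n",
    nrow(x$evaluations), length(x$predictors), x$n_components))
  cat("Selected (Minimax):\n")
  print(x$selected, ...)
  invisible(x)
}

#' @describeIn exhaustive_subset_search All evaluations as a ranked tibble.
#' @param x A `subset_search` object.
#' @param ... Unused.
#' @export
tidy.subset_search <- function(x, ...) x$evaluations

#' Write subset-search results
#'
#' The full ranked table goes to delimited text; the selected model summary
#' to JSON alongside it.
#'
#' @param x A `subset_search` result.
#' @param path Output path for the table (`.tsv`); the JSON summary is
#'   written next to it with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_search_results <- function(x, path) {
  stopifnot(inherits(x, "subset_search"))
  readr::write_tsv(x$evaluations, path, progress = FALSE)
  summary_path <- sub("\\.[^.]*$", ".json", path)
  jsonlite::write_json(
    as.list(x$selected), summary_path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Error profile of the subset search
#'
#' @param object A `subset_search` result.
#' @param ... Unused.
#' @return A ggplot of the best achievable `max(FP, FN)` by subset size.
#' @export
autoplot.subset_search <- function(object, ...) {
  best <- object$evaluations |>
    dplyr::filter(.data$eligible) |>
    dplyr::group_by(.data$n_predictors) |>
    dplyr::summarise(best_max = min(.data$max_errors), .groups = "drop")
  ggplot2::ggplot(best, ggplot2::aes(.data$n_predictors, .data$best_max)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "predictors in subset",
                  y = "best max(FP, FN) under leave-one-out",
                  title = "Minimax error by subset size") +
    ggplot2::theme_minimal()
}
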