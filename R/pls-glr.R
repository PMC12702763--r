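# PLS logistic regression for a binary outcome.
#
# Component construction follows the generalized-linear PLS scheme: the
# first component's weights are the (unit-normalised) slopes of the p
# univariate logistic regressions of y on each standardized predictor; later
# components deflate each predictor by OLS on the earlier components and
# take, as the weight for predictor j, the coefficient of its deflated
# column in a logistic regression of y on (t_1, ..., t_{h-1}, deflated x_j).
# A final logistic regression of y on the components gives the
# component-space coefficients gamma; the adjusted weights W* (absorbing
# deflation) express the components over the original standardized
# predictors, so that gamma_0 + sum_h gamma_h t_h = gamma_0 + sum_j beta_j
# x_j identically.

# Core fit on an already-standardized matrix. Returns bare lists; the
# user-facing wrapper adds tibbles and classes. Kept lean because
# leave-one-out evaluation calls it n times per candidate model.
pls_glr_core <- function(Xs, y, H) {
  n <- nrow(Xs)
  p <- ncol(Xs)
  if (H < 1L || H > p) {
    abort_takeovr("`n_components` must lie between 1 and the number of predictors.",
                  class = "takeovr_error_validation")
  }
  check_both_classes(y, "training data")
  if (n <= H + 1L) {
    abort_takeovr("Need more rows than components + 1.",
                  class = "takeovr_error_validation")
  }
  W <- matrix(0, p, H)    # weights on deflated predictors, unit norm
  Rmat <- matrix(0, p, H) # adjusted weights W*: T = Xs %*% Rmat
  Tm <- matrix(0, n, H)   # components
  Pm <- matrix(0, p, H)   # loadings of original X on components
  stabilized <- FALSE
  Xd <- Xs
  for (h in seq_len(H)) {
    if (h == 1L) {
      uni <- uni_logistic_slopes(Xd, y)
      slopes <- uni$slope
      stabilized <- stabilized || uni$stabilized
    } else {
      slopes <- numeric(p)
      Tprev <- Tm[, seq_len(h - 1L), drop = FALSE]
      for (j in seq_len(p)) {
        xj <- Xd[, j]
        # a column fully explained by earlier components carries no
        # additional information: weight 0
        if (sqrt(sum(xj^2) / (n - 1)) < 1e-10) next
        fit <- logistic_irls(cbind(Tprev, xj), y)
        slopes[j] <- fit$coef[h + 1L]
        stabilized <- stabilized || fit$stabilized
      }
    }
    nrm <- sqrt(sum(slopes^2))
    if (!is.finite(nrm) || nrm < 1e-12) {
      abort_takeovr(
        sprintf("Degenerate component %d: all candidate weights vanish.", h),
        class = "takeovr_error_fit"
      )
    }
    w <- slopes / nrm
    t_h <- drop(Xd %*% w)
    W[, h] <- w
    Tm[, h] <- t_h
    # adjusted weight: t_h = Xs r_h, with r_h = w_h - sum_{l<h} r_l (p_l' w_h)
    r_h <- w
    if (h > 1L) {
      for (l in seq_len(h - 1L)) {
        r_h <- r_h - Rmat[, l] * sum(Pm[, l] * w)
      }
    }
    Rmat[, h] <- r_h
    Pm[, h] <- crossprod(Xs, t_h) / sum(t_h^2)
    if (h < H) Xd <- Xs - Tm[, seq_len(h), drop = FALSE] %*%
                        t(Pm[, seq_len(h), drop = FALSE])
  }
  final <- logistic_irls(Tm, y)
  gamma <- final$coef
  beta <- drop(Rmat %*% gamma[-1L])
  eta <- gamma[1L] + drop(Tm %*% gamma[-1L])
  list(
    W = W, R = Rmat, P = Pm, Tmat = Tm,
    gamma0 = gamma[1L], gamma = gamma[-1L], beta = beta,
    fitted = stats::plogis(eta),
    stabilized = stabilized || final$stabilized,
    iterations = final$iterations
  )
}

#' Fit a PLS logistic regression
#'
#' Fits a partial least squares logistic regression of a binary take-over
#' outcome on a set of oriented ability predictors. Predictors are
#' standardized internally (mean 0, SD 1, divisor `n - 1`); coefficients are
#' therefore per-SD and `exp(beta)` is the success-odds multiplier for a
#' 1-SD increase in that ability ([interpret_coefficient()]).
#'
#' @param data A tibble with the predictor columns and the outcome column.
#' @param predictors Character vector of predictor names; defaults to every
#'   numeric column except `participant_id` and the outcome.
#' @param outcome Name of the binary 0/1 outcome column.
#' @param n_components Number of PLS components `H`.
#'
#' @return An object of class `pls_glr`: weights `W` (unit-norm, one column
#'   per component), adjusted weights `W_star`, component coefficients
#'   `gamma0`/`gamma`, per-predictor standardized coefficients `beta`,
#'   the training standardization parameters, fitted probabilities and
#'   bookkeeping fields. Supports [predict()][predict.pls_glr()],
#'   [tidy()][tidy.pls_glr()], [glance()][glance.pls_glr()] and
#'   [autoplot()][autoplot.pls_glr()].
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_participants = 150, seed = 2))
#' fit <- fit_pls_logistic(cohort$data, n_components = 1)
#' tidy(fit)
fit_pls_logistic <- function(data, predictors = NULL, outcome = "success",
                             n_components = 1L) {
  predictors <- resolve_predictors(data, predictors, outcome)
  y <- check_binary_outcome(data[[outcome]], outcome)
  X <- as_predictor_matrix(data, predictors)
  std <- standardize_abilities(data[predictors], predictors = predictors)
  Xs <- as.matrix(std$data[predictors])
  core <- pls_glr_core(Xs, y, as.integer(n_components))
  structure(
    list(
      predictors = predictors,
      outcome = outcome,
      n_components = as.integer(n_components),
      W = `dimnames<-`(core$W, list(predictors, NULL)),
      W_star = `dimnames<-`(core$R, list(predictors, NULL)),
      gamma0 = core$gamma0,
      gamma = core$gamma,
      beta = stats::setNames(core$beta, predictors),
      std_params = std$params,
      fitted = core$fitted,
      y = y,
      stabilized = core$stabilized,
      n = nrow(X)
    ),
    class = "pls_glr"
  )
}

#' Predict success probabilities from a fitted PLS logistic model
#'
#' New rows are standardized with the model's training parameters before the
#' components are formed, so predictions are valid for raw oriented units.
#'
#' @param object A `pls_glr` fit.
#' @param newdata Tibble containing the model's predictor columns (raw
#'   oriented units).
#' @param type `"prob"` for success probabilities, `"class"` for hard 0/1
#'   calls at `threshold`.
#' @param threshold Classification threshold (probability at the boundary is
#'   assigned to success).
#' @param ... Unused.
#' @return Numeric vector of probabilities, or integer 0/1 classes.
#' @export
predict.pls_glr <- function(object, newdata, type = c("prob", "class"),
                            threshold = 0.5, ...) {
  type <- match.arg(type)
  missing <- setdiff(object$predictors, names(newdata))
  if (length(missing) > 0L) {
    abort_takeovr(
      sprintf("Predictor column(s) missing from `newdata`: %s.",
              paste(missing, collapse = ", ")),
      class = "takeovr_error_missing_column"
    )
  }
  X <- as_predictor_matrix(newdata, object$predictors)
  Xs <- sweep(sweep(X, 2, object$std_params$mean, "-"),
              2, object$std_params$sd, "/")
  eta <- object$gamma0 + drop(Xs %*% object$beta)
  p <- stats::plogis(eta)
  if (type == "prob") p else classify(p, threshold)
}

#' Hard classification of success probabilities
#'
#' @param p Probabilities in `[0, 1]`.
#' @param threshold Decision threshold; `p >= threshold` is called a success
#'   (the boundary goes to success).
#' @return Integer vector of 0/1 calls.
#' @export
classify <- function(p, threshold = 0.5) {
  stopifnot(all(p >= 0 & p <= 1))
  as.integer(p >= threshold)
}

#' Interpret per-SD logistic coefficients
#'
#' `exp(beta)` multiplies the predicted success odds when the ability rises
#' by one training-sample SD, everything else held fixed; the percent change
#' is reported rounded to the nearest integer.
#'
#' @param beta Numeric vector of standardized-scale coefficients.
#' @return Tibble with `beta`, `multiplier` (`exp(beta)`) and
#'   `percent_change` (rounded integer percent).
#' @export
#' @examples
#' interpret_coefficient(c(0.35, -0.42))
interpret_coefficient <- function(beta) {
  stopifnot(all(is.finite(beta)))
  tibble::tibble(
    beta = as.numeric(beta),
    multiplier = exp(beta),
    percent_change = round(100 * (exp(beta) - 1))
  )
}

#' @export
print.pls_glr <- function(x, ...) {
  cat(sprintf("PLS logistic regression: %d component(s), %d predictor(s), n = %d\n",
              x$n_components, length(x$predictors), x$n))
  if (x$stabilized) cat("  (ridge-stabilized inner fit)\n")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a PLS logistic fit
#'
#' @param x A `pls_glr` object.
#' @param ... Unused.
#' @return One row per predictor: `term`, first-component weight `weight`,
#'   standardized coefficient `beta`, odds `multiplier` and rounded
#'   `percent_change`.
#' @export
tidy.pls_glr <- function(x, ...) {
  interp <- interpret_coefficient(x$beta)
  tibble::tibble(
    term = x$predictors,
    weight = x$W[, 1L],
    beta = interp$beta,
    multiplier = interp$multiplier,
    percent_change = interp$percent_change
  )
}

#' Summarise a PLS logistic fit in one row
#'
#' @inheritParams tidy.pls_glr
#' @return One-row tibble: `n`, `n_predictors`, `n_components`, in-sample
#'   `accuracy`, `deviance`, and whether the inner solver needed ridge
#'   stabilization.
#' @export
glance.pls_glr <- function(x, ...) {
  acc <- dev <- NA_real_
  if (!is.null(x$fitted) && !is.null(x$y)) {
    acc <- mean(classify(x$fitted) == x$y)
    dev <- -2 * sum(x$y * log(x$fitted) + (1 - x$y) * log1p(-x$fitted))
  }
  tibble::tibble(
    n = x$n,
    n_predictors = length(x$predictors),
    n_components = x$n_components,
    accuracy = acc,
    deviance = dev,
    stabilized = x$stabilized
  )
}

#' Serialise a fitted model to JSON (and back)
#'
#' Weights, coefficients, standardization parameters and the predictor
#' subset are written at 17 significant digits, so a round trip reproduces
#' the model to printed precision.
#'
#' @param model A `pls_glr` fit.
#' @param path File path.
#' @return `read_pls_model()` returns the reconstructed `pls_glr` object.
#' @export
write_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls_glr"))
  payload <- list(
    predictors = model$predictors,
    outcome = model$outcome,
    n_components = model$n_components,
    subset_bitmask = NULL,
    W = model$W,
    W_star = model$W_star,
    gamma0 = model$gamma0,
    gamma = model$gamma,
    beta = as.numeric(model$beta),
    std_mean = model$std_params$mean,
    std_sd = model$std_params$sd,
    stabilized = model$stabilized,
    n = model$n
  )
  writeLines(
    jsonlite::toJSON(payload, digits = 17, auto_unbox = TRUE, null = "null"),
    path
  )
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  raw <- jsonlite::fromJSON(readLines(path, warn = FALSE))
  W <- matrix(unlist(raw$W), ncol = raw$n_components)
  Ws <- matrix(unlist(raw$W_star), ncol = raw$n_components)
  rownames(W) <- rownames(Ws) <- raw$predictors
  structure(
    list(
      predictors = raw$predictors,
      outcome = raw$outcome,
      n_components = as.integer(raw$n_components),
      W = W, W_star = Ws,
      gamma0 = raw$gamma0,
      gamma = as.numeric(raw$gamma),
      beta = stats::setNames(as.numeric(raw$beta), raw$predictors),
      std_params = tibble::tibble(variable = raw$predictors,
                                  mean = raw$std_mean, sd = raw$std_sd),
      fitted = NULL,
      stabilized = isTRUE(raw$stabilized),
      n = as.integer(raw$n)
    ),
    class = "pls_glr"
  )
}

#' Coefficient plot for a PLS logistic fit
#'
#' @param object A `pls_glr` fit.
#' @param ... Unused.
#' @return A ggplot: per-predictor standardized coefficients, signed bars.
#' @export
autoplot.pls_glr <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(
    x = stats::reorder(.data$term, .data$beta), y = .data$beta,
    fill = .data$beta > 0
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "standardized coefficient (per SD)",
      title = "PLS logistic regression coefficients"
    ) +
    ggplot2::theme_minimal()
}
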