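# Synthetic-cohort generator: equicorrelated Gaussian abilities driving a
# binary take-over outcome through a logistic link.

#' Configuration for a synthetic cohort
#'
#' Defaults reproduce the study conditions the pipeline is designed for:
#' 113 participants, 15 standardized predictors with a common pairwise
#' correlation, a single latent structure in which five active predictors —
#' the Corsi span, visuomanual-coordination score, annual mileage,
#' stop-signal reaction time and flanker accuracy columns of
#' [default_ability_catalogue()] — carry effects
#' `(+0.45, +0.35, +0.22, -0.42, -0.36)` on the standardized scale, and a
#' marginal success rate of 63/113.
#'
#' @param n_participants Cohort size.
#' @param n_predictors Number of ability columns.
#' @param active_set Indices (into the predictor columns) with nonzero
#'   effect.
#' @param effect_vector Per-active-predictor logistic coefficients on the
#'   standardized scale.
#' @param target_success_rate Desired marginal `P(success)`.
#' @param rho Common pairwise predictor correlation in `[0, 1)`.
#' @param seed Integer seed; identical configs give identical cohorts.
#'
#' @return A list with class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 113L,
                          n_predictors = 15L,
                          active_set = c(9L, 4L, 2L, 10L, 11L),
                          effect_vector = c(0.45, 0.35, 0.22, -0.42, -0.36),
                          target_success_rate = 63 / 113,
                          rho = 0.2,
                          seed = 1L) {
  if (length(active_set) != length(effect_vector)) {
    abort_takeovr("`active_set` and `effect_vector` lengths must match.",
                  class = "takeovr_error_config")
  }
  if (n_predictors < length(active_set) || any(active_set > n_predictors) ||
      any(active_set < 1)) {
    abort_takeovr("`active_set` must index into the predictor columns.",
                  class = "takeovr_error_config")
  }
  if (rho < 0 || rho >= 1) {
    # equicorrelation with a common positive factor; rho < 0 would need
    # -1/(p-1) < rho, not supported here
    abort_takeovr("`rho` must lie in [0, 1).", class = "takeovr_error_config")
  }
  if (target_success_rate <= 0 || target_success_rate >= 1) {
    abort_takeovr("`target_success_rate` must lie in (0, 1).",
                  class = "takeovr_error_config")
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_predictors = as.integer(n_predictors),
      active_set = as.integer(active_set),
      effect_vector = as.numeric(effect_vector),
      target_success_rate = target_success_rate,
      rho = rho,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Intercept achieving a target marginal success rate
#'
#' With standardized equicorrelated Gaussian predictors the linear predictor
#' `s = sum(beta_j x_j)` is Gaussian with variance
#' `(1 - rho) * sum(beta^2) + rho * sum(beta)^2`. The intercept `alpha` is
#' found by root-finding on `E[plogis(alpha + s)] = target`, the expectation
#' evaluated by adaptive quadrature over the Gaussian density.
#'
#' @param effect_vector Active-predictor coefficients.
#' @param rho Common pairwise predictor correlation.
#' @param target_success_rate Target marginal success probability.
#' @return The intercept `alpha` (achieved rate within 1e-3 of target).
#' @export
intercept_for_rate <- function(effect_vector, rho, target_success_rate) {
  s2 <- (1 - rho) * sum(effect_vector^2) + rho * sum(effect_vector)^2
  if (s2 < 1e-12) return(stats::qlogis(target_success_rate))
  sigma <- sqrt(s2)
  expected_rate <- function(alpha) {
    stats::integrate(
      function(z) stats::plogis(alpha + sigma * z) * stats::dnorm(z),
      lower = -Inf, upper = Inf, rel.tol = 1e-10
    )$value
  }
  f <- function(alpha) expected_rate(alpha) - target_success_rate
  root <- tryCatch(
    stats::uniroot(f, interval = c(-30, 30), tol = 1e-9),
    error = function(e) abort_takeovr(
      "No intercept in [-30, 30] achieves the target success rate.",
      class = "takeovr_error_numeric"
    )
  )
  root$root
}

#' Generate a synthetic abilities cohort
#'
#' Predictors are drawn from a zero-mean, unit-variance equicorrelated
#' multivariate normal (a single shared factor plus independent noise);
#' the outcome is Bernoulli with `P(success) = plogis(alpha + X_active %*%
#' beta)`, where `alpha` is solved by [intercept_for_rate()] so the expected
#' success rate equals the configured target. One seeded stream drives all
#' randomness: the Gaussian block first, the Bernoulli draws after it.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `data` (tibble:
#'   `participant_id`, predictor columns, `success`), `alpha`, `beta`
#'   (length `n_predictors`, zeros off the active set), `linear_predictor`,
#'   and `config`. When `n_predictors` is 15 the columns carry the
#'   [default_ability_catalogue()] names; otherwise `ability_01`, ....
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 7))
#' mean(cohort$data$success)
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  p <- config$n_predictors
  beta <- numeric(p)
  beta[config$active_set] <- config$effect_vector
  alpha <- intercept_for_rate(config$effect_vector, config$rho,
                              config$target_success_rate)

  rng <- local({
    set.seed(config$seed)
    NULL
  })
  # shared-factor construction gives the exact equicorrelation rho
  g <- stats::rnorm(n)
  E <- matrix(stats::rnorm(n * p), n, p)
  X <- sqrt(config$rho) * g + sqrt(1 - config$rho) * E
  eta <- alpha + drop(X %*% beta)
  y <- as.integer(stats::runif(n) < stats::plogis(eta))

  names_ <- if (p == nrow(default_ability_catalogue()))
    default_ability_catalogue()$name else sprintf("ability_%02d", seq_len(p))
  colnames(X) <- names_
  data <- dplyr::bind_cols(
    tibble::tibble(participant_id = sprintf("S%04d", seq_len(n))),
    tibble::as_tibble(X),
    tibble::tibble(success = y)
  )
  structure(
    list(data = data, alpha = alpha, beta = stats::setNames(beta, names_),
         linear_predictor = eta, config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic take-over cohort: %d participants, %d predictors, %d active\n",
    x$config$n_participants, x$config$n_predictors,
    length(x$config$active_set)
  ))
  cat(sprintf("  observed success rate %.3f (target %.3f), seed %d\n",
              mean(x$data$success), x$config$target_success_rate,
              x$config$seed))
  invisible(x)
}
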