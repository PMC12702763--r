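# Internal maximum-likelihood logistic solvers used to build PLS components.
#
# Two routines: a general Newton/IRLS fit for small multi-column designs, and
# a vectorised solver that fits all p univariate (intercept + slope) logistic
# regressions of y on each column of X simultaneously — the inner loop of
# component construction and of leave-one-out evaluation, so it is written
# for speed (column-parallel 2x2 Newton updates, no model objects).
#
# Both run plain Newton first (equivalent to IRLS; convergence when the
# largest coefficient step falls below 1e-8, at most 100 iterations). A fit
# that fails to converge — in practice (quasi-)separation — is retried with
# a small ridge added to the normal equations (gradient and Hessian both
# penalised, so the iteration targets the finite ridge optimum), escalating
# the ridge if needed, and the result is flagged as stabilized. Steps are
# capped in sup-norm so the saturated region cannot throw the iteration.

MIN_IRLS_WEIGHT <- 1e-10
RIDGE_LADDER <- c(1e-6, 1e-4, 1e-2)
MAX_NEWTON_STEP <- 10

# Newton fit of y ~ 1 + X. Returns list(coef, converged, stabilized,
# iterations); errors if even the largest ridge fails.
logistic_irls <- function(X, y, tol = 1e-8, max_iter = 100L) {
  Xd <- cbind(1, X)
  q <- ncol(Xd)
  run <- function(ridge) {
    beta <- numeric(q)
    for (it in seq_len(max_iter)) {
      eta <- drop(Xd %*% beta)
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), MIN_IRLS_WEIGHT)
      g <- drop(crossprod(Xd, y - mu)) - ridge * beta
      H <- crossprod(Xd * sqrt(w))
      if (ridge > 0) diag(H) <- diag(H) + ridge
      step <- tryCatch(drop(solve(H, g)), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) {
        return(list(coef = beta, converged = FALSE, iterations = it))
      }
      sup <- max(abs(step))
      if (sup > MAX_NEWTON_STEP) step <- step * MAX_NEWTON_STEP / sup
      beta <- beta + step
      if (max(abs(step)) < tol) {
        return(list(coef = beta, converged = TRUE, iterations = it))
      }
    }
    list(coef = beta, converged = FALSE, iterations = max_iter)
  }
  fit <- run(0)
  if (fit$converged) {
    return(list(coef = fit$coef, converged = TRUE, stabilized = FALSE,
                iterations = fit$iterations))
  }
  for (ridge in RIDGE_LADDER) {
    fit <- run(ridge)
    if (fit$converged) {
      return(list(coef = fit$coef, converged = TRUE, stabilized = TRUE,
                  iterations = fit$iterations))
    }
  }
  abort_takeovr(
    "Inner logistic solver failed to converge even after ridge stabilization.",
    class = "takeovr_error_fit"
  )
}

# All-columns univariate logistic slopes: fits y ~ 1 + X[, j] for every j by
# column-parallel Newton steps with closed-form 2x2 solves. Returns
# list(slope, intercept, stabilized).
uni_logistic_slopes <- function(X, y, tol = 1e-8, max_iter = 100L) {
  n <- nrow(X)
  p <- ncol(X)
  a0 <- stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
  run <- function(ridge, active) {
    a <- rep(a0, p)
    b <- numeric(p)
    done <- !active
    for (it in seq_len(max_iter)) {
      eta <- X * rep(b, each = n) + rep(a, each = n)
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), MIN_IRLS_WEIGHT)
      r <- y - mu
      g1 <- colSums(r) - ridge * a
      g2 <- colSums(X * r) - ridge * b
      s11 <- colSums(w) + ridge
      s12 <- colSums(w * X)
      s22 <- colSums(w * X * X) + ridge
      det <- s11 * s22 - s12^2
      det[det < 1e-300 | !is.finite(det)] <- NA_real_
      da <- (s22 * g1 - s12 * g2) / det
      db <- (-s12 * g1 + s11 * g2) / det
      sup <- pmax(abs(da), abs(db))
      shrink <- ifelse(sup > MAX_NEWTON_STEP, MAX_NEWTON_STEP / sup, 1)
      da <- da * shrink
      db <- db * shrink
      da[done | is.na(da)] <- 0
      db[done | is.na(db)] <- 0
      a <- a + da
      b <- b + db
      done <- done | (pmax(abs(da), abs(db)) < tol & !is.na(det))
      if (all(done)) break
    }
    list(a = a, b = b, converged = done, finite = is.finite(b))
  }
  fit <- run(0, rep(TRUE, p))
  bad <- !fit$converged | !fit$finite
  stabilized <- FALSE
  for (ridge in RIDGE_LADDER) {
    if (!any(bad)) break
    refit <- run(ridge, bad)
    fit$a[bad] <- refit$a[bad]
    fit$b[bad] <- refit$b[bad]
    bad <- bad & (!refit$converged | !refit$finite)
    stabilized <- TRUE
  }
  if (any(bad)) {
    abort_takeovr(
      "Univariate logistic fit failed to converge after ridge stabilization.",
      class = "takeovr_error_fit"
    )
  }
  list(slope = fit$b, intercept = fit$a, stabilized = stabilized)
}
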