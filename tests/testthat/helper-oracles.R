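# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately use different code paths from the package:
# stats::glm for logistic fits, plain loops and order() scans elsewhere.

# One-component PLS logistic regression written from the algorithm's
# definition using stats::glm throughout, with fold-local standardization
# and a full leave-one-out loop. Returns c(fp, fn).
oracle_loo_h1 <- function(X, y) {
  n <- nrow(X)
  fp <- fn <- 0L
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    mu <- colMeans(Xtr)
    sd_ <- apply(Xtr, 2, sd)
    Xs <- sweep(sweep(Xtr, 2, mu, "-"), 2, sd_, "/")
    w <- vapply(seq_len(ncol(Xs)), function(j) {
      suppressWarnings(
        coef(glm(ytr ~ Xs[, j], family = binomial,
                 control = glm.control(maxit = 100)))[2]
      )
    }, numeric(1))
    w <- w / sqrt(sum(w^2))
    t1 <- drop(Xs %*% w)
    fin <- suppressWarnings(glm(ytr ~ t1, family = binomial,
                                control = glm.control(maxit = 100)))
    th <- sum(((X[i, ] - mu) / sd_) * w)
    p <- plogis(coef(fin)[1] + coef(fin)[2] * th)
    pred <- as.integer(p >= 0.5)
    if (pred == 1L && y[i] == 0L) fp <- fp + 1L
    if (pred == 0L && y[i] == 1L) fn <- fn + 1L
  }
  c(fp = fp, fn = fn)
}

# Brute-force Minimax scan: a single order() call over the documented
# tie-break cascade.
oracle_minimax <- function(cand) {
  keys <- list(cand$max_errors, cand$total_errors)
  for (col in c("n_predictors", "h", "bitmask")) {
    if (col %in% names(cand)) keys <- c(keys, list(cand[[col]]))
  }
  cand[do.call(order, keys)[1], , drop = FALSE]
}

# Small logistic fixture: n rows, p standardized-ish Gaussian predictors,
# outcome through a logistic link. Returns a tibble with a success column.
make_logistic_fixture <- function(n, p, beta = NULL, intercept = 0.2,
                                  seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  beta <- beta %||% seq(0.6, 0.2, length.out = p) * rep_len(c(1, -1), p)
  y <- rbinom(n, 1, plogis(intercept + drop(X %*% beta)))
  # guard against degenerate draws in tiny fixtures
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  d <- tibble::as_tibble(as.data.frame(X))
  d$success <- y
  d
}

`%||%` <- function(x, y) if (is.null(x)) y else x
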