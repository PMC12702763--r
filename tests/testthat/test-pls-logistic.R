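test_that("one predictor, one component reproduces the univariate ML fit", {
  d <- make_logistic_fixture(70, 1, beta = 0.8, seed = 3)
  fit <- fit_pls_logistic(d, "x1", n_components = 1)
  oracle <- glm(success ~ scale(x1), data = d, family = binomial)
  expect_lt(max(abs(fit$fitted - fitted(oracle))), 1e-6)
})

test_that("orthogonal predictors with H = 2 reproduce the full ML fit", {
  set.seed(8)
  # exactly orthogonal standardized columns via QR
  Q <- qr.Q(qr(matrix(rnorm(60 * 2), 60, 2)))
  X <- scale(Q)
  y <- rbinom(60, 1, plogis(0.1 + X %*% c(0.9, -0.7)))
  d <- tibble::tibble(x1 = X[, 1], x2 = X[, 2], success = y)
  fit <- fit_pls_logistic(d, c("x1", "x2"), n_components = 2)
  oracle <- glm(success ~ scale(x1) + scale(x2), data = d, family = binomial)
  expect_lt(max(abs(fit$fitted - fitted(oracle))), 1e-4)
})

test_that("negating a predictor flips only its coefficient", {
  d <- make_logistic_fixture(90, 4, seed = 12)
  fit <- fit_pls_logistic(d, n_components = 2)
  d2 <- d
  d2$x3 <- -d2$x3
  fit2 <- fit_pls_logistic(d2, n_components = 2)
  expect_equal(unname(fit2$beta["x3"]), -unname(fit$beta["x3"]),
               tolerance = 1e-8)
  others <- setdiff(names(fit$beta), "x3")
  expect_equal(fit2$beta[others], fit$beta[others], tolerance = 1e-8)
  expect_lt(max(abs(fit2$fitted - fit$fitted)), 1e-8)
})

test_that("components are mutually orthogonal and weights unit-norm", {
  for (seed in c(4, 21, 33)) {
    d <- make_logistic_fixture(100, 5, seed = seed)
    fit <- fit_pls_logistic(d, n_components = 3)
    expect_equal(unname(colSums(fit$W^2)), rep(1, 3), tolerance = 1e-12)
    std <- standardize_abilities(d, paste0("x", 1:5))
    Tm <- as.matrix(std$data[paste0("x", 1:5)]) %*% fit$W_star
    ct <- cor(Tm)
    expect_lt(max(abs(ct[upper.tri(ct)])), 1e-8)
  }
})

test_that("component-space and predictor-space coefficients agree on every fit", {
  for (seed in c(2, 14)) {
    d <- make_logistic_fixture(80, 4, seed = seed)
    for (H in c(1, 2, 4)) {
      fit <- fit_pls_logistic(d, n_components = H)
      std <- standardize_abilities(d, paste0("x", 1:4))
      Xs <- as.matrix(std$data[paste0("x", 1:4)])
      eta_gamma <- fit$gamma0 + drop((Xs %*% fit$W_star) %*% fit$gamma)
      eta_beta <- fit$gamma0 + drop(Xs %*% fit$beta)
      expect_lt(max(abs(eta_gamma - eta_beta)), 1e-10)
    }
  }
})

test_that("positive rescaling of a raw column leaves predictions unchanged", {
  d <- make_logistic_fixture(80, 3, seed = 6)
  fit <- fit_pls_logistic(d, n_components = 1)
  d2 <- d
  d2$x2 <- d2$x2 * 1000  # e.g. km -> m
  fit2 <- fit_pls_logistic(d2, n_components = 1)
  expect_equal(fit2$fitted, fit$fitted, tolerance = 1e-10)
  expect_equal(predict(fit2, d2), predict(fit, d), tolerance = 1e-10)
})

test_that("prediction behaves at the training mean, on training rows, and in (0,1)", {
  d <- make_logistic_fixture(60, 3, seed = 10)
  fit <- fit_pls_logistic(d, n_components = 2)
  at_mean <- tibble::as_tibble(as.list(colMeans(d[paste0("x", 1:3)])))
  expect_equal(predict(fit, at_mean), plogis(fit$gamma0), tolerance = 1e-12)
  p_train <- predict(fit, d)
  expect_equal(p_train, fit$fitted, tolerance = 1e-12)
  expect_true(all(p_train > 0 & p_train < 1))
  expect_error(predict(fit, d[c("x1", "x2")]),
               class = "takeovr_error_missing_column")
})

test_that("classification threshold assigns the boundary to success", {
  expect_identical(classify(c(0.51, 0.5, 0.49)), c(1L, 1L, 0L))
})

test_that("coefficients are interpreted as odds multipliers per SD", {
  out <- interpret_coefficient(c(0.35, 0, -0.42))
  expect_equal(out$percent_change, c(42, 0, -34))
  expect_equal(out$multiplier[2], 1)
})

test_that("degenerate outcomes and bad component counts are rejected", {
  d <- make_logistic_fixture(40, 2, seed = 20)
  d$success <- 1L
  expect_error(fit_pls_logistic(d, n_components = 1),
               class = "takeovr_error_single_class")
  d2 <- make_logistic_fixture(40, 2, seed = 20)
  expect_error(fit_pls_logistic(d2, n_components = 3),
               class = "takeovr_error_validation")
})

test_that("a model survives a JSON round trip to printed precision", {
  d <- make_logistic_fixture(70, 4, seed = 18)
  fit <- fit_pls_logistic(d, n_components = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_pls_model(fit, path)
  back <- read_pls_model(path)
  expect_equal(back$beta, fit$beta, tolerance = 1e-15)
  expect_equal(back$gamma, fit$gamma, tolerance = 1e-15)
  expect_equal(back$W_star, fit$W_star, tolerance = 1e-15)
  expect_equal(back$std_params, fit$std_params, tolerance = 1e-15)
  expect_equal(predict(back, d), predict(fit, d), tolerance = 1e-12)
})

test_that("tidy and glance summarise the fit", {
  d <- make_logistic_fixture(60, 3, seed = 25)
  fit <- fit_pls_logistic(d, n_components = 1)
  td <- tidy(fit)
  expect_equal(td$term, paste0("x", 1:3))
  expect_equal(td$percent_change, round(100 * (exp(td$beta) - 1)))
  gl <- glance(fit)
  expect_equal(gl$n, 60)
  expect_true(gl$accuracy >= 0 && gl$accuracy <= 1)
})
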