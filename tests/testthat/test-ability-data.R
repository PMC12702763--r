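small_catalogue <- function() {
  ability_catalogue(
    name = c("corsi_span", "ssrt"),
    task = c("corsi", "stop-signal"),
    unit = c("level", "ms"),
    orientation = c(1L, -1L)
  )
}

write_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("reading a small abilities file keeps shapes, order and outcome", {
  path <- write_fixture(c(
    "ssrt,corsi_span,success",
    "250,6,1",
    "300,4,0",
    "275,5,1"
  ))
  d <- read_abilities(path, small_catalogue())
  expect_equal(nrow(d), 3)
  # catalogue order, not file order
  expect_equal(names(d), c("participant_id", "corsi_span", "ssrt", "success"))
  expect_equal(d$ssrt, c(250, 300, 275))
  expect_type(d$success, "integer")
})

test_that("load errors are addressed to the offending column or cell", {
  cat2 <- small_catalogue()
  no_outcome <- write_fixture(c("corsi_span,ssrt", "6,250"))
  expect_error(read_abilities(no_outcome, cat2), "success",
               class = "takeovr_error_missing_column")
  bad_cell <- write_fixture(c("corsi_span,ssrt,success", "6,250,1", "x,260,0"))
  expect_error(read_abilities(bad_cell, cat2), "corsi_span.*row 2",
               class = "takeovr_error_parse")
  bad_outcome <- write_fixture(c("corsi_span,ssrt,success", "6,250,2"))
  expect_error(read_abilities(bad_outcome, cat2),
               class = "takeovr_error_outcome")
})

test_that("write/read round trip preserves values to full precision", {
  cat2 <- small_catalogue()
  d <- tibble::tibble(
    participant_id = c("P001", "P002"),
    corsi_span = c(6.123456789012345, 5 + pi * 1e-8),
    ssrt = c(250.00000000001, 1 / 3),
    success = c(1L, 0L)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_abilities(d, path)
  back <- read_abilities(path, cat2)
  expect_identical(back$corsi_span, d$corsi_span)
  expect_identical(back$ssrt, d$ssrt)
  expect_identical(back$success, d$success)
})

test_that("orientation negates exactly the negatively-oriented columns", {
  cat2 <- small_catalogue()
  d <- tibble::tibble(corsi_span = c(6, 0), ssrt = c(250, 0), success = c(1L, 0L))
  o <- orient_abilities(d, cat2)
  expect_equal(o$ssrt, c(-250, 0))     # higher raw SSRT = lower ability
  expect_equal(o$corsi_span, c(6, 0))  # positively oriented: identity
  # involution: applying the same flags twice restores the raw data
  expect_equal(orient_abilities(o, cat2), d)
})

test_that("standardization centres, scales, and reapplies exactly", {
  d <- tibble::tibble(a = c(1, 2, 3), b = c(10, 30, 20))
  std <- standardize_abilities(d)
  expect_equal(std$data$a, c(-1, 0, 1))
  expect_equal(vapply(std$data, sd, numeric(1)), c(a = 1, b = 1))
  # reapplying the returned params reproduces the standardized matrix
  again <- standardize_abilities(d, params = std$params)
  expect_equal(again$data, std$data)
  expect_error(standardize_abilities(tibble::tibble(a = c(2, 2, 2))),
               "a", class = "takeovr_error_zero_variance")
})

test_that("standardize-after-orient is invariant to positive affine rescaling", {
  cat2 <- small_catalogue()
  set.seed(5)
  d <- tibble::tibble(corsi_span = rnorm(20, 5), ssrt = rnorm(20, 250, 30),
                      success = rbinom(20, 1, 0.5))
  base <- standardize_abilities(orient_abilities(d, cat2),
                                c("corsi_span", "ssrt"))$data
  resc <- d
  resc$ssrt <- 3.7 * d$ssrt + 12  # positive affine change of raw units
  resc_std <- standardize_abilities(orient_abilities(resc, cat2),
                                    c("corsi_span", "ssrt"))$data
  expect_equal(resc_std$ssrt, base$ssrt)
  # flipping one orientation flag negates exactly that standardized column
  flipped <- cat2
  flipped$orientation <- c(-1L, -1L)
  flip_std <- standardize_abilities(orient_abilities(d, flipped),
                                    c("corsi_span", "ssrt"))$data
  expect_equal(flip_std$corsi_span, -base$corsi_span)
  expect_equal(flip_std$ssrt, base$ssrt)
})

test_that("catalogue construction validates names and flags, round-trips as JSON", {
  expect_error(ability_catalogue("a", "t", "u", orientation = 2L),
               class = "takeovr_error_catalogue")
  expect_error(ability_catalogue(c("a", "a"), "t", "u", c(1L, 1L)),
               class = "takeovr_error_catalogue")
  cat15 <- default_ability_catalogue()
  expect_equal(nrow(cat15), 15)
  expect_equal(sum(cat15$orientation == -1L), 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_catalogue(cat15, path)
  expect_equal(read_catalogue(path)$orientation, cat15$orientation)
  expect_equal(read_catalogue(path)$name, cat15$name)
})
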