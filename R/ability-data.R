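#' Read an abilities table from delimited text
#'
#' The file must contain one header row, one row per participant, every
#' predictor column named in the catalogue, and a binary outcome column
#' (default `"success"`, 1 = no collision during the take-over, 0 =
#' collision). Values are read as doubles in raw units; orientation and
#' standardization are separate, explicit steps ([orient_abilities()],
#' [standardize_abilities()]).
#'
#' @param path Path to a comma- (default) or tab-delimited UTF-8 text file.
#' @param catalogue An [ability_catalogue()] fixing the predictor columns and
#'   their order.
#' @param outcome Name of the binary outcome column.
#' @param delim Field delimiter; `","` or `"\t"`.
#'
#' @return A tibble with `participant_id` (row number unless the file has an
#'   id column), the predictor columns in catalogue order, and the outcome
#'   column as integer 0/1.
#' @export
#' @examples
#' path <- system.file("extdata", "synthetic_abilities_example.csv",
#'                     package = "takeovr")
#' read_abilities(path)
read_abilities <- function(path, catalogue = default_ability_catalogue(),
                           outcome = "success", delim = ",") {
  validate_catalogue(catalogue)
  raw <- readr::read_delim(
    path, delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  missing <- setdiff(c(catalogue$name, outcome), names(raw))
  if (length(missing) > 0L) {
    abort_takeovr(
      sprintf("Column(s) missing from '%s': %s.", path,
              paste(missing, collapse = ", ")),
      class = "takeovr_error_missing_column"
    )
  }
  parse_col <- function(col, nm) {
    x <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(x))
    if (length(bad) > 0L) {
      abort_takeovr(
        sprintf("Non-numeric or missing value in column '%s', row %d.",
                nm, bad[1]),
        class = "takeovr_error_parse"
      )
    }
    x
  }
  vals <- purrr::imap(raw[c(catalogue$name, outcome)], parse_col)
  out <- tibble::as_tibble(vals)
  out[[outcome]] <- check_binary_outcome(out[[outcome]], outcome)
  id <- if ("participant_id" %in% names(raw)) raw$participant_id
        else sprintf("P%03d", seq_len(nrow(out)))
  dplyr::bind_cols(tibble::tibble(participant_id = id), out)
}

#' Write an abilities table to delimited text
#'
#' Values round-trip through [read_abilities()] at full double precision.
#'
#' @param data Abilities tibble (as returned by [read_abilities()] or
#'   [simulate_cohort()]).
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_abilities <- function(data, path, delim = ",") {
  readr::write_delim(data, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Orient ability columns so that larger always means better
#'
#' Multiplies each predictor column by its catalogue orientation flag.
#' Variables where a larger raw value indicates lower ability (orientation
#' `-1`, e.g. the stop-signal reaction time) become negative-valued, so that
#' after the call a higher value always corresponds to a higher ability.
#' Applying the same catalogue twice restores the raw data.
#'
#' @inheritParams write_abilities
#' @param catalogue An [ability_catalogue()].
#' @return The tibble with oriented predictor columns.
#' @export
orient_abilities <- function(data, catalogue = default_ability_catalogue()) {
  validate_catalogue(catalogue)
  missing <- setdiff(catalogue$name, names(data))
  if (length(missing) > 0L) {
    abort_takeovr(
      sprintf("Column(s) missing from data: %s.", paste(missing, collapse = ", ")),
      class = "takeovr_error_missing_column"
    )
  }
  for (k in seq_len(nrow(catalogue))) {
    nm <- catalogue$name[k]
    data[[nm]] <- data[[nm]] * catalogue$orientation[k]
  }
  data
}

#' Standardize oriented ability columns
#'
#' Centres and scales each predictor to mean 0, standard deviation 1
#' (divisor `n - 1`), returning the standardized data together with the
#' per-column means and SDs so the same transformation can be applied to
#' held-out rows — inside cross-validation the parameters are recomputed on
#' each training fold.
#'
#' @param data Oriented abilities tibble.
#' @param predictors Character vector of columns to standardize; defaults to
#'   every numeric column except `participant_id` and the outcome.
#' @param params Optional tibble of previously computed `variable`, `mean`,
#'   `sd` rows to apply instead of estimating new ones.
#' @return A list with `data` (standardized tibble) and `params` (tibble:
#'   `variable`, `mean`, `sd`).
#' @export
standardize_abilities <- function(data, predictors = NULL, params = NULL) {
  predictors <- resolve_predictors(data, predictors)
  if (is.null(params)) {
    mu <- unname(vapply(data[predictors], mean, numeric(1)))
    sd_ <- unname(vapply(data[predictors], stats::sd, numeric(1)))
    bad <- predictors[sd_ == 0 | !is.finite(sd_)]
    if (length(bad) > 0L) {
      abort_takeovr(
        sprintf("Zero-variance column(s): %s.", paste(bad, collapse = ", ")),
        class = "takeovr_error_zero_variance"
      )
    }
    params <- tibble::tibble(variable = predictors, mean = mu, sd = sd_)
  } else {
    stopifnot(all(predictors %in% params$variable))
    params <- params[match(predictors, params$variable), ]
  }
  for (k in seq_along(predictors)) {
    nm <- predictors[k]
    data[[nm]] <- (data[[nm]] - params$mean[k]) / params$sd[k]
  }
  list(data = data, params = params)
}
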