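#' Build an ability-variable catalogue
#'
#' A catalogue describes the columns of an abilities table: one row per
#' predictor, with the source task, measurement unit and an orientation flag.
#' The orientation is `+1` when a larger raw value already means higher
#' ability and `-1` when it means lower ability (e.g. a stop-signal reaction
#' time), in which case [orient_abilities()] negates the column so that,
#' after orientation, larger always means better.
#'
#' @param name Character vector of unique, syntactic column names.
#' @param task Source test for each variable.
#' @param unit Measurement unit (free text).
#' @param orientation Integer vector of `+1` / `-1` flags.
#' @param description Optional free-text description.
#'
#' @return A tibble with class `ability_catalogue`.
#' @seealso [default_ability_catalogue()]
#' @export
ability_catalogue <- function(name, task, unit, orientation,
                              description = NA_character_) {
  if (anyDuplicated(name)) {
    abort_takeovr("Catalogue variable names must be unique.",
                  class = "takeovr_error_catalogue")
  }
  if (!all(orientation %in% c(-1L, 1L))) {
    abort_takeovr("`orientation` must be +1 or -1 for every variable.",
                  class = "takeovr_error_catalogue")
  }
  out <- tibble::tibble(
    name = as.character(name),
    task = as.character(task),
    unit = as.character(unit),
    orientation = as.integer(orientation),
    description = rep_len(as.character(description), length(name))
  )
  class(out) <- c("ability_catalogue", class(out))
  out
}

#' The reference 15-variable ability catalogue
#'
#' The predictor set used throughout the package examples: three biographical
#' measures, three visuo-attentional test scores and nine executive test
#' scores. Five variables measure constructs where a larger raw value means
#' lower ability (reaction-time differences, stop-signal reaction time,
#' unnecessary moves) and carry orientation `-1`.
#'
#' @return An [ability_catalogue()] tibble with 15 rows.
#' @export
#' @examples
#' default_ability_catalogue()
default_ability_catalogue <- function() {
  ability_catalogue(
    name = c(
      "age", "km_per_year", "licence_years",
      "vmc_time_close", "moa_mean_time", "mot_speed",
      "nback_acc_diff", "nback_rt_diff", "corsi_span",
      "ssrt", "flanker_acc", "flanker_rt_diff",
      "tmt_b_minus_a", "tol_correct", "tol_extra_moves"
    ),
    task = c(
      "questionnaire", "questionnaire", "questionnaire",
      "visuomanual coordination", "multiple object avoidance",
      "multiple object tracking",
      "n-back", "n-back", "corsi",
      "stop-signal", "flanker", "flanker",
      "trail making test", "tower of london", "tower of london"
    ),
    unit = c(
      "year", "1000 km/year", "year",
      "percent", "s", "a.u.",
      "percent", "ms", "level",
      "ms", "percent", "ms",
      "s", "count", "count"
    ),
    orientation = c(
      1L, 1L, 1L,
      1L, 1L, 1L,
      1L, -1L, 1L,
      -1L, 1L, -1L,
      -1L, 1L, -1L
    ),
    description = c(
      "age at inclusion",
      "self-reported annual mileage",
      "years since obtaining the driving licence",
      "percent of time the cursor stays within the closeness threshold",
      "mean time before a collision, averaged over trials",
      "visual tracking speed threshold",
      "accuracy difference, 3-back minus 1-back",
      "mean response-time difference, 3-back minus 1-back",
      "highest level reached in the block-tapping task",
      "stop-signal reaction time, integration method",
      "percent of successful flanker trials",
      "mean response-time difference, incongruent minus congruent",
      "completion-time difference, board B minus board A",
      "number of models correctly reproduced",
      "unnecessary moves on successful models"
    )
  )
}

validate_catalogue <- function(catalogue) {
  required <- c("name", "orientation")
  if (!is.data.frame(catalogue) || !all(required %in% names(catalogue))) {
    abort_takeovr(
      "A catalogue needs at least `name` and `orientation` columns.",
      class = "takeovr_error_catalogue"
    )
  }
  if (anyDuplicated(catalogue$name) ||
      !all(catalogue$orientation %in% c(-1L, 1L))) {
    abort_takeovr(
      "Catalogue names must be unique and orientations +1 or -1.",
      class = "takeovr_error_catalogue"
    )
  }
  invisible(catalogue)
}

#' Read or write a variable catalogue as JSON
#'
#' @param path File path.
#' @param catalogue An [ability_catalogue()].
#' @return `read_catalogue()` returns the catalogue tibble;
#'   `write_catalogue()` returns `path` invisibly.
#' @export
read_catalogue <- function(path) {
  raw <- jsonlite::fromJSON(path)
  cat <- ability_catalogue(
    name = raw$name, task = raw$task %||% NA_character_,
    unit = raw$unit %||% NA_character_,
    orientation = raw$orientation,
    description = raw$description %||% NA_character_
  )
  cat
}

#' @rdname read_catalogue
#' @export
write_catalogue <- function(catalogue, path) {
  validate_catalogue(catalogue)
  jsonlite::write_json(as.data.frame(catalogue), path,
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}
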