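# Predictor-level scores from trial-level cognitive / visuo-attentional
# test records.

#' Stop-signal reaction time by the integration method
#'
#' Estimates the latency of the inhibitory process from a stop-signal task.
#' Go-trial reaction times are ranked ascending, with omitted go responses
#' replaced by the maximum observed go RT; the n-th RT is taken at
#' `n = ceiling(p * n_go)`, where `p` is the probability of responding on a
#' stop trial; SSRT is that quantile minus the mean stop-signal delay.
#'
#' @param go_rts Numeric vector of go-trial reaction times in ms (observed
#'   responses only).
#' @param n_go_omissions Number of go trials with no response; each is
#'   entered into the ranking as the maximum observed go RT.
#' @param stop_ssd Numeric vector of stop-signal delays (ms), one per stop
#'   trial.
#' @param stop_responded Logical vector, one per stop trial: did the
#'   participant respond despite the stop signal?
#'
#' @return SSRT in ms (a single double).
#' @export
#' @examples
#' ssrt_integration(seq(300, 500, length.out = 10),
#'                  stop_ssd = rep(180, 10),
#'                  stop_responded = rep(c(TRUE, FALSE), 5))
ssrt_integration <- function(go_rts, n_go_omissions = 0L,
                             stop_ssd, stop_responded) {
  if (length(go_rts) == 0L) {
    abort_takeovr("At least one observed go trial is required.",
                  class = "takeovr_error_validation")
  }
  if (length(stop_ssd) != length(stop_responded) || length(stop_ssd) == 0L) {
    abort_takeovr("`stop_ssd` and `stop_responded` must be equal-length, non-empty.",
                  class = "takeovr_error_validation")
  }
  if (any(go_rts < 0) || any(stop_ssd < 0)) {
    abort_takeovr("Reaction times and stop-signal delays must be non-negative.",
                  class = "takeovr_error_validation")
  }
  p_respond <- mean(stop_responded)
  if (p_respond == 0) {
    abort_takeovr(
      "SSRT is undefined when the participant never responded on stop trials.",
      class = "takeovr_error_undefined_ssrt"
    )
  }
  ranked <- sort(c(go_rts, rep(max(go_rts), n_go_omissions)))
  n_go <- length(ranked)
  nth <- ceiling(p_respond * n_go)
  ranked[nth] - mean(stop_ssd)
}

#' Hard-minus-easy difference score
#'
#' The generic two-condition contrast used for the n-back response-time
#' difference (3-back minus 1-back), the flanker congruency effect
#' (incongruent minus congruent) and the trail-making contrast (board B
#' minus board A): the harder condition's summary statistic minus the
#' easy / calibration condition's.
#'
#' @param hard,easy Summary statistics (same unit) for the two conditions.
#' @return `hard - easy`, vectorized.
#' @export
difference_score <- function(hard, easy) {
  stopifnot(is.numeric(hard), is.numeric(easy),
            all(is.finite(hard)), all(is.finite(easy)))
  hard - easy
}

#' Percentage of time spent close to the target
#'
#' Visuomanual-coordination score: the share of tracking samples whose
#' cursor-to-target distance is at or below the closeness threshold
#' (boundary inclusive).
#'
#' @param distances Per-sample cursor-to-target distances in cm.
#' @param threshold Closeness threshold in cm (default 0.5).
#' @return Percentage in `[0, 100]`.
#' @export
percent_time_close <- function(distances, threshold = 0.5) {
  if (length(distances) == 0L) {
    abort_takeovr("At least one tracking sample is required.",
                  class = "takeovr_error_validation")
  }
  if (threshold <= 0 || any(distances < 0)) {
    abort_takeovr("Distances must be non-negative and the threshold positive.",
                  class = "takeovr_error_validation")
  }
  100 * mean(distances <= threshold)
}

#' Span score: highest level passed
#'
#' For span-type tasks (e.g. block tapping), the highest difficulty level
#' with at least one passed trial, or 0 if the participant never passed.
#' The termination rule (two consecutive failures at a level) is assumed to
#' have been applied when the task was run.
#'
#' @param level Integer vector of attempted levels (non-decreasing).
#' @param passed Logical vector, one per attempt.
#' @return Highest passed level (single number).
#' @export
span_score <- function(level, passed) {
  stopifnot(length(level) == length(passed))
  if (!any(passed)) return(0)
  max(level[passed])
}

#' Score stop-signal task trials per participant
#'
#' Convenience wrapper turning a long trial-level table into one SSRT row
#' per participant via [ssrt_integration()]. Go trials with `responded =
#' FALSE` are counted as omissions; go errors (wrong key) are retained as
#' responses upstream and are not distinguished here.
#'
#' @param data Tibble with columns `participant_id`, `trial_type` (`"go"` or
#'   `"stop"`), `rt` (ms; `NA` on omitted go trials and unanswered stop
#'   trials), `ssd` (ms; `NA` on go trials) and `responded` (logical).
#' @return Tibble with `participant_id` and `ssrt`.
#' @export
score_stop_signal <- function(data) {
  stopifnot(all(c("participant_id", "trial_type", "rt", "ssd", "responded")
                %in% names(data)))
  data |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      ssrt = ssrt_integration(
        go_rts = .data$rt[.data$trial_type == "go" & .data$responded],
        n_go_omissions = sum(.data$trial_type == "go" & !.data$responded),
        stop_ssd = .data$ssd[.data$trial_type == "stop"],
        stop_responded = .data$responded[.data$trial_type == "stop"]
      ),
      .groups = "drop"
    )
}
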