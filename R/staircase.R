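#' Configuration of a transformed up-down staircase
#'
#' A generic n-up / n-down adaptive track over a real-valued stimulus
#' variable. "Harder" means the direction in which the task becomes more
#' difficult; its sign on the tracked variable is set by
#' `harder_direction` (-1 for a speech-in-noise SNR track where lower SNR
#' is harder, +1 for a density track where higher density is harder).
#'
#' @param n_up Consecutive correct responses required before the task is
#'   made harder.
#' @param n_down Incorrect responses required before the task is made
#'   easier (1 in the procedures implemented here).
#' @param step_schedule Data frame with columns `after_reversals`
#'   (nondecreasing thresholds, first row 0) and `step` (positive step
#'   sizes in tracked units). The step in force is the row with the
#'   largest `after_reversals` not exceeding the number of reversals
#'   already logged at the moment of the move.
#' @param start_level Starting value of the tracked variable.
#' @param min_level,max_level Track limits; levels are clamped.
#' @param harder_direction `+1` or `-1`.
#' @param stop_rule Either `stop_after_trials(n)` or
#'   `stop_after_reversals(n)`.
#' @return A `staircase_config` object.
#' @seealso [din_staircase_config()], [stripes_staircase_config()]
#' @export
staircase_config <- function(n_up, n_down = 1L, step_schedule, start_level,
                             min_level, max_level, harder_direction,
                             stop_rule) {
  n_up <- as.integer(n_up); n_down <- as.integer(n_down)
  if (n_up < 1L || n_down < 1L) {
    abort("`n_up` and `n_down` must be positive integers.",
          class = "auditest_bad_config")
  }
  step_schedule <- as_tibble(step_schedule)
  if (!all(c("after_reversals", "step") %in% names(step_schedule)) ||
      nrow(step_schedule) < 1L) {
    abort("`step_schedule` needs columns `after_reversals` and `step`.",
          class = "auditest_bad_config")
  }
  if (step_schedule$after_reversals[1] != 0 ||
      is.unsorted(step_schedule$after_reversals, strictly = TRUE) &&
      nrow(step_schedule) > 1L) {
    abort("`after_reversals` must start at 0 and be strictly increasing.",
          class = "auditest_bad_config")
  }
  if (any(step_schedule$step <= 0)) {
    abort("Step sizes must be positive.", class = "auditest_bad_config")
  }
  if (!(min_level <= start_level && start_level <= max_level)) {
    abort("Require min_level <= start_level <= max_level.",
          class = "auditest_bad_config")
  }
  if (!harder_direction %in% c(-1, 1)) {
    abort("`harder_direction` must be +1 or -1.",
          class = "auditest_bad_config")
  }
  if (!inherits(stop_rule, "staircase_stop_rule")) {
    abort("`stop_rule` must come from stop_after_trials()/stop_after_reversals().",
          class = "auditest_bad_config")
  }
  structure(
    list(n_up = n_up, n_down = n_down, step_schedule = step_schedule,
         start_level = as.double(start_level),
         min_level = as.double(min_level), max_level = as.double(max_level),
         harder_direction = as.double(harder_direction),
         stop_rule = stop_rule),
    class = "staircase_config"
  )
}

#' Staircase stop rules
#'
#' @param n Positive integer: total trials, or total reversals.
#' @return A `staircase_stop_rule` object.
#' @export
stop_after_trials <- function(n) {
  structure(list(type = "trials", n = as.integer(n)),
            class = "staircase_stop_rule")
}

#' @rdname stop_after_trials
#' @export
stop_after_reversals <- function(n) {
  structure(list(type = "reversals", n = as.integer(n)),
            class = "staircase_stop_rule")
}

#' Digits-in-noise staircase configuration
#'
#' 1-up-1-down over SNR in dB: start 0 dB, fixed 2 dB steps, track limits
#' -20 to +20 dB, lower SNR harder, stopping after 24 trials. The SRT is
#' then estimated with [estimate_srt_final_trials()].
#'
#' @return A [staircase_config()].
#' @export
din_staircase_config <- function() {
  staircase_config(
    n_up = 1L, n_down = 1L,
    step_schedule = tibble(after_reversals = 0L, step = 2),
    start_level = 0, min_level = -20, max_level = 20,
    harder_direction = -1,
    stop_rule = stop_after_trials(24L)
  )
}

#' STRIPES staircase configuration
#'
#' 2-up-1-down over sweep density: start 1.1, step 0.5 for the first four
#' reversals then 0.2 for the final four, eight reversals in total, higher
#' density harder. The run threshold is the mean of the final four
#' reversal densities ([estimate_threshold_reversal_mean()]); the task is
#' run twice and the two run thresholds averaged ([combine_runs()]).
#'
#' @param max_level Track ceiling for density (default 20); the floor is
#'   1.0, below which a sweep stimulus is not defined.
#' @return A [staircase_config()].
#' @export
stripes_staircase_config <- function(max_level = 20) {
  staircase_config(
    n_up = 2L, n_down = 1L,
    step_schedule = tibble(after_reversals = c(0L, 4L), step = c(0.5, 0.2)),
    start_level = 1.1, min_level = 1, max_level = max_level,
    harder_direction = +1,
    stop_rule = stop_after_reversals(8L)
  )
}

#' Start a staircase
#'
#' @param cfg A [staircase_config()].
#' @return A fresh `staircase` state object.
#' @export
staircase_start <- function(cfg) {
  stopifnot(inherits(cfg, "staircase_config"))
  structure(
    list(
      cfg = cfg,
      current_level = cfg$start_level,
      levels = numeric(0), correct = logical(0),
      reversal_trial = integer(0), reversal_level = numeric(0),
      consecutive_correct = 0L, consecutive_incorrect = 0L,
      last_intent = 0, # 0 none, +1 harder, -1 easier (task-difficulty sense)
      finished = FALSE
    ),
    class = "staircase"
  )
}

step_for_reversals <- function(cfg, n_reversals) {
  sched <- cfg$step_schedule
  i <- max(which(sched$after_reversals <= n_reversals))
  sched$step[i]
}

#' Advance a staircase by one trial
#'
#' Logs the response at the current level, moves the level harder after
#' `n_up` consecutive correct responses (resetting the counter) or easier
#' after `n_down` incorrect responses, clamps to the track limits, and
#' logs a reversal whenever the intended movement direction flips. A
#' direction change across a clamped step still counts as a reversal only
#' when the intended direction flips, which keeps reversal semantics
#' well defined at the rails. The consecutive-correct counter resets after
#' every level change and after any incorrect response.
#'
#' @param state A running `staircase` from [staircase_start()].
#' @param correct Logical: was the response correct?
#' @return The updated `staircase`.
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase"))
  if (state$finished) {
    abort("Staircase is finished; no further trials may be scored.",
          class = "auditest_staircase_finished")
  }
  if (!is.logical(correct) || length(correct) != 1L || is.na(correct)) {
    abort("`correct` must be TRUE or FALSE.", class = "auditest_bad_argument")
  }
  cfg <- state$cfg
  state$levels <- c(state$levels, state$current_level)
  state$correct <- c(state$correct, correct)
  trial <- length(state$levels)

  move <- 0 # +1 harder, -1 easier
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    state$consecutive_incorrect <- 0L
    if (state$consecutive_correct >= cfg$n_up) {
      move <- +1
      state$consecutive_correct <- 0L
    }
  } else {
    state$consecutive_incorrect <- state$consecutive_incorrect + 1L
    state$consecutive_correct <- 0L
    if (state$consecutive_incorrect >= cfg$n_down) {
      move <- -1
      state$consecutive_incorrect <- 0L
    }
  }

  if (move != 0) {
    if (state$last_intent != 0 && move != state$last_intent) {
      state$reversal_trial <- c(state$reversal_trial, trial)
      state$reversal_level <- c(state$reversal_level, state$current_level)
    }
    step <- step_for_reversals(cfg, length(state$reversal_level))
    state$current_level <- clamp(
      state$current_level + move * cfg$harder_direction * step,
      cfg$min_level, cfg$max_level
    )
    state$last_intent <- move
  }

  sr <- cfg$stop_rule
  if (sr$type == "trials" && trial >= sr$n) state$finished <- TRUE
  if (sr$type == "reversals" && length(state$reversal_level) >= sr$n) {
    state$finished <- TRUE
  }
  state
}

#' Run a staircase against a response sequence or responder function
#'
#' @param cfg A [staircase_config()].
#' @param responder Either a logical vector of responses (consumed in
#'   order) or a function of the presented level returning TRUE/FALSE.
#' @param max_trials Safety cap for reversal-stopped tracks.
#' @return The finished (or exhausted) `staircase`.
#' @export
staircase_run <- function(cfg, responder, max_trials = 1000L) {
  state <- staircase_start(cfg)
  if (is.logical(responder)) {
    seq_resp <- responder
    i <- 0L
    responder <- function(level) {
      i <<- i + 1L
      seq_resp[i]
    }
    max_trials <- min(max_trials, length(seq_resp))
  }
  while (!state$finished && length(state$levels) < max_trials) {
    state <- staircase_update(state, isTRUE(responder(state$current_level)))
  }
  state
}

#' @export
print.staircase <- function(x, ...) {
  cat(sprintf(
    "<staircase: %d trials, %d reversals, level %.3g%s>\n",
    length(x$levels), length(x$reversal_level), x$current_level,
    if (x$finished) ", finished" else ""
  ))
  invisible(x)
}

#' @export
tidy.staircase <- function(x, ...) {
  tibble(
    trial = seq_along(x$levels),
    level = x$levels,
    correct = x$correct,
    reversal = seq_along(x$levels) %in% x$reversal_trial
  )
}

#' @export
glance.staircase <- function(x, ...) {
  tibble(
    n_trials = length(x$levels),
    n_reversals = length(x$reversal_level),
    current_level = x$current_level,
    finished = x$finished
  )
}

#' Plot a staircase track
#'
#' @param object A `staircase`.
#' @param ... Unused.
#' @return A ggplot object: level per trial, reversals circled.
#' @export
autoplot.staircase <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trial, y = .data$level)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$correct), size = 2) +
    ggplot2::geom_point(data = dplyr::filter(d, .data$reversal),
                        shape = 1, size = 4) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4)) +
    ggplot2::labs(x = "Trial", y = "Tracked level", shape = "Correct") +
    ggplot2::theme_minimal()
}

#' Speech reception threshold from the final trials of a track
#'
#' The SRT estimator for the 24-trial digits-in-noise procedure: discard
#' the first 8 trials and average the presented SNR over the final 16.
#'
#' @param state A `staircase` with exactly `discard_first + use_last`
#'   logged trials.
#' @param discard_first,use_last Trial counts (defaults 8 and 16).
#' @return The SRT in tracked units (dB SNR).
#' @export
estimate_srt_final_trials <- function(state, discard_first = 8L,
                                      use_last = 16L) {
  stopifnot(inherits(state, "staircase"))
  n <- length(state$levels)
  if (n != discard_first + use_last) {
    abort(sprintf("Expected %d trials (discard %d + use %d), found %d.",
                  discard_first + use_last, discard_first, use_last, n),
          class = "auditest_contract_error")
  }
  mean(state$levels[(discard_first + 1L):n])
}

#' Threshold as the mean of the final reversals
#'
#' The estimator for the eight-reversal STRIPES procedure: average the
#' tracked densities at the final four reversals of a finished run.
#'
#' @param state A finished `staircase` with at least `n_last` reversals.
#' @param n_last Number of final reversals to average (default 4).
#' @return Threshold in tracked units.
#' @export
estimate_threshold_reversal_mean <- function(state, n_last = 4L) {
  stopifnot(inherits(state, "staircase"))
  n_rev <- length(state$reversal_level)
  if (!state$finished || n_rev < n_last) {
    abort(sprintf(
      "Need a finished track with at least %d reversals (found %d%s).",
      n_last, n_rev, if (state$finished) "" else ", unfinished"),
      class = "auditest_contract_error")
  }
  mean(tail(state$reversal_level, n_last))
}

#' Combine run thresholds into a final score
#'
#' @param thresholds Numeric vector of per-run thresholds (at least one).
#' @return Their arithmetic mean.
#' @export
combine_runs <- function(thresholds) {
  if (!is.numeric(thresholds) || length(thresholds) < 1L ||
      anyNA(thresholds)) {
    abort("`thresholds` must be a nonempty numeric vector.",
          class = "auditest_bad_argument")
  }
  mean(thresholds)
}

#' Serialize / restore a staircase configuration
#'
#' Round-trips a [staircase_config()] through a JSON-compatible plain-text
#' form so tracks are shareable between sessions and tools.
#'
#' @param cfg A [staircase_config()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `staircase_config_to_json()`: JSON string or `path` invisibly;
#'   `staircase_config_from_json()`: a [staircase_config()].
#' @export
staircase_config_to_json <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "staircase_config"))
  x <- list(
    n_up = cfg$n_up, n_down = cfg$n_down,
    step_schedule = as.data.frame(cfg$step_schedule),
    start_level = cfg$start_level, min_level = cfg$min_level,
    max_level = cfg$max_level, harder_direction = cfg$harder_direction,
    stop_rule = list(type = cfg$stop_rule$type, n = cfg$stop_rule$n)
  )
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname staircase_config_to_json
#' @param json JSON string or path to a JSON file.
#' @export
staircase_config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  stop_rule <- switch(x$stop_rule$type,
    trials = stop_after_trials(x$stop_rule$n),
    reversals = stop_after_reversals(x$stop_rule$n),
    abort("Unknown stop rule type.", class = "auditest_bad_config")
  )
  staircase_config(
    n_up = x$n_up, n_down = x$n_down,
    step_schedule = x$step_schedule,
    start_level = x$start_level, min_level = x$min_level,
    max_level = x$max_level, harder_direction = x$harder_direction,
    stop_rule = stop_rule
  )
}
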