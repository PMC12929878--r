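#' Simulated listener with a cumulative-Gaussian psychometric function
#'
#' The probability of a correct response at tracked level `x` is
#' `gamma + (1 - gamma - lambda) * pnorm(s * (x - mu) / sigma)` where `s`
#' is +1 when higher levels are easier (`easier_at_high`, e.g. SNR
#' tracks) and -1 when lower levels are easier (`easier_at_low`, e.g.
#' density tracks). `gamma` is the guess floor (1/2 for a
#' first-or-last-interval forced choice), `lambda` the lapse rate.
#'
#' @param threshold_mu Level of the 50% point of the scaled Gaussian.
#' @param slope_sigma Spread of the Gaussian, > 0, in tracked units.
#' @param guess_rate Guess rate gamma in [0, 1).
#' @param lapse_rate Lapse rate lambda in `[0, 0.1]`.
#' @param orientation `"easier_at_high"` or `"easier_at_low"`.
#' @return A `psychometric_listener` object.
#' @export
psychometric_listener <- function(threshold_mu, slope_sigma,
                                  guess_rate = 0, lapse_rate = 0,
                                  orientation = c("easier_at_high",
                                                  "easier_at_low")) {
  orientation <- match.arg(orientation)
  if (slope_sigma <= 0) {
    abort("`slope_sigma` must be > 0.", class = "auditest_bad_argument")
  }
  if (guess_rate < 0 || guess_rate >= 1) {
    abort("`guess_rate` must be in [0, 1).", class = "auditest_bad_argument")
  }
  if (lapse_rate < 0 || lapse_rate > 0.1) {
    abort("`lapse_rate` must be in [0, 0.1].",
          class = "auditest_bad_argument")
  }
  structure(
    list(threshold_mu = threshold_mu, slope_sigma = slope_sigma,
         guess_rate = guess_rate, lapse_rate = lapse_rate,
         orientation = orientation),
    class = "psychometric_listener"
  )
}

#' Probability of a correct response at a level
#' @param listener A [psychometric_listener()].
#' @param level Tracked level(s).
#' @return Probability in `[gamma, 1 - lambda]`.
#' @export
p_correct <- function(listener, level) {
  stopifnot(inherits(listener, "psychometric_listener"))
  s <- if (listener$orientation == "easier_at_high") 1 else -1
  listener$guess_rate +
    (1 - listener$guess_rate - listener$lapse_rate) *
    pnorm(s * (level - listener$threshold_mu) / listener$slope_sigma)
}

#' Level at which the listener reaches a target probability correct
#'
#' Inverts the psychometric function; used to locate the theoretical
#' convergence points of transformed up-down tracks (50% correct for
#' 1-up-1-down, 70.7% for 2-up-1-down).
#'
#' @param listener A [psychometric_listener()].
#' @param p Target probability, strictly between `guess_rate` and
#'   `1 - lapse_rate`.
#' @return The level in tracked units.
#' @export
level_at_p <- function(listener, p) {
  stopifnot(inherits(listener, "psychometric_listener"))
  g <- listener$guess_rate
  l <- listener$lapse_rate
  if (p <= g || p >= 1 - l) {
    abort("`p` must lie strictly between guess and 1 - lapse.",
          class = "auditest_bad_argument")
  }
  z <- qnorm((p - g) / (1 - g - l))
  s <- if (listener$orientation == "easier_at_high") 1 else -1
  listener$threshold_mu + s * listener$slope_sigma * z
}

#' Draw one response from a simulated listener
#'
#' A Bernoulli draw from the psychometric function using the current R
#' RNG stream, so enclosing code controls reproducibility with
#' `set.seed()` / `withr::with_seed()`.
#'
#' @param listener A [psychometric_listener()].
#' @param level Presented level.
#' @return TRUE/FALSE.
#' @export
respond <- function(listener, level) {
  runif(1) < p_correct(listener, level)
}

new_simulation_report <- function(procedure, estimates, target, n_runs,
                                  seed) {
  structure(
    list(procedure = procedure, estimates = estimates, target = target,
         n_runs = n_runs, seed = seed),
    class = "simulation_report"
  )
}

#' @export
print.simulation_report <- function(x, ...) {
  cat(sprintf(
    "<%s simulation: %d runs, mean %.3f, SD %.3f, target %.3f, bias %+.3f>\n",
    x$procedure, x$n_runs, mean(x$estimates), sd(x$estimates), x$target,
    mean(x$estimates) - x$target
  ))
  invisible(x)
}

#' @export
tidy.simulation_report <- function(x, ...) {
  tibble(run = seq_along(x$estimates), estimate = x$estimates)
}

#' @export
glance.simulation_report <- function(x, ...) {
  tibble(
    procedure = x$procedure, n_runs = x$n_runs,
    mean = mean(x$estimates), sd = sd(x$estimates),
    target = x$target, bias = mean(x$estimates) - x$target,
    seed = x$seed
  )
}

#' Plot a simulation report
#'
#' @param object A `simulation_report`.
#' @param ... Unused.
#' @return A ggplot: estimate distribution with the theoretical
#'   convergence point marked.
#' @export
autoplot.simulation_report <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$target, linetype = 2,
                        colour = "red") +
    ggplot2::labs(
      x = "Per-run estimate (tracked units)", y = "Runs",
      title = sprintf("%s: mean %.3f vs target %.3f", object$procedure,
                      mean(object$estimates), object$target)
    ) +
    ggplot2::theme_minimal()
}

#' Simulate the 24-trial digits-in-noise procedure
#'
#' Runs the full 1-up-1-down SNR track against a simulated listener
#' `n_runs` times and estimates each run's SRT with
#' [estimate_srt_final_trials()]. The report's bias is taken against the
#' listener's 50%-correct SNR, the theoretical 1-up-1-down convergence
#' point.
#'
#' @param listener A [psychometric_listener()] (orientation
#'   `easier_at_high`).
#' @param n_runs Number of simulated runs.
#' @param seed Integer seed; the whole report is reproducible.
#' @param cfg Staircase configuration (default [din_staircase_config()]).
#' @return A `simulation_report`.
#' @export
run_din_simulation <- function(listener, n_runs = 500L, seed = 1L,
                               cfg = din_staircase_config()) {
  stopifnot(inherits(listener, "psychometric_listener"))
  estimates <- withr::with_seed(seed, {
    vapply(seq_len(n_runs), function(i) {
      st <- staircase_run(cfg, function(level) respond(listener, level))
      estimate_srt_final_trials(st)
    }, numeric(1))
  })
  new_simulation_report("din", estimates, level_at_p(listener, 0.5),
                        n_runs, seed)
}

#' Simulate the STRIPES procedure (two runs per session)
#'
#' Each simulated session runs the eight-reversal 2-up-1-down density
#' track twice, estimates each run with
#' [estimate_threshold_reversal_mean()] and combines them with
#' [combine_runs()]. The report's bias is taken against the listener's
#' 70.7%-correct density, the theoretical 2-up-1-down convergence point.
#'
#' @param listener A [psychometric_listener()] with `guess_rate = 0.5`
#'   (first-or-last-interval choice) and orientation `easier_at_low`.
#' @param n_sessions Number of simulated sessions.
#' @param seed Integer seed.
#' @param cfg Staircase configuration
#'   (default [stripes_staircase_config()]).
#' @return A `simulation_report` of combined session thresholds.
#' @export
run_stripes_simulation <- function(listener, n_sessions = 500L, seed = 1L,
                                   cfg = stripes_staircase_config()) {
  stopifnot(inherits(listener, "psychometric_listener"))
  estimates <- withr::with_seed(seed, {
    vapply(seq_len(n_sessions), function(i) {
      runs <- vapply(1:2, function(r) {
        st <- staircase_run(cfg, function(level) respond(listener, level))
        estimate_threshold_reversal_mean(st)
      }, numeric(1))
      combine_runs(runs)
    }, numeric(1))
  })
  new_simulation_report("stripes", estimates,
                        level_at_p(listener, sqrt(0.5)), n_sessions, seed)
}

#' Simulate keyword-scored sentence lists per condition
#'
#' Each condition has a per-keyword recognition probability. For every
#' list, 15 sentences of 3 keywords are simulated: each keyword enters
#' the transcript independently with the condition's probability, the
#' transcript is scored with [score_keywords()] and the list aggregated
#' with [aggregate_keyword_list()]. Expected percent correct equals
#' `100 * p`.
#'
#' @param intelligibility_map Named numeric vector: condition ->
#'   per-keyword recognition probability in `[0, 1]`.
#' @param n_lists Lists simulated per condition.
#' @param seed Integer seed.
#' @return A tibble: `condition`, `p_keyword`, `n_lists`,
#'   `mean_percent`, `sd_percent`.
#' @export
run_keyword_simulation <- function(intelligibility_map, n_lists = 200L,
                                   seed = 1L) {
  p <- intelligibility_map
  if (is.null(names(p)) || any(p < 0 | p > 1)) {
    abort("`intelligibility_map` must be a named vector of probabilities in [0, 1].",
          class = "auditest_bad_argument")
  }
  withr::with_seed(seed, {
    purrr::map_dfr(names(p), function(cond) {
      percents <- vapply(seq_len(n_lists), function(i) {
        scores <- vapply(1:15, function(trial) {
          key <- keyword_key(sprintf("kw%d%s", 1:3, letters[trial]))
          heard <- key$keywords[runif(3) < p[[cond]]]
          transcript <- c("the", heard, "um")
          score_keywords(transcript, key)
        }, integer(1))
        aggregate_keyword_list(scores)
      }, numeric(1))
      tibble(condition = cond, p_keyword = unname(p[[cond]]),
             n_lists = n_lists, mean_percent = mean(percents),
             sd_percent = sd(percents))
    })
  })
}
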