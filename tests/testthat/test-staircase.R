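test_that("the DIN track follows the published hand traces", {
  cfg <- din_staircase_config()
  # one correct at 0 dB moves the next trial to -2 dB
  st <- staircase_update(staircase_start(cfg), TRUE)
  expect_equal(st$current_level, -2)
  # 11 consecutive correct from 0 dB pin the track at the -20 dB rail
  st <- staircase_run(cfg, c(rep(TRUE, 11), rep(TRUE, 13)))
  expect_equal(st$levels[11], -20)
  expect_true(all(st$levels[11:24] == -20))
  expect_true(st$finished)
})

test_that("the STRIPES track follows the published hand trace", {
  cfg <- stripes_staircase_config()
  st <- staircase_update(staircase_start(cfg), TRUE)
  expect_equal(st$current_level, 1.1) # one correct: no move yet (2-up)
  st <- staircase_update(st, TRUE)
  expect_equal(st$current_level, 1.6) # second consecutive correct: +0.5
})

test_that("the step schedule switches from 0.5 to 0.2 after four reversals", {
  cfg <- stripes_staircase_config()
  # drive responses to produce reversals quickly: 2 correct then 1 wrong
  st <- staircase_run(cfg, rep(c(TRUE, TRUE, FALSE), 40))
  expect_true(st$finished)
  expect_length(st$reversal_level, 8)
  steps <- abs(diff(st$levels))
  steps <- steps[steps > 0]
  expect_true(all(abs(steps - 0.5) < 1e-12 | abs(steps - 0.2) < 1e-12))
  expect_true(any(abs(steps - 0.2) < 1e-12)) # late moves use the fine step
  expect_equal(steps[1], 0.5)                # early moves use the coarse step
})

test_that("engine trajectories equal the brute-force oracle bit-exactly", {
  set.seed(101)
  for (i in 1:200) {
    resp <- runif(24) < runif(1, 0.2, 0.9)
    st <- staircase_run(din_staircase_config(), resp)
    o <- oracle_din_trace(resp)
    expect_identical(st$levels, o$levels)
    expect_identical(st$reversal_level, o$reversal_levels)
  }
  for (i in 1:200) {
    resp <- runif(120) < runif(1, 0.3, 0.9)
    st <- staircase_run(stripes_staircase_config(), resp)
    o <- oracle_stripes_trace(resp)
    expect_identical(st$levels, o$levels)
    expect_identical(st$reversal_level, o$reversal_levels)
  }
})

test_that("levels stay within the rails and reversal count never decreases", {
  set.seed(102)
  for (i in 1:50) {
    resp <- runif(24) < 0.5
    st <- staircase_start(din_staircase_config())
    prev_rev <- 0L
    for (r in resp) {
      st <- staircase_update(st, r)
      expect_gte(min(st$levels), -20)
      expect_lte(max(st$levels), 20)
      expect_gte(length(st$reversal_level), prev_rev)
      prev_rev <- length(st$reversal_level)
    }
  }
})

test_that("updating a finished staircase is an error", {
  st <- staircase_run(din_staircase_config(), rep(TRUE, 24))
  expect_true(st$finished)
  expect_error(staircase_update(st, TRUE),
               class = "auditest_staircase_finished")
})

test_that("SRT estimator implements discard-8 / average-16 and its traces", {
  cfg <- din_staircase_config()
  expect_equal(estimate_srt_final_trials(staircase_run(cfg, rep(TRUE, 24))),
               -19.625, tolerance = 1e-12)
  expect_equal(estimate_srt_final_trials(staircase_run(cfg, rep(FALSE, 24))),
               19.625, tolerance = 1e-12)
  expect_equal(
    estimate_srt_final_trials(staircase_run(cfg, rep(c(TRUE, FALSE), 12))),
    -1, tolerance = 1e-12)
  # wrong trial count violates the contract
  st <- staircase_run(cfg, rep(TRUE, 10))
  expect_error(estimate_srt_final_trials(st),
               class = "auditest_contract_error")
  # estimator depends only on presented levels
  st24 <- staircase_run(cfg, rep(c(TRUE, TRUE, FALSE), 8))
  expect_equal(estimate_srt_final_trials(st24), mean(st24$levels[9:24]))
})

test_that("reversal-mean estimator averages the last four reversal levels", {
  st <- staircase_run(stripes_staircase_config(), rep(c(TRUE, TRUE, FALSE), 40))
  expect_equal(estimate_threshold_reversal_mean(st),
               mean(tail(st$reversal_level, 4)))
  expect_error(estimate_threshold_reversal_mean(st, n_last = 9),
               class = "auditest_contract_error")
  unfinished <- staircase_run(stripes_staircase_config(), rep(TRUE, 6))
  expect_error(estimate_threshold_reversal_mean(unfinished),
               class = "auditest_contract_error")
})

test_that("combine_runs is the arithmetic mean", {
  expect_equal(combine_runs(c(4, 6)), 5)
  expect_equal(combine_runs(5), 5)
  expect_equal(combine_runs(c(1.9, 8.5)), 5.2)
  expect_error(combine_runs(numeric(0)), class = "auditest_bad_argument")
})

test_that("staircase configs round-trip through JSON", {
  for (cfg in list(din_staircase_config(), stripes_staircase_config())) {
    js <- staircase_config_to_json(cfg)
    back <- staircase_config_from_json(js)
    expect_equal(back$n_up, cfg$n_up)
    expect_equal(back$harder_direction, cfg$harder_direction)
    expect_equal(as.data.frame(back$step_schedule),
                 as.data.frame(cfg$step_schedule))
    expect_equal(back$stop_rule$type, cfg$stop_rule$type)
    expect_equal(back$stop_rule$n, cfg$stop_rule$n)
    # identical trajectories under the restored config
    set.seed(9)
    resp <- runif(60) < 0.6
    expect_identical(staircase_run(back, resp)$levels,
                     staircase_run(cfg, resp)$levels)
  }
})

test_that("config validation catches inconsistent parameters", {
  expect_error(staircase_config(0, 1, tibble::tibble(after_reversals = 0,
                                                     step = 1),
                                0, -1, 1, -1, stop_after_trials(5)),
               class = "auditest_bad_config")
  expect_error(staircase_config(1, 1, tibble::tibble(after_reversals = 0,
                                                     step = -2),
                                0, -1, 1, -1, stop_after_trials(5)),
               class = "auditest_bad_config")
  expect_error(staircase_config(1, 1, tibble::tibble(after_reversals = 0,
                                                     step = 1),
                                5, -1, 1, -1, stop_after_trials(5)),
               class = "auditest_bad_config")
})
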