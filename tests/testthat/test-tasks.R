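make_manifest <- function(n = 21) {
  tibble::tibble(
    filename = sprintf("stim%02d.wav", seq_len(n)),
    difficulty_level = seq(-20, by = 2, length.out = n)
  )
}

test_that("ordered selection honors fixed, random and adaptive modes", {
  m <- make_manifest()
  fixed <- task_spec("ordered", "constant_fixed")
  expect_equal(ordered_next_stimulus(fixed, m), m$filename[1])
  expect_equal(ordered_next_stimulus(fixed, m, history = m$filename[1:3]),
               m$filename[4])
  rnd <- task_spec("ordered", "constant_random")
  seq1 <- character(0)
  for (i in seq_len(nrow(m))) {
    seq1 <- c(seq1, ordered_next_stimulus(rnd, m, history = seq1, seed = 5))
  }
  # permutation property: each stimulus exactly once, and replayable
  expect_setequal(seq1, m$filename)
  expect_equal(ordered_next_stimulus(rnd, m, history = seq1[1:4], seed = 5),
               seq1[5])
  adap <- task_spec("ordered", "adaptive")
  expect_equal(ordered_next_stimulus(adap, m, level = -2),
               m$filename[m$difficulty_level == -2])
  expect_error(ordered_next_stimulus(adap, m, level = -3),
               class = "auditest_manifest_error")
  expect_error(ordered_next_stimulus(fixed, m, history = m$filename),
               class = "auditest_task_complete")
})

test_that("paired comparisons enumerate the cross product deterministically", {
  a <- paste0("a", 1:3); b <- paste0("b", 1:4)
  p <- paired_comparisons(a, b, order_balance = FALSE)
  expect_equal(nrow(p), 12)
  expect_equal(nrow(dplyr::distinct(p)), 12)
  expect_equal(nrow(paired_comparisons("x", "y", order_balance = FALSE)), 1)
  # determinism of balanced orders
  p1 <- paired_comparisons(a, b, seed = 3)
  p2 <- paired_comparisons(a, b, seed = 3)
  expect_identical(p1, p2)
  # every pair still covers one a and one b after flipping
  expect_true(all(xor(p1$first %in% a, p1$second %in% a)))
  # within-set mode: C(4, 2) pairs of the pooled set
  pw <- paired_comparisons(b, within_set = TRUE, order_balance = FALSE)
  expect_equal(nrow(pw), 6)
  expect_error(paired_comparisons(character(), b),
               class = "auditest_bad_argument")
})

test_that("binary-insertion ranking recovers any transitive order exactly", {
  # exhaustive over all permutations of n = 2..6 (720 cases at n = 6)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  for (n in 2:6) {
    latent <- stats::setNames(seq_len(n), paste0("s", seq_len(n)))
    bound <- sum(ceiling(log2(2:n)))
    for (p in perms(names(latent))) {
      res <- ranking_run(p, function(a, b) latent[[a]] > latent[[b]])
      expect_identical(res$ranked, names(sort(latent, decreasing = TRUE)))
      expect_lte(res$n_comparisons, bound)
    }
  }
})

test_that("ranking respects the comparison bound at larger randomized n", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(7:50, 1)
    ids <- paste0("s", sample(n))
    latent <- stats::setNames(sample(n), ids)
    res <- ranking_run(ids, function(a, b) latent[[a]] > latent[[b]])
    expect_identical(res$ranked,
                     names(sort(latent, decreasing = TRUE)))
    expect_lte(res$n_comparisons, sum(ceiling(log2(2:n))))
  }
})

test_that("ranking edge cases behave", {
  # a single stimulus ranks itself with zero comparisons
  one <- ranking_start("only")
  expect_true(ranking_finished(one))
  expect_error(ranking_next_comparison(one),
               class = "auditest_task_complete")
  # a probe-always-wins comparator sinks the candidate to the bottom
  res <- ranking_run(c("a", "b", "c"), function(cand, probe) FALSE)
  expect_equal(res$ranked[3], "c")
  # inserting the 3rd stimulus takes at most 2 comparisons
  res3 <- ranking_run(c("a", "b", "c"),
                      function(x, y) match(x, c("c", "b", "a")) <
                        match(y, c("c", "b", "a")))
  expect_identical(res3$ranked, c("c", "b", "a"))
  # an intransitive transcript still yields a total order without error
  flip <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  k <- 0
  res_bad <- ranking_run(paste0("s", 1:4), function(a, b) {
    k <<- k + 1
    flip[(k - 1) %% length(flip) + 1]
  })
  expect_length(res_bad$ranked, 4)
  expect_false(anyDuplicated(res_bad$ranked) > 0)
  # winner outside the active pair is rejected
  st <- ranking_start(c("a", "b"))
  expect_error(ranking_record_outcome(st, "zz"),
               class = "auditest_bad_argument")
})

test_that("the session state machine warns, terminates and completes", {
  task <- task_spec("ordered", "constant_fixed", max_trials = 2, n_runs = 2)
  pol <- inactivity_policy(warn_after_s = 60, terminate_after_s = 180)
  s <- session_start(task, pol)
  s <- advance_session(s, session_tick(61))
  expect_equal(s$status, "warned")
  # a response resets the idle clock
  s <- advance_session(s, session_response(trial_record("t1")))
  expect_equal(s$status, "running")
  s <- advance_session(s, session_tick(59))
  expect_equal(s$status, "running")
  s <- advance_session(s, session_tick(2))
  expect_equal(s$status, "warned")
  # crossing the termination threshold preserves recorded trials
  s <- advance_session(s, session_tick(120))
  expect_equal(s$status, "terminated")
  expect_equal(nrow(session_trials(s)), 1)
  expect_error(advance_session(s, session_tick(1)),
               class = "auditest_session_closed")
})

test_that("runs and completion honor max_trials and n_runs", {
  task <- task_spec("ordered", "constant_fixed", max_trials = 2, n_runs = 2)
  s <- session_start(task, inactivity_policy())
  for (i in 1:3) {
    s <- advance_session(s, session_response(trial_record(paste0("t", i))))
  }
  expect_equal(s$status, "running")
  expect_equal(s$runs_completed, 1L)
  s <- advance_session(s, session_response(trial_record("t4")))
  expect_equal(s$status, "complete")
  expect_equal(nrow(session_trials(s)), 4)
  expect_error(advance_session(s, session_response(trial_record("t5"))),
               class = "auditest_session_closed")
})

test_that("task specs validate interfaces and round-trip through JSON", {
  expect_error(task_spec(response_interface = list(type = "buttons",
                                                   labels = letters[1:6])),
               class = "auditest_bad_task")
  expect_error(task_spec(response_interface = list(
    type = "matrix", categories = list(letters[1:6]))),
    class = "auditest_bad_task")
  expect_error(inactivity_policy(100, 50), class = "auditest_bad_task")
  task <- task_spec("ordered", "adaptive",
                    response_interface = list(type = "keypad"),
                    max_trials = 24, n_runs = 2)
  back <- task_spec_from_json(task_spec_to_json(task))
  expect_equal(back$structure, "ordered")
  expect_equal(back$mode, "adaptive")
  expect_equal(back$max_trials, 24)
  expect_equal(back$n_runs, 2L)
})
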