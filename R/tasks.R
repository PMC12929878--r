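#' Listening-task specification
#'
#' Describes one runnable listening task: its structure (ordered list,
#' paired comparison, or ranking), presentation mode, response interface,
#' feedback policy, and run/phase plan.
#'
#' @param structure `"ordered"`, `"paired"` or `"ranked"`.
#' @param mode `"constant_fixed"`, `"constant_random"` or `"adaptive"`
#'   (adaptive applies to the ordered structure and steps through manifest
#'   difficulty levels under a staircase).
#' @param response_interface A list with element `type` in `"buttons"`
#'   (up to 5 labels), `"keypad"` (digits 0-9), `"matrix"` (10 categories
#'   of up to 5 keywords), `"text"` or `"recording"`; plus `labels` /
#'   `categories` where relevant.
#' @param feedback `"overall"`, `"item_specific"` or `"none"`.
#' @param allow_repeat May the listener replay a stimulus?
#' @param max_trials Trials per run (optional for self-terminating modes).
#' @param n_runs Number of runs of the task (>= 1).
#' @param phases Optional list of phase descriptors (free-form lists with
#'   at least a `name`).
#' @param phase_order `"fixed"` or `"randomized"`.
#' @param practice_phase Optional practice phase descriptor; its trials
#'   are flagged and excluded from scoring.
#' @param instructions_pre,instructions_post Instruction texts.
#' @return A `task_spec` object.
#' @export
task_spec <- function(structure = c("ordered", "paired", "ranked"),
                      mode = c("constant_fixed", "constant_random",
                               "adaptive"),
                      response_interface = list(type = "buttons",
                                                labels = c("A", "B")),
                      feedback = c("overall", "item_specific", "none"),
                      allow_repeat = FALSE, max_trials = NULL, n_runs = 1L,
                      phases = list(), phase_order = c("fixed", "randomized"),
                      practice_phase = NULL,
                      instructions_pre = "", instructions_post = "") {
  structure_ <- match.arg(structure)
  mode <- match.arg(mode)
  feedback <- match.arg(feedback)
  phase_order <- match.arg(phase_order)
  ri <- response_interface
  if (!is.list(ri) || is.null(ri$type) ||
      !ri$type %in% c("buttons", "keypad", "matrix", "text", "recording")) {
    abort("Unknown response interface type.", class = "auditest_bad_task")
  }
  if (ri$type == "buttons" && length(ri$labels %||% character()) > 5L) {
    abort("Button interfaces allow at most 5 labels.",
          class = "auditest_bad_task")
  }
  if (ri$type == "matrix") {
    cats <- ri$categories %||% list()
    if (length(cats) > 10L || any(lengths(cats) > 5L)) {
      abort("Matrix interfaces allow 10 categories of up to 5 keywords.",
            class = "auditest_bad_task")
    }
  }
  if (n_runs < 1L) abort("`n_runs` must be >= 1.", class = "auditest_bad_task")
  structure(
    list(structure = structure_, mode = mode, response_interface = ri,
         feedback = feedback, allow_repeat = isTRUE(allow_repeat),
         max_trials = max_trials, n_runs = as.integer(n_runs),
         phases = phases, phase_order = phase_order,
         practice_phase = practice_phase,
         instructions_pre = instructions_pre,
         instructions_post = instructions_post),
    class = "task_spec"
  )
}

#' Serialize / restore a task specification
#'
#' @param task A [task_spec()].
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string or `path` invisibly; `task_spec_from_json()`
#'   returns a [task_spec()].
#' @export
task_spec_to_json <- function(task, path = NULL) {
  stopifnot(inherits(task, "task_spec"))
  js <- jsonlite::toJSON(unclass(task), auto_unbox = TRUE, null = "null",
                         digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname task_spec_to_json
#' @param json JSON string or file path.
#' @export
task_spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  do.call(task_spec, x[intersect(names(x), names(formals(task_spec)))])
}

#' Inactivity policy for a session
#'
#' After `warn_after_s` seconds without a response the session issues a
#' warning; after `terminate_after_s` it terminates, preserving all trials
#' recorded so far.
#'
#' @param warn_after_s,terminate_after_s Durations in seconds with
#'   `warn_after_s < terminate_after_s`.
#' @return An `inactivity_policy` object.
#' @export
inactivity_policy <- function(warn_after_s = 60, terminate_after_s = 180) {
  if (!(warn_after_s > 0 && warn_after_s < terminate_after_s)) {
    abort("Require 0 < warn_after_s < terminate_after_s.",
          class = "auditest_bad_task")
  }
  structure(list(warn_after_s = warn_after_s,
                 terminate_after_s = terminate_after_s),
            class = "inactivity_policy")
}

#' Next stimulus of an ordered task
#'
#' @param task A [task_spec()] with structure `"ordered"`.
#' @param manifest A stimulus manifest tibble (see [load_manifest()]).
#' @param history Character vector of stimulus filenames already
#'   presented this run.
#' @param seed Integer seed fixing the permutation in
#'   `constant_random` mode.
#' @param level Current staircase level (required in `adaptive` mode);
#'   the row whose `difficulty_level` equals it is selected.
#' @return A single stimulus filename.
#' @export
ordered_next_stimulus <- function(task, manifest, history = character(),
                                  seed = 1L, level = NULL) {
  stopifnot(inherits(task, "task_spec"))
  manifest <- as_tibble(manifest)
  n <- nrow(manifest)
  if (task$mode %in% c("constant_fixed", "constant_random") &&
      length(history) >= n) {
    abort("All stimuli of this run have been presented.",
          class = "auditest_task_complete")
  }
  switch(task$mode,
    constant_fixed = manifest$filename[length(history) + 1L],
    constant_random = {
      perm <- withr::with_seed(seed, sample.int(n))
      manifest$filename[perm[length(history) + 1L]]
    },
    adaptive = {
      if (is.null(level)) {
        abort("Adaptive mode needs the staircase `level`.",
              class = "auditest_bad_argument")
      }
      hit <- which(abs(manifest$difficulty_level - level) < 1e-9)
      if (length(hit) == 0L) {
        abort(sprintf("No manifest entry at difficulty level %g.", level),
              class = "auditest_manifest_error")
      }
      manifest$filename[hit[1L]]
    }
  )
}

#' Enumerate paired comparisons between two stimulus sets
#'
#' By default every cross-set pair A x B is produced, the natural design
#' for comparing two processing conditions item by item. `within_set =
#' TRUE` instead enumerates all unordered pairs of the pooled set. With
#' `order_balance` the within-pair presentation order is randomized
#' per pair under the seed.
#'
#' @param set_a,set_b Nonempty character vectors of stimulus ids
#'   (`set_b` ignored when `within_set = TRUE`).
#' @param order_balance Randomize within-pair order?
#' @param seed Integer seed.
#' @param within_set Enumerate C(n, 2) pairs of `set_a` instead of the
#'   cross product.
#' @return A tibble with columns `first` and `second`.
#' @export
paired_comparisons <- function(set_a, set_b = NULL, order_balance = TRUE,
                               seed = 1L, within_set = FALSE) {
  if (length(set_a) == 0L || (!within_set && length(set_b %||% character()) == 0L)) {
    abort("Stimulus sets must be nonempty.", class = "auditest_bad_argument")
  }
  pairs <- if (within_set) {
    if (length(set_a) < 2L) {
      abort("Within-set pairing needs at least two stimuli.",
            class = "auditest_bad_argument")
    }
    idx <- utils::combn(length(set_a), 2L)
    tibble(first = set_a[idx[1, ]], second = set_a[idx[2, ]])
  } else {
    tidyr::expand_grid(first = set_a, second = set_b)
  }
  if (order_balance) {
    flip <- withr::with_seed(seed, runif(nrow(pairs)) < 0.5)
    tmp <- pairs$first[flip]
    pairs$first[flip] <- pairs$second[flip]
    pairs$second[flip] <- tmp
  }
  pairs
}

#' Start a ranking by binary insertion
#'
#' The ranked task obtains a unique best-to-worst order of stimuli from
#' paired comparisons using binary insertion: each pending stimulus is
#' compared against the midpoint of its current search interval in the
#' ranked-so-far list, halving the interval per judgment, which attains
#' the information-theoretic bound of ceiling(log2 k) comparisons for the
#' k-th insertion.
#'
#' @param ids Character vector of stimulus ids (no duplicates).
#' @return A `ranking_state` object.
#' @export
ranking_start <- function(ids) {
  ids <- as.character(ids)
  if (length(ids) == 0L || anyDuplicated(ids)) {
    abort("`ids` must be nonempty and free of duplicates.",
          class = "auditest_bad_argument")
  }
  structure(
    list(ranked = ids[1L], pending = ids[-1L],
         candidate = NULL, low = NA_integer_, high = NA_integer_,
         n_comparisons = 0L),
    class = "ranking_state"
  )
}

#' Next comparison of a ranking
#'
#' @param state A `ranking_state`.
#' @return `NULL` when the ranking is complete; otherwise a list with the
#'   `candidate` (the stimulus being inserted) and the `probe` (the ranked
#'   stimulus at the midpoint of the search interval, even intervals
#'   rounding toward the better-ranked end).
#' @export
ranking_next_comparison <- function(state) {
  stopifnot(inherits(state, "ranking_state"))
  if (ranking_finished(state)) {
    abort("Ranking already complete.", class = "auditest_task_complete")
  }
  if (is.null(state$candidate)) {
    # activate the next pending candidate lazily; search over insertion
    # positions 1..m+1 of the ranked list
    state$candidate <- state$pending[1L]
    state$low <- 1L
    state$high <- length(state$ranked) + 1L
  }
  mid <- (state$low + state$high) %/% 2L
  list(candidate = state$candidate, probe = state$ranked[mid],
       state = state)
}

#' Is a ranking complete?
#' @param state A `ranking_state`.
#' @return TRUE when every stimulus has been inserted.
#' @export
ranking_finished <- function(state) {
  length(state$pending) == 0L && is.null(state$candidate)
}

#' Record the outcome of a ranking comparison
#'
#' @param state The `ranking_state` returned inside
#'   [ranking_next_comparison()]'s result (it carries the active
#'   candidate), or a fresh state.
#' @param winner The preferred stimulus id; must be the active candidate
#'   or the active probe.
#' @return The updated `ranking_state`.
#' @export
ranking_record_outcome <- function(state, winner) {
  stopifnot(inherits(state, "ranking_state"))
  if (ranking_finished(state)) {
    abort("Ranking already complete.", class = "auditest_task_complete")
  }
  if (is.null(state$candidate)) {
    state$candidate <- state$pending[1L]
    state$low <- 1L
    state$high <- length(state$ranked) + 1L
  }
  mid <- (state$low + state$high) %/% 2L
  probe <- state$ranked[mid]
  if (!winner %in% c(state$candidate, probe)) {
    abort("`winner` is not part of the active comparison.",
          class = "auditest_bad_argument")
  }
  state$n_comparisons <- state$n_comparisons + 1L
  if (winner == state$candidate) {
    state$high <- mid            # candidate ranks above the probe
  } else {
    state$low <- mid + 1L        # candidate ranks below the probe
  }
  if (state$low >= state$high) {
    pos <- state$low
    state$ranked <- append(state$ranked, state$candidate, after = pos - 1L)
    state$pending <- state$pending[-1L]
    state$candidate <- NULL
    state$low <- NA_integer_
    state$high <- NA_integer_
  }
  state
}

#' Rank stimuli with a comparator function
#'
#' Convenience driver for simulations and tests: runs the full binary
#' insertion using `prefer(a, b)`, which returns TRUE when `a` is
#' preferred over `b`.
#'
#' @param ids Stimulus ids.
#' @param prefer Function of two ids returning TRUE if the first wins.
#' @return A list with `ranked` (best to worst) and `n_comparisons`.
#' @export
ranking_run <- function(ids, prefer) {
  state <- ranking_start(ids)
  while (!ranking_finished(state)) {
    cmp <- ranking_next_comparison(state)
    state <- cmp$state
    winner <- if (isTRUE(prefer(cmp$candidate, cmp$probe))) {
      cmp$candidate
    } else {
      cmp$probe
    }
    state <- ranking_record_outcome(state, winner)
  }
  list(ranked = state$ranked, n_comparisons = state$n_comparisons)
}

#' Open a listening-task session
#'
#' @param task A [task_spec()].
#' @param policy An [inactivity_policy()].
#' @return A `task_session` object in status `"running"`.
#' @export
session_start <- function(task, policy = inactivity_policy()) {
  stopifnot(inherits(task, "task_spec"), inherits(policy, "inactivity_policy"))
  structure(
    list(task = task, policy = policy, status = "running",
         idle_s = 0, trials = list(), trials_this_run = 0L,
         runs_completed = 0L, comfort_gain_db = NULL),
    class = "task_session"
  )
}

#' Advance a session by a response or a clock tick
#'
#' The session state machine drives the inactivity policy: ticks without a
#' response accumulate idle time, crossing the warning then the
#' termination threshold; any response resets the idle clock. Completing
#' `max_trials` trials finishes the run, and completing `n_runs` runs
#' completes the session. Recorded trials are preserved on warning and on
#' termination.
#'
#' @param session A `task_session`.
#' @param event Either `session_response(record)` or
#'   `session_tick(seconds)`.
#' @return The updated `task_session`; inspect `$status` for one of
#'   `"running"`, `"warned"`, `"terminated"`, `"complete"`.
#' @export
advance_session <- function(session, event) {
  stopifnot(inherits(session, "task_session"))
  if (session$status %in% c("terminated", "complete")) {
    abort(sprintf("Session is %s; no further events accepted.",
                  session$status),
          class = "auditest_session_closed")
  }
  stopifnot(inherits(event, "session_event"))
  pol <- session$policy
  if (event$type == "tick") {
    session$idle_s <- session$idle_s + event$seconds
    if (session$idle_s > pol$terminate_after_s) {
      session$status <- "terminated"
    } else if (session$idle_s > pol$warn_after_s) {
      session$status <- "warned"
    }
  } else { # response
    session$idle_s <- 0
    session$status <- "running"
    session$trials <- c(session$trials, list(event$record))
    session$trials_this_run <- session$trials_this_run + 1L
    mt <- session$task$max_trials
    if (!is.null(mt) && session$trials_this_run >= mt) {
      session$runs_completed <- session$runs_completed + 1L
      session$trials_this_run <- 0L
      if (session$runs_completed >= session$task$n_runs) {
        session$status <- "complete"
      }
    }
  }
  session
}

#' Session events
#'
#' @param record A trial record (see [trial_record()]) to log with the
#'   response.
#' @return A `session_event`.
#' @export
session_response <- function(record = NULL) {
  structure(list(type = "response", record = record),
            class = "session_event")
}

#' @rdname session_response
#' @param seconds Elapsed seconds of inactivity.
#' @export
session_tick <- function(seconds) {
  structure(list(type = "tick", seconds = seconds), class = "session_event")
}

#' Collect a session's trial records
#'
#' @param session A `task_session`.
#' @return A tibble of trial records (zero rows if none were recorded).
#' @export
session_trials <- function(session) {
  stopifnot(inherits(session, "task_session"))
  if (length(session$trials) == 0L) return(empty_trial_records())
  dplyr::bind_rows(session$trials)
}
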