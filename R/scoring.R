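#' Normalize response or key tokens
#'
#' Lower-cases and strips punctuation so scoring compares canonical word
#' tokens.
#'
#' @param tokens Character vector of words (or a single string, which is
#'   split on whitespace).
#' @return Character vector of normalized tokens.
#' @export
normalize_tokens <- function(tokens) {
  if (length(tokens) == 1L && grepl("\\s", tokens)) {
    tokens <- strsplit(tokens, "\\s+")[[1]]
  }
  tokens <- stringr::str_to_lower(tokens)
  tokens <- stringr::str_remove_all(tokens, "[[:punct:]]")
  tokens[nzchar(tokens)]
}

#' Keyword key for one sentence
#'
#' Sentence tests of the Bamford-Kowal-Bench kind are scored on exactly
#' three keywords per sentence.
#'
#' @param keywords Character vector of exactly three keywords.
#' @return A `keyword_key` object (tokens stored normalized).
#' @export
keyword_key <- function(keywords) {
  keywords <- normalize_tokens(keywords)
  if (length(keywords) != 3L) {
    abort("A keyword key holds exactly 3 keywords.",
          class = "auditest_bad_argument")
  }
  structure(list(keywords = keywords), class = "keyword_key")
}

#' Score a sentence response against its keyword key
#'
#' Counts how many of the three key words appear in the response, each
#' credited at most once, giving a per-trial score of 0-3. Matching is
#' exact token match after normalization; morphological leniency
#' (plural/tense variants) can be enabled with `lenient = TRUE`, which
#' additionally accepts a trailing "s"/"es"/"ed"/"ing" difference.
#'
#' @param response_tokens Response words (string or character vector).
#' @param key A [keyword_key()].
#' @param lenient Allow simple morphological variants?
#' @return Integer score 0-3.
#' @export
score_keywords <- function(response_tokens, key, lenient = FALSE) {
  stopifnot(inherits(key, "keyword_key"))
  resp <- normalize_tokens(response_tokens)
  if (length(resp) == 0L) return(0L)
  hit <- function(kw) {
    if (kw %in% resp) return(TRUE)
    if (!lenient) return(FALSE)
    variants <- function(w) unique(c(
      w, paste0(w, "s"), paste0(w, "es"), paste0(w, "ed"), paste0(w, "ing"),
      sub("(s|es|ed|ing)$", "", w)
    ))
    any(variants(kw) %in% unlist(lapply(resp, variants)))
  }
  sum(vapply(key$keywords, hit, logical(1)))
}

#' Aggregate keyword scores into a percent-correct
#'
#' A list of 15 sentences scored 0-3 each yields a percentage of the 45
#' possible keywords.
#'
#' @param scores Integer vector of per-trial scores, each in 0-3.
#' @param n_expected Expected number of trials (default 15; `NULL` to
#'   accept any length).
#' @return Percent correct in 0-100.
#' @export
aggregate_keyword_list <- function(scores, n_expected = 15L) {
  if (any(scores < 0 | scores > 3 | scores != round(scores))) {
    abort("Keyword scores must be integers in 0-3.",
          class = "auditest_bad_argument")
  }
  if (!is.null(n_expected) && length(scores) != n_expected) {
    abort(sprintf("Expected %d trial scores, got %d.", n_expected,
                  length(scores)),
          class = "auditest_contract_error")
  }
  100 * sum(scores) / (3 * length(scores))
}

#' Score one digits-in-noise trial
#'
#' All-or-nothing: the trial is correct only if all three digits were
#' reported correctly and in order. Responses with the wrong length are
#' incorrect, never an error.
#'
#' @param response_digits Reported digits.
#' @param presented_digits The three presented digits.
#' @return TRUE/FALSE.
#' @export
score_din_trial <- function(response_digits, presented_digits) {
  presented_digits <- as.integer(presented_digits)
  stopifnot(length(presented_digits) == 3L)
  response_digits <- suppressWarnings(as.integer(response_digits))
  if (length(response_digits) != 3L || anyNA(response_digits)) return(FALSE)
  all(response_digits == presented_digits)
}

#' Assemble per-condition, per-run score summaries
#'
#' Groups completed trial records by condition and run, excludes
#' practice-flagged trials, and computes the task's summary score:
#' keyword tasks report percent correct over the 0-3 trial scores,
#' all-or-nothing tasks report percent of correct trials. Adaptive
#' threshold tasks summarize through the staircase estimators instead and
#' are rejected here.
#'
#' @param trials A trial-record tibble (see [trial_record()]); keyword
#'   tasks carry the 0-3 score in `response`, other tasks carry
#'   `correct`.
#' @param task A [task_spec()].
#' @param score_type `"keyword"` (0-3 per trial) or `"binary"`.
#' @return A tibble with one row per condition x run: `condition`, `run`,
#'   `n_trials`, `percent_correct`.
#' @export
assemble_results <- function(trials, task,
                             score_type = c("keyword", "binary")) {
  score_type <- match.arg(score_type)
  stopifnot(inherits(task, "task_spec"))
  trials <- as_tibble(trials)
  if (length(unique(trials$phase)) > 1L &&
      any(table(trials$phase, trials$condition) == 0)) {
    # mixed phases are fine; mixed tasks are not - detected by schema use
  }
  scored <- dplyr::filter(trials, !.data$practice)
  if (score_type == "keyword") {
    sc <- suppressWarnings(as.integer(scored$response))
    if (anyNA(sc) || any(sc < 0 | sc > 3)) {
      abort("Keyword trials must carry a 0-3 score in `response`; mixed or non-keyword trial sets are rejected.",
            class = "auditest_bad_argument")
    }
    scored$score <- sc
    dplyr::summarise(
      dplyr::group_by(scored, .data$condition, .data$run),
      n_trials = dplyr::n(),
      percent_correct = 100 * sum(.data$score) / (3 * dplyr::n()),
      .groups = "drop"
    )
  } else {
    if (anyNA(scored$correct)) {
      abort("Binary-scored trials must carry TRUE/FALSE in `correct`.",
            class = "auditest_bad_argument")
    }
    dplyr::summarise(
      dplyr::group_by(scored, .data$condition, .data$run),
      n_trials = dplyr::n(),
      percent_correct = 100 * mean(.data$correct),
      .groups = "drop"
    )
  }
}
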