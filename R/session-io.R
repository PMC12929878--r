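results_schema_version <- 1L

#' One trial record
#'
#' The atom of result export: one presented stimulus, the response and
#' its timing.
#'
#' @param stimulus_id Stimulus filename or id.
#' @param condition Condition label.
#' @param level Presented level in tracked units (NA for constant tasks).
#' @param response Response payload, stored as character.
#' @param correct Logical or NA for unscoreable tasks.
#' @param response_time_ms Nonnegative response time.
#' @param timestamp UTC ISO-8601 string.
#' @param run Run index (1-based).
#' @param phase Phase label.
#' @param practice Practice flag; practice trials are excluded from
#'   scoring.
#' @return A one-row tibble with the versioned trial-record schema.
#' @export
trial_record <- function(stimulus_id, condition = "default",
                         level = NA_real_, response = NA_character_,
                         correct = NA, response_time_ms = 0,
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                            tz = "UTC"),
                         run = 1L, phase = "main", practice = FALSE) {
  if (response_time_ms < 0) {
    abort("`response_time_ms` must be >= 0.", class = "auditest_bad_argument")
  }
  tibble(
    stimulus_id = as.character(stimulus_id),
    condition = as.character(condition),
    level = as.double(level),
    response = as.character(response),
    correct = as.logical(correct),
    response_time_ms = as.double(response_time_ms),
    timestamp = as.character(timestamp),
    run = as.integer(run),
    phase = as.character(phase),
    practice = as.logical(practice)
  )
}

empty_trial_records <- function() trial_record("x")[0, ]

trial_record_cols <- function() {
  readr::cols(
    stimulus_id = readr::col_character(),
    condition = readr::col_character(),
    level = readr::col_double(),
    response = readr::col_character(),
    correct = readr::col_logical(),
    response_time_ms = readr::col_double(),
    timestamp = readr::col_character(),
    run = readr::col_integer(),
    phase = readr::col_character(),
    practice = readr::col_logical()
  )
}

#' Load and validate a stimulus manifest
#'
#' A manifest is a UTF-8 CSV with a mandatory header binding each audio
#' file to its task properties. Recognized columns: `filename`
#' (mandatory, unique), `difficulty_level` (mandatory for adaptive
#' tasks), `response_options` (labels separated by `|`),
#' `correct_answer` and `condition`. Closed-set tasks require
#' response options containing the correct answer. Every validation
#' failure is reported with its row number.
#'
#' @param path Manifest CSV path.
#' @param task_type `"any"`, `"adaptive"` or `"closed_set"` - controls
#'   which columns are mandatory.
#' @param audio_dir Directory the filenames are relative to (defaults to
#'   the manifest's directory).
#' @param check_audio Verify that every referenced file exists and reads
#'   as mono WAV?
#' @return The validated manifest as a tibble, with attribute `"levels"`
#'   giving the sorted unique difficulty levels when present.
#' @export
load_manifest <- function(path, task_type = c("any", "adaptive",
                                              "closed_set"),
                          audio_dir = dirname(path), check_audio = TRUE) {
  task_type <- match.arg(task_type)
  if (!file.exists(path)) {
    abort(sprintf("Manifest not found: %s", path),
          class = "auditest_manifest_error")
  }
  m <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  if (!"filename" %in% names(m)) {
    abort("Manifest must have a `filename` column.",
          class = "auditest_manifest_error")
  }
  problems <- character()
  bad <- function(row, msg) sprintf("row %d: %s", row, msg)
  dup <- duplicated(m$filename)
  for (i in which(dup)) {
    problems <- c(problems, bad(i, sprintf("duplicate filename '%s'",
                                           m$filename[i])))
  }
  if ("difficulty_level" %in% names(m)) {
    lv <- suppressWarnings(as.numeric(m$difficulty_level))
    for (i in which(is.na(lv) & !is.na(m$difficulty_level))) {
      problems <- c(problems, bad(i, "difficulty_level is not numeric"))
    }
    m$difficulty_level <- lv
  } else if (task_type == "adaptive") {
    abort("Adaptive tasks require a `difficulty_level` column.",
          class = "auditest_manifest_error")
  }
  if (task_type == "adaptive") {
    for (i in which(is.na(m$difficulty_level))) {
      problems <- c(problems, bad(i, "missing difficulty_level"))
    }
  }
  if (task_type == "closed_set") {
    for (col in c("response_options", "correct_answer")) {
      if (!col %in% names(m)) {
        abort(sprintf("Closed-set tasks require a `%s` column.", col),
              class = "auditest_manifest_error")
      }
    }
  }
  if (all(c("response_options", "correct_answer") %in% names(m))) {
    for (i in seq_len(nrow(m))) {
      opts <- m$response_options[i]
      ans <- m$correct_answer[i]
      if (is.na(opts) || is.na(ans)) {
        if (task_type == "closed_set") {
          problems <- c(problems, bad(i, "missing response options or answer"))
        }
        next
      }
      if (!ans %in% strsplit(opts, "|", fixed = TRUE)[[1]]) {
        problems <- c(problems, bad(
          i, sprintf("correct_answer '%s' not among response options '%s'",
                     ans, opts)))
      }
    }
  }
  if (check_audio) {
    for (i in seq_len(nrow(m))) {
      f <- file.path(audio_dir, m$filename[i])
      if (!file.exists(f)) {
        problems <- c(problems, bad(i, sprintf("audio file missing: %s",
                                               m$filename[i])))
      } else {
        ok <- tryCatch({ read_wav(f); TRUE }, error = function(e) FALSE)
        if (!ok) {
          problems <- c(problems, bad(
            i, sprintf("not a readable mono WAV: %s", m$filename[i])))
        }
      }
    }
  }
  if (length(problems) > 0L) {
    abort(paste0("Invalid manifest:\n", paste("-", problems,
                                              collapse = "\n")),
          class = "auditest_manifest_error")
  }
  if ("difficulty_level" %in% names(m)) {
    attr(m, "levels") <- sort(unique(m$difficulty_level[
      !is.na(m$difficulty_level)]))
  }
  m
}

#' Generate an anonymous participant token
#'
#' Tokens are opaque 128-bit hex strings scoped to a project and carry no
#' personal data; at 128 random bits the collision probability between
#' any two tokens is 2^-128, far below 2^-64 for realistic token counts.
#'
#' @param project Project identifier.
#' @param seed Optional integer seed for reproducible token streams
#'   (`NULL` uses the session RNG).
#' @return A one-row tibble: `token`, `project`, `created`.
#' @export
generate_token <- function(project, seed = NULL) {
  draw <- function() {
    paste(sprintf("%02x", sample.int(256L, 16L, replace = TRUE) - 1L),
          collapse = "")
  }
  token <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble(token = token, project = as.character(project),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
}

#' Export session results
#'
#' Writes the per-trial records as CSV and the session settings (with the
#' schema version and trial count) as JSON next to it, so exported
#' sessions are self-describing and round-trip losslessly through
#' [import_results()].
#'
#' @param records Trial-record tibble (see [trial_record()]).
#' @param settings Named list of session settings (task parameters,
#'   seeds, gains ...) embedded for provenance.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Files written: `trials.csv`,
#'   `settings.json`.
#' @export
export_results <- function(records, settings = list(), dir) {
  records <- as_tibble(records)
  required <- names(empty_trial_records())
  missing <- setdiff(required, names(records))
  if (length(missing) > 0L) {
    abort(sprintf("Records are missing columns: %s",
                  paste(missing, collapse = ", ")),
          class = "auditest_bad_argument")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(records[required], file.path(dir, "trials.csv"),
                   na = "")
  meta <- list(schema_version = results_schema_version,
               n_trials = nrow(records), settings = settings)
  jsonlite::write_json(meta, file.path(dir, "settings.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Import session results
#'
#' @param dir Directory written by [export_results()].
#' @return A list with `records` (tibble) and `settings` (list).
#' @export
import_results <- function(dir) {
  sfile <- file.path(dir, "settings.json")
  tfile <- file.path(dir, "trials.csv")
  if (!file.exists(sfile) || !file.exists(tfile)) {
    abort(sprintf("Not a results directory: %s", dir),
          class = "auditest_io_error")
  }
  meta <- jsonlite::fromJSON(sfile, simplifyDataFrame = FALSE)
  if (is.null(meta$schema_version) ||
      meta$schema_version != results_schema_version) {
    abort(sprintf(
      "Results schema version %s does not match supported version %d; migrate the export first.",
      meta$schema_version %||% "<missing>", results_schema_version),
      class = "auditest_schema_mismatch")
  }
  records <- readr::read_csv(tfile, col_types = trial_record_cols(),
                             na = "")
  # drop reader bookkeeping so the round trip is the identity
  attr(records, "spec") <- NULL
  attr(records, "problems") <- NULL
  class(records) <- c("tbl_df", "tbl", "data.frame")
  if (!is.null(meta$n_trials) && nrow(records) != meta$n_trials) {
    abort(sprintf("Trial count mismatch: settings say %d, file has %d.",
                  meta$n_trials, nrow(records)),
          class = "auditest_schema_mismatch")
  }
  list(records = records, settings = meta$settings)
}

#' Bundle / unpack stimulus sets
#'
#' Stimulus sets travel as compressed archives. The bundle format is a
#' gzip-compressed tar built with R's internal tar so no external tool is
#' needed; members unpack byte-identical.
#'
#' @param files Character vector of file paths (e.g. WAVs + manifest).
#' @param bundle Output `.tar.gz` path.
#' @return `bundle` invisibly; `unbundle_stimuli()` returns the unpacked
#'   file paths.
#' @export
bundle_stimuli <- function(files, bundle) {
  miss <- files[!file.exists(files)]
  if (length(miss) > 0L) {
    abort(sprintf("Missing files: %s", paste(miss, collapse = ", ")),
          class = "auditest_io_error")
  }
  owd <- getwd()
  on.exit(setwd(owd))
  # store members by basename so bundles are relocatable
  tmp <- file.path(tempdir(), paste0("bundle-", basename(bundle)))
  dir.create(tmp, showWarnings = FALSE, recursive = TRUE)
  file.copy(files, file.path(tmp, basename(files)), overwrite = TRUE)
  setwd(tmp)
  bundle_abs <- if (grepl("^(/|[A-Za-z]:)", bundle)) bundle else
    file.path(owd, bundle)
  utils::tar(bundle_abs, files = basename(files), compression = "gzip",
             tar = "internal")
  setwd(owd)
  unlink(tmp, recursive = TRUE)
  invisible(bundle)
}

#' @rdname bundle_stimuli
#' @param exdir Directory to unpack into.
#' @export
unbundle_stimuli <- function(bundle, exdir) {
  if (!file.exists(bundle)) {
    abort(sprintf("Bundle not found: %s", bundle),
          class = "auditest_io_error")
  }
  dir.create(exdir, showWarnings = FALSE, recursive = TRUE)
  utils::untar(bundle, exdir = exdir, tar = "internal")
  list.files(exdir, full.names = TRUE)
}
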