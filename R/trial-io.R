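# Trial-table CSV input/output with header and invariant validation.

TRIAL_COLUMNS <- c("participant", "task", "s_v", "s_a", "reliability",
  "response_loc", "response_cat")

#' Write a trial table to CSV
#'
#' @param trials Trial tibble (see [sample_experiment()] for the column
#'   contract). Absent fields are written as empty cells.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  readr::write_csv(trials[, TRIAL_COLUMNS], path, na = "")
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Validates the header, parses degree values as decimals, and checks the
#' task/response-type invariants (UV carries `s_v` + reliability and no `s_a`;
#' UA carries `s_a` only; bisensory tasks carry both stimuli; BC responses are
#' categorical, all other responses continuous). Malformed rows are reported
#' with their row numbers.
#'
#' @param path CSV file written by [write_trials()] or following the same
#'   layout.
#' @return A trial tibble.
#' @export
read_trials <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
    na = character())
  missing <- setdiff(TRIAL_COLUMNS, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Trial file is missing column(s): ", paste(missing, collapse = ", ")))
  }
  num <- function(col) {
    x <- raw[[col]]
    out <- suppressWarnings(as.numeric(x))
    bad <- which(x != "" & is.na(out))
    if (length(bad) > 0) {
      abort(sprintf("Unparseable `%s` value in row(s) %s.", col,
        paste(bad, collapse = ", ")))
    }
    out
  }
  part <- raw$participant
  part_num <- suppressWarnings(as.numeric(part))
  if (!anyNA(part_num)) {
    part <- if (all(part_num == round(part_num))) as.integer(part_num) else part_num
  }
  trials <- tibble::tibble(
    participant = part,
    task = raw$task,
    s_v = num("s_v"),
    s_a = num("s_a"),
    reliability = dplyr::if_else(raw$reliability == "", NA_character_, raw$reliability),
    response_loc = num("response_loc"),
    response_cat = as.integer(num("response_cat"))
  )
  validate_trials(trials)
  trials
}

# Structural invariants of a trial table; called by IO and the engines.
validate_trials <- function(trials) {
  if (!all(TRIAL_COLUMNS %in% names(trials))) {
    abort(paste0("Trial table must have columns: ", paste(TRIAL_COLUMNS, collapse = ", ")))
  }
  bad_task <- which(!trials$task %in% TASKS)
  if (length(bad_task) > 0) {
    abort(sprintf("Unknown task in row(s) %s.", paste(head(bad_task, 5), collapse = ", ")))
  }
  check <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0) {
      abort(sprintf("%s (row(s) %s).", what, paste(head(rows, 5), collapse = ", ")))
    }
  }
  check(trials$task == "UV" & (is.na(trials$s_v) | !is.na(trials$s_a) | is.na(trials$reliability)),
    "UV trials must carry s_v and reliability and no s_a")
  check(trials$task == "UA" & (is.na(trials$s_a) | !is.na(trials$s_v)),
    "UA trials must carry s_a and no s_v")
  check(trials$task %in% c("BC", "BV", "BA") &
          (is.na(trials$s_v) | is.na(trials$s_a) | is.na(trials$reliability)),
    "Bisensory trials must carry s_v, s_a and reliability")
  check(trials$task == "BC" & !is.na(trials$response_loc),
    "BC trials must not carry a continuous response")
  check(trials$task != "BC" & !is.na(trials$response_cat),
    "Localization trials must not carry a categorical response")
  check(!is.na(trials$response_cat) & !trials$response_cat %in% c(1L, 2L),
    "Categorical responses must be 1 (same) or 2 (different)")
  bad_rel <- which(!is.na(trials$reliability) & !trials$reliability %in% RELIABILITIES)
  if (length(bad_rel) > 0) {
    abort(sprintf("Unknown reliability in row(s) %s.",
      paste(head(bad_rel, 5), collapse = ", ")))
  }
  invisible(trials)
}
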