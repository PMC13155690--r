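#' Experiment design for the audiovisual localization study
#'
#' Describes the stimulus-generation scheme of the five-task experiment:
#' unisensory visual (UV) and auditory (UA) localization, bisensory causal
#' judgment (BC), and bisensory localization with visual (BV) or auditory (BA)
#' report. Defaults reproduce the study conditions: 15 participants; 500 UV,
#' 500 UA, 1000 bisensory-localization and 1000 BC trials each; auditory
#' locations on seven speakers at `{0, +/-5, +/-10, +/-15}` degrees; visual
#' locations uniform on `[-20, 20]` degrees; a 0.5 probability that the two
#' stimuli of a bisensory trial share a location; three equiprobable visual
#' reliability levels; responses collected on `[-45, 45]` degrees.
#'
#' @param n_participants Number of participants.
#' @param trials_per_task Named counts for tasks `UV`, `UA`, `B` (bisensory
#'   localization, split between BV and BA response types) and `BC`.
#' @param auditory_locations Speaker locations in degrees.
#' @param visual_range Interval (degrees) for uniform visual sampling.
#' @param p_same_location Probability that a bisensory trial is common-source
#'   (visual location forced equal to the auditory location).
#' @param reliability_levels Ordered visual reliability labels.
#' @param response_range Response interval in degrees.
#' @return An object of class `experiment_design`.
#' @export
#' @examples
#' design <- experiment_design()
#' design$response_range_width
experiment_design <- function(n_participants = 15,
                              trials_per_task = c(UV = 500, UA = 500, B = 1000, BC = 1000),
                              auditory_locations = c(0, -5, 5, -10, 10, -15, 15),
                              visual_range = c(-20, 20),
                              p_same_location = 0.5,
                              reliability_levels = c("high", "medium", "low"),
                              response_range = c(-RANGE_HALF, RANGE_HALF)) {
  needed <- c("UV", "UA", "B", "BC")
  if (!all(needed %in% names(trials_per_task))) {
    abort("`trials_per_task` must name counts for UV, UA, B and BC.")
  }
  trials_per_task <- trials_per_task[needed]
  if (any(trials_per_task <= 0)) abort("All task trial counts must be positive.")
  if (length(auditory_locations) == 0) abort("`auditory_locations` must be non-empty.")
  assert_scalar_prob(p_same_location, "p_same_location")
  if (any(auditory_locations < response_range[1] | auditory_locations > response_range[2]) ||
      visual_range[1] < response_range[1] || visual_range[2] > response_range[2]) {
    abort("Stimulus locations must lie within the response range.")
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      trials_per_task = trials_per_task,
      auditory_locations = sort(auditory_locations),
      visual_range = visual_range,
      p_same_location = p_same_location,
      reliability_levels = reliability_levels,
      response_range = response_range,
      response_range_width = diff(response_range)
    ),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design>\n")
  cat("  participants:", x$n_participants, "\n")
  cat("  trials/task: ", paste(names(x$trials_per_task), x$trials_per_task,
    sep = "=", collapse = ", "), "\n")
  cat("  auditory locations:", paste(x$auditory_locations, collapse = ", "), "deg\n")
  cat(sprintf("  visual range: [%g, %g] deg; p(same) = %g\n",
    x$visual_range[1], x$visual_range[2], x$p_same_location))
  invisible(x)
}

#' Sample the stimuli of a full experiment
#'
#' Draws the stimulus table (no responses) for every participant of a design:
#' auditory locations uniform over the speaker set, visual locations uniform on
#' the visual range except common-source bisensory trials where the visual
#' stimulus is moved onto the speaker, visual reliability uniform over the three
#' levels, and bisensory-localization trials assigned the BV or BA response type
#' with equal probability. Bit-reproducible for a fixed seed.
#'
#' @param design An [experiment_design()].
#' @param seed Integer seed; per-participant substreams are derived with
#'   [derive_seed()].
#' @return A trial tibble with columns `participant`, `task`, `s_v`, `s_a`,
#'   `reliability`, `response_loc`, `response_cat`.
#' @export
#' @examples
#' trials <- sample_experiment(experiment_design(n_participants = 1), seed = 1)
#' nrow(trials)
sample_experiment <- function(design, seed) {
  stopifnot(inherits(design, "experiment_design"))
  purrr::map_dfr(seq_len(design$n_participants), function(p) {
    set.seed(derive_seed(seed, "participant", p))
    sample_participant(design, p)
  })
}

sample_participant <- function(design, participant) {
  n <- design$trials_per_task
  rel <- design$reliability_levels
  vr <- design$visual_range

  uv <- tibble::tibble(
    participant = participant, task = "UV",
    s_v = runif(n[["UV"]], vr[1], vr[2]), s_a = NA_real_,
    reliability = sample(rel, n[["UV"]], replace = TRUE)
  )
  ua <- tibble::tibble(
    participant = participant, task = "UA",
    s_v = NA_real_,
    s_a = sample(design$auditory_locations, n[["UA"]], replace = TRUE),
    reliability = NA_character_
  )
  bis <- function(n_trials, tasks) {
    s_a <- sample(design$auditory_locations, n_trials, replace = TRUE)
    same <- runif(n_trials) < design$p_same_location
    s_v <- ifelse(same, s_a, runif(n_trials, vr[1], vr[2]))
    tibble::tibble(
      participant = participant, task = tasks,
      s_v = s_v, s_a = s_a,
      reliability = sample(rel, n_trials, replace = TRUE)
    )
  }
  b <- bis(n[["B"]], sample(c("BV", "BA"), n[["B"]], replace = TRUE))
  bc <- bis(n[["BC"]], "BC")

  dplyr::bind_rows(uv, ua, b, bc) |>
    dplyr::mutate(response_loc = NA_real_, response_cat = NA_integer_)
}

#' Pixel / degree unit conversion
#'
#' Linear map between screen pixels and degrees of visual angle. The default
#' anchors the map on the stimulus span used in the study: 448 pixels (screen
#' positions 283 to 731) correspond to 40 degrees, i.e. 0.08928 degrees per
#' pixel, with the straight-ahead direction at pixel 507.
#'
#' @param degrees_per_pixel Scale of the linear map (deg/px).
#' @param origin_px Pixel column mapping to 0 degrees.
#' @return An object of class `unit_conversion`.
#' @export
#' @examples
#' conv <- unit_conversion()
#' pixels_to_degrees(731, conv)
unit_conversion <- function(degrees_per_pixel = 40 / 448, origin_px = 507) {
  if (degrees_per_pixel <= 0) abort("`degrees_per_pixel` must be positive.")
  structure(list(degrees_per_pixel = degrees_per_pixel, origin_px = origin_px),
    class = "unit_conversion")
}

#' Convert screen pixels to degrees (and back)
#'
#' @param px Pixel positions (or spans, with `span = TRUE`).
#' @param conv A [unit_conversion()].
#' @param span If `TRUE`, convert a length (no origin shift) rather than a
#'   position.
#' @return Degrees of visual angle.
#' @export
#' @examples
#' pixels_to_degrees(250, unit_conversion(), span = TRUE) # low-reliability radius
pixels_to_degrees <- function(px, conv = unit_conversion(), span = FALSE) {
  if (span) px * conv$degrees_per_pixel else (px - conv$origin_px) * conv$degrees_per_pixel
}

#' @rdname pixels_to_degrees
#' @param deg Degrees of visual angle.
#' @export
degrees_to_pixels <- function(deg, conv = unit_conversion(), span = FALSE) {
  if (span) deg / conv$degrees_per_pixel else deg / conv$degrees_per_pixel + conv$origin_px
}

#' Discard localization responses outside the response range
#'
#' Mirrors the study's preprocessing: continuous location responses outside the
#' response range (default `[-45, 45]` degrees) are discarded; categorical
#' same/different (BC) responses are never removed by this rule.
#'
#' @param trials A trial tibble with responses.
#' @param response_range Admissible interval in degrees.
#' @return A list with `trials` (the filtered tibble) and `n_discarded`.
#' @export
#' @examples
#' tab <- tibble::tibble(participant = 1, task = "UV", s_v = 0, s_a = NA,
#'   reliability = "high", response_loc = c(3, 46), response_cat = NA_integer_)
#' filter_valid_responses(tab)$n_discarded
filter_valid_responses <- function(trials, response_range = c(-RANGE_HALF, RANGE_HALF)) {
  bad <- trials$task != "BC" & !is.na(trials$response_loc) &
    (trials$response_loc < response_range[1] | trials$response_loc > response_range[2])
  list(trials = trials[!bad, , drop = FALSE], n_discarded = sum(bad))
}
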