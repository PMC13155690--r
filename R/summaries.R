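# Binned response summaries, computed identically for data and model
# predictive samples (source-tagged), mirroring the study's figure statistics.

sem <- function(x) sd(x) / sqrt(length(x))

group_mean_sem <- function(per_participant, value_col, by) {
  per_participant |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      mean = mean(.data[[value_col]]),
      sem = sem(.data[[value_col]]),
      n_participants = dplyr::n(),
      .groups = "drop"
    )
}

# Response histogram bins of width 3 deg with one bin centered at r = 0.
response_bin_edges <- function(width = 3) {
  half <- width / 2
  k <- ceiling((RANGE_HALF + half) / width)
  seq(-half - (k - 1) * width, half + (k - 1) * width, by = width)
}

#' Unisensory response summaries (distribution, bias, SD)
#'
#' Stratifies localization responses into 7 stimulus bins — the 7 speaker
#' locations for UA, or 7 equal partitions of the visual range for UV — and
#' computes, per participant and stimulus bin: the normalized response
#' histogram (3-degree response bins, one centered at 0), the mean bias
#' (per-trial `r - s`, averaged), and the response SD. Group curves are the
#' mean with SEM across participants.
#'
#' @param trials Responded trial tibble.
#' @param task `"UV"` or `"UA"`.
#' @param reliability For UV, the visual reliability level to summarize.
#' @param source Tag carried in the output (`"data"` or `"model"`).
#' @param visual_range Stimulus range partitioned into the UV bins.
#' @return A `unisensory_summary` object: list of tibbles `distribution`,
#'   `bias`, `sd`, each with group `mean` and `sem` per bin.
#' @export
unisensory_summary <- function(trials, task = c("UV", "UA"), reliability = NULL,
                               source = "data", visual_range = c(-20, 20)) {
  task <- match.arg(task)
  dat <- trials[trials$task == task & !is.na(trials$response_loc), , drop = FALSE]
  if (task == "UV") {
    if (is.null(reliability)) abort("UV summaries need a reliability level.")
    dat <- dat[dat$reliability == reliability, , drop = FALSE]
    edges <- seq(visual_range[1], visual_range[2], length.out = 8)
    dat$stim_bin <- cut(dat$s_v, edges, include.lowest = TRUE, labels = FALSE)
    centers <- (edges[-1] + edges[-8]) / 2
    dat$s <- dat$s_v
  } else {
    locs <- sort(unique(dat$s_a))
    dat$stim_bin <- match(dat$s_a, locs)
    centers <- locs
    dat$s <- dat$s_a
  }
  if (nrow(dat) == 0) abort("No trials to summarize.")
  dat$bin_center <- centers[dat$stim_bin]

  redges <- response_bin_edges()
  rcenters <- (redges[-1] + redges[-length(redges)]) / 2
  per_hist <- dat |>
    dplyr::mutate(response_bin = cut(.data$response_loc, redges, labels = FALSE)) |>
    dplyr::count(.data$participant, .data$bin_center, .data$response_bin) |>
    dplyr::group_by(.data$participant, .data$bin_center) |>
    tidyr::complete(response_bin = seq_along(rcenters), fill = list(n = 0)) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(response_bin_center = rcenters[.data$response_bin])

  per_stats <- dat |>
    dplyr::group_by(.data$participant, .data$bin_center) |>
    dplyr::summarise(
      bias = mean(.data$response_loc - .data$s),
      sd_resp = sd(.data$response_loc),
      .groups = "drop"
    )

  out <- list(
    distribution = group_mean_sem(per_hist, "prop",
      c("bin_center", "response_bin_center")),
    bias = group_mean_sem(per_stats, "bias", "bin_center"),
    sd = group_mean_sem(per_stats[!is.na(per_stats$sd_resp), ], "sd_resp",
      "bin_center")
  )
  out <- lapply(out, function(tb) dplyr::mutate(tb, task = task,
    reliability = reliability %||% NA_character_, source = source))
  structure(out, class = "unisensory_summary")
}

#' Causal-judgment ("same" rate) summary for the BC task
#'
#' Stratifies BC trials by visual reliability and by center/periphery (median
#' split of `|s_A + s_V|` over all BC trials of all participants), assigns
#' trials to 9 disparity (`s_A - s_V`) bins with percentile edges computed
#' within each stratum, and reports the per-bin fraction of "same" responses,
#' mean with SEM across participants.
#'
#' @param trials Responded trial tibble.
#' @param source Tag carried in the output.
#' @return A tibble with the group "same"-rate per
#'   reliability x eccentricity x disparity bin.
#' @export
bc_summary <- function(trials, source = "data") {
  dat <- trials[trials$task == "BC" & !is.na(trials$response_cat), , drop = FALSE]
  if (nrow(dat) == 0) abort("No BC trials to summarize.")
  med <- median(abs(dat$s_a + dat$s_v))
  dat$eccentricity <- ifelse(abs(dat$s_a + dat$s_v) <= med, "center", "periphery")
  dat$disparity <- dat$s_a - dat$s_v
  per <- dat |>
    dplyr::group_by(.data$reliability, .data$eccentricity) |>
    dplyr::group_modify(function(d, key) {
      edges <- unique(quantile(d$disparity, probs = seq(0, 1, length.out = 10)))
      d$disp_bin <- if (length(edges) < 2) 1L else
        cut(d$disparity, edges, include.lowest = TRUE, labels = FALSE)
      d |>
        dplyr::group_by(.data$participant, .data$disp_bin) |>
        dplyr::summarise(
          p_same = mean(.data$response_cat == 1L),
          disparity_center = mean(.data$disparity),
          .groups = "drop"
        )
    }) |>
    dplyr::ungroup()
  centers <- per |>
    dplyr::group_by(.data$reliability, .data$eccentricity, .data$disp_bin) |>
    dplyr::summarise(disparity_center = mean(.data$disparity_center), .groups = "drop")
  group_mean_sem(per, "p_same", c("reliability", "eccentricity", "disp_bin")) |>
    dplyr::left_join(centers, by = c("reliability", "eccentricity", "disp_bin")) |>
    dplyr::mutate(source = source)
}

#' Bias-versus-disparity summary for bisensory localization
#'
#' Stratifies BV or BA trials by visual reliability and by left/center/right
#' (25th/75th percentiles of `s_A + s_V` over all trials of the task), assigns
#' trials to 7 disparity (`s_A - s_V`) bins with percentile edges computed
#' over all trials regardless of stratum, and reports the per-bin mean
#' estimation bias (`r - s_target`), mean with SEM across participants.
#'
#' @param trials Responded trial tibble.
#' @param target `"V"` (BV trials) or `"A"` (BA trials).
#' @param source Tag carried in the output.
#' @return A tibble with the group bias per reliability x side x disparity bin.
#' @export
bisensory_localization_summary <- function(trials, target = c("V", "A"),
                                           source = "data") {
  target <- match.arg(target)
  task <- if (target == "V") "BV" else "BA"
  dat <- trials[trials$task == task & !is.na(trials$response_loc), , drop = FALSE]
  if (nrow(dat) == 0) abort(sprintf("No %s trials to summarize.", task))
  qs <- quantile(dat$s_a + dat$s_v, probs = c(0.25, 0.75))
  dat$side <- cut(dat$s_a + dat$s_v, c(-Inf, qs[1], qs[2], Inf),
    labels = c("left", "center", "right"))
  dat$disparity <- dat$s_a - dat$s_v
  edges <- unique(quantile(dat$disparity, probs = seq(0, 1, length.out = 8)))
  dat$disp_bin <- if (length(edges) < 2) 1L else
    cut(dat$disparity, edges, include.lowest = TRUE, labels = FALSE)
  dat$bias <- dat$response_loc - (if (target == "V") dat$s_v else dat$s_a)
  per <- dat |>
    dplyr::group_by(.data$participant, .data$reliability, .data$side,
      .data$disp_bin) |>
    dplyr::summarise(bias = mean(.data$bias),
      disparity_center = mean(.data$disparity), .groups = "drop")
  centers <- per |>
    dplyr::group_by(.data$reliability, .data$side, .data$disp_bin) |>
    dplyr::summarise(disparity_center = mean(.data$disparity_center), .groups = "drop")
  group_mean_sem(per, "bias", c("reliability", "side", "disp_bin")) |>
    dplyr::left_join(centers, by = c("reliability", "side", "disp_bin")) |>
    dplyr::mutate(target = target, source = source)
}

#' Model predictive samples for ribbon summaries
#'
#' Simulates `n_reps` synthetic repetitions of each trial at the given observer
#' (typically at fitted parameters) and stacks them, so that the same summary
#' code path produces model "ribbons" comparable to data error bars.
#'
#' @param trials Trial tibble (stimuli are reused; responses regenerated).
#' @param observer An [observer_model()].
#' @param n_reps Number of synthetic repetitions.
#' @param seed Integer seed.
#' @return A trial tibble with `n_reps` simulated responses per input trial.
#' @export
simulate_predictive <- function(trials, observer, n_reps = 10, seed = 1) {
  purrr::map_dfr(seq_len(n_reps), function(k) {
    simulate_responses(trials, observer, seed = derive_seed(seed, "rep", k))
  })
}

#' One-sample t-test of a fitted parameter across participants
#'
#' Convenience helper for group-level tests such as whether the bisensory
#' noise multipliers exceed 1 or the recalibration gain differs from 4/3.
#'
#' @param values Per-participant fitted values.
#' @param mu Null value.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return A tibble with `estimate`, `sem`, `statistic`, `df`, `p_value`.
#' @export
t_test_participants <- function(values, mu = 1, alternative = "two.sided") {
  tt <- t.test(values, mu = mu, alternative = alternative)
  tibble::tibble(
    estimate = unname(tt$estimate), sem = sem(values),
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value
  )
}
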