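## Accept either a vns_trial / trial record (tibble with time_s + hr_norm) or
## a plain data frame; returns time and normalized-HR vectors.
trace_xy <- function(record) {
  stopifnot(all(c("time_s", "hr_norm") %in% names(record)))
  list(t = record$time_s, y = record$hr_norm)
}

#' Time to reach the target band
#'
#' Time from controller start until normalized heart rate first falls under
#' the upper band edge. Trials start near 100%, so this is the time to drop
#' under 60% at the default band; `Inf` if the band is never reached.
#'
#' @param record A trial record (e.g. a [run_trial()] result): a data frame
#'   with `time_s` and `hr_norm` columns.
#' @param band Length-2 numeric, the target band in percent (default 40-60).
#' @return Time in seconds (or `Inf`).
#' @export
time_to_band <- function(record, band = c(40, 60)) {
  xy <- trace_xy(record)
  hit <- which(xy$y < band[2])
  if (!length(hit)) Inf else xy$t[hit[1]] - xy$t[1]
}

#' Total time inside the target band
#'
#' Sums the duration spent with normalized heart rate inside
#' `[band[1], band[2]]` over the controller-on window. Each inter-sample
#' interval is attributed to the sample at its right edge.
#'
#' @inheritParams time_to_band
#' @return Time in seconds.
#' @export
time_in_band <- function(record, band = c(40, 60)) {
  xy <- trace_xy(record)
  if (length(xy$t) < 2) return(0)
  dt <- diff(xy$t)
  inside <- xy$y >= band[1] & xy$y <= band[2]
  sum(dt[inside[-1]])
}

#' Count above-and-below band excursions
#'
#' An excursion event is a maximal run of samples strictly above the upper
#' band edge or strictly below the lower one. The count is the number of
#' alternations between above-events and below-events in order of occurrence:
#' repeated exits on the same side do not count, so two above-only exits give
#' zero, while a trace that goes above, below, above, ... k+1 times gives k.
#'
#' @inheritParams time_to_band
#' @return Non-negative integer alternation count.
#' @export
count_excursions <- function(record, band = c(40, 60)) {
  xy <- trace_xy(record)
  state <- ifelse(xy$y > band[2], 1L, ifelse(xy$y < band[1], -1L, 0L))
  r <- rle(state)
  types <- r$values[r$values != 0L]
  if (length(types) < 2L) 0L else sum(diff(types) != 0L)
}

#' Categorize a trial as Slow, Oscillations or Stable
#'
#' The trial categorization rule: a trial is `Oscillations` if the heart rate
#' went above and below the 40-60% band at least `oscillation_threshold` (5)
#' times; otherwise `Slow` if it spent more than half the controller-on window
#' outside the band; otherwise `Stable`. Oscillations takes precedence.
#'
#' @inheritParams time_to_band
#' @param oscillation_threshold Minimum alternation count for `Oscillations`.
#' @param duration Controller-on duration (s); defaults to the record's time
#'   span.
#' @return One of `"Slow"`, `"Oscillations"`, `"Stable"`.
#' @examples
#' rec <- tibble::tibble(time_s = seq(0, 840, 0.5), hr_norm = 50)
#' categorize_trial(rec)
#' @export
categorize_trial <- function(record, band = c(40, 60),
                             oscillation_threshold = 5, duration = NULL) {
  xy <- trace_xy(record)
  duration <- duration %||% (max(xy$t) - min(xy$t))
  if (count_excursions(record, band) >= oscillation_threshold) {
    "Oscillations"
  } else if (duration - time_in_band(record, band) > duration / 2) {
    "Slow"
  } else {
    "Stable"
  }
}

#' Per-trial performance metrics
#'
#' @inheritParams categorize_trial
#' @return One-row tibble: `time_to_band`, `time_in_band`, `excursions`,
#'   `fraction_outside`, `category`.
#' @export
trial_metrics <- function(record, band = c(40, 60),
                          oscillation_threshold = 5, duration = NULL) {
  xy <- trace_xy(record)
  duration <- duration %||% (max(xy$t) - min(xy$t))
  tib <- time_in_band(record, band)
  tibble::tibble(
    time_to_band = time_to_band(record, band),
    time_in_band = tib,
    excursions = count_excursions(record, band),
    fraction_outside = (duration - tib) / duration,
    category = categorize_trial(record, band,
                                oscillation_threshold = oscillation_threshold,
                                duration = duration)
  )
}

#' Pairwise Wilcoxon rank-sum comparisons across gains
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) tests on each pair of gain
#' groups for a chosen per-trial metric, with the exact distribution for group
#' sizes up to 12 without ties and the normal approximation (continuity and
#' tie corrected) otherwise. Identical groups (same multiset of values) give
#' p = 1 with a ties warning.
#'
#' @param data A data frame with a grouping column and a metric column (e.g. a
#'   [sweep_gains()] result).
#' @param metric Name of the metric column. Default `"time_in_band"`.
#' @param group Name of the grouping column. Default `"gain"`.
#' @param alpha Significance level for the decision column. Default 0.005 as
#'   used in the gain study.
#' @return A tibble with one row per group pair: `group1`, `group2`, `n1`,
#'   `n2`, `statistic` (Mann-Whitney U of group1), `p_value`, `significant`.
#' @examples
#' d <- tibble::tibble(gain = rep(c(2, 5), each = 3),
#'                     time_in_band = c(1, 2, 3, 10, 11, 12))
#' compare_gains(d)
#' @export
compare_gains <- function(data, metric = "time_in_band", group = "gain",
                          alpha = 0.005) {
  stopifnot(all(c(metric, group) %in% names(data)))
  g <- data[[group]]
  v <- data[[metric]]
  levels <- sort(unique(g))
  if (length(levels) < 2L) abort("need >= 2 groups.", class = "vagusloop_input_error")
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  purrr::map(pairs, function(p) {
    x <- v[g == p[1]]; y <- v[g == p[2]]
    if (length(x) < 3L || length(y) < 3L) {
      abort("need >= 3 values per group.", class = "vagusloop_input_error")
    }
    if (identical(sort(x), sort(y))) {
      warn("identical groups (all ties): p = 1.", class = "vagusloop_ties_warning")
      u <- length(x) * length(y) / 2
      pv <- 1
    } else {
      ties <- any(duplicated(c(x, y)))
      exact <- !ties && max(length(x), length(y)) <= 12L
      wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
      u <- unname(wt$statistic)
      pv <- wt$p.value
    }
    tibble::tibble(group1 = p[1], group2 = p[2],
                   n1 = length(x), n2 = length(y),
                   statistic = u, p_value = pv, significant = pv < alpha)
  }) |> dplyr::bind_rows()
}

#' Summaries of a gain sweep
#'
#' Category counts and metric summaries per gain, the tabular analogue of the
#' category / time-to-setpoint / time-at-setpoint figures.
#'
#' @param sweep A [sweep_gains()] result (or any data frame with `gain`,
#'   `category`, `time_to_band`, `time_in_band` columns).
#' @return A tibble with one row per gain.
#' @export
summarize_gains <- function(sweep) {
  dplyr::group_by(tibble::as_tibble(sweep), .data$gain) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_slow = sum(.data$category == "Slow"),
      n_stable = sum(.data$category == "Stable"),
      n_oscillations = sum(.data$category == "Oscillations"),
      median_time_to_band = stats::median(.data$time_to_band),
      mean_time_to_band = mean(.data$time_to_band[is.finite(.data$time_to_band)]),
      median_time_in_band = stats::median(.data$time_in_band),
      mean_time_in_band = mean(.data$time_in_band),
      .groups = "drop")
}

#' @rdname summarize_gains
#' @param x A `vns_gain_sweep`.
#' @param ... Unused.
#' @export
glance.vns_gain_sweep <- function(x, ...) summarize_gains(x)
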