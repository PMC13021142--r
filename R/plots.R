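#' Plot a trial record
#'
#' Normalized heart rate over the trial with the 40-60% target band, the
#' setpoint line and the perturbation ramp, plus the controller output
#' coefficient in a lower panel.
#'
#' @param object A [run_trial()] result.
#' @param band Target band in percent.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vns_trial <- function(object, band = c(40, 60), ...) {
  rec <- tidy(object)
  long <- dplyr::bind_rows(
    tibble::tibble(time_s = rec$time_s, value = rec$hr_norm,
                   panel = "normalized HR (%)"),
    tibble::tibble(time_s = rec$time_s, value = rec$cout,
                   panel = "cout"),
    tibble::tibble(time_s = rec$time_s, value = rec$perturb_hz,
                   panel = "perturbation (Hz)")
  )
  band_df <- tibble::tibble(panel = "normalized HR (%)",
                            ymin = band[1], ymax = band[2])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_rect(data = band_df,
                       ggplot2::aes(ymin = .data$ymin, ymax = .data$ymax),
                       xmin = -Inf, xmax = Inf, inherit.aes = FALSE,
                       fill = "grey85") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "time since controller start (s)", y = NULL,
                  title = sprintf("closed-loop trial, gain %s bpm/s",
                                  attr(object, "gain"))) +
    ggplot2::theme_minimal()
}

#' Plot a calibration result
#'
#' The two calibration sweeps: heart rate against stimulation frequency and
#' against block amplitude, with the fitted lines.
#'
#' @param object A [calibrate_plant()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vns_calibration <- function(object, ...) {
  stim <- dplyr::mutate(object$sweeps$stim, panel = "stimulation (Hz)",
                        x = .data$freq_hz)
  blk <- dplyr::mutate(object$sweeps$block, panel = "block (mA p-p)",
                       x = .data$amp_ma)
  ggplot2::ggplot(dplyr::bind_rows(stim, blk),
                  ggplot2::aes(x = .data$x, y = .data$hr_bpm)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "red") +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "heart rate (bpm)",
                  title = sprintf("calibration: %.1f bpm/Hz, onset %.2f mA, %.1f bpm/mA",
                                  object$stim_sensitivity, object$block_start_amp,
                                  object$block_sensitivity)) +
    ggplot2::theme_minimal()
}

#' Plot a gain sweep
#'
#' Boxplots of a per-trial metric by controller gain, points overlaid and
#' coloured by trial category.
#'
#' @param object A [sweep_gains()] result.
#' @param metric Metric column to plot (default `"time_in_band"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vns_gain_sweep <- function(object, metric = "time_in_band", ...) {
  d <- tibble::as_tibble(object)
  d$gain_f <- factor(d$gain)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gain_f, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$category),
                         width = 0.1, size = 1.6) +
    ggplot2::labs(x = "controller gain (bpm/s)", y = metric,
                  colour = "category") +
    ggplot2::theme_minimal()
}
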