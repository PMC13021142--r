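#' Rolling-window heart-rate estimate from R-event times
#'
#' The controller's measured heart rate: the mean R-R interval over a rolling
#' window (2 s nominal), converted to bpm. An interval belongs to the window if
#' its later R event falls in the half-open window `(t - window, t]`; the mean
#' of those intervals telescopes to
#' `(last beat - first preceding beat) / n_intervals`, and the estimate is
#' `60 / mean_RR`.
#'
#' If a time point has no complete interval in its window, the last valid
#' estimate is held (carried forward) and a data-gap warning is raised; leading
#' gaps give `NA`.
#'
#' @param r_times Strictly increasing R-event times (s).
#' @param t Time(s) at which to evaluate the estimate (s); vectorised.
#' @param window Window length (s), default 2.
#' @return Heart-rate estimates in bpm, one per element of `t`.
#' @examples
#' beats <- seq(0, 10, by = 0.15)  # 400 bpm
#' rolling_hr(beats, c(2, 5, 10))
#' @export
rolling_hr <- function(r_times, t, window = 2) {
  check_finite(r_times, "r_times"); check_finite(t, "t")
  if (length(r_times) && any(diff(r_times) <= 0)) {
    abort("`r_times` must be strictly increasing.", class = "vagusloop_input_error")
  }
  if (window <= 0) abort("`window` must be > 0.", class = "vagusloop_input_error")
  i1 <- findInterval(t, r_times)                 # last beat at or before t
  i0 <- findInterval(t - window, r_times)        # beats at or before t - window
  lo <- pmax(i0 + 1L, 2L)                        # first in-window beat with a predecessor
  n_iv <- i1 - lo + 1L
  hr <- rep(NA_real_, length(t))
  ok <- n_iv >= 1L
  if (any(ok)) {
    span <- r_times[i1[ok]] - r_times[lo[ok] - 1L]
    hr[ok] <- 60 * n_iv[ok] / span
  }
  if (any(!ok)) {
    warn("data gap: fewer than 2 beats in window; holding last valid estimate.",
         class = "vagusloop_data_gap_warning")
    hr <- locf(hr)
  }
  hr
}

## last-observation-carried-forward (leading NAs stay NA)
locf <- function(x) {
  idx <- cumsum(!is.na(x))
  filled <- x[!is.na(x)][pmax(idx, 1L)]
  filled[idx == 0L] <- NA_real_
  filled
}
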