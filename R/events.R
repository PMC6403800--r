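#' Estimate the open-pore current and baseline noise of a trace
#'
#' The open-pore level is taken as the mode of the sample amplitude
#' distribution (the highest peak of a kernel-smoothed histogram), which is
#' robust to substantial blocked-state occupancy because blockades here are
#' deep. The noise is the scaled median absolute deviation (1.4826 * MAD) of
#' the samples within 3 initial MADs of that level.
#'
#' @param trace An `np_trace` tibble, or any data frame with a `current_pA`
#'   column.
#' @return A named numeric vector `c(i_open, noise_sd)` in pA.
#' @examples
#' cfg <- acquisition_config(duration = 0.2, seed = 3)
#' estimate_baseline(simulate_trace(gating_model(), cfg))
#' @export
estimate_baseline <- function(trace) {
  x <- trace$current_pA
  if (length(x) == 0) abort("Empty trace: cannot estimate a baseline.")
  if (length(x) < 1000) {
    warn("Fewer than 1000 samples; baseline estimate may be unstable.")
  }
  if (sd(x) == 0) {
    return(c(i_open = x[1], noise_sd = 0))
  }
  d <- density(x, n = 2048)
  i_open <- d$x[which.max(d$y)]
  mad0 <- mad(x)
  sel <- abs(x - i_open) <= 3 * mad0
  noise_sd <- if (any(sel)) mad(x[sel]) else 0
  c(i_open = i_open, noise_sd = noise_sd)
}

#' Detect blockade events in a current trace by hysteresis thresholding
#'
#' An event opens when the current drops below `enter_frac * i_open` and
#' closes when it rises back above `exit_frac * i_open`; the gap between the
#' two thresholds prevents noise-driven chatter around a single threshold.
#' Both thresholds are fractions of the estimated baseline, so detection is
#' invariant to rescaling the whole trace. Events shorter than
#' `min_duration` are discarded (the default, 100 us, is five samples at
#' 50 kHz, respecting the rise time of a 10 kHz filter); events touching
#' either end of the trace are flagged `censored`.
#'
#' Event boundaries are reported on the sample grid: `start_s` is the time
#' of the first in-event sample and `end_s` is one sample period after the
#' last, so `duration_s` is an exact multiple of the sample period. Mean
#' amplitudes exclude the two samples nearest each boundary, where the
#' low-pass filter smears the transition.
#'
#' @param trace An `np_trace` tibble (or data frame with `time_s`,
#'   `current_pA`).
#' @param enter_frac,exit_frac Hysteresis thresholds as fractions of the
#'   open-pore current; require `0 < enter_frac < exit_frac <= 1`.
#' @param min_duration Shortest retained event, s.
#' @param baseline Optional `c(i_open, noise_sd)` override (pA); estimated
#'   with [estimate_baseline()] when `NULL`.
#'
#' @return A tibble of class `np_events`: `event`, `start_s`, `end_s`,
#'   `duration_s`, `wait_s` (time since the previous event's end; `NA` for
#'   the first event, whose waiting time is left-censored), `mean_amplitude_pA`,
#'   `n_samples`, `censored`. Attributes: `i_open`, `noise_sd`, `config`.
#' @export
detect_events <- function(trace, enter_frac = 0.7, exit_frac = 0.9,
                          min_duration = 1e-4, baseline = NULL) {
  if (!(enter_frac > 0 && enter_frac < exit_frac && exit_frac <= 1)) {
    abort("Require 0 < enter_frac < exit_frac <= 1.")
  }
  x <- trace$current_pA
  n <- length(x)
  if (n == 0) abort("Empty trace.")
  fs <- .trace_fs(trace)
  if (is.null(baseline)) baseline <- estimate_baseline(trace)
  i_open <- baseline[[1]]
  noise_sd <- baseline[[2]]

  # Hysteresis as last-observation-carried-forward over the forced states:
  # below the enter threshold forces "in event", above the exit threshold
  # forces "out"; samples between the thresholds keep the previous state.
  s <- rep(NA_real_, n)
  s[x < enter_frac * i_open] <- 1
  s[x > exit_frac * i_open] <- 0
  known <- which(!is.na(s))
  if (length(known) == 0) {
    filled <- rep(0, n)
  } else {
    filled <- c(0, s[known])[findInterval(seq_len(n), known) + 1L]
  }

  r <- rle(filled)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- r$values == 1
  starts <- run_start[keep]
  ends <- run_end[keep]
  if (length(starts) > 0) {
    censored <- (starts == 1L) | (ends == n)
    dur <- (ends - starts + 1L) / fs
    ok <- dur >= min_duration
    starts <- starts[ok]; ends <- ends[ok]; censored <- censored[ok]
  } else {
    censored <- logical(0)
  }

  mean_amp <- purrr::map2_dbl(starts, ends, function(i0, i1) {
    j0 <- i0 + 2L; j1 <- i1 - 2L
    if (j1 < j0) { j0 <- i0; j1 <- i1 }
    mean(x[j0:j1])
  })

  t0 <- if (!is.null(trace$time_s)) trace$time_s[1] else 0
  out <- tibble(
    event = seq_along(starts),
    start_s = t0 + (starts - 1L) / fs,
    end_s = t0 + ends / fs,
    duration_s = (ends - starts + 1L) / fs,
    mean_amplitude_pA = mean_amp,
    n_samples = ends - starts + 1L,
    censored = censored
  )
  out$wait_s <- out$start_s - dplyr::lag(out$end_s)
  out <- out[, c("event", "start_s", "end_s", "duration_s", "wait_s",
                 "mean_amplitude_pA", "n_samples", "censored")]
  class(out) <- c("np_events", class(out))
  attr(out, "i_open") <- unname(i_open)
  attr(out, "noise_sd") <- unname(noise_sd)
  attr(out, "config") <- trace_config(trace)
  out
}

# Sampling rate from metadata, falling back to the time column.
.trace_fs <- function(trace) {
  cfg <- trace_config(trace)
  if (!is.null(cfg)) return(cfg$sampling_rate)
  if (!is.null(trace$time_s) && length(trace$time_s) > 1) {
    return(1 / median(diff(trace$time_s)))
  }
  abort("Cannot determine the sampling rate of the trace.")
}

#' Inter-event intervals (tau_on samples) of an event table
#'
#' The waiting time preceding the first event is left-censored by the start
#' of the recording and is discarded.
#'
#' @param events An `np_events` tibble.
#' @return Numeric vector of waiting times, s.
#' @export
event_intervals <- function(events) {
  as.numeric(stats::na.omit(events$wait_s))
}

#' Event durations (tau_off samples) of an event table
#'
#' @param events An `np_events` tibble.
#' @param include_censored Keep events truncated by the trace boundaries
#'   (default `FALSE`; censored durations bias the exponential MLE downward).
#' @return Numeric vector of durations, s.
#' @export
event_durations <- function(events, include_censored = FALSE) {
  if (include_censored) events$duration_s else events$duration_s[!events$censored]
}

#' Segment each event into deep/shallow substates
#'
#' Assigns every in-event sample to the nearer of the two guess levels
#' (deep `i1_guess` < shallow `i2_guess`), merges runs shorter than
#' `min_duration` into their longer neighbour, and recomputes per-segment
#' mean amplitudes from the data. Events with fewer than 3 samples get a
#' single substate.
#'
#' @param events An `np_events` tibble.
#' @param trace The trace the events were detected in.
#' @param i1_guess,i2_guess Initial deep and shallow current levels, pA
#'   (`i1_guess < i2_guess`).
#' @param min_duration Shortest retained substate run, s.
#' @return `events` with list-column `substates` (tibbles of `level`,
#'   `start_s`, `end_s`, `mean_amplitude_pA` tiling each event exactly) and
#'   column `n_substates`.
#' @export
segment_substates <- function(events, trace, i1_guess, i2_guess,
                              min_duration = 1e-4) {
  if (!(i1_guess < i2_guess)) {
    abort("`i1_guess` must be below `i2_guess` (the deep substate carries less current).")
  }
  x <- trace$current_pA
  fs <- .trace_fs(trace)
  t0 <- if (!is.null(trace$time_s)) trace$time_s[1] else 0
  min_len <- max(1L, round(min_duration * fs))

  events$substates <- purrr::map2(events$start_s, events$end_s, function(a, b) {
    i0 <- round((a - t0) * fs) + 1L
    i1 <- round((b - t0) * fs)
    xs <- x[i0:i1]
    m <- length(xs)
    if (m < 3L) {
      lev <- if (abs(mean(xs) - i1_guess) <= abs(mean(xs) - i2_guess)) 1L else 2L
      return(tibble(level = lev, start_s = a, end_s = b,
                    mean_amplitude_pA = mean(xs)))
    }
    assign <- ifelse(abs(xs - i1_guess) <= abs(xs - i2_guess), 1L, 2L)
    r <- rle(assign)
    while (length(r$lengths) > 1L && any(r$lengths < min_len)) {
      j <- which.min(r$lengths)
      nb <- if (j == 1L) 2L
            else if (j == length(r$lengths)) j - 1L
            else if (r$lengths[j - 1L] >= r$lengths[j + 1L]) j - 1L else j + 1L
      r$values[j] <- r$values[nb]
      r <- rle(inverse.rle(r))
    }
    seg_end <- cumsum(r$lengths)
    seg_start <- seg_end - r$lengths + 1L
    tibble(
      level = r$values,
      start_s = a + (seg_start - 1L) / fs,
      end_s = a + seg_end / fs,
      mean_amplitude_pA = purrr::map2_dbl(seg_start, seg_end,
                                          ~ mean(xs[.x:.y]))
    )
  })
  events$n_substates <- purrr::map_int(events$substates, nrow)
  events
}

#' Fractional current blockade of an event or substate
#'
#' The magnitude of the current drop relative to the open-pore current,
#' `|i_blocked - i_open| / i_open`. Reported as a positive number in `[0, 1]`
#' regardless of the voltage sign convention.
#'
#' @param i_blocked Blocked-state current, pA (in `[0, i_open]`).
#' @param i_open Open-pore current, pA (positive).
#' @return Dimensionless fractional blockade(s).
#' @examples
#' fractional_blockade(9, 100)  # 0.91
#' @export
fractional_blockade <- function(i_blocked, i_open) {
  if (any(i_open <= 0)) abort("`i_open` must be positive.")
  if (any(i_blocked < 0) || any(i_blocked > i_open)) {
    abort("`i_blocked` must lie in [0, i_open].")
  }
  abs(i_blocked - i_open) / i_open
}
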