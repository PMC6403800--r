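#' Simulate peptide capture events for a nanopore recording
#'
#' Draws a sequence of blockade events from the gating model: waiting times
#' between an event's end and the next capture are exponential with rate
#' `k_on(dV) * C`, residence times are exponential with rate `k_off(dV)`,
#' and within each event the current level follows a two-state
#' continuous-time Markov chain over the deep (1) and shallow (2) substates.
#'
#' Events are generated sequentially, so they never overlap (the pore holds
#' one peptide at a time). An event still in progress when the recording
#' ends is truncated at `config$duration` and flagged `censored`; censored
#' durations should be excluded from dwell-time fits, which keeps the
#' exponential maximum-likelihood estimate unbiased.
#'
#' @param model A [gating_model()].
#' @param config An [acquisition_config()]; its `voltage` scales the rates
#'   and its `seed` makes the draw reproducible.
#' @param n_events If given, exactly this many events are generated and the
#'   recording duration is ignored (event-level simulation; nothing is
#'   censored). Useful for kinetics studies at low capture rates.
#'
#' @return A tibble of class `np_event_sim` with one row per event:
#'   `event`, `wait_s` (waiting time preceding the capture), `start_s`,
#'   `duration_s`, `censored`, and a `substates` list-column of tibbles
#'   (`level`, `start_s`, `end_s`) tiling the event.
#' @examples
#' cfg <- acquisition_config(duration = 2, seed = 42)
#' ev <- simulate_events(gating_model(k_on_0 = 1e4, concentration = 1e-3), cfg)
#' @export
simulate_events <- function(model, config, n_events = NULL) {
  stopifnot(inherits(model, "gating_model"), inherits(config, "acquisition_config"))
  rates <- gating_rates(model, config$voltage)
  if (any(!is.finite(rates[c("capture_rate")])) || rates[["capture_rate"]] < 0) {
    abort("Capture rate must be finite and non-negative.")
  }
  if (!is.finite(rates[["k_off"]]) || rates[["k_off"]] < 0) {
    abort("Dissociation rate must be finite and non-negative.")
  }
  withr::with_seed(config$seed, {
    events <- .draw_events(
      capture_rate = rates[["capture_rate"]],
      k_off        = rates[["k_off"]],
      duration     = config$duration,
      n_events     = n_events
    )
    events$substates <- purrr::pmap(
      list(events$start_s, events$duration_s),
      function(start, dur) .draw_substate_path(model, start, dur)
    )
  })
  events <- as_tibble(events)
  class(events) <- c("np_event_sim", class(events))
  attr(events, "config") <- config
  attr(events, "gating_truth") <- model
  events
}

# Sequential gap/duration draws; either fixed count or fill a duration.
.draw_events <- function(capture_rate, k_off, duration, n_events = NULL) {
  if (!is.null(n_events)) {
    waits <- rexp(n_events, rate = capture_rate)
    durs <- if (k_off > 0) rexp(n_events, rate = k_off) else rep(Inf, n_events)
    starts <- cumsum(waits + dplyr::lag(durs, default = 0))
    return(tibble(
      event = seq_len(n_events), wait_s = waits, start_s = starts,
      duration_s = durs, censored = FALSE
    ))
  }
  waits <- numeric(0); starts <- numeric(0); durs <- numeric(0); cens <- logical(0)
  t <- 0
  repeat {
    w <- rexp(1, rate = capture_rate)
    start <- t + w
    if (start >= duration) break
    d <- if (k_off > 0) rexp(1, rate = k_off) else Inf
    censored <- (start + d) > duration
    d_obs <- min(d, duration - start)
    waits <- c(waits, w); starts <- c(starts, start)
    durs <- c(durs, d_obs); cens <- c(cens, censored)
    if (censored) break
    t <- start + d_obs
  }
  tibble(event = seq_along(starts), wait_s = waits, start_s = starts,
         duration_s = durs, censored = cens)
}

# Two-state CTMC path over [start, start + dur]; level 1 = deep substate.
.draw_substate_path <- function(model, start, dur) {
  r <- model$substate_switch_rates  # (1 -> 2, 2 -> 1)
  level <- sample.int(2L, 1L, prob = model$substate_init)
  lv <- integer(0); t0 <- numeric(0); t1 <- numeric(0)
  t <- 0
  while (t < dur) {
    exit_rate <- if (level == 1L) r[[1]] else r[[2]]
    dwell <- if (exit_rate > 0) rexp(1, rate = exit_rate) else Inf
    end <- min(t + dwell, dur)
    lv <- c(lv, level); t0 <- c(t0, t); t1 <- c(t1, end)
    t <- end
    level <- 3L - level
  }
  if (length(lv) == 0L) {  # zero-duration event (censored at trace end)
    lv <- 1L; t0 <- 0; t1 <- dur
  }
  tibble(level = lv, start_s = start + t0, end_s = start + t1)
}

#' Render a simulated event sequence as a sampled current trace
#'
#' Builds the noiseless piecewise-constant current signal (open-pore level
#' `i_open`, substate levels `i_open * (1 - frac_block_k)`), emulates the
#' acquisition low-pass filter by Gaussian smoothing, then adds i.i.d.
#' Gaussian noise. Filtering the noiseless square signal and adding broadband
#' noise afterwards keeps `noise_sd` directly interpretable as the sample
#' standard deviation of the baseline; set `filter_noise = TRUE` to pass the
#' noise through the same kernel instead (its sd then shrinks accordingly).
#'
#' The Gaussian kernel sd is `0.1325 * sampling_rate / filter_cutoff`
#' samples, matching the -3 dB point of the nominal filter. Currents are
#' stored as positive magnitudes in pA; the voltage sign lives in the
#' configuration metadata.
#'
#' @param events Event table from [simulate_events()], or any tibble with
#'   `start_s`, `duration_s` and a `substates` list-column.
#' @param model A [gating_model()].
#' @param config An [acquisition_config()].
#' @param seed Seed for the noise draw; defaults to `config$seed + 1` so a
#'   trace built from `simulate_events(model, config)` is reproducible from
#'   the single configuration seed.
#' @param filter_noise Also low-pass the noise (default `FALSE`).
#'
#' @return A tibble of class `np_trace` with columns `time_s`, `current_pA`
#'   and attributes `config`, `gating_truth` and `true_events`.
#' @examples
#' cfg <- acquisition_config(duration = 0.5, seed = 7)
#' mod <- gating_model(k_on_0 = 2e5, concentration = 1e-3)
#' tr <- render_trace(simulate_events(mod, cfg), mod, cfg)
#' @export
render_trace <- function(events, model, config, seed = config$seed + 1L,
                         filter_noise = FALSE) {
  stopifnot(inherits(model, "gating_model"), inherits(config, "acquisition_config"))
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  tol <- 0.5 / fs
  if (nrow(events) > 0) {
    ends <- events$start_s + events$duration_s
    if (any(events$start_s < -tol) || any(ends > config$duration + tol)) {
      abort("Events extend beyond the trace duration.")
    }
    if (is.unsorted(events$start_s)) {
      events <- dplyr::arrange(events, .data$start_s)
    }
    overlap <- events$start_s[-1] < ends[-length(ends)] - tol
    if (any(overlap)) {
      warn("Overlapping events merged during rendering.")
    }
  }
  signal <- rep(model$i_open, n)
  fracs <- c(model$frac_block_1, model$frac_block_2)
  if (nrow(events) > 0) {
    segs <- dplyr::bind_rows(events$substates)
    for (k in seq_len(nrow(segs))) {
      i0 <- max(1L, floor(segs$start_s[k] * fs) + 1L)
      i1 <- min(n, ceiling(segs$end_s[k] * fs))
      if (i1 >= i0) {
        signal[i0:i1] <- model$i_open * (1 - fracs[segs$level[k]])
      }
    }
  }
  signal <- .gaussian_lowpass(signal, fs, config$filter_cutoff)
  if (model$noise_sd > 0) {
    noise <- withr::with_seed(seed, rnorm(n, sd = model$noise_sd))
    if (filter_noise) noise <- .gaussian_lowpass(noise, fs, config$filter_cutoff)
    signal <- signal + noise
  }
  out <- tibble(time_s = (seq_len(n) - 1) / fs, current_pA = signal)
  class(out) <- c("np_trace", class(out))
  attr(out, "config") <- config
  attr(out, "gating_truth") <- model
  attr(out, "true_events") <- events
  out
}

# Gaussian kernel smoothing with edge replication; sd in samples equals
# 0.1325 * fs / fc (-3 dB equivalent of the nominal low-pass).
.gaussian_lowpass <- function(x, fs, fc) {
  sigma <- 0.1325 * fs / fc
  r <- max(1L, ceiling(4 * sigma))
  kern <- dnorm(seq(-r, r), sd = sigma)
  kern <- kern / sum(kern)
  n <- length(x)
  xp <- c(rep(x[1], r), x, rep(x[n], r))
  y <- stats::filter(xp, kern, sides = 2)
  as.numeric(y[(r + 1):(r + n)])
}

#' Simulate a complete current trace in one call
#'
#' Convenience wrapper: [simulate_events()] followed by [render_trace()],
#' both driven by `config$seed`.
#'
#' @inheritParams render_trace
#' @inheritParams simulate_events
#' @return An `np_trace` tibble (see [render_trace()]).
#' @export
simulate_trace <- function(model, config, filter_noise = FALSE) {
  events <- simulate_events(model, config)
  render_trace(events, model, config, filter_noise = filter_noise)
}

#' Simulate one trace per clamped voltage
#'
#' Replays the same gating model across a ladder of clamped voltages, with
#' the association and dissociation rates scaled by `exp(a * dV)` and
#' `exp(b * dV)`. Voltage `i` uses seed `config$seed + (i - 1)`, so a
#' single-voltage series is identical to calling [simulate_trace()] with the
#' same configuration.
#'
#' @inheritParams simulate_events
#' @param voltages Numeric vector of clamped voltages, mV (non-empty).
#' @param events_only If `TRUE`, skip rendering and return event tables
#'   (event-level simulation; much faster at low capture rates).
#' @param n_events Passed to [simulate_events()] when `events_only = TRUE`.
#' @return Named list (names = voltages, mV) of `np_trace` tibbles, or of
#'   event tables when `events_only = TRUE`.
#' @export
generate_voltage_series <- function(model, voltages, config,
                                    events_only = FALSE, n_events = NULL) {
  if (length(voltages) == 0) abort("`voltages` must be non-empty.")
  out <- purrr::imap(as.list(voltages), function(v, i) {
    cfg <- config
    cfg$voltage <- v
    cfg$seed <- config$seed + (i - 1L)
    if (events_only) {
      simulate_events(model, cfg, n_events = n_events)
    } else {
      simulate_trace(model, cfg)
    }
  })
  names(out) <- as.character(voltages)
  out
}

#' Acquisition metadata attached to a trace or event table
#' @param x An `np_trace` or `np_events` object.
#' @return The [acquisition_config()] stored on `x`, or `NULL`.
#' @export
trace_config <- function(x) attr(x, "config", exact = TRUE)

#' Generating model attached to a synthetic trace
#' @param x An `np_trace` object.
#' @return The [gating_model()] used to generate `x`, or `NULL` for
#'   non-synthetic traces.
#' @export
trace_truth <- function(x) attr(x, "gating_truth", exact = TRUE)
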