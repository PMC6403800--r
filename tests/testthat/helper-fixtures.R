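# Shared fixtures and oracles for the test suite. Everything is generated
# in code; nothing is read from disk except files the tests themselves write.

# Pe6-like study conditions: deep/shallow depths 0.91/0.83, 2 pA noise,
# 100 pA open pore, 50 kHz sampling.
pe6_model <- function(capture_rate = 10, k_off = 50, noise_sd = 2) {
  gating_model(
    k_on_0 = capture_rate / 3e-5, a = 0, concentration = 3e-5,
    k_off_0 = k_off, i_open = 100,
    frac_block_1 = 0.91, frac_block_2 = 0.83, noise_sd = noise_sd
  )
}

pe4_model <- function(capture_rate = 10, k_off = 50, noise_sd = 2) {
  gating_model(
    k_on_0 = capture_rate / 3e-5, a = 0, concentration = 3e-5,
    k_off_0 = k_off, i_open = 100,
    frac_block_1 = 0.93, frac_block_2 = 0.83, noise_sd = noise_sd
  )
}

# Overlap-based matching of detected to true event intervals. Recall is
# restricted to true events longer than min_true (shorter ones are below the
# detector's design resolution); precision counts a detection as correct if
# it overlaps any true event.
match_events <- function(truth, detected, min_true = 0) {
  t_start <- truth$start_s
  t_end <- truth$start_s + truth$duration_s
  long <- truth$duration_s > min_true
  matched_true <- logical(nrow(truth))
  matched_det <- logical(nrow(detected))
  for (i in seq_len(nrow(detected))) {
    ov <- which(detected$start_s[i] < t_end & detected$end_s[i] > t_start)
    if (length(ov) > 0) {
      matched_det[i] <- TRUE
      matched_true[ov] <- TRUE
    }
  }
  c(recall = mean(matched_true[long]), precision = mean(matched_det))
}

# Event-level per-voltage k_on estimates and the voltage fit, the protocol
# used for near-equilibrium constant recovery.
fit_k0_event_level <- function(k0_true, a, volts, seed, n_events = 1000,
                               concentration = 3e-5) {
  mod <- gating_model(
    k_on_0 = k0_true, a = a, concentration = concentration,
    k_off_0 = 100, substate_switch_rates = c(0, 0)
  )
  series <- generate_voltage_series(
    mod, volts, acquisition_config(seed = seed),
    events_only = TRUE, n_events = n_events
  )
  pts <- purrr::imap_dfr(series, function(ev, v) {
    kon <- compute_kon(exp_mle(ev$wait_s), concentration)
    tibble::tibble(voltage_mV = as.numeric(v), k = kon$rate)
  })
  fit_voltage_dependence(pts)
}
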