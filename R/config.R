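#' Acquisition configuration for simulated voltage-clamp recordings
#'
#' Bundles the recording parameters of a patch-clamp acquisition: sampling
#' rate, analogue low-pass filter cutoff, clamped transmembrane voltage and
#' recording duration. Defaults follow a typical single-channel setup for
#' protein nanopores: 50 kHz sampling after a 10 kHz Bessel-type low-pass
#' filter.
#'
#' The voltage is signed (trans minus cis, with cis grounded); current
#' samples are stored as positive magnitudes in pA regardless of the voltage
#' sign, which is kept in the metadata.
#'
#' @param sampling_rate Sampling frequency, Hz.
#' @param filter_cutoff Low-pass filter cutoff, Hz; must be at most the
#'   Nyquist frequency `sampling_rate / 2`.
#' @param voltage Clamped transmembrane voltage, mV (signed).
#' @param duration Recording length, s.
#' @param seed Integer seed driving every stochastic stage that uses this
#'   configuration.
#'
#' @return An object of class `acquisition_config` (a named list).
#' @examples
#' acquisition_config(voltage = 100, duration = 5, seed = 1)
#' @export
acquisition_config <- function(sampling_rate = 5e4,
                               filter_cutoff = 1e4,
                               voltage = 100,
                               duration = 1,
                               seed = 1L) {
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be a positive number (Hz).")
  }
  if (!is.numeric(filter_cutoff) || filter_cutoff <= 0 ||
      filter_cutoff > sampling_rate / 2) {
    abort("`filter_cutoff` must lie in (0, sampling_rate/2] (Hz).")
  }
  if (!is.numeric(duration) || duration <= 0) {
    abort("`duration` must be positive (s).")
  }
  structure(
    list(
      sampling_rate = as.numeric(sampling_rate),
      filter_cutoff = as.numeric(filter_cutoff),
      voltage       = as.numeric(voltage),
      duration      = as.numeric(duration),
      seed          = as.integer(seed)
    ),
    class = "acquisition_config"
  )
}

#' Gating model for peptide capture and blockade of a nanopore
#'
#' Parameterizes the stochastic interaction of a peptide with the pore:
#' capture events arrive as a Poisson process with voltage-dependent rate
#' `k_on(dV) * C` where `k_on(dV) = k_on_0 * exp(a * dV)`, residence times
#' are exponential with rate `k_off(dV) = k_off_0 * exp(b * dV)`, and during
#' an event the current alternates between a deep substate (fractional
#' blockade `frac_block_1`) and a shallow substate (`frac_block_2`) as a
#' two-state continuous-time Markov chain.
#'
#' The substate switching rates are free parameters of the simulator, not
#' experimentally derived quantities; defaults give a 2 ms mean dwell per
#' substate, long enough to resolve both amplitude-histogram peaks at 50 kHz.
#'
#' @param k_on_0 Zero-voltage association rate constant, 1/(M s).
#' @param a Voltage sensitivity of the association rate, 1/mV.
#' @param k_off_0 Zero-voltage dissociation rate constant, 1/s.
#' @param b Voltage sensitivity of the dissociation rate, 1/mV (the package
#'   makes no claim that dissociation follows this law; `b = 0` by default).
#' @param concentration Bulk peptide concentration, M.
#' @param i_open Open-pore current magnitude, pA.
#' @param frac_block_1 Deep-substate fractional blockade, in (0, 1].
#' @param frac_block_2 Shallow-substate fractional blockade, must be smaller
#'   than `frac_block_1`.
#' @param substate_switch_rates Length-2 numeric: switching rates (1/s) for
#'   deep-to-shallow and shallow-to-deep transitions.
#' @param substate_init Length-2 probability vector for the substate the
#'   chain starts in (deep first); default starts deep.
#' @param noise_sd Standard deviation of the additive Gaussian current
#'   noise, pA.
#' @param side Chamber the peptide is added to, `"cis"` or `"trans"`.
#'
#' @return An object of class `gating_model` (a named list).
#' @examples
#' gating_model(k_on_0 = 8.35e4, a = 0.02, concentration = 3e-5)
#' @export
gating_model <- function(k_on_0 = 8.35e4,
                         a = 0.02,
                         k_off_0 = 50,
                         b = 0,
                         concentration = 3e-5,
                         i_open = 100,
                         frac_block_1 = 0.91,
                         frac_block_2 = 0.83,
                         substate_switch_rates = c(500, 500),
                         substate_init = c(1, 0),
                         noise_sd = 2,
                         side = c("trans", "cis")) {
  side <- match.arg(side)
  rates <- c(k_on_0 = k_on_0, k_off_0 = k_off_0,
             switch_12 = substate_switch_rates[[1]],
             switch_21 = substate_switch_rates[[2]])
  if (any(!is.finite(rates)) || any(rates < 0)) {
    abort("All rates must be finite and non-negative.")
  }
  if (!is.finite(a) || !is.finite(b)) {
    abort("Voltage sensitivities `a` and `b` must be finite.")
  }
  if (concentration <= 0) abort("`concentration` must be positive (M).")
  if (i_open <= 0) abort("`i_open` must be positive (pA).")
  if (frac_block_1 <= 0 || frac_block_1 > 1) {
    abort("`frac_block_1` must lie in (0, 1].")
  }
  if (frac_block_2 < 0 || frac_block_2 >= frac_block_1) {
    abort("`frac_block_2` must lie in [0, frac_block_1): level 1 is the deeper substate.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be non-negative (pA).")
  substate_init <- substate_init / sum(substate_init)
  structure(
    list(
      k_on_0 = as.numeric(k_on_0),
      a = as.numeric(a),
      k_off_0 = as.numeric(k_off_0),
      b = as.numeric(b),
      concentration = as.numeric(concentration),
      i_open = as.numeric(i_open),
      frac_block_1 = as.numeric(frac_block_1),
      frac_block_2 = as.numeric(frac_block_2),
      substate_switch_rates = as.numeric(substate_switch_rates),
      substate_init = as.numeric(substate_init),
      noise_sd = as.numeric(noise_sd),
      side = side
    ),
    class = "gating_model"
  )
}

#' Voltage-dependent rates implied by a gating model
#'
#' @param model A [gating_model()].
#' @param voltage Voltage, mV.
#' @return Named numeric: `k_on` (1/(M s)), `capture_rate` (1/s, already
#'   multiplied by the concentration) and `k_off` (1/s) at that voltage.
#' @export
gating_rates <- function(model, voltage) {
  k_on <- model$k_on_0 * exp(model$a * voltage)
  k_off <- model$k_off_0 * exp(model$b * voltage)
  c(k_on = k_on, capture_rate = k_on * model$concentration, k_off = k_off)
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "<acquisition_config> %.3g kHz sampling, %.3g kHz filter, %+g mV, %g s, seed %d\n",
    x$sampling_rate / 1e3, x$filter_cutoff / 1e3, x$voltage, x$duration, x$seed
  ))
  invisible(x)
}

#' @export
print.gating_model <- function(x, ...) {
  cat(sprintf(
    paste0("<gating_model> k_on(0) = %.3g /M/s (a = %g /mV), k_off(0) = %.3g /s (b = %g /mV)\n",
           "  [peptide] = %.3g M (%s side), i_open = %g pA, blockades %.3g / %.3g, noise %g pA\n"),
    x$k_on_0, x$a, x$k_off_0, x$b,
    x$concentration, x$side, x$i_open, x$frac_block_1, x$frac_block_2, x$noise_sd
  ))
  invisible(x)
}
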