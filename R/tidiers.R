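#' Tidy a dwell-time fit
#'
#' @param x A `dwell_fit` from [exp_mle()].
#' @param ... Unused.
#' @return One-row tibble: `tau_hat`, `n`, `ci_low`, `ci_high`, `alpha`,
#'   `low_n`.
#' @export
tidy.dwell_fit <- function(x, ...) {
  tibble(tau_hat = x$tau_hat, n = x$n, ci_low = x$ci_low,
         ci_high = x$ci_high, alpha = x$alpha, low_n = x$low_n)
}

#' @rdname tidy.dwell_fit
#' @export
glance.dwell_fit <- function(x, ...) {
  tibble(tau_hat = x$tau_hat, n = x$n, rate = 1 / x$tau_hat,
         ci_width = x$ci_high - x$ci_low)
}

#' Tidy a rate estimate
#'
#' @param x A `rate_estimate` from [compute_kon()] or [compute_koff()].
#' @param ... Unused.
#' @return One-row tibble: `kind`, `rate`, `ci_low`, `ci_high`, `n`,
#'   `units`.
#' @export
tidy.rate_estimate <- function(x, ...) {
  tibble(kind = x$kind, rate = x$rate, ci_low = x$ci_low,
         ci_high = x$ci_high, n = x$n, units = x$units)
}

#' Tidy a voltage-dependence fit
#'
#' @param x A `rate_fit` from [fit_voltage_dependence()].
#' @param ... Unused.
#' @return Two-row tibble (`term` = `k0`, `a`) with `estimate` and
#'   `std.error`.
#' @export
tidy.rate_fit <- function(x, ...) {
  tibble(term = c("k0", "a"),
         estimate = c(x$k0, x$a),
         std.error = c(x$k0_se, x$a_se))
}

#' @rdname tidy.rate_fit
#' @export
glance.rate_fit <- function(x, ...) {
  s <- summary(x$model)
  r2 <- if (!is.null(s$r.squared)) s$r.squared else NA_real_
  tibble(k0 = x$k0, a = x$a, n_voltages = nrow(x$per_voltage),
         r.squared = r2, method = x$method)
}

#' Tidy pooled blockade statistics
#'
#' @param x A `blockade_stats` from [amplitude_histogram()].
#' @param ... Unused.
#' @return One-row tibble: `i_open`, `i1_level`, `i2_level`,
#'   `frac_block_1`, `frac_block_2`, `n_samples`.
#' @export
tidy.blockade_stats <- function(x, ...) {
  tibble(i_open = x$i_open, i1_level = x$i1_level, i2_level = x$i2_level,
         frac_block_1 = x$frac_block_1, frac_block_2 = x$frac_block_2,
         n_samples = x$n_samples)
}

#' Tidy an excluded-volume blockade prediction
#'
#' @param x A `blockade_prediction` from [predict_blockade()].
#' @param ... Unused.
#' @return One-row tibble: `peptide`, `placement`, `excluded_volume_A3`,
#'   `r_open`, `r_blocked`, `frac_block`.
#' @export
tidy.blockade_prediction <- function(x, ...) {
  tibble(peptide = x$peptide, placement = x$placement,
         excluded_volume_A3 = x$excluded_volume_A3,
         r_open = x$r_open, r_blocked = x$r_blocked,
         frac_block = x$frac_block)
}
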