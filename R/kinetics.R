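#' Exponential maximum-likelihood fit of dwell times with exact CI
#'
#' For i.i.d. exponential dwell times the MLE of the mean is the arithmetic
#' mean, and `2 * n * tau_hat / tau` follows a chi-square distribution with
#' `2n` degrees of freedom, giving the exact two-sided confidence interval
#' `[2 n tau_hat / q(1 - alpha/2), 2 n tau_hat / q(alpha/2)]` where `q(p)`
#' is the chi-square quantile with `2n` degrees of freedom.
#'
#' Censored samples must be excluded before calling (see
#' [event_durations()]); including them biases the estimate downward.
#'
#' @param durations Positive dwell-time samples, s.
#' @param alpha Two-sided miscoverage level (default 0.05 for a 95% CI).
#' @return An object of class `dwell_fit`: `tau_hat`, `n`, `ci_low`,
#'   `ci_high` (s), `alpha`, `low_n` (flag, `n < 5`).
#' @examples
#' exp_mle(rexp(100, rate = 50))
#' @export
exp_mle <- function(durations, alpha = 0.05) {
  durations <- as.numeric(durations)
  if (length(durations) == 0) abort("No dwell times supplied.")
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    abort("All dwell times must be finite and positive.")
  }
  n <- length(durations)
  tau <- mean(durations)
  ci_low <- 2 * n * tau / qchisq(1 - alpha / 2, df = 2 * n)
  ci_high <- 2 * n * tau / qchisq(alpha / 2, df = 2 * n)
  low_n <- n < 5
  if (low_n) warn(sprintf("Only %d dwell times: confidence interval is wide and flagged low-n.", n))
  structure(
    list(tau_hat = tau, n = n, ci_low = ci_low, ci_high = ci_high,
         alpha = alpha, low_n = low_n, durations = durations),
    class = "dwell_fit"
  )
}

#' Association rate constant from the mean inter-event interval
#'
#' `k_on = 1 / (tau_on * C)`: the reciprocal of the mean waiting time
#' between captures, divided by the bulk peptide concentration. Confidence
#' bounds transform monotonically (the reciprocal swaps them).
#'
#' @param tau_on A `dwell_fit` of the inter-event intervals, from
#'   [exp_mle()].
#' @param concentration Bulk peptide concentration, M (positive). Use the
#'   per-dataset value from the recording metadata, never a global constant.
#' @return An object of class `rate_estimate` with `rate` (1/(M s)),
#'   `ci_low`, `ci_high`, `n`, `kind = "k_on"`.
#' @examples
#' compute_kon(exp_mle(rexp(500, 2)), concentration = 3e-5)
#' @export
compute_kon <- function(tau_on, concentration) {
  stopifnot(inherits(tau_on, "dwell_fit"))
  if (!is.numeric(concentration) || concentration <= 0) {
    abort("`concentration` must be positive (M).")
  }
  structure(
    list(
      rate = 1 / (tau_on$tau_hat * concentration),
      ci_low = 1 / (tau_on$ci_high * concentration),
      ci_high = 1 / (tau_on$ci_low * concentration),
      n = tau_on$n,
      concentration = concentration,
      kind = "k_on", units = "1/(M s)"
    ),
    class = "rate_estimate"
  )
}

#' Dissociation rate constant from the mean residence time
#'
#' `k_off = 1 / tau_off`; confidence bounds are reciprocal-transformed.
#'
#' @param tau_off A `dwell_fit` of the event durations, from [exp_mle()].
#' @return An object of class `rate_estimate` with `rate` (1/s), `ci_low`,
#'   `ci_high`, `n`, `kind = "k_off"`.
#' @export
compute_koff <- function(tau_off) {
  stopifnot(inherits(tau_off, "dwell_fit"))
  structure(
    list(
      rate = 1 / tau_off$tau_hat,
      ci_low = 1 / tau_off$ci_high,
      ci_high = 1 / tau_off$ci_low,
      n = tau_off$n,
      kind = "k_off", units = "1/s"
    ),
    class = "rate_estimate"
  )
}

#' Fit the exponential voltage dependence of a rate constant
#'
#' Fits `k(dV) = k0 * exp(a * dV)` by least squares on the log scale:
#' `ln k = ln k0 + a * dV`. The log-linear fit is numerically stable and
#' equivalent to the nonlinear fit at typical dwell-time precision; set
#' `method = "nls"` for the direct nonlinear fit (started from the
#' log-linear estimates). Optional inverse-variance weights use the
#' delta-method variance of `ln k`, `(se/k)^2`.
#'
#' @param points Data frame with columns `voltage_mV`, `k` (positive rates)
#'   and optionally `se` (standard errors of `k`).
#' @param weights `"none"` (default) or `"inverse_variance"` (requires
#'   `se`).
#' @param method `"log_linear"` (default) or `"nls"`.
#' @return An object of class `rate_fit`: `k0`, `a` (1/mV), `k0_se`, `a_se`,
#'   the per-voltage data, and the underlying model object.
#' @examples
#' pts <- tibble::tibble(voltage_mV = seq(40, 140, 20),
#'                       k = 1e3 * exp(0.02 * seq(40, 140, 20)))
#' fit_voltage_dependence(pts)
#' @export
fit_voltage_dependence <- function(points,
                                   weights = c("none", "inverse_variance"),
                                   method = c("log_linear", "nls")) {
  weights <- match.arg(weights)
  method <- match.arg(method)
  points <- as_tibble(points)
  if (!all(c("voltage_mV", "k") %in% names(points))) {
    abort("`points` needs columns `voltage_mV` and `k`.")
  }
  if (length(unique(points$voltage_mV)) < 3) {
    abort("Need at least 3 distinct voltages to fit the voltage dependence.")
  }
  if (any(!is.finite(points$k)) || any(points$k <= 0)) {
    abort("All rates must be finite and positive.")
  }
  w <- NULL
  if (weights == "inverse_variance") {
    if (is.null(points[["se"]])) abort("Inverse-variance weighting needs an `se` column.")
    w <- (points$k / points[["se"]])^2
  }
  df <- data.frame(logk = log(points$k), v = points$voltage_mV)
  fit <- lm(logk ~ v, data = df, weights = w)
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  k0 <- exp(cf[[1]]); a <- cf[[2]]
  k0_se <- k0 * se[[1]]; a_se <- se[[2]]
  model <- fit
  if (method == "nls") {
    nd <- data.frame(k = points$k, v = points$voltage_mV)
    model <- stats::nls(k ~ k0 * exp(a * v), data = nd,
                        start = list(k0 = k0, a = a),
                        weights = if (is.null(points[["se"]])) NULL else
                          1 / points[["se"]]^2)
    cf <- coef(model)
    se <- sqrt(diag(vcov(model)))
    k0 <- cf[["k0"]]; a <- cf[["a"]]
    k0_se <- se[["k0"]]; a_se <- se[["a"]]
  }
  structure(
    list(k0 = k0, a = a, k0_se = k0_se, a_se = a_se,
         per_voltage = points, model = model,
         weights = weights, method = method),
    class = "rate_fit"
  )
}

#' Rate predicted by a fitted voltage-dependence model
#' @param fit A `rate_fit`.
#' @param voltage Voltage(s), mV.
#' @return Predicted rate(s), `k0 * exp(a * voltage)`.
#' @export
predict_rate <- function(fit, voltage) {
  stopifnot(inherits(fit, "rate_fit"))
  fit$k0 * exp(fit$a * voltage)
}

#' Check the pairwise ordering of capture rates across the four conditions
#'
#' The four experimental conditions combine the peptide addition side (cis
#' or trans) with the polarity of the clamped voltage. At high voltage
#' magnitudes the expected chain is
#' `cis,-dV < cis,+dV < trans,+dV < trans,-dV`, while extrapolated to
#' zero voltage (on `k0`) it is
#' `cis,-dV < cis,+dV < trans,-dV < trans,+dV`.
#'
#' @param fits Named list with elements `cis_neg`, `cis_pos`, `trans_neg`,
#'   `trans_pos`; each either a `rate_fit` or a bare positive number
#'   (interpreted as `k0` with `a = 0`).
#' @param regime `"near_equilibrium"` (compare `k0`) or `"high_voltage"`
#'   (compare `k(+|voltage|)` for positive polarity and `k(-|voltage|)` for
#'   negative polarity).
#' @param voltage Magnitude used in the high-voltage regime, mV.
#' @return A tibble of class `ordering_report` with one row per adjacent
#'   pair of the expected chain: `lhs`, `rhs`, `k_lhs`, `k_rhs`, `holds`
#'   (strict inequality). Attribute `chain_holds` is `TRUE` when the whole
#'   chain is satisfied.
#' @export
check_orderings <- function(fits,
                            regime = c("near_equilibrium", "high_voltage"),
                            voltage = 140) {
  regime <- match.arg(regime)
  needed <- c("cis_neg", "cis_pos", "trans_neg", "trans_pos")
  missing <- setdiff(needed, names(fits))
  if (length(missing) > 0) {
    abort(paste0("Missing condition(s): ", paste(missing, collapse = ", "), "."))
  }
  val <- function(f, cond) {
    if (inherits(f, "rate_fit")) {
      if (regime == "near_equilibrium") return(f$k0)
      sgn <- if (grepl("neg$", cond)) -1 else 1
      return(predict_rate(f, sgn * abs(voltage)))
    }
    as.numeric(f)
  }
  ks <- vapply(needed, function(nm) val(fits[[nm]], nm), numeric(1))
  chain <- if (regime == "near_equilibrium") {
    c("cis_neg", "cis_pos", "trans_neg", "trans_pos")
  } else {
    c("cis_neg", "cis_pos", "trans_pos", "trans_neg")
  }
  out <- tibble(
    lhs = chain[-length(chain)],
    rhs = chain[-1],
    k_lhs = unname(ks[chain[-length(chain)]]),
    k_rhs = unname(ks[chain[-1]]),
    holds = unname(ks[chain[-length(chain)]] < ks[chain[-1]])
  )
  class(out) <- c("ordering_report", class(out))
  attr(out, "regime") <- regime
  attr(out, "chain_holds") <- all(out$holds)
  out
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("<dwell_fit> tau = %.4g s (n = %d, %d%% CI %.4g-%.4g s)%s\n",
              x$tau_hat, x$n, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
              if (x$low_n) " [low n]" else ""))
  invisible(x)
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %s = %.4g %s (CI %.4g-%.4g, n = %d)\n",
              x$kind, x$rate, x$units, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> k(dV) = k0 * exp(a dV); k0 = %.4g +/- %.2g, a = %.4g +/- %.2g /mV (%d voltages)\n",
              x$k0, x$k0_se, x$a, x$a_se, nrow(x$per_voltage)))
  invisible(x)
}

#' @export
print.ordering_report <- function(x, ...) {
  cat(sprintf("<ordering_report> regime: %s; chain %s\n",
              attr(x, "regime"),
              if (attr(x, "chain_holds")) "HOLDS" else "violated"))
  print(as_tibble(x))
  invisible(x)
}
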