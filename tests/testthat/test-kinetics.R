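test_that("exponential MLE equals the mean with the exact chi-square CI", {
  d <- rep(0.003, 20)
  f <- exp_mle(d)
  expect_equal(f$tau_hat, 0.003)
  expect_lt(f$ci_low, f$tau_hat)
  expect_gt(f$ci_high, f$tau_hat)
  # frozen oracle: n = 4, tau = 1 -> CI = [2n/q(0.975), 2n/q(0.025)], df = 8
  suppressWarnings(f4 <- exp_mle(rep(1, 4)))
  expect_equal(f4$ci_low, 8 / qchisq(0.975, 8))
  expect_equal(f4$ci_high, 8 / qchisq(0.025, 8))
  expect_true(f4$low_n)
  expect_error(exp_mle(numeric()), "No dwell")
  expect_error(exp_mle(c(1, -1)), "positive")
})

test_that("MLE on large samples matches the asymptotic error scaling", {
  set.seed(55)
  d <- rexp(1e4, rate = 1000)  # mean 1 ms
  f <- exp_mle(d)
  expect_lt(abs(f$tau_hat - 1e-3) / 1e-3, 0.02)
  asym <- 2 * 1.96 * f$tau_hat / sqrt(1e4)
  expect_lt(abs((f$ci_high - f$ci_low) - asym) / asym, 0.05)
})

test_that("exp_mle is scale-equivariant", {
  set.seed(6)
  d <- rexp(200, 30)
  f1 <- exp_mle(d)
  f2 <- exp_mle(d * 7)
  expect_equal(f2$tau_hat, 7 * f1$tau_hat)
  expect_equal(f2$ci_low, 7 * f1$ci_low)
  expect_equal(f2$ci_high, 7 * f1$ci_high)
})

test_that("k_on and k_off transforms are reciprocal with swapped CI bounds", {
  set.seed(2)
  f <- exp_mle(rexp(500, 2))
  kon <- compute_kon(f, concentration = 2e-5)
  expect_equal(kon$rate, 1 / (f$tau_hat * 2e-5))
  expect_equal(kon$ci_low, 1 / (f$ci_high * 2e-5))
  expect_equal(kon$ci_high, 1 / (f$ci_low * 2e-5))
  expect_lt(kon$ci_low, kon$rate)
  # doubling C halves k_on
  expect_equal(compute_kon(f, 4e-5)$rate, kon$rate / 2)
  expect_error(compute_kon(f, 0), "concentration")
  koff <- compute_koff(exp_mle(rep(0.01, 50)))
  expect_equal(koff$rate, 100)
})

test_that("simulated k_on and k_off are recovered within their CIs", {
  mod <- gating_model(k_on_0 = 1e5, a = 0, concentration = 3e-5, k_off_0 = 80,
                      substate_switch_rates = c(0, 0))
  ev <- simulate_events(mod, acquisition_config(seed = 23), n_events = 2500)
  kon <- compute_kon(exp_mle(ev$wait_s), 3e-5)
  expect_gt(1e5, kon$ci_low)
  expect_lt(1e5, kon$ci_high)
  koff <- compute_koff(exp_mle(ev$duration_s))
  expect_gt(80, koff$ci_low)
  expect_lt(80, koff$ci_high)
})

test_that("round-trip k_on recovery falls inside the 95% CI in most replicates", {
  hits <- vapply(1:20, function(s) {
    ev <- simulate_events(
      gating_model(k_on_0 = 1e5, a = 0, concentration = 3e-5, k_off_0 = 100,
                   substate_switch_rates = c(0, 0)),
      acquisition_config(seed = 400 + s), n_events = 300
    )
    kon <- compute_kon(exp_mle(ev$wait_s), 3e-5)
    kon$ci_low <= 1e5 && 1e5 <= kon$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("voltage fit recovers noiseless parameters to machine precision", {
  volts <- seq(40, 140, 20)
  pts <- tibble::tibble(voltage_mV = volts, k = 1e3 * exp(0.02 * volts))
  # lm warns about the zero-residual fit; the point estimates are the check
  fit <- suppressWarnings(fit_voltage_dependence(pts))
  expect_equal(fit$k0, 1e3, tolerance = 1e-10)
  expect_equal(fit$a, 0.02, tolerance = 1e-12)
  # data generated with a = 0 plus scatter, voltages centered on zero:
  # the fitted k0 is the geometric mean of the rates
  ks <- c(2, 8, 4)
  flat <- fit_voltage_dependence(tibble::tibble(voltage_mV = c(-50, 0, 50),
                                                k = ks))
  expect_equal(flat$k0, exp(mean(log(ks))), tolerance = 1e-10)
  expect_equal(suppressWarnings(fit_voltage_dependence(tibble::tibble(
    voltage_mV = c(40, 90, 140), k = rep(7, 3))))$k0, 7, tolerance = 1e-10)
  expect_error(fit_voltage_dependence(pts[1:2, ]), "3 distinct")
  expect_error(
    fit_voltage_dependence(tibble::tibble(voltage_mV = volts,
                                          k = c(-1, 1, 1, 1, 1, 1))),
    "positive"
  )
  # nonlinear option agrees with the log-linear fit on scattered data
  set.seed(12)
  noisy <- tibble::tibble(voltage_mV = volts,
                          k = 1e3 * exp(0.02 * volts) * exp(rnorm(6, 0, 0.03)))
  nl <- fit_voltage_dependence(noisy, method = "nls")
  ll <- fit_voltage_dependence(noisy)
  expect_equal(nl$a, ll$a, tolerance = 0.05)
  expect_equal(log(nl$k0), log(ll$k0), tolerance = 0.02)
})

test_that("voltage-fit bias shrinks as events per voltage grow", {
  err <- vapply(c(100, 1000), function(n_ev) {
    errs <- vapply(1:5, function(s) {
      fit <- fit_k0_event_level(8.35e4, 0.02, seq(40, 140, 20),
                                seed = 600 + s, n_events = n_ev)
      abs(log(fit$k0 / 8.35e4))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("condition orderings are evaluated per regime", {
  # near-equilibrium chain from scalar k0 values in the expected order
  fits <- list(cis_neg = 1, cis_pos = 10, trans_neg = 100, trans_pos = 1000)
  rep_ne <- check_orderings(fits, "near_equilibrium")
  expect_true(attr(rep_ne, "chain_holds"))
  # identical conditions: no strict inequality holds
  same <- list(cis_neg = 5, cis_pos = 5, trans_neg = 5, trans_pos = 5)
  expect_false(any(check_orderings(same, "near_equilibrium")$holds))
  # missing condition named in the error
  expect_error(check_orderings(fits[-1], "near_equilibrium"), "cis_neg")
  # high-voltage regime evaluates k at the signed voltage
  mk <- function(k0, a) {
    suppressWarnings(fit_voltage_dependence(tibble::tibble(
      voltage_mV = c(40, 90, 140), k = k0 * exp(a * c(40, 90, 140))
    )))
  }
  hv <- list(cis_neg = mk(10, -0.001), cis_pos = mk(20, 0.001),
             trans_pos = mk(30, 0.001), trans_neg = mk(5, -0.03))
  rep_hv <- check_orderings(hv, "high_voltage", voltage = 140)
  # trans_neg k(-140) = 5 * exp(4.2) ~ 333 dominates the chain
  expect_true(attr(rep_hv, "chain_holds"))
})
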