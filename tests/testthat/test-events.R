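test_that("baseline estimation finds the open-pore mode and noise level", {
  # constant trace
  flat <- tibble::tibble(time_s = (0:1999) / 5e4, current_pA = rep(100, 2000))
  expect_equal(unname(estimate_baseline(flat)), c(100, 0))
  # bimodal mixture: 20% blocked at 9 pA, noise 2 pA
  set.seed(42)
  n <- 2e5
  blocked <- runif(n) < 0.2
  x <- ifelse(blocked, rnorm(n, 9, 2), rnorm(n, 100, 2))
  tr <- tibble::tibble(time_s = (seq_len(n) - 1) / 5e4, current_pA = x)
  bl <- estimate_baseline(tr)
  expect_lt(abs(bl[["i_open"]] - 100), 0.5)
  expect_lt(abs(bl[["noise_sd"]] - 2), 0.3)
  # shift equivariance
  tr2 <- tr
  tr2$current_pA <- tr2$current_pA + 25
  expect_equal(estimate_baseline(tr2)[["i_open"]], bl[["i_open"]] + 25,
               tolerance = 0.05)
  expect_error(estimate_baseline(tibble::tibble(current_pA = numeric())),
               "Empty")
})

test_that("noise-free square-wave events are recovered exactly", {
  cfg <- acquisition_config(duration = 2, seed = 1)
  mod <- gating_model(noise_sd = 0, frac_block_1 = 0.91,
                      substate_switch_rates = c(0, 0))
  starts <- 0.005 + (0:49) * 0.04
  ev_true <- tibble::tibble(event = 1:50, start_s = starts, duration_s = 0.01,
                            censored = FALSE)
  ev_true$substates <- purrr::map(starts, ~ tibble::tibble(
    level = 1L, start_s = .x, end_s = .x + 0.01))
  tr <- render_trace(ev_true, mod, cfg)
  det <- detect_events(tr)
  expect_identical(nrow(det), 50L)
  expect_true(all(abs(det$start_s - starts) <= 1 / 5e4 + 1e-12))
  expect_true(all(abs(det$duration_s - 0.01) <= 2 / 5e4 + 1e-12))
  # exact up to filter-smeared boundary samples (edges are trimmed, but the
  # exit hysteresis keeps one partially smeared sample inside the event)
  expect_true(all(abs(det$mean_amplitude_pA - 9) < 5e-3))
})

test_that("a trace with no excursions yields an empty event table", {
  tr <- tibble::tibble(time_s = (0:9999) / 5e4,
                       current_pA = 100 + rnorm(10000, sd = 0.5))
  attr(tr, "config") <- acquisition_config(duration = 0.2, seed = 1)
  class(tr) <- c("np_trace", class(tr))
  expect_identical(nrow(detect_events(tr)), 0L)
})

test_that("hysteresis thresholds are validated", {
  tr <- tibble::tibble(time_s = (0:999) / 5e4, current_pA = rep(100, 1000))
  expect_error(detect_events(tr, enter_frac = 0.9, exit_frac = 0.7),
               "enter_frac")
})

test_that("detection achieves near-perfect recall and precision on noisy data", {
  mod <- pe6_model(capture_rate = 5, k_off = 50)
  cfg <- acquisition_config(duration = 60, seed = 77)
  tr <- simulate_trace(mod, cfg)
  truth <- attr(tr, "true_events")
  det <- detect_events(tr)
  m <- match_events(truth, det, min_true = 2e-4)
  expect_gte(m[["recall"]], 0.99)
  expect_gte(m[["precision"]], 0.99)
})

test_that("detection is invariant to rescaling the whole trace", {
  mod <- pe6_model(capture_rate = 8)
  tr <- simulate_trace(mod, acquisition_config(duration = 10, seed = 13))
  det1 <- detect_events(tr)
  tr2 <- tr
  tr2$current_pA <- tr2$current_pA * 3.7
  attr(tr2, "config") <- attr(tr, "config")
  det2 <- detect_events(tr2)
  expect_identical(nrow(det1), nrow(det2))
  expect_equal(det1$start_s, det2$start_s)
  expect_equal(det1$duration_s, det2$duration_s)
})

test_that("substate segmentation recovers noise-free alternation exactly", {
  cfg <- acquisition_config(duration = 0.2, seed = 1)
  mod <- gating_model(noise_sd = 0, i_open = 100, frac_block_1 = 0.91,
                      frac_block_2 = 0.83)
  segs <- tibble::tibble(
    level = rep(c(1L, 2L), 5),
    start_s = 0.05 + (0:9) * 0.004,
    end_s = 0.05 + (1:10) * 0.004
  )
  ev <- tibble::tibble(event = 1L, start_s = 0.05, duration_s = 0.04,
                       censored = FALSE, substates = list(segs))
  tr <- render_trace(ev, mod, cfg)
  det <- detect_events(tr)
  seg <- segment_substates(det, tr, i1_guess = 9, i2_guess = 17)
  s <- seg$substates[[1]]
  expect_identical(nrow(s), 10L)
  expect_equal(s$level, rep(c(1L, 2L), 5))
  expect_equal(s$start_s, segs$start_s, tolerance = 1 / 5e4)
  # substates tile the event exactly
  expect_equal(sum(s$end_s - s$start_s), seg$duration_s[1])
  expect_equal(s$start_s[-1], s$end_s[-nrow(s)])
  # single-level event gives a single segment
  one <- detect_events(render_trace(
    dplyr::mutate(ev, substates = list(tibble::tibble(level = 1L,
                                                      start_s = 0.05,
                                                      end_s = 0.09))),
    mod, cfg))
  seg1 <- segment_substates(one, render_trace(
    dplyr::mutate(ev, substates = list(tibble::tibble(level = 1L,
                                                      start_s = 0.05,
                                                      end_s = 0.09))),
    mod, cfg), 9, 17)
  expect_identical(nrow(seg1$substates[[1]]), 1L)
})

test_that("noisy substate assignment is at least 95% correct", {
  cfg <- acquisition_config(duration = 0.5, seed = 19)
  mod <- gating_model(noise_sd = 2, i_open = 100, frac_block_1 = 0.91,
                      frac_block_2 = 0.83)
  # one long event alternating every 2 ms
  n_seg <- 100
  segs <- tibble::tibble(
    level = rep(c(1L, 2L), n_seg / 2),
    start_s = 0.05 + (seq_len(n_seg) - 1) * 0.002,
    end_s = 0.05 + seq_len(n_seg) * 0.002
  )
  ev <- tibble::tibble(event = 1L, start_s = 0.05,
                       duration_s = n_seg * 0.002,
                       censored = FALSE, substates = list(segs))
  tr <- render_trace(ev, mod, cfg)
  det <- detect_events(tr)
  seg <- segment_substates(det, tr, 9, 17)
  s <- seg$substates[[1]]
  # score per-sample agreement with the generating path
  fs <- 5e4
  t_mid <- seq(det$start_s[1] + 0.5 / fs, det$end_s[1] - 0.5 / fs, by = 1 / fs)
  truth_lv <- segs$level[pmin(findInterval(t_mid, segs$start_s), n_seg)]
  est_lv <- s$level[pmin(findInterval(t_mid, s$start_s), nrow(s))]
  expect_gte(mean(truth_lv == est_lv), 0.95)
})

test_that("amplitude histogram recovers mixture peaks within 1 pA", {
  set.seed(8)
  n <- 4e4
  x <- c(rnorm(n / 2, 9, 2), rnorm(n / 2, 17, 2))
  tr <- tibble::tibble(time_s = (seq_len(n) - 1) / 5e4, current_pA = x)
  attr(tr, "config") <- acquisition_config(duration = n / 5e4, seed = 1)
  class(tr) <- c("np_trace", class(tr))
  ev <- tibble::tibble(event = 1L, start_s = 0, end_s = n / 5e4,
                       duration_s = n / 5e4, wait_s = NA_real_,
                       mean_amplitude_pA = mean(x), n_samples = n,
                       censored = FALSE)
  class(ev) <- c("np_events", class(ev))
  attr(ev, "i_open") <- 100
  attr(ev, "noise_sd") <- 2
  bs <- amplitude_histogram(ev, tr)
  expect_lt(abs(bs$i1_level - 9), 1)
  expect_lt(abs(bs$i2_level - 17), 1)
  # single-level events: one peak, second absent
  x1 <- rnorm(n, 9, 2)
  tr1 <- tibble::tibble(time_s = (seq_len(n) - 1) / 5e4, current_pA = x1)
  attr(tr1, "config") <- attr(tr, "config")
  class(tr1) <- class(tr)
  ev1 <- ev
  bs1 <- amplitude_histogram(ev1, tr1)
  expect_lt(abs(bs1$i1_level - 9), 1)
  expect_true(is.na(bs1$frac_block_2) || bs1$i2_level > 9 - 3)
})

test_that("closed-loop fractional blockade recovery is accurate across depths", {
  for (depth in c(0.85, 0.91, 0.95)) {
    mod <- gating_model(k_on_0 = 10 / 3e-5, a = 0, concentration = 3e-5,
                        k_off_0 = 50, frac_block_1 = depth,
                        frac_block_2 = depth - 0.08, noise_sd = 2)
    tr <- simulate_trace(mod, acquisition_config(duration = 25,
                                                 seed = 100 + round(100 * depth)))
    ev <- detect_events(tr)
    expect_gte(nrow(ev), 200)
    bs <- amplitude_histogram(ev, tr)
    expect_lt(abs(bs$frac_block_1 - depth), 0.01)
  }
})

test_that("fractional blockade arithmetic and guards", {
  expect_equal(fractional_blockade(9, 100), 0.91)
  expect_equal(fractional_blockade(100, 100), 0)
  expect_equal(fractional_blockade(0, 100), 1)
  expect_error(fractional_blockade(5, 0), "i_open")
  expect_error(fractional_blockade(-1, 100), "i_blocked")
})
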