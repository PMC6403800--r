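#' Pooled amplitude histogram and substate levels of blockade events
#'
#' Pools every in-event sample across events (dropping the two samples
#' nearest each event boundary, where the filter smears the transition),
#' histograms them, and locates the two substate current levels `I1` (deep)
#' and `I2` (shallow) as the two highest local maxima of the 3-bin
#' moving-average-smoothed histogram separated by at least
#' `min_peak_sep_bins` bins. Peak positions are refined by quadratic
#' interpolation through the peak bin and its neighbours, so the reported
#' level is not quantized to the bin grid. Ties are broken toward the
#' lower-current bin. If only one peak exists, `I2` is reported absent.
#'
#' Substate amplitudes are reported as histogram peak positions, matching
#' the two-peak analysis of pooled recordings; per-segment means from
#' [segment_substates()] remain available for diagnostics.
#'
#' @param events An `np_events` tibble from [detect_events()].
#' @param trace The trace the events were detected in.
#' @param bin_width Histogram bin width, pA; default
#'   `max(noise_sd / 2, 0.1)`.
#' @param min_peak_sep_bins Minimum separation between the two reported
#'   peaks, bins.
#' @return An object of class `blockade_stats`: fields `i1_level`,
#'   `i2_level` (pA; `i2_level` may be `NA`), `frac_block_1`,
#'   `frac_block_2`, `i_open`, `bin_width` and a `histogram` tibble
#'   (`bin_mid`, `count`, `smoothed`).
#' @export
amplitude_histogram <- function(events, trace, bin_width = NULL,
                                min_peak_sep_bins = 3L) {
  if (nrow(events) == 0) abort("No events: cannot build an amplitude histogram.")
  x <- trace$current_pA
  fs <- .trace_fs(trace)
  t0 <- if (!is.null(trace$time_s)) trace$time_s[1] else 0
  i_open <- attr(events, "i_open", exact = TRUE) %||%
    estimate_baseline(trace)[[1]]
  noise_sd <- attr(events, "noise_sd", exact = TRUE) %||%
    estimate_baseline(trace)[[2]]
  if (is.null(bin_width)) bin_width <- max(noise_sd / 2, 0.1)

  pooled <- unlist(purrr::map2(events$start_s, events$end_s, function(a, b) {
    i0 <- round((a - t0) * fs) + 1L
    i1 <- round((b - t0) * fs)
    j0 <- i0 + 2L; j1 <- i1 - 2L
    if (j1 < j0) { j0 <- i0; j1 <- i1 }
    x[j0:j1]
  }))

  lo <- floor(min(pooled) / bin_width) * bin_width - bin_width
  hi <- max(pooled) + bin_width
  breaks <- seq(lo, hi + bin_width, by = bin_width)
  counts <- tabulate(findInterval(pooled, breaks), nbins = length(breaks) - 1L)
  mids <- breaks[-length(breaks)] + bin_width / 2

  sm <- as.numeric(stats::filter(counts, rep(1 / 3, 3), sides = 2))
  nb <- length(counts)
  if (nb >= 2) {
    sm[1] <- mean(counts[1:2])
    sm[nb] <- mean(counts[(nb - 1):nb])
  } else {
    sm <- as.numeric(counts)
  }

  peaks <- .local_maxima(sm)
  if (length(peaks) == 0) peaks <- which.max(sm)
  ord <- order(sm[peaks], -peaks, decreasing = TRUE)  # ties -> lower bin
  p1 <- peaks[ord[1]]
  p2 <- NA_integer_
  for (p in peaks[ord[-1]]) {
    if (abs(p - p1) >= min_peak_sep_bins) { p2 <- p; break }
  }

  loc1 <- .refine_peak(mids, sm, p1, bin_width)
  loc2 <- if (is.na(p2)) NA_real_ else .refine_peak(mids, sm, p2, bin_width)
  levels <- sort(c(loc1, loc2), na.last = TRUE)
  i1_level <- levels[1]
  i2_level <- levels[2]

  structure(
    list(
      i1_level = i1_level,
      i2_level = i2_level,
      frac_block_1 = fractional_blockade(min(max(i1_level, 0), i_open), i_open),
      frac_block_2 = if (is.na(i2_level)) NA_real_ else
        fractional_blockade(min(max(i2_level, 0), i_open), i_open),
      i_open = unname(i_open),
      bin_width = bin_width,
      n_samples = length(pooled),
      histogram = tibble(bin_mid = mids, count = counts, smoothed = sm)
    ),
    class = "blockade_stats"
  )
}

# Indices of interior local maxima (>= both neighbours, > at least one).
.local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[y[i] >= y[i - 1] & y[i] >= y[i + 1] & (y[i] > y[i - 1] | y[i] > y[i + 1])]
}

# Quadratic (three-point) interpolation of a peak position.
.refine_peak <- function(mids, y, i, bw) {
  if (i <= 1 || i >= length(y)) return(mids[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (!is.finite(denom) || denom >= 0) return(mids[i])
  delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  mids[i] + max(-0.5, min(0.5, delta)) * bw
}

#' @export
print.blockade_stats <- function(x, ...) {
  cat(sprintf(
    "<blockade_stats> i_open = %.2f pA; I1 = %.2f pA (frac %.3f); I2 = %s (%s)\n",
    x$i_open, x$i1_level, x$frac_block_1,
    if (is.na(x$i2_level)) "absent" else sprintf("%.2f pA", x$i2_level),
    if (is.na(x$frac_block_2)) "-" else sprintf("frac %.3f", x$frac_block_2)
  ))
  invisible(x)
}
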