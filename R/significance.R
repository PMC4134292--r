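#' Monte-Carlo calibration of wavelet-power significance thresholds
#'
#' Builds a look-up table of per-frequency wavelet-power thresholds under
#' Poisson white noise. For each spike count `n` on the grid `10^k`
#' (`k = 0.0, 0.1, ..., 6.0` by default), `n_reps` white-noise correlograms
#' are generated by placing `n` spikes uniformly at random over the
#' transformed window's bins (bin collisions allowed, giving Poisson
#' statistics per bin), each is wavelet-transformed, and the maximum power
#' over the peak-identification window is recorded at each frequency. The
#' threshold at probability `p_level` is the `(p_level * n_reps)`-th highest
#' of those maxima (e.g. the 100th highest of 1e5 for `p = 0.001`).
#'
#' Raw per-count order statistics are made non-decreasing along the
#' spike-count axis (running maximum): the true threshold grows with spike
#' count, so this only irons out Monte-Carlo noise.
#'
#' @param cfg A [wavelet_config()].
#' @param n_reps Null replicates per grid count (full fidelity 1e5; smaller
#'   values with the same `p_level * n_reps` index are supported).
#' @param p_level Significance level (default 0.001); `p_level * n_reps`
#'   must be a positive integer.
#' @param seed Optional RNG seed; per-grid-count child seeds are derived
#'   from it, so results do not depend on execution order.
#' @param log10_counts Grid of log10 spike counts (default `seq(0, 6, 0.1)`).
#' @return An object of class `threshold_table` with fields `log10_counts`,
#'   `freqs`, `thresholds` (counts x frequencies), `p_level`, `n_reps`,
#'   `seed` and `config`.
#' @export
calibrate_thresholds <- function(cfg, n_reps = 1e5, p_level = 0.001,
                                 seed = NULL, log10_counts = seq(0, 6, by = 0.1)) {
  stopifnot(inherits(cfg, "wavelet_config"))
  idx <- p_level * n_reps
  if (idx < 1 - 1e-9 || abs(idx - round(idx)) > 1e-6)
    stop("`p_level * n_reps` must be a positive integer (order-statistic index)")
  idx <- as.integer(round(idx))
  log10_counts <- sort(unique(log10_counts))
  fb <- wavelet_filterbank(cfg)
  seeds <- derive_seeds(seed, length(log10_counts))
  thr <- matrix(NA_real_, length(log10_counts), cfg$n_freq)
  for (ci in seq_along(log10_counts)) {
    n_sp <- as.integer(round(10^log10_counts[ci]))
    mx <- with_seed(seeds[[ci]],
      null_maxima_cpp(fb$G, cfg$n_bins, fb$pad_left, fb$n_edge,
                      fb$peak_lo, fb$peak_hi, n_sp, as.integer(n_reps)))
    thr[ci, ] <- apply(mx, 2L, function(col) sort(col, decreasing = TRUE)[idx])
  }
  thr <- apply(thr, 2L, cummax)
  if (length(log10_counts) == 1L) thr <- matrix(thr, nrow = 1L)
  structure(list(log10_counts = log10_counts, freqs = fb$freqs,
                 thresholds = thr, p_level = p_level,
                 n_reps = as.integer(n_reps),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 config = cfg),
            class = "threshold_table")
}

#' @export
print.threshold_table <- function(x, ...) {
  cat(sprintf(paste0("Threshold table: %d spike-count grid points ",
                     "(10^%.1f..10^%.1f) x %d frequencies,\n  p = %g from %d",
                     " null replicates per count (order statistic %d)\n"),
              length(x$log10_counts), min(x$log10_counts), max(x$log10_counts),
              length(x$freqs), x$p_level, x$n_reps,
              as.integer(round(x$p_level * x$n_reps))))
  invisible(x)
}

#' Look up a significance threshold
#'
#' Linear interpolation in `k = log10(n_spikes)` between the bracketing grid
#' counts; exact at grid points. The frequency is snapped to the nearest
#' table frequency (the table shares the analysis frequency grid, so no
#' frequency interpolation occurs). No extrapolation: `n_spikes` must lie
#' within the calibrated grid range.
#'
#' @param tbl A [calibrate_thresholds()] table.
#' @param n_spikes Total correlogram count (within the transformed window).
#' @param freq Frequency in Hz (vectorized).
#' @return Power threshold(s) at `p_level`.
#' @export
lookup_threshold <- function(tbl, n_spikes, freq) {
  stopifnot(inherits(tbl, "threshold_table"))
  if (!is_number(n_spikes) || n_spikes < 1)
    stop("`n_spikes` must be >= 1")
  k <- log10(n_spikes)
  if (k < min(tbl$log10_counts) - 1e-9 || k > max(tbl$log10_counts) + 1e-9)
    stop("`n_spikes` outside the calibrated grid (10^",
         min(tbl$log10_counts), "..10^", max(tbl$log10_counts),
         "); no extrapolation")
  k <- min(max(k, min(tbl$log10_counts)), max(tbl$log10_counts))
  fi <- vapply(freq, function(f) which.min(abs(log(tbl$freqs) - log(f))),
               integer(1))
  if (length(tbl$log10_counts) == 1L) return(tbl$thresholds[1L, fi])
  vapply(fi, function(j) {
    stats::approx(tbl$log10_counts, tbl$thresholds[, j], xout = k,
                  rule = 1)$y
  }, numeric(1))
}

#' Per-frequency null power maxima
#'
#' Generates fresh Poisson white-noise correlograms (spikes placed uniformly
#' over the transformed window) and returns, for each replicate, the maximum
#' wavelet power over the peak-identification window at each frequency.
#' This is the held-out ensemble used to validate calibrated thresholds.
#'
#' @param cfg A [wavelet_config()].
#' @param n_spikes Spike count per null correlogram.
#' @param n_reps Number of replicates.
#' @param seed Optional RNG seed.
#' @return `n_reps` x `n_freq` matrix of power maxima.
#' @export
null_power_maxima <- function(cfg, n_spikes, n_reps, seed = NULL) {
  stopifnot(inherits(cfg, "wavelet_config"))
  if (!is_count(n_spikes) || n_spikes < 1) stop("`n_spikes` must be >= 1")
  fb <- wavelet_filterbank(cfg)
  with_seed(seed,
    null_maxima_cpp(fb$G, cfg$n_bins, fb$pad_left, fb$n_edge,
                    fb$peak_lo, fb$peak_hi, as.integer(n_spikes),
                    as.integer(n_reps)))
}
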