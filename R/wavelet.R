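#' Complex Morlet mother wavelet
#'
#' `psi0(eta) = pi^(-1/4) exp(i omega0 eta) exp(-eta^2 / 2)` in
#' non-dimensional time `eta`.
#'
#' @param eta Non-dimensional time (vectorized).
#' @param omega0 Non-dimensional central frequency (default 4).
#' @return Complex vector of wavelet values.
#' @export
morlet <- function(eta, omega0 = 4) {
  pi^(-0.25) * exp(1i * omega0 * eta) * exp(-eta^2 / 2)
}

#' Fourier period and scale of the Morlet wavelet
#'
#' The Fourier period equivalent to frequency `freq` is `1/freq`; the Morlet
#' scale matching that period is
#' `s = period * (omega0 + sqrt(2 + omega0^2)) / (4 pi)`.
#'
#' @param freq Frequency in Hz (> 0, vectorized).
#' @param omega0 Non-dimensional central frequency (default 4).
#' @return Seconds (`fourier_period`) or the matching wavelet scale in
#'   seconds (`matching_scale`).
#' @export
fourier_period <- function(freq) {
  if (any(freq <= 0)) stop("`freq` must be > 0")
  1 / freq
}

#' @rdname fourier_period
#' @export
matching_scale <- function(freq, omega0 = 4) {
  fourier_period(freq) * (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
}

#' Wavelet-transform configuration
#'
#' The two analysis presets used throughout:
#' \describe{
#'   \item{scale 1}{50 µs bins, transformed window ±70 ms (2801 bin
#'     centres), peak-identification window ±20 ms, 20–1000 Hz.}
#'   \item{scale 2}{500 µs bins, transformed window ±700 ms (2801 bin
#'     centres), peak-identification window ±200 ms, 2–100 Hz.}
#' }
#' Both use 101 frequencies equally spaced in log frequency (endpoints
#' included) and `omega0 = 4`.
#'
#' @param scale 1 or 2, selecting the preset; individual fields can be
#'   overridden through `...`.
#' @param ... Overrides among `bin_width`, `transform_window`, `peak_window`,
#'   `freq_lo`, `freq_hi`, `n_freq`, `omega0`.
#' @return An object of class `wavelet_config`.
#' @export
wavelet_config <- function(scale = 1, ...) {
  base <- switch(as.character(scale),
    "1" = list(bin_width = 50e-6, transform_window = 70e-3,
               peak_window = 20e-3, freq_lo = 20, freq_hi = 1000),
    "2" = list(bin_width = 500e-6, transform_window = 700e-3,
               peak_window = 200e-3, freq_lo = 2, freq_hi = 100),
    stop("`scale` must be 1 or 2"))
  cfg <- utils::modifyList(c(base, list(n_freq = 101L, omega0 = 4,
                                        scale = as.integer(scale))),
                           list(...))
  nb <- 2 * cfg$transform_window / cfg$bin_width + 1
  if (abs(nb - round(nb)) > 1e-6)
    stop("`transform_window` must be a multiple of `bin_width`")
  cfg$n_bins <- as.integer(round(nb))
  structure(cfg, class = "wavelet_config")
}

#' @export
print.wavelet_config <- function(x, ...) {
  cat(sprintf(paste0("Wavelet config (scale %d): %.0f us bins, +/-%g ms window",
                     " (%d centres),\n  peak window +/-%g ms, %g-%g Hz x %d",
                     " log-spaced frequencies, omega0 = %g\n"),
              x$scale, x$bin_width * 1e6, x$transform_window * 1e3, x$n_bins,
              x$peak_window * 1e3, x$freq_lo, x$freq_hi, x$n_freq, x$omega0))
  invisible(x)
}

#' Analysis frequency grid of a configuration
#'
#' @param cfg A [wavelet_config()].
#' @return `n_freq` frequencies from `freq_lo` to `freq_hi`, equally spaced
#'   in log space, ascending.
#' @export
wavelet_freqs <- function(cfg) {
  stopifnot(inherits(cfg, "wavelet_config"))
  10^seq(log10(cfg$freq_lo), log10(cfg$freq_hi), length.out = cfg$n_freq)
}

# Precomputed frequency-domain Morlet filter bank on the padded power-of-two
# grid, shared by data transforms and the Monte-Carlo null loop. The padded
# length M is the next power of two >= n_bins; the pad is split 647 left /
# 648 right for the 2801-bin presets (as evenly as possible in general).
wavelet_filterbank <- function(cfg) {
  stopifnot(inherits(cfg, "wavelet_config"))
  if (cfg$n_bins < 100)
    stop("transformed window shorter than the 100 edge bins used for padding")
  M <- 2^ceiling(log2(cfg$n_bins))
  pad <- M - cfg$n_bins
  pad_left <- pad %/% 2L
  freqs <- wavelet_freqs(cfg)
  s <- matching_scale(freqs, cfg$omega0)
  kk <- c(0:(M / 2), seq(-M / 2 + 1, -1))
  w <- 2 * pi * kk / (M * cfg$bin_width)
  G <- vapply(seq_along(freqs), function(f) {
    sqrt(2 * pi * s[f] / cfg$bin_width) * pi^(-0.25) *
      exp(-0.5 * (s[f] * w - cfg$omega0)^2)
  }, numeric(M))
  # The Gaussian tails underflow to subnormals, which cripple the FFT loop
  # on x86; values this far below the filter peak are numerically irrelevant.
  G[G < max(G) * 1e-14] <- 0
  ctr <- pad_left + (cfg$n_bins - 1L) %/% 2L      # 0-based padded index of lag 0
  pw <- as.integer(round(cfg$peak_window / cfg$bin_width))
  list(cfg = cfg, M = M, pad_left = pad_left, pad_right = pad - pad_left,
       n_edge = 100L, freqs = freqs, scales = s, G = G,
       center = ctr, peak_lo = ctr - pw, peak_hi = ctr + pw)
}

pad_series <- function(counts, fb) {
  ne <- fb$n_edge
  c(rep(mean(counts[seq_len(ne)]), fb$pad_left), counts,
    rep(mean(counts[seq.int(length(counts) - ne + 1L, length(counts))]),
        fb$pad_right))
}

#' Wavelet power spectrum of a correlogram
#'
#' Convolves the correlogram with scaled, translated and normalized complex
#' Morlet wavelets (Torrence–Compo normalization `sqrt(bin_width / s)`) and
#' returns the squared modulus on the frequency x lag plane. Before
#' transforming, both ends of the correlogram are padded with the average of
#' 100 edge bins so that the total length is a power of two; only the
#' transformed window is returned, so the pad never enters the analysis.
#'
#' @param c A [compute_cch()] result whose bin width matches `cfg` and whose
#'   window spans at least the configured transformed window (wider
#'   correlograms are trimmed centrally).
#' @param cfg A [wavelet_config()].
#' @param fb Optional precomputed filter bank (internal reuse).
#' @return An object of class `wavelet_power` with fields `freqs`
#'   (ascending, log-spaced), `lags` (the transformed window), `power`
#'   (`n_freq` x `n_lags`, `|W|^2 >= 0`), `config` and `n_spikes`.
#' @export
wavelet_power <- function(c, cfg = wavelet_config(1), fb = NULL) {
  stopifnot(inherits(c, "cch"))
  if (abs(c$bin_width - cfg$bin_width) > 1e-12)
    stop("correlogram bin width does not match the wavelet configuration")
  if (length(c$counts) < cfg$n_bins)
    stop("correlogram does not span the configured transformed window")
  if (is.null(fb)) fb <- wavelet_filterbank(cfg)
  counts <- c$counts
  if (length(counts) > cfg$n_bins) {     # trim centrally to the window
    drop <- (length(counts) - cfg$n_bins) %/% 2L
    counts <- counts[seq.int(drop + 1L, drop + cfg$n_bins)]
  }
  P <- cwt_power_cpp(pad_series(counts, fb), fb$G)
  keep <- seq.int(fb$pad_left + 1L, fb$pad_left + cfg$n_bins)
  W <- (cfg$n_bins - 1L) %/% 2L
  structure(list(freqs = fb$freqs, lags = seq(-W, W) * cfg$bin_width,
                 power = P[, keep, drop = FALSE], config = cfg,
                 n_spikes = sum(counts)),
            class = "wavelet_power")
}

#' @export
print.wavelet_power <- function(x, ...) {
  cat(sprintf(paste0("Wavelet power plane: %d frequencies (%.3g-%.3g Hz) x %d",
                     " lags (+/-%g ms), n_spikes = %g\n"),
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$lags),
              max(x$lags) * 1e3, x$n_spikes))
  invisible(x)
}

#' @export
plot.wavelet_power <- function(x, ...) {
  graphics::image(x$lags * 1e3, log10(x$freqs), t(x$power),
                  xlab = "lag (ms)", ylab = "log10 frequency (Hz)",
                  main = "Wavelet power", ...)
  invisible(x)
}
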