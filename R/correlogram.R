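#' Cross-correlation histogram of two spike trains
#'
#' Counts spike pairs by their signed time difference `t_b - t_a` in bins of
#' width `bin_width` over lags `-window .. +window`. Bin centres sit at
#' integer multiples of `bin_width` (half-open bins), so the grid has
#' `2 * window / bin_width + 1` centres with the zero-lag bin in the middle.
#' Following the binary-state reading of the correlogram, each train
#' contributes at most one spike per time bin (clipping); at 50 µs bins this
#' is immaterial for realistic rates. Counts are unnormalized: the
#' Monte-Carlo significance test makes the result independent of
#' normalization.
#'
#' Positive lags mean the second train (`b`, neuron J) fires after the first
#' (`a`, neuron I); this sign convention is fixed throughout the package.
#'
#' @param a,b [spike_train()] objects (I and J).
#' @param bin_width Bin width in seconds (50 µs or 500 µs for the two
#'   analysis scales).
#' @param window Half-width of the lag window in seconds; must be a positive
#'   multiple of `bin_width`.
#' @param clip Logical; count at most one spike per bin per train (default
#'   `TRUE`).
#' @return An object of class `cch` with fields `pair`, `bin_width`,
#'   `window`, `lags`, `counts`, `n_spikes` (sum of counts) and
#'   `pair_distance` (µm, `NA` if either position is unknown).
#' @export
compute_cch <- function(a, b, bin_width, window, clip = TRUE) {
  stopifnot(inherits(a, "spike_train"), inherits(b, "spike_train"))
  if (!is_number(bin_width) || bin_width <= 0) stop("`bin_width` must be > 0")
  W <- window / bin_width
  if (!is_number(window) || window <= 0 || abs(W - round(W)) > 1e-6)
    stop("`window` must be a positive multiple of `bin_width`")
  W <- as.integer(round(W))
  # half-open bins [centre - bw/2, centre + bw/2): floor(t/bw + 1/2)
  ia <- floor(a$times / bin_width + 0.5)
  ib <- floor(b$times / bin_width + 0.5)
  if (clip) { ia <- unique(ia); ib <- unique(ib) }
  counts <- integer(2L * W + 1L)
  if (length(ia) && length(ib)) {
    lo <- findInterval(ia - W - 0.5, ib) + 1L
    hi <- findInterval(ia + W + 0.5, ib)
    lens <- pmax(hi - lo + 1L, 0L)
    if (sum(lens) > 0) {
      idx <- sequence(lens) + rep(lo - 1L, lens)
      d <- ib[idx] - rep(ia, lens)
      counts <- tabulate(d + W + 1L, nbins = 2L * W + 1L)
    }
  }
  dist <- NA_real_
  if (!is.null(a$position) && !is.null(b$position))
    dist <- sqrt(sum((a$position - b$position)^2))
  structure(list(pair = c(a$neuron_id, b$neuron_id),
                 bin_width = bin_width, window = window,
                 lags = seq(-W, W) * bin_width,
                 counts = as.numeric(counts),
                 n_spikes = sum(counts),
                 pair_distance = dist),
            class = "cch")
}

#' Construct a correlogram from raw bin counts
#'
#' Wraps an odd-length vector of lag-bin counts (centre bin at zero lag)
#' as a `cch` object, e.g. for correlograms computed elsewhere or for
#' analytic test signals.
#'
#' @param counts Numeric vector of non-negative bin counts, odd length.
#' @param bin_width Bin width in seconds.
#' @param pair Length-2 integer vector of neuron ids.
#' @param pair_distance Optional pair distance in µm.
#' @return A `cch` object (see [compute_cch()]).
#' @export
as_cch <- function(counts, bin_width, pair = c(1L, 2L),
                   pair_distance = NA_real_) {
  counts <- as.numeric(counts)
  if (length(counts) %% 2L != 1L) stop("`counts` must have odd length")
  if (any(!is.finite(counts) | counts < 0)) stop("counts must be >= 0")
  if (!is_number(bin_width) || bin_width <= 0) stop("`bin_width` must be > 0")
  W <- (length(counts) - 1L) %/% 2L
  structure(list(pair = as.integer(pair), bin_width = bin_width,
                 window = W * bin_width, lags = seq(-W, W) * bin_width,
                 counts = counts, n_spikes = sum(counts),
                 pair_distance = pair_distance),
            class = "cch")
}

#' @export
print.cch <- function(x, ...) {
  cat(sprintf("CCH pair (%d, %d): %d bins of %.0f us over +/-%g ms, %g pairs",
              x$pair[1], x$pair[2], length(x$counts), x$bin_width * 1e6,
              x$window * 1e3, x$n_spikes))
  if (is.finite(x$pair_distance))
    cat(sprintf(", distance %.0f um", x$pair_distance))
  cat("\n")
  invisible(x)
}

#' @export
plot.cch <- function(x, ...) {
  graphics::plot(x$lags * 1e3, x$counts, type = "s", xlab = "lag (ms)",
                 ylab = "count", main = sprintf("CCH (%d, %d)", x$pair[1],
                                                x$pair[2]), ...)
  invisible(x)
}

#' Interpolate the near-electrode sorting artifact
#'
#' When two units are closer than `max_distance_um` (default 180 µm, three
#' inter-electrode distances), spike-sorting cross-talk can carve a spurious
#' trough or ultra-sharp peak into the correlogram near zero lag. For such
#' pairs the central `+/-1 ms` segment is replaced by the straight line
#' joining the flank averages: the mean count over `[-1.5, -1.0] ms`
#' (anchored at -1.25 ms) and over `[+1.0, +1.5] ms` (anchored at +1.25 ms).
#' Pairs at or beyond the distance cut-off are returned unchanged.
#'
#' @param c A [compute_cch()] result with known `pair_distance`.
#' @param max_distance_um Distance gate in µm (default 180).
#' @return The (possibly) interpolated `cch`.
#' @export
interpolate_artifact <- function(c, max_distance_um = 180) {
  stopifnot(inherits(c, "cch"))
  if (!is.finite(c$pair_distance))
    stop("pair distance unknown; artifact interpolation needs positions")
  if (c$pair_distance >= max_distance_um) return(c)
  k1 <- as.integer(round(1e-3 / c$bin_width))
  k15 <- as.integer(round(1.5e-3 / c$bin_width))
  W <- (length(c$counts) - 1L) %/% 2L
  if (W < k15) stop("correlogram window too small to contain the +/-1.5 ms flanks")
  ctr <- W + 1L           # index of the zero-lag bin
  left <- mean(c$counts[ctr + (-k15:-k1)])
  right <- mean(c$counts[ctr + (k1:k15)])
  tau <- c$lags[ctr + (-k1:k1)]
  c$counts[ctr + (-k1:k1)] <- left + (right - left) * (tau + 1.25e-3) / 2.5e-3
  c$n_spikes <- sum(c$counts)
  c$interpolated <- TRUE
  c
}
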