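band_definitions <- function() {
  data.frame(band = c("HFC", "GFC", "BFC", "TFC"),
             scale = c(1L, 2L, 2L, 2L),
             lo = c(100, 30, 12, 4),
             hi = c(1000, 80, 30, 12))
}

#' Assign a frequency band
#'
#' Maps a peak frequency to its connectivity band at the given analysis
#' scale: high-frequency (HFC, 100–1000 Hz, scale 1), gamma (GFC, 30–80 Hz),
#' beta (BFC, 12–30 Hz) and theta (TFC, 4–12 Hz) on scale 2. Intervals are
#' half-open `[lo, hi)` (HFC closed at the 1000 Hz top) so band borders are
#' assigned uniquely; frequencies in covered-but-unbanded gaps (e.g.
#' 80–100 Hz of scale 2) return `NA`.
#'
#' @param freq Frequency in Hz (vectorized).
#' @param scale Analysis scale the frequency came from (1 or 2).
#' @return Character vector of band labels or `NA`.
#' @export
assign_band <- function(freq, scale = 1) {
  defs <- band_definitions()
  defs <- defs[defs$scale == as.integer(scale), , drop = FALSE]
  out <- rep(NA_character_, length(freq))
  for (r in seq_len(nrow(defs))) {
    inside <- freq >= defs$lo[r] &
      (freq < defs$hi[r] | (defs$band[r] == "HFC" & freq <= defs$hi[r]))
    out[inside] <- defs$band[r]
  }
  out
}

#' Classify a connection as delayed (directed) or non-delayed
#'
#' A wavelet-power peak is a delayed (unidirectional) connection when its
#' time offset exceeds one quarter of the full Fourier period of the wavelet
#' at the peak frequency (strictly; at that shift the primary peak of the
#' wavelet's real part no longer overlaps zero lag). Under the package's lag
#' convention (positive lag = J after I), a positive delay orients the edge
#' I -> J. Non-delayed peaks are treated as bidirectional.
#'
#' @param freq Peak frequency in Hz (> 0, vectorized).
#' @param delay Signed peak lag in seconds.
#' @return Data frame with logical `directed` and `orientation` in
#'   `"I->J"`, `"J->I"`, `"both"`.
#' @export
classify_direction <- function(freq, delay) {
  if (any(freq <= 0)) stop("`freq` must be > 0")
  directed <- abs(delay) > fourier_period(freq) / 4
  orientation <- ifelse(!directed, "both", ifelse(delay > 0, "I->J", "J->I"))
  data.frame(directed = directed, orientation = orientation)
}

#' Detect significant wavelet-power peaks
#'
#' Finds strict 8-neighbourhood local maxima of the power plane inside the
#' peak-identification window whose power exceeds the Monte-Carlo threshold
#' for the correlogram's spike count at that frequency. A correlogram can
#' yield several peaks at different frequencies and lags.
#'
#' @param p A [wavelet_power()] plane.
#' @param tbl A [calibrate_thresholds()] table on the same frequency grid.
#' @return Data frame with columns `freq`, `delay`, `power`, `threshold`,
#'   `ratio` (power/threshold), one row per significant peak.
#' @export
detect_peaks <- function(p, tbl) {
  stopifnot(inherits(p, "wavelet_power"), inherits(tbl, "threshold_table"))
  if (length(p$freqs) != length(tbl$freqs) ||
      max(abs(log(p$freqs) - log(tbl$freqs))) > 1e-8)
    stop("power plane and threshold table use different frequency grids")
  empty <- data.frame(freq = numeric(0), delay = numeric(0),
                      power = numeric(0), threshold = numeric(0),
                      ratio = numeric(0))
  if (p$n_spikes < 1) return(empty)
  thr <- lookup_threshold(tbl, p$n_spikes, p$freqs)
  P <- p$power
  nf <- nrow(P); nl <- ncol(P)
  # strict local maxima against the 8 surrounding points (interior only)
  ic <- 2:(nf - 1L); jc <- 2:(nl - 1L)
  C <- P[ic, jc, drop = FALSE]
  is_max <- C > P[ic - 1L, jc, drop = FALSE] & C > P[ic + 1L, jc, drop = FALSE] &
            C > P[ic, jc - 1L, drop = FALSE] & C > P[ic, jc + 1L, drop = FALSE] &
            C > P[ic - 1L, jc - 1L, drop = FALSE] & C > P[ic - 1L, jc + 1L, drop = FALSE] &
            C > P[ic + 1L, jc - 1L, drop = FALSE] & C > P[ic + 1L, jc + 1L, drop = FALSE]
  in_window <- abs(p$lags[jc]) <= p$config$peak_window + 1e-12
  is_max <- is_max & rep(in_window, each = length(ic))
  is_max <- is_max & (C > thr[ic])
  hits <- which(is_max, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(empty)
  fi <- ic[hits[, 1L]]; li <- jc[hits[, 2L]]
  out <- data.frame(freq = p$freqs[fi], delay = p$lags[li],
                    power = P[cbind(fi, li)], threshold = thr[fi])
  out$ratio <- out$power / out$threshold
  out[order(-out$ratio), , drop = FALSE]
}

# Reduce the peaks of one pair to at most one connection per band: within a
# band the pair is connected once, keeping the most significant peak.
peaks_to_connections <- function(peaks, pair, scale) {
  if (nrow(peaks) == 0L) return(NULL)
  peaks$band <- assign_band(peaks$freq, scale)
  peaks <- peaks[!is.na(peaks$band), , drop = FALSE]
  if (nrow(peaks) == 0L) return(NULL)
  best <- do.call(rbind, lapply(split(peaks, peaks$band), function(d) {
    d[which.max(d$ratio), , drop = FALSE]
  }))
  dir <- classify_direction(best$freq, best$delay)
  data.frame(i = pair[1L], j = pair[2L], band = best$band,
             freq_hz = best$freq, delay_s = best$delay, power = best$power,
             threshold = best$threshold, ratio = best$ratio,
             directed = dir$directed, orientation = dir$orientation,
             row.names = NULL)
}

#' Detect band-specific connections across all pairs of a recording
#'
#' Runs the full pairwise pipeline at one analysis scale: cross-correlogram
#' (with near-electrode artifact interpolation for pairs closer than
#' `interpolate_um`), wavelet power, Monte-Carlo significance, peak
#' detection, band assignment and direction classification. Each unordered
#' pair contributes at most one connection per band (the most significant
#' peak); a pair may carry connections in several bands.
#'
#' @param rec A [recording()].
#' @param tbl A [calibrate_thresholds()] table built for `cfg`.
#' @param cfg A [wavelet_config()]; its scale decides the candidate bands.
#' @param interpolate_um Distance gate for artifact interpolation (µm,
#'   default 180; `NA` disables it).
#' @param pairs Optional 2-column matrix of neuron-id pairs to restrict the
#'   scan (default: all unordered pairs).
#' @return Data frame of connections with columns `i`, `j`, `band`,
#'   `freq_hz`, `delay_s`, `power`, `threshold`, `ratio`, `directed`,
#'   `orientation`, with the node table attached as attribute `"nodes"`.
#' @export
detect_connections <- function(rec, tbl, cfg = wavelet_config(1),
                               interpolate_um = 180, pairs = NULL) {
  stopifnot(inherits(rec, "recording"), inherits(tbl, "threshold_table"))
  fb <- wavelet_filterbank(cfg)
  ids <- vapply(rec$trains, function(tr) tr$neuron_id, integer(1))
  if (is.null(pairs)) {
    if (length(ids) < 2) stop("need at least two neurons")
    pairs <- t(utils::combn(sort(ids), 2))
  }
  res <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    a <- rec$trains[[as.character(pairs[r, 1L])]]
    b <- rec$trains[[as.character(pairs[r, 2L])]]
    cc <- compute_cch(a, b, cfg$bin_width, cfg$transform_window)
    if (is.finite(interpolate_um) && is.finite(cc$pair_distance) &&
        cc$pair_distance < interpolate_um)
      cc <- interpolate_artifact(cc, interpolate_um)
    if (cc$n_spikes < 1) next
    pw <- wavelet_power(cc, cfg, fb = fb)
    res[[r]] <- peaks_to_connections(detect_peaks(pw, tbl), pairs[r, ], cfg$scale)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(i = integer(0), j = integer(0), band = character(0),
                      freq_hz = numeric(0), delay_s = numeric(0),
                      power = numeric(0), threshold = numeric(0),
                      ratio = numeric(0), directed = logical(0),
                      orientation = character(0))
  rownames(out) <- NULL
  attr(out, "nodes") <- neuron_positions(rec)
  attr(out, "scale") <- cfg$scale
  out
}

new_functional_network <- function(nodes, edges, band, density_target = NA_real_) {
  n <- nrow(nodes)
  npairs <- n * (n - 1) / 2
  structure(list(nodes = nodes, edges = edges, band = band,
                 density = if (npairs > 0) nrow(edges) / npairs else 0,
                 density_target = density_target),
            class = "functional_network")
}

#' Build a density-controlled band network
#'
#' Orders a band's connections by significance (the ratio of peak power to
#' threshold power, descending; ties broken lexicographically by pair id)
#' and retains connected pairs until the target connectivity density
#' `floor(density_target * n(n-1)/2)` is reached. If the supply runs out
#' first, the network is kept at its smaller achieved density. Edges are
#' binary thereafter; direction is an edge attribute, not a separate edge.
#'
#' @param connections Connection table from [detect_connections()] (or a
#'   compatible data frame).
#' @param band Band label to select (`"HFC"`, `"GFC"`, `"BFC"`, `"TFC"`).
#' @param density_target Target fraction of connected unordered pairs,
#'   in `(0, 1]`.
#' @param nodes Node table (`id`, `x`, `y`); defaults to the `"nodes"`
#'   attribute of `connections`.
#' @return An object of class `functional_network` with fields `nodes`,
#'   `edges`, `band`, `density` (achieved) and `density_target`.
#' @export
build_band_network <- function(connections, band, density_target = 0.01,
                               nodes = attr(connections, "nodes")) {
  if (!is_number(density_target) || density_target <= 0 || density_target > 1)
    stop("`density_target` must be in (0, 1]")
  if (is.null(nodes)) stop("`nodes` table required (id, x, y)")
  ed <- connections[connections$band == band, , drop = FALSE]
  ed <- ed[order(-ed$ratio, ed$i, ed$j), , drop = FALSE]
  n <- nrow(nodes)
  keep <- min(nrow(ed), floor(density_target * n * (n - 1) / 2))
  new_functional_network(nodes, ed[seq_len(keep), , drop = FALSE], band,
                         density_target)
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf(paste0("Functional network [%s]: %d nodes, %d edges ",
                     "(density %.4f%s)\n"),
              x$band, nrow(x$nodes), nrow(x$edges), x$density,
              if (is.finite(x$density_target))
                sprintf(", target %.4f", x$density_target) else ""))
  if (nrow(x$edges))
    cat(sprintf("  directed edges: %d of %d\n", sum(x$edges$directed),
                nrow(x$edges)))
  invisible(x)
}

#' @export
plot.functional_network <- function(x, ...) {
  graphics::plot(x$nodes$x, x$nodes$y, pch = 16, cex = 0.6, asp = 1,
                 xlab = "x (um)", ylab = "y (um)",
                 main = sprintf("%s network (density %.3f)", x$band, x$density),
                 ...)
  if (nrow(x$edges)) {
    ii <- match(x$edges$i, x$nodes$id); jj <- match(x$edges$j, x$nodes$id)
    graphics::segments(x$nodes$x[ii], x$nodes$y[ii], x$nodes$x[jj],
                       x$nodes$y[jj], col = grDevices::grey(0.4, 0.5))
  }
  invisible(x)
}

#' Achieved connectivity density of a network
#' @param net A `functional_network`.
#' @return Fraction of connected unordered pairs.
#' @export
network_density <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  net$density
}

#' Match connectivity density across bands
#'
#' When one band of a data set falls short of the target density, every
#' band's network is re-truncated (by significance order) to the minimum of
#' the target and the smallest achieved density, so that graph measures are
#' compared at equal density.
#'
#' @param networks List of `functional_network`s over the same node set.
#' @param density_target Common target density.
#' @return List of adjusted networks (same order).
#' @export
match_density_across_bands <- function(networks, density_target = 0.01) {
  stopifnot(length(networks) >= 1,
            all(vapply(networks, inherits, logical(1), "functional_network")))
  dmin <- min(density_target,
              vapply(networks, function(nw) nw$density, numeric(1)))
  lapply(networks, function(nw) {
    ed <- nw$edges[order(-nw$edges$ratio, nw$edges$i, nw$edges$j), ,
                   drop = FALSE]
    n <- nrow(nw$nodes)
    keep <- min(nrow(ed), floor(dmin * n * (n - 1) / 2))
    new_functional_network(nw$nodes, ed[seq_len(keep), , drop = FALSE],
                           nw$band, dmin)
  })
}

#' Jitter spike times (low-resolution simulation)
#'
#' Displaces every spike by independent Gaussian noise of SD `sigma`
#' (default 50 ms, emulating the temporal resolution of calcium imaging),
#' re-sorts, and clips to `[0, duration]`. Spike counts are conserved per
#' neuron up to ties created by clipping.
#'
#' @param rec A [recording()].
#' @param sigma Jitter SD in seconds (default 0.05).
#' @param seed Optional RNG seed.
#' @return The jittered [recording()].
#' @export
jitter_spikes <- function(rec, sigma = 0.05, seed = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (sigma < 0) stop("`sigma` must be >= 0")
  if (sigma == 0) return(rec)
  with_seed(seed, {
    rec$trains <- lapply(rec$trains, function(tr) {
      t <- tr$times + stats::rnorm(length(tr$times), 0, sigma)
      t <- sort(unique(pmin(pmax(t, 0), rec$duration)))
      spike_train(tr$neuron_id, t, position = tr$position)
    })
    rec
  })
}
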