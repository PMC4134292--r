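# Fixtures and independent oracles used across the suite. Oracles are kept
# deliberately naive (double loops, Floyd-Warshall, direct convolution sums)
# so they share no code path with the implementation they check.

make_cch <- function(counts, bin_width, pair = c(1L, 2L), distance = NA_real_) {
  W <- (length(counts) - 1L) %/% 2L
  structure(list(pair = pair, bin_width = bin_width, window = W * bin_width,
                 lags = seq(-W, W) * bin_width, counts = as.numeric(counts),
                 n_spikes = sum(counts), pair_distance = distance),
            class = "cch")
}

gaussian_cch <- function(cfg, sigma = 1e-3, center = 0) {
  W <- (cfg$n_bins - 1L) %/% 2L
  lags <- seq(-W, W) * cfg$bin_width
  make_cch(exp(-(lags - center)^2 / (2 * sigma^2)), cfg$bin_width)
}

# Small wavelet configuration (511 bins -> 512 padded) keeping oracle and
# Monte-Carlo runtimes short; frequencies chosen so the wavelet support is
# compact relative to the window.
small_cfg <- function(n_freq = 9) {
  wavelet_config(2, transform_window = 0.1275, peak_window = 0.05,
                 freq_lo = 40, freq_hi = 100, n_freq = n_freq)
}

# O(n^2) pair-counting correlogram oracle.
brute_cch <- function(ta, tb, bw, window, clip = TRUE) {
  ia <- floor(ta / bw + 0.5); ib <- floor(tb / bw + 0.5)
  if (clip) { ia <- unique(ia); ib <- unique(ib) }
  W <- as.integer(round(window / bw))
  counts <- integer(2L * W + 1L)
  for (x in ia) {
    d <- ib - x
    d <- d[abs(d) <= W]
    for (dd in d) counts[dd + W + 1L] <- counts[dd + W + 1L] + 1L
  }
  counts
}

# Direct-summation wavelet power oracle: termwise evaluation of the
# convolution of the edge-padded series with the sampled, normalized Morlet
# (periodic displacement, matching the transform's padded power-of-two
# domain). No FFT anywhere.
direct_cwt_power <- function(counts, cfg) {
  fb <- wavecch:::wavelet_filterbank(cfg)
  xp <- wavecch:::pad_series(counts, fb)
  M <- fb$M; dt <- cfg$bin_width
  P <- matrix(0, length(fb$freqs), cfg$n_bins)
  for (f in seq_along(fb$freqs)) {
    s <- fb$scales[f]
    for (jj in seq_len(cfg$n_bins)) {
      n <- fb$pad_left + jj
      d <- ((seq_len(M) - n) %% M)
      d <- ifelse(d > M / 2, d - M, d)
      w <- sum(xp * sqrt(dt / s) * Conj(morlet(d * dt / s, cfg$omega0)))
      P[f, jj] <- Mod(w)^2
    }
  }
  P
}

# First child seed a master seed expands to (mirrors the calibration's
# per-grid-point derivation).
derive_child_seed <- function(seed) wavecch:::derive_seeds(seed, 1)[[1]]

# Graph-measure oracles on an adjacency matrix / edge index matrix.
oracle_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- ifelse(A, 1, Inf); diag(D) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  inv <- 1 / D; diag(inv) <- 0; inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

oracle_clustering <- function(A) {
  n <- nrow(A); deg <- rowSums(A); loc <- numeric(0)
  for (v in seq_len(n)) {
    if (deg[v] < 2) next
    nb <- which(A[v, ]); cnt <- 0
    prs <- utils::combn(nb, 2)
    for (cc in seq_len(ncol(prs)))
      if (A[prs[1, cc], prs[2, cc]]) cnt <- cnt + 1
    loc <- c(loc, cnt / choose(deg[v], 2))
  }
  if (!length(loc)) NA_real_ else mean(loc)
}

oracle_assortativity <- function(edges, n) {
  if (nrow(edges) < 2) return(NA_real_)
  deg <- tabulate(c(edges), nbins = n)
  x <- c(deg[edges[, 1]], deg[edges[, 2]])
  y <- c(deg[edges[, 2]], deg[edges[, 1]])
  if (stats::sd(x) == 0) return(NA_real_)
  stats::cor(x, y)
}

edges_from_mask <- function(mask, n) {
  prs <- utils::combn(n, 2)
  e <- t(prs[, mask, drop = FALSE])
  attr(e, "n") <- n
  e
}

adj_from_edges <- function(e, n) {
  A <- matrix(FALSE, n, n)
  if (nrow(e)) { A[e] <- TRUE; A[e[, 2:1, drop = FALSE]] <- TRUE }
  A
}

# Wrap an edge data frame + ids into a minimal functional_network for the
# metric functions (ratios descending in input order).
toy_network <- function(n, edges, band = "HFC", directed = NULL,
                        orientation = NULL, pos = NULL) {
  if (is.null(pos)) pos <- cbind(x = seq_len(n) * 100, y = 0)
  nodes <- data.frame(id = seq_len(n), x = pos[, 1], y = pos[, 2])
  m <- nrow(edges)
  ed <- data.frame(i = as.integer(edges[, 1]), j = as.integer(edges[, 2]),
                   band = rep(band, m), freq_hz = rep(500, m),
                   delay_s = rep(0, m), power = rep(2, m),
                   threshold = rep(1, m),
                   ratio = if (m) seq(2, 1.01, length.out = m) else numeric(0),
                   directed = if (is.null(directed)) rep(FALSE, m) else directed,
                   orientation = if (is.null(orientation)) rep("both", m)
                                 else orientation)
  wavecch:::new_functional_network(nodes, ed, band)
}
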