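# A constant threshold table over a config's frequency grid, for driving the
# peak detector with hand-built power planes.
flat_table <- function(cfg, level) {
  structure(list(log10_counts = c(0, 6), freqs = wavelet_freqs(cfg),
                 thresholds = matrix(level, 2, cfg$n_freq),
                 p_level = 0.001, n_reps = 1e5L, seed = NA_integer_,
                 config = cfg),
            class = "threshold_table")
}

fake_power <- function(cfg, power) {
  W <- (cfg$n_bins - 1L) %/% 2L
  structure(list(freqs = wavelet_freqs(cfg), lags = seq(-W, W) * cfg$bin_width,
                 power = power, config = cfg, n_spikes = 100),
            class = "wavelet_power")
}

plane_with_bumps <- function(cfg, bumps, base = 0.1) {
  f <- log(wavelet_freqs(cfg))
  W <- (cfg$n_bins - 1L) %/% 2L
  lag <- seq(-W, W) * cfg$bin_width
  P <- matrix(base, cfg$n_freq, cfg$n_bins)
  for (b in bumps) {
    df <- outer((f - log(b$freq)) / 0.15, rep(1, length(lag)))
    dl <- outer(rep(1, length(f)), (lag - b$lag) / 5e-3)
    P <- P + b$amp * exp(-(df^2 + dl^2) / 2)
  }
  P
}

test_that("peak detection returns strict 8-neighbour maxima above threshold", {
  cfg <- wavelet_config(2)
  tbl <- flat_table(cfg, level = 1)

  below <- fake_power(cfg, plane_with_bumps(cfg, list(
    list(freq = 40, lag = 0, amp = 0.5))))
  expect_equal(nrow(detect_peaks(below, tbl)), 0L)

  one <- fake_power(cfg, plane_with_bumps(cfg, list(
    list(freq = 40, lag = 0, amp = 10))))
  pk <- detect_peaks(one, tbl)
  expect_equal(nrow(pk), 1L)
  ix <- which(one$power == max(one$power), arr.ind = TRUE)
  expect_equal(pk$freq, one$freqs[ix[1]])
  expect_equal(pk$delay, one$lags[ix[2]])
  expect_equal(pk$ratio, pk$power / pk$threshold)

  two <- fake_power(cfg, plane_with_bumps(cfg, list(
    list(freq = 40, lag = 0, amp = 10),
    list(freq = 20, lag = 0.05, amp = 8))))
  pk2 <- detect_peaks(two, tbl)
  expect_equal(nrow(pk2), 2L)
  # each detected peak sits within one grid bin of an injected bump
  step <- log10(two$freqs[2] / two$freqs[1])
  expect_true(all(vapply(pk2$freq, function(f)
    min(abs(log10(f / c(40, 20)))) < 1.5 * step, logical(1))))
})

test_that("peaks outside the peak-identification window are ignored", {
  cfg <- wavelet_config(2)
  tbl <- flat_table(cfg, 1)
  outside <- fake_power(cfg, plane_with_bumps(cfg, list(
    list(freq = 40, lag = 0.5, amp = 10))))   # 500 ms >> 200 ms window
  expect_equal(nrow(detect_peaks(outside, tbl)), 0L)
})

test_that("direction rule is a strict quarter-period threshold", {
  # delay zero is non-delayed
  expect_false(classify_direction(40, 0)$directed)
  expect_equal(classify_direction(40, 0)$orientation, "both")
  # exactly a quarter period stays non-delayed ("more than" is strict)
  qp <- fourier_period(40) / 4
  expect_false(classify_direction(40, qp)$directed)
  expect_true(classify_direction(40, qp * 1.001)$directed)
  expect_equal(classify_direction(40, qp * 1.001)$orientation, "I->J")
  expect_equal(classify_direction(40, -qp * 1.001)$orientation, "J->I")
})

test_that("a Gaussian peak offset by 3 sigma is classified as directed", {
  # full machinery: the best-matching wavelet has T ~ 8.6 sigma, so the
  # direction threshold sits at ~2.15 sigma and 3 sigma exceeds it
  cfg <- wavelet_config(1)
  cc <- gaussian_cch(cfg, sigma = 1e-3, center = 3e-3)
  pw <- wavelet_power(cc, cfg)
  in_window <- abs(pw$lags) <= cfg$peak_window
  Pw <- pw$power[, in_window]
  ix <- which(Pw == max(Pw), arr.ind = TRUE)
  fstar <- pw$freqs[ix[1]]
  delay <- pw$lags[in_window][ix[2]]
  expect_equal(delay, 3e-3, tolerance = 1e-3)
  cls <- classify_direction(fstar, delay)
  expect_true(cls$directed)
  # and the threshold offset itself is ~2.2 sigma
  expect_equal(fourier_period(fstar) / 4 / 1e-3, 2.2, tolerance = 0.1)
})

test_that("band assignment follows the half-open band table", {
  expect_equal(assign_band(500, 1), "HFC")
  expect_equal(assign_band(100, 1), "HFC")
  expect_equal(assign_band(1000, 1), "HFC")   # top border closed
  expect_true(is.na(assign_band(99, 1)))      # scale-1 gap below HFC
  expect_equal(assign_band(40, 2), "GFC")
  expect_equal(assign_band(30, 2), "GFC")     # beta/gamma border -> gamma
  expect_equal(assign_band(20, 2), "BFC")
  expect_equal(assign_band(12, 2), "BFC")     # theta/beta border -> beta
  expect_equal(assign_band(9, 2), "TFC")      # the ~9 Hz cortical theta peak
  expect_true(is.na(assign_band(90, 2)))      # 80-100 Hz gap
  expect_true(is.na(assign_band(2, 2)))
})

test_that("band networks are truncated by significance with stable ties", {
  nodes <- data.frame(id = 1:100, x = runif(100, 0, 900),
                      y = runif(100, 0, 1900))
  set.seed(7)
  conn <- data.frame(i = rep(1:20, each = 5), j = rep(21:25, 20),
                     band = "HFC", freq_hz = 500, delay_s = 1e-3,
                     power = 2, threshold = 1, ratio = 2,
                     directed = TRUE, orientation = "I->J")
  conn$ratio <- c(rep(3, 10), rep(2, 90))   # heavy ties
  net <- build_band_network(conn, "HFC", density_target = 0.01, nodes = nodes)
  expect_lte(nrow(net$edges), floor(0.01 * 100 * 99 / 2))  # <= 49 pairs
  net2 <- build_band_network(conn, "HFC", density_target = 0.01, nodes = nodes)
  expect_identical(net$edges, net2$edges)   # deterministic under ties

  # raising the target never removes an edge (monotone truncation)
  net_hi <- build_band_network(conn, "HFC", density_target = 0.02,
                               nodes = nodes)
  key <- function(e) paste(e$i, e$j)
  expect_true(all(key(net$edges) %in% key(net_hi$edges)))

  # target above supply keeps everything and reports the smaller density
  small <- conn[1:5, ]
  net3 <- build_band_network(small, "HFC", density_target = 0.5, nodes = nodes)
  expect_equal(nrow(net3$edges), 5L)
  expect_lt(net3$density, 0.5)
})

test_that("densities are matched to the sparsest band", {
  nodes <- data.frame(id = 1:50, x = runif(50), y = runif(50))
  npairs <- 50 * 49 / 2
  mk <- function(m, band) {
    conn <- data.frame(i = rep(1, m), j = 2:(m + 1), band = band,
                       freq_hz = 40, delay_s = 0, power = 2, threshold = 1,
                       ratio = seq(3, 2, length.out = m), directed = FALSE,
                       orientation = "both")
    build_band_network(conn, band, density_target = 0.02, nodes = nodes)
  }
  nets <- list(mk(floor(0.02 * npairs), "HFC"),
               mk(floor(0.015 * npairs), "GFC"),
               mk(floor(0.007 * npairs), "BFC"))
  adj <- match_density_across_bands(nets, density_target = 0.02)
  dens <- vapply(adj, network_density, numeric(1))
  expect_equal(dens, rep(floor(0.007 * npairs) / npairs, 3), tolerance = 1e-9)

  # all bands at or above target: everyone sits exactly at target
  nets2 <- list(mk(floor(0.02 * npairs), "HFC"), mk(floor(0.02 * npairs), "GFC"))
  adj2 <- match_density_across_bands(nets2, density_target = 0.01)
  expect_equal(vapply(adj2, network_density, numeric(1)),
               rep(floor(0.01 * npairs) / npairs, 2))

  # single band: unchanged
  one <- mk(20, "HFC")
  expect_equal(match_density_across_bands(list(one), 0.02)[[1]]$density,
               one$density)
})

test_that("jitter preserves spike counts and zero sigma is the identity", {
  rec <- generate_population(5, 100, seed = 55)
  expect_identical(jitter_spikes(rec, sigma = 0), rec)
  j <- jitter_spikes(rec, sigma = 0.005, seed = 56)
  for (k in names(rec$trains))
    expect_equal(length(j$trains[[k]]$times), length(rec$trains[[k]]$times))
  expect_true(all(unlist(lapply(j$trains, `[[`, "times")) <= rec$duration))
  expect_identical(jitter_spikes(rec, 0.005, seed = 56), j)
})

test_that("every retained connection is re-checkably significant", {
  # end-to-end on a small coupled population
  rec <- generate_population(6, 600, rate_log10_mean = log10(3),
                             rate_log10_sd = 0.1, seed = 61)
  rec <- inject_synaptic(rec, 1, 2, delay_ms = 3, jitter_ms = 0.3,
                         efficacy = 0.8, seed = 62)$recording
  cfg <- wavelet_config(1, n_freq = 31)   # coarser grid keeps this test quick
  tbl <- calibrate_thresholds(cfg, n_reps = 500, p_level = 0.01, seed = 63,
                              log10_counts = seq(0.5, 3.5, 0.5))
  conn <- detect_connections(rec, tbl, cfg)
  expect_true(all(conn$power > conn$threshold))
  expect_true(all(conn$ratio > 1))
  expect_true(all(conn$band %in% c("HFC")))
  # the injected pair is found and correctly oriented
  hit <- conn[conn$i == 1 & conn$j == 2, ]
  expect_gte(nrow(hit), 1L)
  expect_equal(hit$orientation[1], "I->J")
  expect_true(abs(hit$delay_s[1] - 3e-3) < 1.5e-3)
})
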