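#' Hexagonal-lattice electrode positions
#'
#' Generates candidate unit positions on a hexagonal lattice with the array
#' geometry of a 512-electrode recording system: 60 µm pitch inside a
#' 0.9 mm x 1.9 mm rectangle. A small uniform scatter (< 30 µm) is added so
#' that inter-neuron distances populate distinct 50 µm bins.
#'
#' @param n Number of positions required (sampled without replacement from
#'   the lattice sites).
#' @param pitch_um Lattice pitch in µm (default 60).
#' @param width_um,height_um Array extent in µm (defaults 900 x 1900).
#' @param scatter_um Half-width of the uniform positional scatter (default 15).
#' @param seed Optional RNG seed.
#' @return An `n` x 2 matrix of (x, y) positions in µm.
#' @export
hex_positions <- function(n, pitch_um = 60, width_um = 900, height_um = 1900,
                          scatter_um = 15, seed = NULL) {
  row_step <- pitch_um * sqrt(3) / 2
  rows <- seq(0, height_um, by = row_step)
  sites <- do.call(rbind, lapply(seq_along(rows), function(r) {
    off <- if (r %% 2 == 0) pitch_um / 2 else 0
    xs <- seq(off, width_um, by = pitch_um)
    cbind(xs, rows[r])
  }))
  if (n > nrow(sites))
    stop("requested ", n, " positions but the lattice has only ", nrow(sites))
  with_seed(seed, {
    pick <- sites[sample.int(nrow(sites), n), , drop = FALSE]
    pick + matrix(stats::runif(2L * n, -scatter_um, scatter_um), n, 2)
  })
}

#' Generate a synthetic spike population
#'
#' Independent homogeneous Poisson spike trains with firing rates drawn from
#' a base-10 lognormal distribution; the defaults reproduce the cortical rate
#' statistics of organotypic slice recordings (10^(-0.16 +/- 0.64) Hz).
#' Positions are placed on a hexagonal 60 µm lattice spanning 0.9 x 1.9 mm.
#' Optionally, population-wide "network burst" epochs multiply every unit's
#' rate by a common factor.
#'
#' @param n_neurons Number of units (>= 2).
#' @param duration Recording duration in seconds (> 0).
#' @param rate_log10_mean,rate_log10_sd Mean and SD of log10(rate/Hz)
#'   (defaults -0.16 and 0.64).
#' @param seed Optional RNG seed; identical seeds give identical recordings.
#' @param region_label Label stored on the recording.
#' @param bursts Optional list `list(rate_hz =, duration_s =, multiplier =)`
#'   describing Poisson-timed population bursts; `NULL` (default) disables
#'   them.
#' @return A [recording()].
#' @export
generate_population <- function(n_neurons, duration,
                                rate_log10_mean = -0.16, rate_log10_sd = 0.64,
                                seed = NULL, region_label = "synthetic",
                                bursts = NULL) {
  if (!is_count(n_neurons) || n_neurons < 2) stop("`n_neurons` must be >= 2")
  if (!is_number(duration) || duration <= 0) stop("`duration` must be > 0")
  if (rate_log10_sd < 0) stop("`rate_log10_sd` must be >= 0")
  with_seed(seed, {
    rates <- 10^stats::rnorm(n_neurons, rate_log10_mean, rate_log10_sd)
    pos <- hex_positions(n_neurons)
    env <- burst_envelope(duration, bursts)
    trains <- lapply(seq_len(n_neurons), function(i) {
      times <- poisson_train(rates[i], duration, env)
      spike_train(i, times, position = pos[i, ])
    })
    recording(trains, duration, region_label)
  })
}

# Piecewise-constant rate envelope for optional network bursts.
burst_envelope <- function(duration, bursts) {
  if (is.null(bursts)) return(NULL)
  stopifnot(is.list(bursts), bursts$multiplier >= 1)
  n_ev <- stats::rpois(1L, bursts$rate_hz * duration)
  starts <- sort(stats::runif(n_ev, 0, duration))
  list(starts = starts, len = bursts$duration_s, mult = bursts$multiplier)
}

poisson_train <- function(rate, duration, env = NULL) {
  peak <- if (is.null(env)) rate else rate * env$mult
  n <- stats::rpois(1L, peak * duration)
  t <- sort(stats::runif(n, 0, duration))
  if (!is.null(env) && length(t)) {
    in_burst <- vapply(t, function(x) any(x >= env$starts & x < env$starts + env$len),
                       logical(1))
    p_keep <- ifelse(in_burst, 1, 1 / env$mult)
    t <- t[stats::runif(length(t)) < p_keep]
  }
  unique(t)
}

empty_ground_truth <- function() {
  data.frame(source = integer(0), target = integer(0),
             mechanism = character(0), delay_ms = numeric(0),
             strength = numeric(0), freq_hz = numeric(0))
}

#' Inject a synaptic-like delayed coupling
#'
#' Each source spike elicits, with probability `efficacy`, an extra target
#' spike at the source time plus a fixed delay and Gaussian timing jitter.
#' This produces the short-latency offset cross-correlogram peak that is the
#' signature of high-frequency (putatively synaptic) connectivity.
#'
#' @param rec A [recording()].
#' @param source,target Neuron ids (must exist in `rec`, distinct).
#' @param delay_ms Synaptic delay in milliseconds (> 0).
#' @param jitter_ms Gaussian SD of the transmission jitter in ms (>= 0).
#' @param efficacy Per-spike transmission probability in `[0, 1]`.
#' @param seed Optional RNG seed.
#' @return `list(recording =, ground_truth =)`; the ground-truth table has
#'   columns `source`, `target`, `mechanism`, `delay_ms`, `strength`,
#'   `freq_hz`.
#' @export
inject_synaptic <- function(rec, source, target, delay_ms = 3, jitter_ms = 0.3,
                            efficacy = 0.5, seed = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (!is_number(efficacy) || efficacy < 0 || efficacy > 1)
    stop("`efficacy` must be in [0, 1]")
  if (!is_number(delay_ms) || delay_ms <= 0) stop("`delay_ms` must be > 0")
  if (jitter_ms < 0) stop("`jitter_ms` must be >= 0")
  skey <- as.character(as.integer(source)); tkey <- as.character(as.integer(target))
  if (!skey %in% names(rec$trains)) stop("unknown source id ", source)
  if (!tkey %in% names(rec$trains)) stop("unknown target id ", target)
  if (skey == tkey) stop("source and target must differ")
  gt <- data.frame(source = as.integer(source), target = as.integer(target),
                   mechanism = "synaptic", delay_ms = delay_ms,
                   strength = efficacy, freq_hz = NA_real_)
  if (efficacy == 0) return(list(recording = rec, ground_truth = gt))
  with_seed(seed, {
    src_t <- rec$trains[[skey]]$times
    fire <- stats::runif(length(src_t)) < efficacy
    extra <- src_t[fire] + delay_ms / 1000 +
      if (jitter_ms > 0) stats::rnorm(sum(fire), 0, jitter_ms / 1000) else 0
    extra <- extra[extra >= 0 & extra <= rec$duration]
    tt <- sort(unique(c(rec$trains[[tkey]]$times, extra)))
    rec$trains[[tkey]] <- spike_train(as.integer(target), tt,
                                      position = rec$trains[[tkey]]$position)
    list(recording = rec, ground_truth = gt)
  })
}

#' Inject an oscillatory common drive
#'
#' Regenerates the member trains as inhomogeneous Poisson processes sharing a
#' sinusoidal rate modulation at `freq_hz` with a random common phase, while
#' preserving each member's mean rate. Pairwise correlograms of members then
#' oscillate at `freq_hz` centred on zero lag, emulating rhythmic common
#' input (gamma/beta/theta-like) without simulating a field potential.
#'
#' @param rec A [recording()].
#' @param members Vector of neuron ids (>= 2) that share the drive.
#' @param freq_hz Modulation frequency in Hz (> 0).
#' @param modulation_depth Modulation depth in `[0, 1]`; 0 leaves the members
#'   statistically independent.
#' @param seed Optional RNG seed.
#' @return `list(recording =, ground_truth =)` with one ground-truth row per
#'   unordered member pair (`mechanism = "common_drive"`).
#' @export
inject_common_drive <- function(rec, members, freq_hz, modulation_depth = 0.9,
                                seed = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (!is_number(freq_hz) || freq_hz <= 0) stop("`freq_hz` must be > 0")
  if (modulation_depth < 0 || modulation_depth > 1)
    stop("`modulation_depth` must be in [0, 1]")
  keys <- as.character(as.integer(members))
  if (!all(keys %in% names(rec$trains)))
    stop("unknown member id(s): ",
         paste(members[!keys %in% names(rec$trains)], collapse = ", "))
  if (length(unique(keys)) < 2) stop("need at least two distinct members")
  with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    for (key in keys) {
      r0 <- length(rec$trains[[key]]$times) / rec$duration
      if (r0 <= 0) next
      peak <- r0 * (1 + modulation_depth)
      cand <- sort(stats::runif(stats::rpois(1L, peak * rec$duration), 0, rec$duration))
      accept <- stats::runif(length(cand)) <
        (1 + modulation_depth * sin(2 * pi * freq_hz * cand + phase)) /
        (1 + modulation_depth)
      rec$trains[[key]] <- spike_train(rec$trains[[key]]$neuron_id,
                                       unique(cand[accept]),
                                       position = rec$trains[[key]]$position)
    }
    prs <- utils::combn(sort(as.integer(members)), 2)
    gt <- data.frame(source = prs[1, ], target = prs[2, ],
                     mechanism = "common_drive", delay_ms = 0,
                     strength = modulation_depth, freq_hz = freq_hz)
    list(recording = rec, ground_truth = gt)
  })
}

#' Simulate a network wired by exponential distance decay
#'
#' Draws a binary functional network whose unordered pairs are connected
#' independently with probability `P(d) = A exp(-d / lambda) + C` of the
#' inter-neuron distance `d`. Edge significance ratios are random, so the
#' network can be re-truncated by density like a detected one. Used to
#' validate the distance-decay fit against a known wiring rule.
#'
#' @param nodes Data frame with columns `id`, `x`, `y` (µm), e.g. from
#'   [hex_positions()].
#' @param A Amplitude of the decaying component (probability).
#' @param lambda_um Decay length in µm (> 0).
#' @param C Distance-independent baseline probability.
#' @param band Band label for the resulting network (default `"HFC"`).
#' @param seed Optional RNG seed.
#' @return A `functional_network` (see [build_band_network()]).
#' @export
simulate_decay_network <- function(nodes, A = 0.05, lambda_um = 300, C = 0.002,
                                   band = "HFC", seed = NULL) {
  stopifnot(is.data.frame(nodes), all(c("id", "x", "y") %in% names(nodes)))
  if (lambda_um <= 0) stop("`lambda_um` must be > 0")
  with_seed(seed, {
    n <- nrow(nodes)
    prs <- utils::combn(n, 2)
    d <- sqrt((nodes$x[prs[1, ]] - nodes$x[prs[2, ]])^2 +
              (nodes$y[prs[1, ]] - nodes$y[prs[2, ]])^2)
    p <- pmin(pmax(A * exp(-d / lambda_um) + C, 0), 1)
    on <- stats::runif(length(p)) < p
    edges <- data.frame(i = nodes$id[prs[1, on]], j = nodes$id[prs[2, on]],
                        band = band, freq_hz = NA_real_, delay_s = 0,
                        power = NA_real_, threshold = NA_real_,
                        ratio = 1 + stats::runif(sum(on)),
                        directed = FALSE, orientation = "both")
    new_functional_network(nodes, edges, band)
  })
}
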