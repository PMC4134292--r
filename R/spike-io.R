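#' Construct a spike train
#'
#' A spike train is the list of spike times of one sorted unit, optionally
#' with the unit's estimated (x, y) position on the array in micrometres.
#' Times are stored in seconds and must be strictly increasing.
#'
#' @param neuron_id Integer unit identifier, unique within a recording.
#' @param times Numeric vector of spike times in seconds (sorted internally;
#'   exact duplicates are an error, since two spikes of one unit cannot share
#'   a time stamp).
#' @param position Optional numeric `c(x, y)` position in micrometres.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(neuron_id, times, position = NULL) {
  if (!is_count(neuron_id)) stop("`neuron_id` must be a single non-negative integer")
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times))) stop("spike times must be finite")
  if (any(times < 0)) stop("spike times must be non-negative")
  times <- sort(times)
  if (anyDuplicated(times)) stop("duplicate spike times in neuron ", neuron_id)
  if (!is.null(position)) {
    position <- as.numeric(position)
    if (length(position) != 2L || anyNA(position)) stop("`position` must be c(x, y)")
  }
  structure(list(neuron_id = as.integer(neuron_id), times = times,
                 position = position),
            class = "spike_train")
}

#' Construct a spike recording
#'
#' Bundles a set of spike trains with the recording duration and a free-text
#' region label (e.g. `"cortex"` or `"hippocampus"`).
#'
#' @param trains List of [spike_train()] objects with unique neuron ids.
#' @param duration Recording duration in seconds (> 0).
#' @param region_label Free-text label for the tissue/region.
#' @return An object of class `recording`.
#' @export
recording <- function(trains, duration, region_label = "") {
  if (!is_number(duration) || duration <= 0) stop("`duration` must be > 0")
  if (!is.list(trains)) stop("`trains` must be a list of spike_train objects")
  ok <- vapply(trains, inherits, logical(1), what = "spike_train")
  if (length(trains) && !all(ok)) stop("`trains` must contain spike_train objects")
  ids <- vapply(trains, function(tr) tr$neuron_id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate neuron ids in recording")
  for (tr in trains) {
    if (length(tr$times) && max(tr$times) > duration)
      stop("neuron ", tr$neuron_id, " has spike times beyond the recording duration")
  }
  names(trains) <- as.character(ids)
  structure(list(trains = trains, duration = as.numeric(duration),
                 region_label = as.character(region_label)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  n <- length(x$trains)
  nsp <- sum(vapply(x$trains, function(tr) length(tr$times), integer(1)))
  npos <- sum(vapply(x$trains, function(tr) !is.null(tr$position), logical(1)))
  cat("Spike recording", if (nzchar(x$region_label)) paste0("(", x$region_label, ")"),
      "\n  neurons:", n, " spikes:", nsp,
      " duration:", x$duration, "s\n  positions known for", npos, "neurons\n")
  invisible(x)
}

#' @export
summary.recording <- function(object, ...) {
  counts <- vapply(object$trains, function(tr) length(tr$times), integer(1))
  rates <- counts / object$duration
  out <- list(n_neurons = length(counts), duration = object$duration,
              region_label = object$region_label,
              rate_hz = summary(rates),
              log10_rate_mean = mean(log10(rates[rates > 0])),
              log10_rate_sd = stats::sd(log10(rates[rates > 0])))
  class(out) <- "summary.recording"
  out
}

#' @export
print.summary.recording <- function(x, ...) {
  cat("Recording summary:", x$n_neurons, "neurons over", x$duration, "s",
      if (nzchar(x$region_label)) paste0("(", x$region_label, ")"), "\n")
  cat("  firing rate (Hz): "); print(x$rate_hz)
  cat(sprintf("  log10 rate: mean %.3f, sd %.3f (non-silent units)\n",
              x$log10_rate_mean, x$log10_rate_sd))
  invisible(x)
}

#' Number of neurons in a recording
#' @param rec A [recording()].
#' @return Integer count of spike trains.
#' @export
n_neurons <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  length(rec$trains)
}

#' Neuron positions as a data frame
#'
#' @param rec A [recording()].
#' @return Data frame with columns `id`, `x`, `y` (µm); `NA` coordinates for
#'   neurons without a known position.
#' @export
neuron_positions <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  ids <- vapply(rec$trains, function(tr) tr$neuron_id, integer(1))
  xy <- t(vapply(rec$trains, function(tr) {
    if (is.null(tr$position)) c(NA_real_, NA_real_) else tr$position
  }, numeric(2)))
  data.frame(id = ids, x = xy[, 1], y = xy[, 2], row.names = NULL)
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return(",")
  if (grepl("\t", first)) "\t" else ","
}

read_numeric_table <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_sep(path)
  dat <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                      strip.white = TRUE, comment.char = ""),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  if (nrow(dat) == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0, length(columns)))
    names(out) <- columns
    return(out)
  }
  if (ncol(dat) < length(columns))
    stop("file ", path, " has ", ncol(dat), " columns; expected ",
         paste(columns, collapse = ", "))
  dat <- dat[seq_along(columns)]
  names(dat) <- columns
  for (cn in columns) {
    v <- suppressWarnings(as.numeric(dat[[cn]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("malformed value in column '", cn, "' of ", path,
           " at line ", bad[1] + 1L, " (counting the header)")
    dat[[cn]] <- v
  }
  dat
}

#' Read a spike recording from delimited-text files
#'
#' Spike files have a header row and columns `neuron_id`, `time_s`; position
#' files have columns `neuron_id`, `x_um`, `y_um`. Comma- or tab-delimited
#' files are accepted (detected from the header line). Spike times are sorted
#' per neuron. Neurons present in the spike file but absent from the position
#' file are kept with an unknown (flagged `NA`) position.
#'
#' @param spike_file Path to the spike file.
#' @param position_file Optional path to the position file.
#' @param duration Recording duration in seconds; all spike times must lie in
#'   `[0, duration]`.
#' @param region_label Free-text label attached to the recording.
#' @return A [recording()].
#' @export
read_spikes <- function(spike_file, position_file = NULL, duration,
                        region_label = "") {
  if (!is_number(duration) || duration <= 0) stop("`duration` must be > 0")
  sp <- read_numeric_table(spike_file, c("neuron_id", "time_s"))
  if (nrow(sp) && any(sp$time_s < 0 | sp$time_s > duration))
    stop("spike times outside [0, duration] in ", spike_file)
  pos <- NULL
  if (!is.null(position_file))
    pos <- read_numeric_table(position_file, c("neuron_id", "x_um", "y_um"))
  ids <- sort(unique(as.integer(sp$neuron_id)))
  trains <- lapply(ids, function(id) {
    p <- NULL
    if (!is.null(pos)) {
      hit <- which(as.integer(pos$neuron_id) == id)
      if (length(hit)) p <- c(pos$x_um[hit[1]], pos$y_um[hit[1]])
    }
    spike_train(id, sp$time_s[as.integer(sp$neuron_id) == id], position = p)
  })
  recording(trains, duration, region_label)
}

#' Write a spike recording to delimited-text files
#'
#' Mirrors the input format of [read_spikes()] (comma-delimited with header).
#'
#' @param rec A [recording()].
#' @param spike_file Output path for the spike table.
#' @param position_file Optional output path for the position table (neurons
#'   without positions are omitted from it).
#' @return `rec`, invisibly.
#' @export
write_spikes <- function(rec, spike_file, position_file = NULL) {
  stopifnot(inherits(rec, "recording"))
  ids <- rep(vapply(rec$trains, function(tr) tr$neuron_id, integer(1)),
             vapply(rec$trains, function(tr) length(tr$times), integer(1)))
  times <- unlist(lapply(rec$trains, function(tr) tr$times), use.names = FALSE)
  if (is.null(times)) times <- numeric(0)
  utils::write.csv(data.frame(neuron_id = ids, time_s = times),
                   spike_file, row.names = FALSE, quote = FALSE)
  if (!is.null(position_file)) {
    pos <- neuron_positions(rec)
    pos <- pos[is.finite(pos$x), , drop = FALSE]
    names(pos) <- c("neuron_id", "x_um", "y_um")
    utils::write.csv(pos, position_file, row.names = FALSE, quote = FALSE)
  }
  invisible(rec)
}

#' Exclude low-rate units
#'
#' Drops spike trains firing fewer than `min_spikes_per_hour` spikes per hour;
#' the boundary is kept (the exclusion is strictly "less than").
#'
#' @param rec A [recording()].
#' @param min_spikes_per_hour Rate threshold (default 100 spikes/hour).
#' @return The filtered [recording()].
#' @export
filter_low_rate <- function(rec, min_spikes_per_hour = 100) {
  stopifnot(inherits(rec, "recording"))
  hours <- rec$duration / 3600
  keep <- vapply(rec$trains, function(tr) {
    length(tr$times) / hours >= min_spikes_per_hour
  }, logical(1))
  recording(rec$trains[keep], rec$duration, rec$region_label)
}

#' Check the minimum-population rule
#'
#' Networks are only analysed for tissues with at least `min_neurons` sorted
#' units; smaller populations are excluded.
#'
#' @param rec A [recording()].
#' @param min_neurons Minimum population size (default 100).
#' @return `TRUE` iff the recording has at least `min_neurons` neurons.
#' @export
require_min_population <- function(rec, min_neurons = 100) {
  stopifnot(inherits(rec, "recording"))
  n_neurons(rec) >= min_neurons
}
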