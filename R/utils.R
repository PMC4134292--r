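#' @useDynLib wavecch, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Run code under a given seed without disturbing the caller's RNG stream.
# seed = NULL means "use the current stream" (non-reproducible call).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive k reproducible child seeds from one master seed, so that stages of a
# pipeline (or grid points of a calibration) are order-independent.
derive_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  as.list(with_seed(seed, sample.int(.Machine$integer.max, k)))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && abs(x - round(x)) < 1e-8
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
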