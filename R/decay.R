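#' Fit the exponential distance decay of connection probability
#'
#' Counts unordered neuron pairs as a function of inter-neuron distance in
#' `bin_width_um` bins, computes the probability of observing a connected
#' pair per bin for each network, averages over networks (mean and SEM per
#' bin), and fits `P(d) = A exp(-d / lambda) + C` by least squares.
#' Confidence intervals come from the fit covariance (Wald, 95%).
#'
#' @param nets A `functional_network` or list of them with known node
#'   positions.
#' @param bin_width_um Distance bin width in µm (default 50).
#' @param min_pairs Minimum pair count for a bin to enter the fit
#'   (default 1).
#' @return An object of class `decay_fit` with `coefficients` (`A`,
#'   `lambda`, `C`), `ci` (95% intervals), the binned `data`, the underlying
#'   `nls` fit and a `converged` flag. Methods: `print`, `summary`, `coef`,
#'   `confint`, `predict`, `plot`.
#' @export
fit_decay <- function(nets, bin_width_um = 50, min_pairs = 1) {
  if (inherits(nets, "functional_network")) nets <- list(nets)
  stopifnot(length(nets) >= 1,
            all(vapply(nets, inherits, logical(1), "functional_network")))
  per_net <- lapply(nets, function(nw) {
    if (!all(is.finite(nw$nodes$x))) stop("node positions required")
    n <- nrow(nw$nodes)
    prs <- utils::combn(n, 2)
    d <- sqrt((nw$nodes$x[prs[1, ]] - nw$nodes$x[prs[2, ]])^2 +
              (nw$nodes$y[prs[1, ]] - nw$nodes$y[prs[2, ]])^2)
    bin <- floor(d / bin_width_um)
    conn <- rep(FALSE, ncol(prs))
    if (nrow(nw$edges)) {
      key <- paste(pmin(prs[1, ], prs[2, ]), pmax(prs[1, ], prs[2, ]))
      ekey <- paste(pmin(match(nw$edges$i, nw$nodes$id),
                         match(nw$edges$j, nw$nodes$id)),
                    pmax(match(nw$edges$i, nw$nodes$id),
                         match(nw$edges$j, nw$nodes$id)))
      conn <- key %in% ekey
    }
    data.frame(bin = bin, conn = conn)
  })
  max_bin <- max(vapply(per_net, function(d) max(d$bin), numeric(1)))
  bins <- 0:max_bin
  prob <- sapply(per_net, function(d) {
    npair <- tabulate(d$bin + 1L, nbins = max_bin + 1L)
    nconn <- tabulate(d$bin[d$conn] + 1L, nbins = max_bin + 1L)
    ifelse(npair >= min_pairs, nconn / npair, NA_real_)
  })
  prob <- matrix(prob, nrow = max_bin + 1L)
  n_obs <- rowSums(is.finite(prob))
  p_mean <- ifelse(n_obs > 0, rowMeans(prob, na.rm = TRUE), NA_real_)
  p_sem <- apply(prob, 1L, function(x) {
    x <- x[is.finite(x)]
    if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  })
  dat <- data.frame(d = (bins + 0.5) * bin_width_um, p = p_mean, sem = p_sem,
                    n_networks = n_obs)
  dat <- dat[is.finite(dat$p), , drop = FALSE]
  if (nrow(dat) < 4) stop("need at least 4 populated distance bins")
  start <- list(A = max(dat$p) - min(dat$p) + 1e-4,
                lambda = diff(range(dat$d)) / 3, C = min(dat$p))
  fit <- tryCatch(
    minpack.lm::nlsLM(p ~ A * exp(-d / lambda) + C, data = dat, start = start,
                      lower = c(A = 0, lambda = 1e-3, C = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(coefficients = c(A = NA_real_, lambda = NA_real_, C = NA_real_),
                ci = NULL, data = dat, fit = NULL, converged = FALSE,
                message = conditionMessage(fit))
    class(out) <- "decay_fit"
    return(out)
  }
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  tq <- stats::qt(0.975, stats::df.residual(fit))
  ci <- cbind(lower = est - tq * se, upper = est + tq * se)
  out <- list(coefficients = est, ci = ci, se = se, data = dat, fit = fit,
              converged = TRUE, message = "converged")
  class(out) <- "decay_fit"
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Exponential distance-decay fit: P(d) = A exp(-d / lambda) + C\n")
  if (!x$converged) {
    cat("  fit did not converge:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  A      = %.4g  [%.4g, %.4g]\n", x$coefficients["A"],
              x$ci["A", 1], x$ci["A", 2]))
  cat(sprintf("  lambda = %.4g um  [%.4g, %.4g]\n", x$coefficients["lambda"],
              x$ci["lambda", 1], x$ci["lambda", 2]))
  cat(sprintf("  C      = %.4g  [%.4g, %.4g]\n", x$coefficients["C"],
              x$ci["C", 1], x$ci["C", 2]))
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  if (object$converged) print(summary(object$fit)) else print(object)
  invisible(object)
}

#' @export
coef.decay_fit <- function(object, ...) object$coefficients

#' @export
confint.decay_fit <- function(object, parm, level = 0.95, ...) {
  if (!object$converged) stop("fit did not converge")
  est <- object$coefficients
  tq <- stats::qt(1 - (1 - level) / 2, stats::df.residual(object$fit))
  ci <- cbind(est - tq * object$se, est + tq * object$se)
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("fit did not converge")
  d <- if (is.null(newdata)) object$data$d else newdata$d
  cf <- object$coefficients
  cf["A"] * exp(-d / cf["lambda"]) + cf["C"]
}

#' @export
plot.decay_fit <- function(x, ...) {
  graphics::plot(x$data$d, x$data$p, pch = 16, xlab = "distance (um)",
                 ylab = "connection probability", main = "Distance decay", ...)
  if (!is.null(x$data$sem) && any(is.finite(x$data$sem)))
    graphics::arrows(x$data$d, x$data$p - x$data$sem, x$data$d,
                     x$data$p + x$data$sem, angle = 90, code = 3,
                     length = 0.02)
  if (x$converged) {
    dd <- seq(min(x$data$d), max(x$data$d), length.out = 200)
    graphics::lines(dd, predict(x, data.frame(d = dd)), col = 2, lwd = 2)
  }
  invisible(x)
}
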