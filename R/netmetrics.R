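# Internal: undirected edge index matrix (m x 2, 1-based node indices) of a
# functional_network, or pass-through for a plain matrix plus node count.
edge_index <- function(net) {
  if (inherits(net, "functional_network")) {
    if (nrow(net$edges) == 0L)
      return(list(edges = matrix(integer(0), 0, 2), n = nrow(net$nodes)))
    list(edges = cbind(match(net$edges$i, net$nodes$id),
                       match(net$edges$j, net$nodes$id)),
         n = nrow(net$nodes))
  } else if (is.matrix(net)) {
    n <- attr(net, "n")
    if (is.null(n)) n <- if (length(net)) max(net) else 0L
    list(edges = net, n = as.integer(n))
  } else stop("expected a functional_network or an edge index matrix")
}

adjacency_from_edges <- function(e, n) {
  A <- matrix(FALSE, n, n)
  if (nrow(e)) {
    A[e] <- TRUE
    A[e[, 2:1, drop = FALSE]] <- TRUE
  }
  diag(A) <- FALSE
  A
}

#' Global clustering coefficient
#'
#' Mean of the local clustering coefficients over nodes with at least two
#' neighbours; the local coefficient of a node is the fraction of realized
#' links among its neighbours. Connections are treated as undirected pairs.
#' Returns `NA` (undefined) when no node has two neighbours.
#'
#' @param net A `functional_network`, or an m x 2 edge index matrix with
#'   attribute `n` (node count).
#' @return Value in `[0, 1]`, or `NA`.
#' @export
clustering_global <- function(net) {
  ei <- edge_index(net)
  A <- adjacency_from_edges(ei$edges, ei$n)
  deg <- rowSums(A)
  elig <- which(deg >= 2)
  if (!length(elig)) return(NA_real_)
  local <- vapply(elig, function(v) {
    nb <- which(A[v, ])
    sum(A[nb, nb, drop = FALSE]) / (deg[v] * (deg[v] - 1))
  }, numeric(1))
  mean(local)
}

#' Network efficiency
#'
#' Mean over ordered node pairs of the inverse shortest path length (in
#' hops), with unreachable pairs contributing zero, so the measure stays
#' finite for disconnected graphs.
#'
#' @inheritParams clustering_global
#' @return Value in `[0, 1]` (0 for an empty graph).
#' @export
efficiency <- function(net) {
  ei <- edge_index(net)
  if (ei$n < 2) return(0)
  if (nrow(ei$edges) == 0L) return(0)
  g <- igraph::make_empty_graph(ei$n, directed = FALSE)
  g <- igraph::add_edges(g, t(ei$edges))
  D <- igraph::distances(g)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (ei$n * (ei$n - 1))
}

#' Degree assortativity
#'
#' Newman's assortativity coefficient: the Pearson correlation of the
#' degrees at the two ends of each edge, computed over the edge list with
#' each edge counted in both orientations. Undefined (`NA`) when there are
#' fewer than two edges or the end-degrees have zero variance (e.g. regular
#' graphs).
#'
#' @inheritParams clustering_global
#' @return Value in `[-1, 1]`, or `NA`.
#' @export
assortativity <- function(net) {
  ei <- edge_index(net)
  m <- nrow(ei$edges)
  if (m < 2) return(NA_real_)
  deg <- tabulate(c(ei$edges), nbins = ei$n)
  j <- deg[ei$edges[, 1L]]; k <- deg[ei$edges[, 2L]]
  mean_jk <- mean(j * k)
  mean_sum <- mean((j + k) / 2)
  mean_sq <- mean((j^2 + k^2) / 2)
  den <- mean_sq - mean_sum^2
  if (den <= .Machine$double.eps * mean_sq) return(NA_real_)
  (mean_jk - mean_sum^2) / den
}

#' Count of disconnected nodes
#'
#' Nodes with zero degree (no input or output connections).
#'
#' @inheritParams clustering_global
#' @return Integer count.
#' @export
disconnected_count <- function(net) {
  ei <- edge_index(net)
  sum(tabulate(c(ei$edges), nbins = ei$n) == 0L)
}

#' Subsampling specification
#'
#' Parameters of the subsampling protocol used to compare networks at equal
#' node and edge counts: draw `n_nodes` neurons uniformly without
#' replacement, `n_repeats` times, and evaluate each measure at each
#' connectivity density.
#'
#' @param n_nodes Subsample size (default 100).
#' @param n_repeats Number of subsamples (default 100).
#' @param densities Connectivity densities to evaluate (default
#'   `c(0.005, 0.01, 0.015, 0.02)`).
#' @param seed Optional RNG seed.
#' @return An object of class `subsample_spec`.
#' @export
subsample_spec <- function(n_nodes = 100, n_repeats = 100,
                           densities = c(0.005, 0.01, 0.015, 0.02),
                           seed = NULL) {
  if (!is_count(n_nodes) || n_nodes < 2) stop("`n_nodes` must be >= 2")
  if (!is_count(n_repeats) || n_repeats < 1) stop("`n_repeats` must be >= 1")
  if (any(densities <= 0 | densities > 1)) stop("densities must be in (0, 1]")
  structure(list(n_nodes = as.integer(n_nodes),
                 n_repeats = as.integer(n_repeats),
                 densities = sort(densities), seed = seed),
            class = "subsample_spec")
}

#' Subsampling-controlled graph measures
#'
#' For each repeat, draws `n_nodes` neurons without replacement from the
#' network's node set, restricts the edge supply to the sample, truncates to
#' each connectivity density by significance order, and computes the
#' disconnected-node count, global clustering coefficient, efficiency and
#' assortativity. Reports the mean and root-mean-square spread over repeats
#' per density; undefined values are excluded from aggregation with their
#' count reported. Also pools the out-degree distribution at
#' `reference_density` (non-delayed edges count toward both nodes'
#' out-degree).
#'
#' @param net A `functional_network` whose edges carry significance ratios
#'   (build it at density 1 to keep the full supply).
#' @param spec A [subsample_spec()]; its `n_nodes` must not exceed the
#'   population size.
#' @param reference_density Density at which the degree distribution is
#'   pooled (default 0.01).
#' @return An object of class `metrics_result`: a data frame `measures`
#'   (density, measure, mean, rms, n_undefined) plus the pooled
#'   `degree_distribution`.
#' @export
subsample_metrics <- function(net, spec, reference_density = 0.01) {
  stopifnot(inherits(net, "functional_network"), inherits(spec, "subsample_spec"))
  n_pop <- nrow(net$nodes)
  if (n_pop < spec$n_nodes)
    stop("population (", n_pop, ") smaller than the subsample size (",
         spec$n_nodes, ")")
  ed <- net$edges[order(-net$edges$ratio, net$edges$i, net$edges$j), ,
                  drop = FALSE]
  n <- spec$n_nodes
  npairs <- n * (n - 1) / 2
  densities <- sort(unique(c(spec$densities, reference_density)))
  vals <- array(NA_real_, c(spec$n_repeats, length(densities), 4L),
                dimnames = list(NULL, NULL, c("disconnected", "clustering",
                                              "efficiency", "assortativity")))
  degree_pool <- integer(0)
  with_seed(spec$seed, {
    for (r in seq_len(spec$n_repeats)) {
      samp <- sort(sample(net$nodes$id, n))
      sub <- ed[ed$i %in% samp & ed$j %in% samp, , drop = FALSE]
      for (di in seq_along(densities)) {
        keep <- min(nrow(sub), floor(densities[di] * npairs))
        e <- sub[seq_len(keep), , drop = FALSE]
        em <- cbind(match(e$i, samp), match(e$j, samp))
        attr(em, "n") <- n
        vals[r, di, "disconnected"] <- disconnected_count(em)
        vals[r, di, "clustering"] <- clustering_global(em)
        vals[r, di, "efficiency"] <- efficiency(em)
        vals[r, di, "assortativity"] <- assortativity(em)
        if (abs(densities[di] - reference_density) < 1e-12)
          degree_pool <- c(degree_pool, out_degrees(e, samp))
      }
    }
  })
  measures <- do.call(rbind, lapply(seq_along(densities), function(di) {
    do.call(rbind, lapply(dimnames(vals)[[3]], function(msr) {
      x <- vals[, di, msr]
      ok <- is.finite(x)
      data.frame(density = densities[di], measure = msr,
                 mean = if (any(ok)) mean(x[ok]) else NA_real_,
                 rms = if (any(ok)) sqrt(mean((x[ok] - mean(x[ok]))^2)) else NA_real_,
                 n_undefined = sum(!ok))
    }))
  }))
  rownames(measures) <- NULL
  dd <- if (length(degree_pool)) {
    tab <- tabulate(degree_pool + 1L, nbins = max(degree_pool) + 1L)
    stats::setNames(tab / sum(tab), 0:max(degree_pool))
  } else stats::setNames(1, "0")
  structure(list(measures = measures, degree_distribution = dd,
                 reference_density = reference_density, spec = spec,
                 band = net$band),
            class = "metrics_result")
}

#' @export
print.metrics_result <- function(x, ...) {
  cat("Subsampled network measures", if (!is.null(x$band)) paste0("[", x$band, "]"),
      sprintf("(%d nodes x %d repeats):\n", x$spec$n_nodes, x$spec$n_repeats))
  print(x$measures, digits = 3)
  invisible(x)
}

# Out-degrees over a node sample: a directed edge counts for its source,
# a non-delayed (bidirectional) edge counts for both nodes.
out_degrees <- function(edges, ids) {
  deg <- stats::setNames(integer(length(ids)), ids)
  if (nrow(edges)) {
    src <- c(edges$i[edges$orientation != "J->I"],
             edges$j[edges$orientation != "I->J"])
    tab <- table(factor(as.character(src), levels = names(deg)))
    deg <- deg + as.integer(tab)
  }
  as.integer(deg)
}

#' Pooled out-degree distribution
#'
#' Normalized histogram of out-degree pooled over a list of networks of
#' equal size. Delayed edges count for the source node only; non-delayed
#' edges count for both end nodes.
#'
#' @param nets A `functional_network` or list of them (same node count).
#' @return Named numeric vector of probabilities over degree 0, 1, ...;
#'   sums to 1.
#' @export
degree_distribution <- function(nets) {
  if (inherits(nets, "functional_network")) nets <- list(nets)
  sizes <- vapply(nets, function(nw) nrow(nw$nodes), integer(1))
  if (length(unique(sizes)) != 1L) stop("networks must have equal node counts")
  pool <- unlist(lapply(nets, function(nw) out_degrees(nw$edges, nw$nodes$id)))
  tab <- tabulate(pool + 1L, nbins = max(pool) + 1L)
  stats::setNames(tab / sum(tab), 0:max(pool))
}

#' Model degree distributions
#'
#' Reference degree laws at network size `n` and connectivity density `p`:
#' \describe{
#'   \item{random}{binomial `Binom(n - 1, p)` (Erdős–Rényi).}
#'   \item{exponential}{discretized exponential `P(k) ∝ exp(-k / kbar)` over
#'     `k = 0..n-1`, with `kbar` fixed so the mean degree equals
#'     `(n - 1) p` — the one free parameter is determined by `n` and `p`.}
#'   \item{scalefree_subsampled}{empirical degree law of `n`-node uniform
#'     subsamples of `parent_n`-node Barabási–Albert preferential-attachment
#'     graphs matched to density `p` (subsampling destroys the power-law
#'     tail, which is why the subsampled law is the fair comparison).}
#' }
#'
#' @param n Subsampled network size (default 100).
#' @param p Connectivity density (default 0.01).
#' @param parent_n Parent scale-free network size (default 1000).
#' @param n_parents,n_subsamples Monte-Carlo replicates for the scale-free
#'   law (full fidelity 1000 x 100; reducible for speed).
#' @param seed Optional RNG seed.
#' @return Named list of three probability vectors over `k = 0..n-1`, each
#'   summing to 1.
#' @export
model_degree_distributions <- function(n = 100, p = 0.01, parent_n = 1000,
                                       n_parents = 1000, n_subsamples = 100,
                                       seed = NULL) {
  if (p <= 0 || p >= 1) stop("`p` must be in (0, 1)")
  k <- 0:(n - 1)
  random <- stats::dbinom(k, n - 1, p)
  mean_deg <- (n - 1) * p
  kbar <- stats::uniroot(function(kb) {
    w <- exp(-k / kb)
    sum(k * w) / sum(w) - mean_deg
  }, interval = c(1e-6, 10 * n))$root
  expo <- exp(-k / kbar); expo <- expo / sum(expo)
  m_real <- p * (parent_n - 1) / 2       # per-node attachment for parent density p
  counts <- numeric(n)
  with_seed(seed, {
    for (g in seq_len(n_parents)) {
      out_seq <- floor(m_real) +
        (stats::runif(parent_n) < (m_real - floor(m_real)))
      out_seq[1L] <- 0L
      gr <- igraph::sample_pa(parent_n, out.seq = out_seq, directed = FALSE)
      for (s in seq_len(n_subsamples)) {
        vs <- sample.int(parent_n, n)
        dd <- igraph::degree(igraph::induced_subgraph(gr, vs))
        dd <- dd[dd <= n - 1]
        counts <- counts + tabulate(dd + 1L, nbins = n)
      }
    }
  })
  list(random = random, exponential = expo,
       scalefree_subsampled = counts / sum(counts))
}

#' Reduced chi-square distance between degree laws
#'
#' `chi2_red = sum((obs - model)^2 / sem^2) / dof` over bins with a defined
#' positive SEM, where `dof` is the number of such bins.
#'
#' @param observed Observed probability per degree bin.
#' @param model Model probability per degree bin (same length).
#' @param sem Standard error of the observed probabilities.
#' @return The reduced chi-square value.
#' @export
chi2_compare <- function(observed, model, sem) {
  if (length(observed) != length(model) || length(observed) != length(sem))
    stop("`observed`, `model` and `sem` must have equal length")
  use <- is.finite(sem) & sem > 0 & is.finite(observed) & is.finite(model)
  dof <- sum(use)
  if (dof == 0L) stop("no bins with defined SEM: zero degrees of freedom")
  sum(((observed[use] - model[use]) / sem[use])^2) / dof
}

#' Two-condition comparison of a network measure
#'
#' Reporting utility: two-tailed Welch t-test between two groups of
#' per-tissue measure values (as used at the 1% density point).
#'
#' @param x,y Numeric vectors of per-network measure values.
#' @return `htest` object from [stats::t.test()].
#' @export
compare_measure <- function(x, y) stats::t.test(x, y, alternative = "two.sided")
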