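test_that("clustering coefficient follows the k >= 2 convention", {
  K5 <- edges_from_mask(rep(TRUE, 10), 5)
  expect_equal(clustering_global(K5), 1)
  star <- cbind(rep(1L, 4), 2:5); attr(star, "n") <- 5
  expect_equal(clustering_global(star), 0)
  # triangle plus a pendant: local coefficients 1/3, 1, 1 -> mean 7/9
  tp <- cbind(c(1L, 2L, 1L, 1L), c(2L, 3L, 3L, 4L)); attr(tp, "n") <- 4
  expect_equal(clustering_global(tp), oracle_clustering(adj_from_edges(tp, 4)))
  expect_equal(clustering_global(tp), 7 / 9)
  # no node with two neighbours: undefined
  pair <- cbind(1L, 2L); attr(pair, "n") <- 4
  expect_true(is.na(clustering_global(pair)))
})

test_that("efficiency handles complete, path and disconnected graphs", {
  K5 <- edges_from_mask(rep(TRUE, 10), 5)
  expect_equal(efficiency(K5), 1)
  path3 <- cbind(c(1L, 2L), c(2L, 3L)); attr(path3, "n") <- 3
  expect_equal(efficiency(path3), 5 / 6)   # (4*1 + 2*0.5)/6
  none <- matrix(integer(0), 0, 2); attr(none, "n") <- 5
  expect_equal(efficiency(none), 0)
  expect_equal(disconnected_count(none), 5L)
})

test_that("assortativity matches the edge-list Pearson definition", {
  star <- cbind(rep(1L, 4), 2:5); attr(star, "n") <- 5
  expect_equal(assortativity(star), -1)
  K4 <- edges_from_mask(rep(TRUE, 6), 4)
  expect_true(is.na(assortativity(K4)))           # zero degree variance
  disj <- cbind(c(1L, 3L), c(2L, 4L)); attr(disj, "n") <- 4
  expect_true(is.na(assortativity(disj)))          # all degrees 1
})

test_that("graph measures agree with oracles and igraph on random graphs", {
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(4:7, 1)
    npairs <- n * (n - 1) / 2
    mask <- runif(npairs) < runif(1, 0.2, 0.8)
    e <- edges_from_mask(mask, n)
    A <- adj_from_edges(e, n)
    expect_equal(clustering_global(e), oracle_clustering(A))
    expect_equal(efficiency(e), oracle_efficiency(A))
    expect_equal(assortativity(e), oracle_assortativity(e, n))
    if (nrow(e)) {
      g <- igraph::graph_from_edgelist(e, directed = FALSE)
      g <- igraph::add_vertices(g, n - igraph::vcount(g))
      expect_equal(efficiency(e), igraph::global_efficiency(g),
                   tolerance = 1e-12)
      r_ig <- suppressWarnings(igraph::assortativity_degree(g))
      r_us <- assortativity(e)
      if (is.finite(r_ig) && !is.na(r_us))
        expect_equal(r_us, r_ig, tolerance = 1e-12)
    }
  }
})

test_that("out-degree distributions respect edge direction", {
  # A->B, A->C: out-degrees {2, 0, 0}
  net <- toy_network(3, cbind(c(1L, 1L), c(2L, 3L)),
                     directed = c(TRUE, TRUE),
                     orientation = c("I->J", "I->J"))
  dd <- degree_distribution(net)
  expect_equal(unname(dd[c("0", "2")]), c(2 / 3, 1 / 3))
  expect_equal(sum(dd), 1, tolerance = 1e-12)

  # a bidirectional edge counts for both ends
  net2 <- toy_network(3, cbind(1L, 2L))
  dd2 <- degree_distribution(net2)
  expect_equal(unname(dd2[c("0", "1")]), c(1 / 3, 2 / 3))

  empty <- toy_network(4, matrix(integer(0), 0, 2))
  expect_equal(unname(degree_distribution(empty)["0"]), 1)
})

test_that("model degree laws are normalized with the prescribed means", {
  mods <- model_degree_distributions(n = 100, p = 0.01, n_parents = 5,
                                     n_subsamples = 10, seed = 3)
  k <- 0:99
  for (m in mods) expect_equal(sum(m), 1, tolerance = 1e-12)
  expect_equal(sum(k * mods$random), 99 * 0.01, tolerance = 1e-12)
  expect_equal(sum(k * mods$exponential), 99 * 0.01, tolerance = 1e-6)
  expect_equal(mods$random, dbinom(k, 99, 0.01))
})

test_that("subsampled scale-free law is insensitive to the parent size", {
  m1 <- model_degree_distributions(n = 100, p = 0.01, parent_n = 500,
                                   n_parents = 30, n_subsamples = 30,
                                   seed = 4)$scalefree_subsampled
  m2 <- model_degree_distributions(n = 100, p = 0.01, parent_n = 1000,
                                   n_parents = 30, n_subsamples = 30,
                                   seed = 5)$scalefree_subsampled
  tv <- sum(abs(m1 - m2)) / 2
  expect_lt(tv, 0.05)
})

test_that("reduced chi-square is an arithmetic identity", {
  obs <- c(0.5, 0.3, 0.2); sem <- c(0.05, 0.04, 0.02)
  expect_equal(chi2_compare(obs, obs, sem), 0)
  model <- c(0.45, 0.35, 0.20)
  byhand <- ((0.05 / 0.05)^2 + (0.05 / 0.04)^2 + 0) / 3
  expect_equal(chi2_compare(obs, model, sem), byhand)
  perm <- c(2, 3, 1)
  expect_equal(chi2_compare(obs[perm], model[perm], sem[perm]),
               chi2_compare(obs, model, sem))
  expect_error(chi2_compare(obs, model, c(0, 0, 0)), "zero degrees")
})

test_that("subsampling the whole population reproduces the direct measures", {
  set.seed(17)
  n <- 30
  mask <- runif(n * (n - 1) / 2) < 0.2
  e <- edges_from_mask(mask, n)
  net <- toy_network(n, e)
  spec <- subsample_spec(n_nodes = n, n_repeats = 1,
                         densities = 1, seed = 1)
  res <- subsample_metrics(net, spec, reference_density = 1)
  g <- res$measures
  pick <- function(m) g$mean[g$measure == m & g$density == 1]
  expect_equal(pick("clustering"), clustering_global(net))
  expect_equal(pick("efficiency"), efficiency(net))
  expect_equal(pick("assortativity"), assortativity(net))
  expect_equal(pick("disconnected"), disconnected_count(net))
})

test_that("subsampling is deterministic and flags undefined values", {
  net <- toy_network(20, matrix(integer(0), 0, 2))
  spec <- subsample_spec(n_nodes = 10, n_repeats = 3, densities = 0.02,
                         seed = 9)
  res <- subsample_metrics(net, spec, reference_density = 0.02)
  res2 <- subsample_metrics(net, spec, reference_density = 0.02)
  expect_equal(res$measures, res2$measures)
  g <- res$measures
  expect_equal(g$mean[g$measure == "disconnected"], 10)
  expect_equal(g$mean[g$measure == "efficiency"], 0)
  expect_equal(g$n_undefined[g$measure == "clustering"], 3L)
  expect_equal(g$n_undefined[g$measure == "assortativity"], 3L)
  expect_error(subsample_metrics(net, subsample_spec(n_nodes = 50)),
               "smaller than")
})

test_that("RMS spread shrinks as the subsample approaches the population", {
  set.seed(23)
  n <- 60
  e <- edges_from_mask(runif(n * (n - 1) / 2) < 0.1, n)
  net <- toy_network(n, e)
  rms_at <- function(k) {
    spec <- subsample_spec(n_nodes = k, n_repeats = 40, densities = 0.05,
                           seed = 31)
    g <- subsample_metrics(net, spec, reference_density = 0.05)$measures
    g$rms[g$measure == "efficiency"]
  }
  expect_lt(rms_at(55), rms_at(15))
})

test_that("binomial model equals Erdos-Renyi simulation within error", {
  set.seed(41)
  n <- 40; p <- 0.1; reps <- 400
  degs <- unlist(lapply(seq_len(reps), function(r) {
    e <- edges_from_mask(runif(n * (n - 1) / 2) < p, n)
    tabulate(c(e), nbins = n)
  }))
  emp <- tabulate(degs + 1L, nbins = n) / length(degs)
  model <- dbinom(0:(n - 1), n - 1, p)
  expect_lt(sum(abs(emp - model)) / 2, 0.02)   # total variation
})

test_that("distance-decay fit recovers binned probabilities and errors", {
  nodes <- data.frame(id = 1:80,
                      x = rep(seq(0, 700, by = 100), 10),
                      y = rep(seq(0, 900, by = 100), each = 8))
  net <- simulate_decay_network(nodes, A = 0.9, lambda_um = 200, C = 0.01,
                                seed = 51)
  fit <- fit_decay(net, bin_width_um = 100)
  expect_s3_class(fit, "decay_fit")
  expect_true(fit$converged)
  expect_true(all(c("A", "lambda", "C") %in% names(coef(fit))))
  expect_true(all(is.finite(confint(fit))))
  # fitted curve stays a probability over the observed distance range
  p <- predict(fit, data.frame(d = seq(min(fit$data$d), max(fit$data$d),
                                       length.out = 50)))
  expect_true(all(p >= 0 & p <= 1 + 1e-6))
  expect_error(fit_decay(net, bin_width_um = 5000), "at least 4")
})

test_that("distance-independent wiring leaves lambda unidentified", {
  nodes <- data.frame(id = 1:100,
                      x = runif(100, 0, 900), y = runif(100, 0, 1900))
  set.seed(61)
  net <- simulate_decay_network(nodes, A = 0, lambda_um = 300, C = 0.05,
                                seed = 62)
  fit <- fit_decay(net, bin_width_um = 100)
  if (fit$converged) {
    ci <- confint(fit)["lambda", ]
    expect_gt(ci[2] - ci[1], 500)   # wide interval: decay length meaningless
  } else {
    expect_false(fit$converged)     # reported with diagnostics
  }
})
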