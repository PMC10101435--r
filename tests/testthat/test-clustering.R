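# K-means for graphs and gCEM.

test_that("silhouette matches hand values and the brute-force oracle", {
  # two perfectly separated pairs: within-distance 0, between-distance 1
  d <- matrix(1, 4, 4) - diag(4)
  d[1, 2] <- d[2, 1] <- 0
  d[3, 4] <- d[4, 3] <- 0
  expect_equal(silhouette_score(c(1, 1, 2, 2), d), 1)
  # all pairwise distances equal
  expect_equal(silhouette_score(c(1, 1, 2, 2), matrix(1, 4, 4) - diag(4)), 0)
  # single cluster: 0 by convention
  expect_equal(silhouette_score(rep(1, 4), d), 0)
  # random matrices vs the independent oracle
  set.seed(12)
  for (i in 1:20) {
    n <- sample(5:9, 1)
    m <- matrix(runif(n * n), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    labels <- sample(1:3, n, replace = TRUE)
    expect_equal(silhouette_score(labels, m), oracle_silhouette(labels, m),
                 tolerance = 1e-12)
  }
})

test_that("k-means separates ring-lattice-like and Erdos-Renyi graphs perfectly", {
  truth <- rep(1:2, each = 10)
  for (s in 1:5) {
    graphs <- c(
      lapply(1:10, function(i) gen_watts_strogatz(100, 20, 0.1, seed = 100 * s + i)),
      lapply(1:10, function(i) gen_erdos_renyi_gnm(100, 1000, seed = 100 * s + 50 + i))
    )
    fit <- kmeans_graphs(graphs, 2, n_restarts = 10, seed = s)
    expect_equal(jaccard_index(truth, fit$labels), 1)
    expect_true(fit$converged)
  }
})

test_that("k-means handles K = 1, degenerate identical inputs, and bad calls", {
  graphs <- lapply(1:6, function(i) gen_erdos_renyi_gnp(30, 0.3, seed = i))
  fit1 <- kmeans_graphs(graphs, 1, n_restarts = 2, seed = 1)
  expect_equal(unique(fit1$labels), 1L)
  expect_equal(fit1$silhouette, 0)

  one <- gen_erdos_renyi_gnp(30, 0.3, seed = 9)
  same <- rep(list(one), 20)
  fit2 <- kmeans_graphs(same, 2, n_restarts = 2, max_iter = 20, seed = 2)
  expect_true(fit2$converged)
  expect_equal(sort(unique(fit2$labels)), 1:2)  # both clusters stay populated

  mixed <- list(gen_erdos_renyi_gnp(30, 0.3, seed = 1),
                gen_erdos_renyi_gnp(40, 0.3, seed = 2))
  expect_error(kmeans_graphs(mixed, 2), "different vertex counts")
  expect_error(kmeans_graphs(graphs, 7), "more clusters")
})

test_that("the k-means objective never increases within a restart", {
  for (s in 1:5) {
    graphs <- c(
      lapply(1:5, function(i) gen_erdos_renyi_gnp(60, 0.2, seed = 10 * s + i)),
      lapply(1:5, function(i) gen_erdos_renyi_gnp(60, 0.35, seed = 10 * s + 5 + i))
    )
    fit <- kmeans_graphs(graphs, 2, n_restarts = 1, seed = s)
    expect_true(all(diff(fit$objective_trace) <= 1e-10))
  }
})

test_that("k-means is reproducible and its scores are coherent", {
  graphs <- c(lapply(1:5, function(i) gen_watts_strogatz(60, 8, 0.05, seed = i)),
              lapply(1:5, function(i) gen_erdos_renyi_gnm(60, 240, seed = 50 + i)))
  f1 <- kmeans_graphs(graphs, 2, n_restarts = 3, seed = 11)
  f2 <- kmeans_graphs(graphs, 2, n_restarts = 3, seed = 11)
  expect_identical(f1$labels, f2$labels)
  expect_equal(dim(f1$assignment_scores), c(10, 2))
  # every graph is assigned to its nearest centroid
  expect_equal(apply(f1$assignment_scores, 1, which.min), f1$labels)
})

test_that("single-cluster gCEM recovers the shared ER parameter", {
  spec <- graph_model_spec("erdos_renyi_gnp", grid = seq(0.05, 0.5, by = 0.025))
  hits <- vapply(1:10, function(s) {
    sizes <- withr::with_seed(s, sample(30:120, 10, replace = TRUE))
    graphs <- lapply(seq_along(sizes), function(i) {
      gen_erdos_renyi_gnp(sizes[i], 0.2, seed = 100 * s + i)
    })
    fit <- gcem(graphs, 1, spec, n_mc = 10, seed = s, n_points = 256)
    abs(fit$theta[[1]] - 0.2) <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("two-cluster gCEM beats chance and straddles the true parameters", {
  spec <- graph_model_spec("erdos_renyi_gnp", grid = seq(0.05, 0.5, by = 0.025))
  truth <- rep(1:2, each = 10)
  res <- lapply(1:10, function(s) {
    sizes <- withr::with_seed(1000 + s, sample(30:120, 20, replace = TRUE))
    graphs <- lapply(seq_along(sizes), function(i) {
      gen_erdos_renyi_gnp(sizes[i], c(0.2, 0.3)[truth[i]], seed = 500 * s + i)
    })
    fit <- gcem(graphs, 2, spec, n_mc = 10, seed = s, n_points = 256)
    th <- sort(unlist(fit$theta))
    list(jac = jaccard_index(truth, fit$labels), lo = th[1], hi = th[2])
  })
  expect_gt(median(vapply(res, `[[`, numeric(1), "jac")), 0.32)
  expect_lte(abs(median(vapply(res, `[[`, numeric(1), "lo")) - 0.2), 0.05)
  expect_lte(abs(median(vapply(res, `[[`, numeric(1), "hi")) - 0.3), 0.05)
})

test_that("gCEM responsibilities are proper probabilities inside the grid hull", {
  spec <- graph_model_spec("erdos_renyi_gnp", grid = seq(0.1, 0.4, by = 0.05))
  graphs <- lapply(1:8, function(i) {
    gen_erdos_renyi_gnp(30 + 5 * i, 0.25, seed = i)
  })
  fit <- gcem(graphs, 2, spec, n_mc = 10, seed = 3, n_points = 256)
  expect_equal(rowSums(fit$responsibilities), rep(1, 8), tolerance = 1e-12)
  for (th in fit$theta) {
    expect_gte(th, 0.1)
    expect_lte(th, 0.4)
  }
  refit <- gcem(graphs, 2, spec, n_mc = 10, seed = 3, n_points = 256)
  expect_identical(fit$labels, refit$labels)
  expect_error(gcem(graphs, 9, spec), "more clusters")
})

test_that("a graph no model supports falls back to uniform responsibilities", {
  # a large star's leading eigenvalue sqrt(n - 1) lies so far outside the
  # [-2, 2] support of 2-regular model spectra that the model density
  # underflows to exact zero there
  star <- igraph::make_star(600, mode = "undirected")
  ring <- lapply(1:5, function(i) gen_k_regular(100, 2, seed = i))
  spec <- graph_model_spec("k_regular", grid = 2)
  expect_warning(
    fit <- gcem(c(ring, list(star)), 2, spec, n_mc = 5, seed = 4, n_points = 256),
    "infinite KL"
  )
  expect_equal(fit$responsibilities[6, ], c(0.5, 0.5))
})
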