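# KL-minimising parameter estimation and model selection.

test_that("model_mean_density has unit area, reduces to one draw at n_mc = 1, and caches", {
  spec <- graph_model_spec("erdos_renyi_gnp", grid = c(0.3))
  grid <- seq(-8, 31, length.out = 400)
  d1 <- model_mean_density(spec, 0.3, 60, grid, n_mc = 1, seed = 5)
  single <- netspectra:::density_on_grid(
    graph_spectrum(generate_model_graph(spec, 0.3, 60,
                                        seed = netspectra:::derive_seed(5, 0.3, 60, 1))),
    grid
  )
  expect_equal(d1$density, single$density)
  dm <- model_mean_density(spec, 0.3, 60, grid, n_mc = 10, seed = 5)
  expect_lt(abs(trap_area(grid, dm$density) - 1), 1e-6)
  # repeated calls are bit-identical (cache + deterministic streams)
  expect_identical(dm$density,
                   model_mean_density(spec, 0.3, 60, grid, n_mc = 10, seed = 5)$density)
})

test_that("Monte-Carlo mean densities are more stable across seeds than across parameters", {
  spec <- graph_model_spec("erdos_renyi_gnp")
  grid <- seq(-12, 50, length.out = 500)
  a1 <- model_mean_density(spec, 0.3, 100, grid, n_mc = 50, seed = 1)
  a2 <- model_mean_density(spec, 0.3, 100, grid, n_mc = 50, seed = 2)
  b <- model_mean_density(spec, 0.45, 100, grid, n_mc = 50, seed = 3)
  expect_lt(js_divergence(a1, a2), js_divergence(a1, b))
})

test_that("the estimate sits at the grid argmin and a singleton grid is returned as-is", {
  g <- gen_erdos_renyi_gnp(50, 0.25, seed = 31)
  single <- estimate_parameter(g, graph_model_spec("erdos_renyi_gnp", grid = 0.4),
                               n_mc = 5, seed = 1)
  expect_equal(single$theta_hat, 0.4)
  est <- estimate_parameter(g, graph_model_spec("erdos_renyi_gnp",
                                                grid = seq(0.1, 0.5, 0.1)),
                            n_mc = 10, seed = 1)
  expect_equal(est$kl_min, min(est$grid_kl$kl))
  expect_true(paste(est$theta_hat) %in% est$grid_kl$theta)
})

test_that("ER edge probability is recovered from single graphs", {
  spec <- graph_model_spec("erdos_renyi_gnp", grid = seq(0.05, 0.5, by = 0.05))
  hits <- vapply(1:30, function(s) {
    g <- gen_erdos_renyi_gnp(100, 0.3, seed = 8000 + s)
    est <- estimate_parameter(g, spec, n_mc = 20, seed = 1, n_points = 256)
    est$theta_hat
  }, numeric(1))
  expect_gte(mean(hits %in% c(0.25, 0.3, 0.35)), 0.9)
})

test_that("k-regular degree is recovered essentially always", {
  spec <- graph_model_spec("k_regular", grid = c(2, 4, 6, 8))
  hits <- vapply(1:20, function(s) {
    g <- gen_k_regular(100, 6, seed = 8100 + s)
    estimate_parameter(g, spec, n_mc = 20, seed = 1, n_points = 256)$theta_hat
  }, numeric(1))
  expect_gte(mean(hits == 6), 0.95)
})

test_that("recovery improves (weakly) with graph size", {
  spec <- graph_model_spec("erdos_renyi_gnp", grid = seq(0.1, 0.5, by = 0.1))
  rate <- vapply(c(30, 60, 120), function(n) {
    hit <- vapply(1:20, function(s) {
      g <- gen_erdos_renyi_gnp(n, 0.3, seed = 8200 + s)
      estimate_parameter(g, spec, n_mc = 10, seed = 1,
                         n_points = 256)$theta_hat == 0.3
    }, logical(1))
    mean(hit)
  }, numeric(1))
  expect_true(all(diff(rate) >= 0))
})

test_that("model selection identifies the generating family", {
  er_spec <- graph_model_spec("erdos_renyi_gnp", grid = seq(0.1, 0.5, by = 0.1))
  kr_spec <- graph_model_spec("k_regular", grid = c(2, 4, 6, 8))
  ws_spec <- graph_model_spec("watts_strogatz", grid = seq(0, 0.3, by = 0.05),
                              fixed = list(k = 16))

  sel_single <- select_model(gen_erdos_renyi_gnp(60, 0.3, seed = 1),
                             list(er_spec), n_mc = 5, seed = 1)
  expect_equal(sel_single$model, "erdos_renyi_gnp")

  er_hits <- vapply(1:15, function(s) {
    g <- gen_erdos_renyi_gnp(100, 0.3, seed = 8300 + s)
    select_model(g, list(er_spec, kr_spec), n_mc = 10, seed = 1,
                 n_points = 256)$model
  }, character(1))
  expect_gte(mean(er_hits == "erdos_renyi_gnp"), 0.9)

  ws_hits <- vapply(1:15, function(s) {
    g <- gen_watts_strogatz(100, 16, 0.05, seed = 8400 + s)
    select_model(g, list(ws_spec, er_spec), n_mc = 10, seed = 1,
                 n_points = 256)$model
  }, character(1))
  expect_gte(mean(ws_hits == "watts_strogatz"), 0.9)
})

test_that("infeasible parameter projections snap to the model domain", {
  kr <- graph_model_spec("k_regular", grid = c(2, 4))
  expect_equal(netspectra:::theta_project(kr, 4.7), 4)
  expect_equal(netspectra:::theta_project(kr, 5.1), 6)
  er <- graph_model_spec("erdos_renyi_gnp", grid = c(0.2))
  expect_equal(netspectra:::theta_project(er, 1.2), 1)
  expect_equal(netspectra:::theta_project(er, -0.1), 0)
})
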