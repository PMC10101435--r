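# Random-graph generators and degree-preserving rewiring.

model_draws <- list(
  gnp = function(seed) gen_erdos_renyi_gnp(30, 0.2, seed),
  gnm = function(seed) gen_erdos_renyi_gnm(30, 60, seed),
  geometric = function(seed) gen_geometric(30, 0.3, seed),
  k_regular = function(seed) gen_k_regular(30, 4, seed),
  watts_strogatz = function(seed) gen_watts_strogatz(30, 6, 0.2, seed),
  pref_attachment = function(seed) gen_pref_attachment(30, 3, 1.5, seed)
)

test_that("every generator yields simple undirected seeded-deterministic graphs", {
  for (name in names(model_draws)) {
    gen <- model_draws[[name]]
    for (seed in 1:50) {
      g <- gen(seed)
      expect_false(igraph::is_directed(g), info = name)
      expect_true(igraph::is_simple(g), info = name)
      expect_equal(igraph::vcount(g), 30, info = name)
      el <- igraph::as_edgelist(g, names = FALSE)
      if (nrow(el) > 0) {
        expect_true(all(el >= 1 & el <= 30), info = name)
      }
    }
    expect_identical(
      igraph::as_edgelist(gen(99), names = FALSE),
      igraph::as_edgelist(gen(99), names = FALSE),
      info = name
    )
  }
})

test_that("deterministic edge-count contracts hold for every model", {
  expect_equal(igraph::ecount(gen_erdos_renyi_gnp(50, 0, seed = 1)), 0)
  expect_equal(igraph::ecount(gen_erdos_renyi_gnp(50, 1, seed = 1)), 1225)
  expect_equal(igraph::ecount(gen_erdos_renyi_gnm(100, 1000, seed = 1)), 1000)
  expect_equal(igraph::ecount(gen_erdos_renyi_gnm(10, 0, seed = 1)), 0)
  expect_equal(igraph::ecount(gen_erdos_renyi_gnm(10, 45, seed = 1)), 45)
  expect_equal(igraph::ecount(gen_geometric(30, 0, seed = 1)), 0)
  expect_equal(igraph::ecount(gen_geometric(30, sqrt(2) + 1e-9, seed = 1)),
               choose(30, 2))
  ws0 <- gen_watts_strogatz(100, 20, 0, seed = 1)
  expect_equal(unique(igraph::degree(ws0)), 20)
  expect_equal(igraph::ecount(ws0), 1000)
  expect_equal(igraph::ecount(gen_watts_strogatz(100, 20, 0.5, seed = 2)), 1000)
  expect_equal(igraph::ecount(gen_pref_attachment(100, 10, 1, seed = 3)),
               choose(10, 2) + 90 * 10)
  expect_equal(igraph::ecount(gen_pref_attachment(5, 5, 2, seed = 4)),
               choose(5, 2))
  expect_equal(unique(igraph::degree(gen_k_regular(10, 2, seed = 5))), 2)
})

test_that("domain violations raise errors", {
  expect_error(gen_erdos_renyi_gnp(50, 1.2))
  expect_error(gen_erdos_renyi_gnp(0, 0.5))
  expect_error(gen_erdos_renyi_gnm(10, 46))
  expect_error(gen_geometric(10, -0.1))
  expect_error(gen_k_regular(9, 3), "even")
  expect_error(gen_k_regular(10, 10), "smaller")
  expect_error(gen_watts_strogatz(100, 7, 0.1), "even")
  expect_error(gen_pref_attachment(5, 6, 1))
})

test_that("k-regular graphs have leading eigenvalue k", {
  g <- gen_k_regular(100, 6, seed = 7)
  expect_equal(max(graph_spectrum(g)), 6, tolerance = 1e-10)
})

test_that("G(n,p) edge counts follow the Binomial(C(n,2), p) law", {
  n <- 20
  p <- 0.3
  n_pairs <- choose(n, 2)
  counts <- vapply(1:2000, function(s) {
    igraph::ecount(gen_erdos_renyi_gnp(n, p, seed = 10000 + s))
  }, numeric(1))
  # chi-squared GOF against the binomial pmf, pooling tails to keep
  # expected cell counts above 5
  lo <- qbinom(0.001, n_pairs, p)
  hi <- qbinom(0.999, n_pairs, p)
  breaks <- lo:hi
  obs <- c(sum(counts < lo),
           vapply(breaks, function(b) sum(counts == b), numeric(1)),
           sum(counts > hi))
  prob <- c(pbinom(lo - 1, n_pairs, p),
            dbinom(breaks, n_pairs, p),
            pbinom(hi, n_pairs, p, lower.tail = FALSE))
  keep <- prob * 2000 >= 5
  obs <- c(obs[keep], sum(obs[!keep]))
  prob <- c(prob[keep], sum(prob[!keep]))
  gof <- chisq.test(obs, p = prob)
  expect_gt(gof$p.value, 0.01)
})

test_that("mean G(n,p) edge count is within 3 SE of the binomial expectation", {
  n_pairs <- choose(100, 2)
  counts <- vapply(1:200, function(s) {
    igraph::ecount(gen_erdos_renyi_gnp(100, 0.2, seed = s))
  }, numeric(1))
  se <- sqrt(n_pairs * 0.2 * 0.8 / 200)
  expect_lt(abs(mean(counts) - n_pairs * 0.2), 3 * se)
})

test_that("geometric edge density matches the unit-square distance probability", {
  r <- 0.25
  # independent Monte-Carlo oracle for P(|X - Y| < r), X, Y uniform in the
  # unit square
  set.seed(424242)
  p_oracle <- mean(sqrt((runif(2e5) - runif(2e5))^2 +
                        (runif(2e5) - runif(2e5))^2) < r)
  dens <- vapply(1:200, function(s) {
    igraph::ecount(gen_geometric(100, r, seed = s)) / choose(100, 2)
  }, numeric(1))
  se <- sd(dens) / sqrt(200) + sqrt(p_oracle * (1 - p_oracle) / 2e5)
  expect_lt(abs(mean(dens) - p_oracle), 3 * se)
})

test_that("preferential attachment forms stronger hubs at larger exponents", {
  max_deg <- function(ps) {
    mean(vapply(1:40, function(s) {
      max(igraph::degree(gen_pref_attachment(200, 10, ps, seed = 3000 + s)))
    }, numeric(1)))
  }
  expect_gt(max_deg(3), max_deg(1))
})

test_that("heavy rewiring drives the ring lattice toward the ER spectrum", {
  n <- 500
  k <- 16
  er <- gen_erdos_renyi_gnm(n, n * k / 2, seed = 61)
  js_to_er <- vapply(c(0.1, 0.3, 1), function(p) {
    ws <- gen_watts_strogatz(n, k, p, seed = 62)
    ds <- graph_density_set(list(ws, er))
    js_divergence(ds$densities[[1]], ds$densities[[2]])
  }, numeric(1))
  expect_lt(js_to_er[3], js_to_er[1])
  expect_lt(js_to_er[3], js_to_er[2])
})

test_that("markov_rewire conserves size, edges, and the exact degree sequence", {
  ws <- gen_watts_strogatz(100, 20, 0, seed = 8)
  rw <- markov_rewire(ws, 500, seed = 9)
  expect_equal(igraph::vcount(rw), 100)
  expect_equal(igraph::ecount(rw), 1000)
  expect_equal(sort(igraph::degree(rw)), sort(igraph::degree(ws)))
  expect_true(igraph::is_simple(rw))
  # zero swaps: identical graph
  expect_identical(
    igraph::as_edgelist(markov_rewire(ws, 0), names = FALSE),
    igraph::as_edgelist(ws, names = FALSE)
  )
})

test_that("markov_rewire errors when no legal swap exists", {
  k5 <- gen_erdos_renyi_gnp(5, 1, seed = 1)
  expect_error(markov_rewire(k5, 1, seed = 1), "stalled")
})
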