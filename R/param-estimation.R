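#' Random-graph model specification
#'
#' Bundles a model family, a search grid for its free parameter, and any
#' fixed auxiliary parameters, for use by [estimate_parameter()],
#' [select_model()], and [gcem()].
#'
#' The free parameter per family is: edge probability `p` (`erdos_renyi_gnp`),
#' edge count `m` (`erdos_renyi_gnm`), radius `r` (`geometric`), degree `k`
#' (`k_regular`), rewiring probability `p` (`watts_strogatz`, with the
#' neighbour count `k` in `fixed`), and attachment exponent `ps`
#' (`preferential_attachment`, with `m` in `fixed`). `watts_strogatz` also
#' accepts a two-column grid (`k`, `p`) when `k` is not fixed, supplied as a
#' list of length-2 vectors.
#'
#' @param model One of `"erdos_renyi_gnp"`, `"erdos_renyi_gnm"`,
#'   `"geometric"`, `"k_regular"`, `"watts_strogatz"`,
#'   `"preferential_attachment"`.
#' @param grid Candidate values of the free parameter: a numeric vector, or
#'   a list of numeric vectors for multi-parameter grids.
#' @param fixed Named list of fixed auxiliary parameters (e.g.
#'   `list(k = 16)` for Watts–Strogatz).
#' @return A `graph_model_spec` object.
#' @export
graph_model_spec <- function(model, grid = NULL, fixed = list()) {
  model <- match.arg(model, c(
    "erdos_renyi_gnp", "erdos_renyi_gnm", "geometric",
    "k_regular", "watts_strogatz", "preferential_attachment"
  ))
  if (is.null(grid)) grid <- default_grid(model)
  if (is.numeric(grid)) grid <- as.list(grid)
  stopifnot(length(grid) >= 1)
  structure(
    list(model = model, grid = grid, fixed = fixed),
    class = "graph_model_spec"
  )
}

default_grid <- function(model) {
  switch(model,
    erdos_renyi_gnp = seq(0.05, 0.5, by = 0.025),
    geometric = seq(0.05, 0.95, by = 0.05),
    k_regular = seq(2, 20, by = 2),
    watts_strogatz = seq(0, 1, by = 0.05),
    preferential_attachment = seq(0.5, 3, by = 0.25),
    stop(sprintf("no default grid for model '%s'; supply one", model))
  )
}

#' @export
print.graph_model_spec <- function(x, ...) {
  cat(sprintf(
    "<graph_model_spec: %s, %d grid points%s>\n",
    x$model, length(x$grid),
    if (length(x$fixed)) {
      paste0(", fixed ", paste(names(x$fixed), unlist(x$fixed),
                               sep = " = ", collapse = ", "))
    } else ""
  ))
  invisible(x)
}

#' Draw one graph from a model specification
#'
#' @param spec A [graph_model_spec()].
#' @param theta Free-parameter value.
#' @param n Number of vertices.
#' @param seed Optional seed.
#' @return An `igraph` graph.
#' @export
generate_model_graph <- function(spec, theta, n, seed = NULL) {
  fx <- spec$fixed
  switch(spec$model,
    erdos_renyi_gnp = gen_erdos_renyi_gnp(n, theta, seed),
    erdos_renyi_gnm = gen_erdos_renyi_gnm(n, round(theta), seed),
    geometric = gen_geometric(n, theta, seed),
    k_regular = gen_k_regular(n, feasible_degree(theta, n), seed),
    watts_strogatz = if (length(theta) == 2) {
      gen_watts_strogatz(n, round(theta[1]), theta[2], seed)
    } else {
      gen_watts_strogatz(n, fx$k, theta, seed)
    },
    preferential_attachment = if (length(theta) == 2) {
      gen_pref_attachment(n, round(theta[1]), theta[2], seed)
    } else {
      gen_pref_attachment(n, fx$m, theta, seed)
    }
  )
}

# nearest even degree: feasible for every graph size, needed when gCEM's
# M-step averages grid degrees to a non-integer
feasible_degree <- function(k, n) {
  k <- max(2, 2 * round(k / 2))
  min(k, if (n %% 2 == 0) n - 1 else n - 2)
}

# project an averaged parameter back into the model's feasible domain
theta_project <- function(spec, theta) {
  switch(spec$model,
    k_regular = max(2, 2 * round(theta / 2)),
    erdos_renyi_gnm = round(theta),
    erdos_renyi_gnp = min(max(theta, 0), 1),
    watts_strogatz = if (length(theta) == 2) {
      c(max(2, 2 * round(theta[1] / 2)), min(max(theta[2], 0), 1))
    } else {
      min(max(theta, 0), 1)
    },
    geometric = max(theta, 0),
    theta
  )
}

# ---- Monte-Carlo model spectra (cached) ------------------------------------

.spectra_cache <- new.env(parent = emptyenv())

#' Clear the Monte-Carlo model-spectrum cache
#' @return Invisibly, the number of entries dropped.
#' @export
clear_model_cache <- function() {
  n <- length(ls(.spectra_cache))
  rm(list = ls(.spectra_cache), envir = .spectra_cache)
  invisible(n)
}

# spectra of n_mc model draws at (theta, n); deterministic in (spec, theta,
# n, n_mc, seed) and cached because gCEM re-evaluates them heavily.
# Algorithms that hammer the cache (gCEM) pass their own call-local
# environment so the accumulated spectra are collected when the call
# returns; holding them in the global cache makes every subsequent GC walk
# tens of thousands of small vectors and slows the whole session down.
model_spectra <- function(spec, theta, n, n_mc, seed, cache = .spectra_cache) {
  key <- paste(spec$model, paste(signif(theta, 10), collapse = ","),
               paste(names(spec$fixed), unlist(spec$fixed), collapse = ","),
               n, n_mc, seed, sep = "|")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  spectra <- lapply(seq_len(n_mc), function(r) {
    model_spectrum_draw(spec, theta, n, derive_seed(seed, theta, n, r))
  })
  assign(key, spectra, envir = cache)
  spectra
}

# One model draw reduced straight to its spectrum: uses the generators'
# edge cores and a dense eigen call, skipping igraph construction (the
# same RNG stream as generate_model_graph, so the spectra are identical)
model_spectrum_draw <- function(spec, theta, n, seed) {
  if (spec$model == "k_regular") {
    return(graph_spectrum(gen_k_regular(n, feasible_degree(theta, n), seed)))
  }
  fx <- spec$fixed
  edges <- with_seed_if(seed, switch(spec$model,
    erdos_renyi_gnp = er_gnp_edges(n, theta),
    erdos_renyi_gnm = er_gnm_edges(n, round(theta)),
    geometric = geometric_edges(n, theta),
    watts_strogatz = if (length(theta) == 2) {
      ws_edges(n, round(theta[1]), theta[2])
    } else {
      ws_edges(n, fx$k, theta)
    },
    preferential_attachment = if (length(theta) == 2) {
      pa_edges(n, round(theta[1]), theta[2])
    } else {
      pa_edges(n, fx$m, theta)
    }
  ))
  spectrum_from_edges(n, edges)
}

# density evaluated on a prescribed grid without the coverage check: mass
# falling outside the grid is truncated and the rest renormalised
density_on_grid <- function(values, grid) {
  h <- kernel_bandwidth(values)
  dens <- rowMeans(stats::dnorm(outer(grid, values, "-"), sd = h))
  new_spectral_density(grid, dens, h)
}

# mean of the per-draw unit-area densities of a set of spectra, evaluated
# on one grid with one scalar-bandwidth kernel pass per draw: the
# Monte-Carlo model-density hot path of estimation and gCEM
mean_density_of_spectra <- function(spectra, grid) {
  wts <- trapezoid_weights(grid)
  acc <- numeric(length(grid))
  hs <- numeric(length(spectra))
  for (r in seq_along(spectra)) {
    vals <- spectra[[r]]
    h <- kernel_bandwidth(vals)
    hs[r] <- h
    dens <- rowMeans(stats::dnorm(outer(grid, vals, "-"), sd = h))
    area <- sum(wts * dens)
    if (area <= 0) stop("density has nonpositive area")
    acc <- acc + dens / area
  }
  new_spectral_density(grid, acc / length(spectra), mean(hs))
}

#' Monte-Carlo mean spectral density of a random-graph model
#'
#' Estimates the model's spectral density at parameter `theta` and size `n`
#' as the arithmetic mean of the spectral densities of `n_mc` independent
#' draws, evaluated on `grid`. Results are cached by
#' `(model, theta, n, n_mc, seed)`.
#'
#' @param spec A [graph_model_spec()].
#' @param theta Free-parameter value.
#' @param n Graph size for the draws.
#' @param grid Evaluation abscissae.
#' @param n_mc Number of Monte-Carlo replicates (default 50).
#' @param seed Seed for the Monte-Carlo stream.
#' @return A `spectral_density` on `grid` (unit area).
#' @export
model_mean_density <- function(spec, theta, n, grid, n_mc = 50, seed = 1) {
  stopifnot(n >= 2, n_mc >= 1)
  spectra <- model_spectra(spec, theta, n, n_mc, seed)
  mean_density_of_spectra(spectra, grid)
}

# ---- KL-minimising parameter estimation ------------------------------------

#' Estimate a random-graph model parameter from one graph
#'
#' Grid search for the parameter value whose Monte-Carlo mean model
#' density is closest, in Kullback–Leibler divergence, to the graph's own
#' spectral density: `theta_hat = argmin_theta KL(rho_G | rho_M(theta))`.
#' Model graphs are drawn at the target graph's own size. The KL grid is
#' built from the union of the graph's spectrum and all Monte-Carlo
#' spectra so every density is fully supported.
#'
#' @param g A simple undirected `igraph` graph (at least 2 vertices).
#' @param spec A [graph_model_spec()] with a grid.
#' @param n_mc Monte-Carlo replicates per grid point (default 50).
#' @param seed Seed controlling the Monte-Carlo draws.
#' @param n_points Density grid resolution.
#' @param cache Optional environment for reusing Monte-Carlo spectra
#'   across calls (draws are deterministic in `(model, theta, n, n_mc,
#'   seed)` either way); by default each call uses a private cache that is
#'   released on return.
#' @return A `param_estimate` object with elements `theta_hat`, `kl_min`,
#'   `grid_kl` (tibble of theta and KL), `model`, `n_mc`, and `size`.
#' @export
estimate_parameter <- function(g, spec, n_mc = 50, seed = 1, n_points = 512,
                               cache = NULL) {
  assert_simple_graph(g)
  n <- igraph::vcount(g)
  stopifnot(n >= 2)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  sg <- graph_spectrum(g)
  mc <- lapply(spec$grid, function(th) {
    model_spectra(spec, th, n, n_mc, seed, cache = cache)
  })
  grid <- shared_grid(c(list(sg), unlist(mc, recursive = FALSE)), n_points)
  rho_g <- spectral_density(sg, grid)
  kl <- vapply(mc, function(spectra) {
    kl_divergence(rho_g, mean_density_of_spectra(spectra, grid))
  }, numeric(1))
  if (all(!is.finite(kl))) {
    stop("estimation failed: infinite KL at every grid point")
  }
  best <- which.min(kl)
  theta_chr <- vapply(spec$grid, function(t) paste(signif(t, 10), collapse = ","),
                      character(1))
  structure(
    list(
      theta_hat = spec$grid[[best]],
      kl_min = kl[best],
      grid_kl = tibble::tibble(theta = theta_chr, kl = kl),
      model = spec$model,
      n_mc = n_mc,
      size = n
    ),
    class = "param_estimate"
  )
}

#' @export
print.param_estimate <- function(x, ...) {
  cat(sprintf(
    "<param_estimate: %s, theta_hat = %s, KL = %.4g (size %d, %d MC draws)>\n",
    x$model, paste(signif(x$theta_hat, 4), collapse = ", "), x$kl_min,
    x$size, x$n_mc
  ))
  invisible(x)
}

#' Select the best-fitting random-graph model for a graph
#'
#' Runs [estimate_parameter()] under each candidate specification and
#' returns the model whose best grid point attains the smallest KL
#' divergence from the graph's spectral density.
#'
#' @param g A simple undirected `igraph` graph.
#' @param candidates List of [graph_model_spec()] objects.
#' @inheritParams estimate_parameter
#' @return A list with `model` (the winning model id), `estimate` (its
#'   `param_estimate`), and `fits` (tibble of per-candidate best KL).
#' @export
select_model <- function(g, candidates, n_mc = 50, seed = 1, n_points = 512) {
  stopifnot(length(candidates) >= 1)
  cache <- new.env(parent = emptyenv())
  fits <- lapply(candidates, function(sp) {
    tryCatch(estimate_parameter(g, sp, n_mc = n_mc, seed = seed,
                                n_points = n_points, cache = cache),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("model selection failed for every candidate")
  kl <- vapply(fits, function(f) if (is.null(f)) Inf else f$kl_min, numeric(1))
  best <- which.min(kl)
  list(
    model = fits[[best]]$model,
    estimate = fits[[best]],
    fits = tibble::tibble(
      model = vapply(candidates, `[[`, character(1), "model"),
      kl_min = kl
    )
  )
}
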