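#' Adjacency spectrum of a graph
#'
#' Eigenvalues of the 0/1 adjacency matrix, sorted in descending order.
#' For an undirected simple graph the matrix is symmetric and hollow, so
#' the eigenvalues are real, sum to zero, and their squares sum to twice
#' the edge count.
#'
#' @param g A simple undirected `igraph` graph.
#' @return Numeric vector of eigenvalues, descending.
#' @export
graph_spectrum <- function(g) {
  assert_simple_graph(g)
  a <- igraph::as_adjacency_matrix(g, type = "both", sparse = FALSE)
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  sort(ev, decreasing = TRUE)
}

#' Sturges bin count
#'
#' `ceiling(1 + log2(n))` bins for a sample of `n` values; used to fix the
#' Gaussian kernel bandwidth of the spectral density estimate.
#'
#' @param n Number of eigenvalues.
#' @return Integer bin count.
#' @export
sturges_bins <- function(n) {
  if (n < 1) stop("n must be at least 1")
  as.integer(ceiling(1 + log2(n)))
}

#' Kernel bandwidth for a spectrum
#'
#' The spectral-density bandwidth is the eigenvalue spread divided by the
#' Sturges bin count, `(lambda_1 - lambda_n) / sturges_bins(n)`. A
#' degenerate spectrum (zero spread) falls back to
#' `max(abs(lambda_1), 1) * 1e-3` so the kernel stays well defined.
#'
#' @param values Numeric eigenvalues (any order).
#' @return Positive bandwidth.
#' @export
kernel_bandwidth <- function(values) {
  stopifnot(length(values) >= 1)
  spread <- max(values) - min(values)
  if (spread <= 0) return(max(abs(values[1]), 1) * 1e-3)
  spread / sturges_bins(length(values))
}

#' Shared evaluation grid for a set of spectra
#'
#' Densities can only be compared or averaged on a common abscissa. The
#' grid is uniform with `n_points` points, extending three times the
#' largest per-spectrum bandwidth beyond the most extreme eigenvalues in
#' the collection, so every Gaussian tail is captured.
#'
#' @param spectra A list of numeric eigenvalue vectors (or a single one).
#' @param n_points Grid resolution (default 512).
#' @return Strictly increasing numeric grid of length `n_points`.
#' @export
shared_grid <- function(spectra, n_points = 512) {
  if (is.numeric(spectra)) spectra <- list(spectra)
  if (length(spectra) == 0) stop("need at least one spectrum")
  h <- max(vapply(spectra, kernel_bandwidth, numeric(1)))
  lo <- min(vapply(spectra, min, numeric(1))) - 3 * h
  hi <- max(vapply(spectra, max, numeric(1))) + 3 * h
  seq(lo, hi, length.out = n_points)
}

#' Spectral density of a graph spectrum
#'
#' Smooths the eigenvalue point masses with a Gaussian kernel of the
#' bandwidth from [kernel_bandwidth()], evaluates on `grid`, and
#' renormalises so the trapezoid-rule area equals one. The grid must cover
#' the spectrum padded by three bandwidths on each side.
#'
#' @param values Numeric eigenvalues.
#' @param grid Strictly increasing evaluation abscissae (see
#'   [shared_grid()]).
#' @param bandwidth Optional override of the automatic bandwidth.
#' @return A `spectral_density` object: list with `grid`, `density`, and
#'   `bandwidth`.
#' @export
spectral_density <- function(values, grid, bandwidth = NULL) {
  stopifnot(length(values) >= 1, length(grid) >= 2)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  h <- if (is.null(bandwidth)) kernel_bandwidth(values) else bandwidth
  slack <- 1e-8 * max(1, max(abs(values)))
  if (min(grid) > min(values) - 3 * h + slack ||
      max(grid) < max(values) + 3 * h - slack) {
    stop("grid does not cover the spectrum padded by 3 bandwidths")
  }
  dens <- rowMeans(stats::dnorm(outer(grid, values, "-"), sd = h))
  new_spectral_density(grid, dens, h)
}

new_spectral_density <- function(grid, density, bandwidth) {
  area <- trapezoid_area(grid, density)
  if (area <= 0) stop("density has nonpositive area")
  structure(
    list(grid = grid, density = density / area, bandwidth = bandwidth),
    class = "spectral_density"
  )
}

trapezoid_area <- function(grid, y) {
  sum(diff(grid) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# trapezoid quadrature weights: integrating f on the grid is sum(w * f)
trapezoid_weights <- function(grid) {
  d <- diff(grid)
  c(d / 2, 0) + c(0, d / 2)
}

#' @export
print.spectral_density <- function(x, ...) {
  cat(sprintf(
    "<spectral_density: %d grid points on [%.3g, %.3g], bandwidth %.4g>\n",
    length(x$grid), min(x$grid), max(x$grid), x$bandwidth
  ))
  invisible(x)
}

#' @method as_tibble spectral_density
#' @export
as_tibble.spectral_density <- function(x, ...) {
  tibble::tibble(lambda = x$grid, density = x$density)
}

#' Pointwise mean of spectral densities
#'
#' The centroid of a cluster of graphs is the arithmetic mean of their
#' spectral densities; linearity of the integral keeps the area at one.
#' All densities must share an identical grid.
#'
#' @param densities List of `spectral_density` objects on one grid.
#' @return A `spectral_density` on the same grid.
#' @export
mean_density <- function(densities) {
  stopifnot(length(densities) >= 1)
  g0 <- densities[[1]]$grid
  for (d in densities) {
    if (length(d$grid) != length(g0) || any(d$grid != g0)) {
      stop("all densities must share the identical grid")
    }
  }
  dens <- Reduce(`+`, lapply(densities, `[[`, "density")) / length(densities)
  new_spectral_density(g0, dens, mean(vapply(densities, `[[`, numeric(1), "bandwidth")))
}

#' Spectral densities of a graph collection on one shared grid
#'
#' Convenience wrapper: computes every spectrum, builds one common grid
#' with [shared_grid()], and returns the per-graph densities ready for
#' divergence computations or clustering.
#'
#' @param graphs List of simple undirected `igraph` graphs.
#' @param n_points Grid resolution.
#' @param rescale_by_size Divide each spectrum by its vertex count before
#'   smoothing (a normalisation that makes Erdős–Rényi graphs of different
#'   sizes comparable).
#' @return List with `grid`, `densities` (list of `spectral_density`), and
#'   `spectra`.
#' @export
graph_density_set <- function(graphs, n_points = 512, rescale_by_size = FALSE) {
  stopifnot(length(graphs) >= 1)
  spectra <- lapply(graphs, graph_spectrum)
  if (rescale_by_size) {
    spectra <- lapply(spectra, function(s) s / length(s))
  }
  grid <- shared_grid(spectra, n_points)
  densities <- lapply(spectra, spectral_density, grid = grid)
  list(grid = grid, densities = densities, spectra = spectra)
}
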