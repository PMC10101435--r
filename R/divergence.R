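# Divergences between spectral densities.
#
# Both densities are first converted to discrete probability masses on the
# shared grid (density times trapezoid weight, renormalised), so the
# Riemann-sum KL is a true discrete KL and the Gibbs inequality guarantees
# nonnegativity. Values below 1e-300 are treated as exact zeros to avoid
# underflow artefacts.

.mass_floor <- 1e-300

check_same_grid <- function(rho1, rho2) {
  if (length(rho1$grid) != length(rho2$grid) || any(rho1$grid != rho2$grid)) {
    stop("densities must be evaluated on the identical grid")
  }
}

discrete_mass <- function(rho) {
  m <- rho$density * trapezoid_weights(rho$grid)
  m[m < .mass_floor] <- 0
  m / sum(m)
}

kl_mass <- function(p, q) {
  active <- p > 0
  if (any(active & q == 0)) return(Inf)
  max(0, sum(p[active] * log(p[active] / q[active])))
}

#' Kullback-Leibler divergence between spectral densities
#'
#' `KL(rho1 | rho2)`: the Riemann-sum divergence of `rho1` from the
#' reference `rho2`, using natural logarithms. Returns `Inf` when `rho1`
#' carries mass at a grid point where `rho2` is (numerically) zero, i.e.
#' when the reference's support does not contain the target's. Grid points
#' where `rho1` is zero contribute nothing.
#'
#' @param rho1,rho2 `spectral_density` objects on the identical grid.
#' @return Nonnegative number, possibly `Inf`.
#' @export
kl_divergence <- function(rho1, rho2) {
  check_same_grid(rho1, rho2)
  kl_mass(discrete_mass(rho1), discrete_mass(rho2))
}

#' Jensen-Shannon divergence between spectral densities
#'
#' Symmetrised divergence `JS(rho1, rho2) = KL(rho1|rho_m)/2 +
#' KL(rho2|rho_m)/2` with `rho_m` the equal-weight mixture. Always finite
#' (the mixture's support contains both), bounded by `log(2)`, and zero
#' exactly when the densities coincide on the grid.
#'
#' @inheritParams kl_divergence
#' @return Value in `[0, log(2)]`.
#' @export
js_divergence <- function(rho1, rho2) {
  check_same_grid(rho1, rho2)
  p <- discrete_mass(rho1)
  q <- discrete_mass(rho2)
  m <- (p + q) / 2
  js <- kl_mass(p, m) / 2 + kl_mass(q, m) / 2
  min(js, log(2))
}

#' Square-root Jensen-Shannon distance
#'
#' `sqrt(JS)` is a true metric between densities (it satisfies the
#' triangle inequality), and is the distance the graph k-means minimises.
#'
#' @inheritParams kl_divergence
#' @return Value in `[0, sqrt(log(2))]`.
#' @export
spectral_distance <- function(rho1, rho2) {
  sqrt(js_divergence(rho1, rho2))
}

#' Pairwise square-root JS distance matrix
#'
#' @param densities List of `spectral_density` objects on one grid.
#' @return Symmetric matrix of [spectral_distance()] values with zero
#'   diagonal.
#' @export
spectral_distance_matrix <- function(densities) {
  n <- length(densities)
  for (d in densities) check_same_grid(densities[[1]], d)
  masses <- lapply(densities, discrete_mass)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- masses[[i]]
      q <- masses[[j]]
      m <- (p + q) / 2
      js <- min(kl_mass(p, m) / 2 + kl_mass(q, m) / 2, log(2))
      d[i, j] <- d[j, i] <- sqrt(js)
    }
  }
  d
}
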