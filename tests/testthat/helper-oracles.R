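# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive and share no code with the package.

# Rousseeuw silhouette by direct per-item loops.
oracle_silhouette <- function(labels, d) {
  ks <- sort(unique(labels))
  if (length(ks) < 2) return(0)
  vals <- numeric(length(labels))
  for (i in seq_along(labels)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) {
      vals[i] <- 0
      next
    }
    a <- mean(d[i, own])
    b <- Inf
    for (k in ks) {
      if (k == labels[i]) next
      b <- min(b, mean(d[i, which(labels == k)]))
    }
    vals[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(vals)
}

# Pair-counting Jaccard by exhaustive enumeration of all item pairs.
oracle_jaccard <- function(lt, lp) {
  n <- length(lt)
  n11 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      st <- lt[i] == lt[j]
      sp <- lp[i] == lp[j]
      if (st && sp) n11 <- n11 + 1
      if (st && !sp) n10 <- n10 + 1
      if (!st && sp) n01 <- n01 + 1
    }
  }
  if (n11 + n10 + n01 == 0) 1 else n11 / (n11 + n10 + n01)
}

# Eigenvalues via the characteristic polynomial (pracma) and polyroot.
oracle_spectrum <- function(adj) {
  cp <- pracma::charpoly(adj)
  ev <- polyroot(rev(cp))
  sort(Re(ev), decreasing = TRUE)
}

# A random unit-area density on a grid: mixture of a few Gaussians.
random_density <- function(grid, n_comp = 3) {
  mu <- stats::runif(n_comp, min(grid) + 1, max(grid) - 1)
  sd <- stats::runif(n_comp, 0.3, 1.5)
  w <- stats::runif(n_comp)
  w <- w / sum(w)
  dens <- Reduce(`+`, Map(function(m, s, ww) ww * stats::dnorm(grid, m, s),
                          mu, sd, w))
  netspectra:::new_spectral_density(grid, dens, 1)
}

trap_area <- function(grid, y) {
  sum(diff(grid) * (head(y, -1) + tail(y, -1)) / 2)
}

# Canonical form of a partition (labels renamed by first appearance).
canon_partition <- function(l) {
  match(l, unique(l))
}

# All set partitions of 1..n (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    m <- if (length(prefix) == 0) 0 else max(prefix)
    for (v in seq_len(m + 1)) grow(c(prefix, v))
  }
  grow(integer(0))
  out
}
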