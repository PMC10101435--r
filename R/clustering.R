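# Whole-graph clustering: k-means in square-root JS distance (same-size
# graphs) and gCEM, the model-based EM-like algorithm (any sizes).

# ---- silhouette -------------------------------------------------------------

#' Overall silhouette of a clustering
#'
#' Rousseeuw's silhouette averaged over items: per item,
#' `(b - a) / max(a, b)` with `a` the mean distance to the item's own
#' cluster and `b` the smallest mean distance to another cluster.
#' Singleton clusters contribute 0; a single-cluster labelling scores 0 by
#' convention.
#'
#' @param labels Integer cluster labels in `1..K`.
#' @param distances Symmetric distance matrix with zero diagonal.
#' @return Overall silhouette in `[-1, 1]`.
#' @export
silhouette_score <- function(labels, distances) {
  n <- length(labels)
  stopifnot(nrow(distances) == n, ncol(distances) == n)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) return(0)
  s <- vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1) return(0)
    a <- mean(distances[i, setdiff(own, i)])
    b <- min(vapply(setdiff(clusters, labels[i]), function(k) {
      mean(distances[i, labels == k])
    }, numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# ---- k-means for graphs -----------------------------------------------------

# JS divergence between two discrete mass vectors (shared support);
# incremental centroid updates can leave -1e-20-scale residues, so clamp
js_mass <- function(p, q) {
  p <- pmax(p, 0)
  q <- pmax(q, 0)
  m <- (p + q) / 2
  min(kl_mass(p, m) / 2 + kl_mass(q, m) / 2, log(2))
}

# sum of p * log(p) with the 0 log 0 = 0 convention
xlogx_sum <- function(p) {
  nz <- p > 0
  sum(p[nz] * log(p[nz]))
}

# JS via the entropy decomposition JS = (L_p + L_q)/2 - sum(m log m),
# m = (p + q)/2, with the L terms precomputed once per density — the
# clustering hot path
js_mass_fast <- function(p, q, lp, lq) {
  m <- (p + q) * 0.5
  nz <- m > 0
  js <- (lp + lq) * 0.5 - sum(m[nz] * log(m[nz]))
  if (js < 0) return(0)
  min(js, log(2))
}

#' K-means clustering of same-size graphs by spectral density
#'
#' Represents each graph by its spectral density on one shared grid and
#' runs a k-means in square-root Jensen–Shannon distance: centroids are
#' arithmetic means of member densities, and each pass reassigns graphs
#' greedily in randomised order, updating the two affected centroids
#' immediately after every move. The algorithm stops when a full pass
#' moves nothing. Because the greedy search depends on the initial
#' assignment and visiting order, the algorithm is restarted
#' `n_restarts` times and the restart with the largest overall silhouette
#' (on pairwise square-root JS distances) is returned.
#'
#' All graphs must have the same number of vertices: spectra of different
#' lengths yield densities whose differences reflect size, not structure.
#'
#' @param graphs List of simple undirected `igraph` graphs, all of one
#'   size.
#' @param k Number of clusters.
#' @param n_restarts Independent restarts (default 10).
#' @param max_iter Maximum reassignment passes per restart.
#' @param seed Optional seed making the whole run reproducible.
#' @param n_points Density grid resolution.
#' @return A `graph_kmeans` object: `labels`, `centroids` (list of
#'   `spectral_density`), `assignment_scores` (N x K matrix of distances),
#'   `silhouette`, `n_iterations`, `converged`, `objective_trace`.
#' @export
kmeans_graphs <- function(graphs, k, n_restarts = 10, max_iter = 100,
                          seed = NULL, n_points = 512) {
  n <- length(graphs)
  stopifnot(k >= 1)
  if (k > n) stop("more clusters than graphs")
  sizes <- vapply(graphs, function(g) as.integer(igraph::vcount(g)), integer(1))
  if (length(unique(sizes)) > 1) {
    stop("graphs have different vertex counts; use gcem() for mixed sizes")
  }
  ds <- graph_density_set(graphs, n_points)
  masses <- lapply(ds$densities, discrete_mass)
  pair_d <- mass_distance_matrix(masses)

  with_seed_if(seed, {
    best <- NULL
    for (restart in seq_len(n_restarts)) {
      fit <- kmeans_one_restart(masses, k, max_iter)
      fit$silhouette <- if (k == 1) 0 else silhouette_score(fit$labels, pair_d)
      if (is.null(best) || fit$silhouette > best$silhouette) best <- fit
    }
    centroid_dens <- lapply(seq_len(k), function(j) {
      mean_density(ds$densities[best$labels == j])
    })
    structure(
      list(
        labels = best$labels,
        centroids = centroid_dens,
        assignment_scores = best$scores,
        silhouette = best$silhouette,
        n_iterations = best$n_iterations,
        converged = best$converged,
        objective_trace = best$objective_trace,
        distance_matrix = pair_d,
        grid = ds$grid,
        k = k
      ),
      class = "graph_kmeans"
    )
  })
}

mass_distance_matrix <- function(masses) {
  n <- length(masses)
  d <- matrix(0, n, n)
  if (n < 2) return(d)
  l <- vapply(masses, xlogx_sum, numeric(1))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <-
        sqrt(js_mass_fast(masses[[i]], masses[[j]], l[i], l[j]))
    }
  }
  d
}

kmeans_one_restart <- function(masses, k, max_iter) {
  n <- length(masses)
  len <- length(masses[[1]])
  l_mass <- vapply(masses, xlogx_sum, numeric(1))
  labels <- sample(rep_len(seq_len(k), n))  # every cluster starts nonempty
  sums <- matrix(0, len, k)
  counts <- integer(k)
  for (i in seq_len(n)) {
    sums[, labels[i]] <- sums[, labels[i]] + masses[[i]]
    counts[labels[i]] <- counts[labels[i]] + 1L
  }
  # centroids and their entropy terms, recomputed lazily after updates
  cent <- vector("list", k)
  l_cent <- rep(NA_real_, k)
  refresh <- function(j) {
    if (is.null(cent[[j]])) {
      cent[[j]] <<- pmax(sums[, j], 0) / counts[j]
      l_cent[j] <<- xlogx_sum(cent[[j]])
    }
  }
  invalidate <- function(j) {
    cent[j] <<- list(NULL)
    l_cent[j] <<- NA_real_
  }
  dist_to <- function(i, j) {
    refresh(j)
    sqrt(js_mass_fast(masses[[i]], cent[[j]], l_mass[i], l_cent[j]))
  }

  objective <- function() {
    sum(vapply(seq_len(n), function(i) dist_to(i, labels[i]), numeric(1)))
  }
  trace <- objective()
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    moved <- 0L
    for (i in sample.int(n)) {
      d <- vapply(seq_len(k), function(j) dist_to(i, j), numeric(1))
      target <- which.min(d)  # ties resolve to the lowest index
      # move only on a strict improvement: exact ties (e.g. identical
      # graphs) would otherwise oscillate between equivalent centroids
      if (target != labels[i] && d[target] < d[labels[i]]) {
        from <- labels[i]
        sums[, from] <- sums[, from] - masses[[i]]
        counts[from] <- counts[from] - 1L
        sums[, target] <- sums[, target] + masses[[i]]
        counts[target] <- counts[target] + 1L
        invalidate(from)
        invalidate(target)
        labels[i] <- target
        moved <- moved + 1L
        if (counts[from] == 0L) {
          # repair: seed the empty cluster with the graph farthest from
          # its current centroid
          far <- which.max(vapply(seq_len(n), function(q) {
            if (counts[labels[q]] <= 1L) -Inf else dist_to(q, labels[q])
          }, numeric(1)))
          old <- labels[far]
          sums[, old] <- sums[, old] - masses[[far]]
          counts[old] <- counts[old] - 1L
          sums[, from] <- sums[, from] + masses[[far]]
          counts[from] <- counts[from] + 1L
          invalidate(old)
          invalidate(from)
          labels[far] <- from
        }
      }
    }
    trace <- c(trace, objective())
    if (moved == 0L) {
      converged <- TRUE
      break
    }
  }
  scores <- t(vapply(seq_len(n), function(i) {
    vapply(seq_len(k), function(j) dist_to(i, j), numeric(1))
  }, numeric(k)))
  if (k == 1) scores <- matrix(scores, ncol = 1)
  list(labels = labels, scores = scores, n_iterations = iter,
       converged = converged, objective_trace = trace)
}

#' @export
print.graph_kmeans <- function(x, ...) {
  cat(sprintf(
    "<graph_kmeans: %d graphs in %d clusters (sizes %s), silhouette %.3f, %d passes%s>\n",
    length(x$labels), x$k, paste(tabulate(x$labels, x$k), collapse = "/"),
    x$silhouette, x$n_iterations,
    if (x$converged) "" else ", not converged"
  ))
  invisible(x)
}

# ---- gCEM -------------------------------------------------------------------

# KL from a graph's density to a model's Monte-Carlo mean density at the
# graph's own size, on a grid covering both supports
graph_model_kl <- function(sg, spec, theta, n, n_mc, seed, n_points, cache) {
  spectra <- model_spectra(spec, theta, n, n_mc, seed, cache = cache)
  grid <- shared_grid(c(list(sg), spectra), n_points)
  rho_g <- spectral_density(sg, grid)
  kl_divergence(rho_g, mean_density_of_spectra(spectra, grid))
}

#' Model-based clustering of graphs of different sizes (gCEM)
#'
#' Graph classification expectation–maximisation. Each cluster is
#' represented by a random-graph model with parameter `theta_k`; model
#' densities are always generated at the size of the graph being scored,
#' which is what makes mixed-size collections comparable. The algorithm
#' alternates: an E-step computing per-graph cluster weights
#' `t_k(G_i)` proportional to `1 / KL(rho_Gi | rho_Mk(theta_k))`
#' (normalised over clusters), a classification step assigning each graph
#' to its highest-weight cluster, and an M-step re-estimating `theta_k` as
#' the average of the KL-minimising per-graph estimates
#' ([estimate_parameter()]) within the cluster. Iterations stop when the
#' objective `sum_i t_{k(i)}(G_i) * KL_i` changes by less than `tol`
#' relatively, or when labels repeat, or at `max_iter`.
#'
#' @param graphs List of simple undirected `igraph` graphs (sizes may
#'   differ).
#' @param k Number of clusters.
#' @param models A single [graph_model_spec()] shared by all clusters, or
#'   a list of `k` specifications (one model family per cluster).
#' @param n_mc Monte-Carlo replicates for model densities (default 50).
#' @param max_iter Maximum EM iterations.
#' @param tol Relative objective-change tolerance for convergence.
#' @param seed Optional seed for initialisation and Monte-Carlo streams.
#' @param n_points Density grid resolution.
#' @return A `graph_gcem` object: `labels`, `theta` (per-cluster
#'   estimates), `responsibilities` (N x K matrix `t`, rows sum to 1),
#'   `kl` (N x K divergences), `models`, `n_iterations`, `converged`,
#'   `objective_trace`.
#' @export
gcem <- function(graphs, k, models, n_mc = 50, max_iter = 50, tol = 1e-3,
                 seed = NULL, n_points = 512) {
  n <- length(graphs)
  stopifnot(k >= 1)
  if (k > n) stop("more clusters than graphs")
  if (inherits(models, "graph_model_spec")) models <- list(models)
  if (length(models) == 1) models <- rep(models, k)
  if (length(models) != k) stop("supply one model spec, or one per cluster")
  sizes <- vapply(graphs, function(g) as.integer(igraph::vcount(g)), integer(1))
  spectra <- lapply(graphs, graph_spectrum)

  master <- if (is.null(seed)) sample.int(2^31 - 2, 1) else as.integer(seed)
  mc_seed <- derive_seed(master, 7L)
  # call-local Monte-Carlo spectrum cache: reused across E/M steps, freed
  # when this call returns
  mc_cache <- new.env(parent = emptyenv())

  # per-graph Eq.-4 estimates depend only on (graph, model family): memoise
  # across iterations, and share across clusters with identical specs
  spec_key <- vapply(models, function(m) {
    paste(m$model, paste(names(m$fixed), unlist(m$fixed), collapse = ","),
          paste(vapply(m$grid, paste, character(1), collapse = ","),
                collapse = ";"))
  }, character(1))
  est_memo <- new.env(parent = emptyenv())
  graph_estimate <- function(i, kk) {
    key <- paste(i, spec_key[kk], sep = "@")
    hit <- est_memo[[key]]
    if (!is.null(hit)) return(hit)
    # a graph outside the model's support has infinite KL everywhere; it
    # then contributes nothing to the cluster parameter average
    est <- tryCatch(
      estimate_parameter(graphs[[i]], models[[kk]], n_mc = n_mc,
                         seed = mc_seed, n_points = n_points,
                         cache = mc_cache)$theta_hat,
      error = function(e) NA_real_
    )
    assign(key, est, envir = est_memo)
    est
  }
  m_step <- function(labels) {
    lapply(seq_len(k), function(kk) {
      members <- which(labels == kk)
      ests <- lapply(members, graph_estimate, kk = kk)
      ests <- ests[!vapply(ests, function(e) any(is.na(e)), logical(1))]
      if (length(ests) == 0) {
        # no member is representable: fall back to the grid centre
        mid <- Reduce(`+`, models[[kk]]$grid) / length(models[[kk]]$grid)
        return(theta_project(models[[kk]], mid))
      }
      theta_project(models[[kk]], Reduce(`+`, ests) / length(ests))
    })
  }
  e_step <- function(theta) {
    kl <- matrix(NA_real_, n, k)
    for (i in seq_len(n)) {
      for (kk in seq_len(k)) {
        kl[i, kk] <- graph_model_kl(spectra[[i]], models[[kk]], theta[[kk]],
                                    sizes[i], n_mc, mc_seed, n_points,
                                    cache = mc_cache)
      }
    }
    t_mat <- matrix(0, n, k)
    degenerate <- 0L
    for (i in seq_len(n)) {
      row <- kl[i, ]
      if (any(row == 0)) {
        t_mat[i, ] <- (row == 0) / sum(row == 0)
      } else if (all(!is.finite(row))) {
        t_mat[i, ] <- 1 / k  # no model supports this graph: uniform fallback
        degenerate <- degenerate + 1L
      } else {
        inv <- ifelse(is.finite(row), 1 / row, 0)
        t_mat[i, ] <- inv / sum(inv)
      }
    }
    if (degenerate > 0) {
      warning(sprintf(
        "%d graph(s) had infinite KL to every model; responsibilities set uniform",
        degenerate
      ))
    }
    list(kl = kl, t = t_mat)
  }

  with_seed_if(master, {
    labels <- sample(rep_len(seq_len(k), n))
    theta <- m_step(labels)
    trace <- numeric(0)
    converged <- FALSE
    iter <- 0L
    prev_labels <- labels
    es <- NULL
    while (iter < max_iter) {
      iter <- iter + 1L
      es <- e_step(theta)
      new_labels <- apply(es$t, 1, which.max)  # ties: lowest cluster index
      for (kk in seq_len(k)) {
        if (!any(new_labels == kk)) {
          # repair: seed the empty cluster with the least-committed graph
          cand <- which.min(apply(es$t, 1, max) +
                              ifelse(tabulate(new_labels, k)[new_labels] <= 1, Inf, 0))
          new_labels[cand] <- kk
        }
      }
      obj <- sum(vapply(seq_len(n), function(i) {
        v <- es$t[i, new_labels[i]] * es$kl[i, new_labels[i]]
        if (is.finite(v)) v else 0
      }, numeric(1)))
      trace <- c(trace, obj)
      labels_stable <- all(new_labels == prev_labels) && iter > 1
      obj_stable <- length(trace) >= 2 &&
        abs(trace[length(trace)] - trace[length(trace) - 1]) <=
          tol * max(abs(trace[length(trace) - 1]), .Machine$double.eps)
      prev_labels <- new_labels
      theta <- m_step(new_labels)
      if (labels_stable || obj_stable) {
        converged <- TRUE
        break
      }
    }
    structure(
      list(
        labels = prev_labels,
        theta = theta,
        responsibilities = es$t,
        kl = es$kl,
        models = models,
        n_iterations = iter,
        converged = converged,
        objective_trace = trace,
        k = k
      ),
      class = "graph_gcem"
    )
  })
}

#' @export
print.graph_gcem <- function(x, ...) {
  th <- vapply(x$theta, function(t) paste(signif(t, 4), collapse = ","),
               character(1))
  cat(sprintf(
    "<graph_gcem: %d graphs in %d clusters (sizes %s), theta = {%s}, %d iterations%s>\n",
    length(x$labels), x$k, paste(tabulate(x$labels, x$k), collapse = "/"),
    paste(th, collapse = ", "), x$n_iterations,
    if (x$converged) "" else ", not converged"
  ))
  invisible(x)
}
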