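#' Random-graph generators
#'
#' Five classical random-graph models used throughout the package, all
#' returning simple undirected [igraph] graphs: Erdős–Rényi (both the
#' G(n, p) and G(n, m) flavours), the 2-dimensional geometric random graph,
#' the random k-regular graph, the Watts–Strogatz small-world model, and a
#' preferential-attachment model with tunable attachment exponent.
#'
#' All generators draw from R's RNG; pass `seed` for a reproducible graph
#' without disturbing the caller's RNG state.
#'
#' @param n Number of vertices.
#' @param p Edge probability (`gen_erdos_renyi_gnp`) or per-edge rewiring
#'   probability (`gen_watts_strogatz`), in `[0, 1]`.
#' @param m Number of edges (`gen_erdos_renyi_gnm`) or edges added per new
#'   vertex (`gen_pref_attachment`).
#' @param r Connection radius; vertices are dropped uniformly in the unit
#'   square and joined when their Euclidean distance is below `r`.
#' @param k Vertex degree (`gen_k_regular`) or, for `gen_watts_strogatz`,
#'   the even number of ring-lattice neighbours (`k/2` on each side).
#' @param ps Attachment exponent: a new vertex picks targets with
#'   probability proportional to `degree^ps`.
#' @param seed Optional integer seed for a self-contained draw.
#' @return An undirected simple `igraph` graph with `n` vertices.
#' @name graph_generators
NULL

# Edge-matrix cores of the generators. The public gen_* functions wrap
# them into igraph objects; the Monte-Carlo model-spectrum path consumes
# the edge matrices directly (see model_spectra) to skip graph
# construction it does not need. All return canonical (i < j) matrices.

er_gnp_edges <- function(n, p) {
  pairs <- all_pairs(n)
  pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
}

er_gnm_edges <- function(n, m) {
  pairs <- all_pairs(n)
  pairs[sample.int(nrow(pairs), m), , drop = FALSE]
}

geometric_edges <- function(n, r) {
  xy <- cbind(stats::runif(n), stats::runif(n))
  d <- as.matrix(stats::dist(xy))
  which(upper.tri(d) & d < r, arr.ind = TRUE)
}

#' @rdname graph_generators
#' @export
gen_erdos_renyi_gnp <- function(n, p, seed = NULL) {
  stopifnot(n >= 1, length(p) == 1, p >= 0, p <= 1)
  with_seed_if(seed, make_graph_from_edges(n, er_gnp_edges(n, p), validated = TRUE))
}

#' @rdname graph_generators
#' @export
gen_erdos_renyi_gnm <- function(n, m, seed = NULL) {
  n_possible <- choose(n, 2)
  stopifnot(n >= 1, m >= 0)
  if (m > n_possible) {
    stop(sprintf("m = %d exceeds the %d possible edges", m, n_possible))
  }
  with_seed_if(seed, make_graph_from_edges(n, er_gnm_edges(n, m), validated = TRUE))
}

#' @rdname graph_generators
#' @export
gen_geometric <- function(n, r, seed = NULL) {
  stopifnot(n >= 1, r >= 0)
  with_seed_if(seed, make_graph_from_edges(n, geometric_edges(n, r), validated = TRUE))
}

#' @rdname graph_generators
#' @export
gen_k_regular <- function(n, k, seed = NULL) {
  stopifnot(n >= 1, k >= 0)
  if (k >= n) stop("k must be smaller than n")
  if ((n * k) %% 2 != 0) stop("n * k must be even: no k-regular graph exists")
  if (k == 0) return(igraph::make_empty_graph(n, directed = FALSE))
  # degree-constrained trial-and-error sampling; a naive whole-pairing
  # rejection has acceptance probability ~ exp(-(k^2 - 1)/4) and is
  # unusable beyond k ~ 4, so the draw is delegated to igraph's k-regular
  # sampler (deterministic under R's RNG)
  with_seed_if(seed, {
    g <- igraph::sample_k_regular(n, k)
    assert_simple_graph(g)
    g
  })
}

#' @rdname graph_generators
#' @export
gen_watts_strogatz <- function(n, k, p, seed = NULL) {
  stopifnot(n >= 1, k > 0, k < n, p >= 0, p <= 1)
  if (k %% 2 != 0) stop("k must be even (k/2 lattice neighbours per side)")
  with_seed_if(seed, make_graph_from_edges(n, ws_edges(n, k, p), validated = TRUE))
}

ws_edges <- function(n, k, p) {
  adj <- matrix(FALSE, n, n)
  half <- k / 2
  for (off in seq_len(half)) {
    j <- ((seq_len(n) + off - 1L) %% n) + 1L
    adj[cbind(seq_len(n), j)] <- TRUE
    adj[cbind(j, seq_len(n))] <- TRUE
  }
  if (p > 0) {
    # scan lattice edges in canonical (vertex, offset) order so a fixed
    # seed reproduces the same rewiring; all Bernoulli draws up front
    flags <- stats::runif(n * half) < p
    fi <- 0L
    for (i in seq_len(n)) {
      for (off in seq_len(half)) {
        fi <- fi + 1L
        if (!flags[fi]) next
        j <- ((i + off - 1L) %% n) + 1L
        candidates <- which(!adj[i, ] & seq_len(n) != i & seq_len(n) != j)
        if (length(candidates) == 0) next  # vertex saturated, keep edge
        l <- candidates[sample.int(length(candidates), 1)]
        adj[i, j] <- adj[j, i] <- FALSE
        adj[i, l] <- adj[l, i] <- TRUE
      }
    }
  }
  which(upper.tri(adj) & adj, arr.ind = TRUE)
}

#' @rdname graph_generators
#' @export
gen_pref_attachment <- function(n, m, ps, seed = NULL) {
  stopifnot(n >= 1, m >= 1, is.numeric(ps), length(ps) == 1)
  if (m > n) stop("m must not exceed n")
  with_seed_if(seed, make_graph_from_edges(n, pa_edges(n, m, ps), validated = TRUE))
}

pa_edges <- function(n, m, ps) {
  edges <- all_pairs(m)
  deg <- integer(n)
  if (m >= 2) deg[seq_len(m)] <- m - 1L
  if (n > m) {
    new_edges <- vector("list", n - m)
    for (v in (m + 1L):n) {
      existing <- seq_len(v - 1L)
      w <- deg[existing]^ps
      # degenerate only when m = 1 (isolated seed vertex): fall back to
      # uniform attachment for that step
      if (!any(w > 0) || any(!is.finite(w))) w <- rep(1, length(existing))
      targets <- existing[sample.int(length(existing), m, prob = w)]
      new_edges[[v - m]] <- cbind(targets, v)
      deg[targets] <- deg[targets] + 1L
      deg[v] <- m
    }
    edges <- rbind(edges, do.call(rbind, new_edges))
  }
  edges
}

#' Degree-preserving Markov edge rewiring
#'
#' Randomises a graph's wiring while conserving its size, edge count, and
#' exact degree sequence by repeated double-edge swaps: two edges
#' `(i1, j1)` and `(i2, j2)` with four distinct endpoints are replaced by
#' `(i1, j2)` and `(i2, j1)` whenever neither replacement edge already
#' exists. Proposals that would create a loop or duplicate edge are
#' rejected and redrawn.
#'
#' @param g A simple undirected `igraph` graph.
#' @param n_swaps Number of successful swaps to apply.
#' @param seed Optional integer seed.
#' @param max_proposals Proposal budget before declaring the graph too
#'   constrained; defaults to `100 * n_swaps`.
#' @return The rewired graph (same vertex count, edge count, and degree
#'   sequence as `g`).
#' @export
markov_rewire <- function(g, n_swaps, seed = NULL, max_proposals = NULL) {
  assert_simple_graph(g)
  stopifnot(n_swaps >= 0)
  if (n_swaps == 0) return(g)
  if (is.null(max_proposals)) max_proposals <- 100 * n_swaps
  n <- igraph::vcount(g)
  edges <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(edges) < 2) stop("graph has fewer than 2 edges: no swap possible")
  adj <- matrix(FALSE, n, n)
  adj[edges] <- TRUE
  adj[edges[, c(2, 1)]] <- TRUE
  n_edges <- nrow(edges)
  with_seed_if(seed, {
    done <- 0L
    proposals <- 0L
    chunk <- 0L
    chunk_size <- 512L
    while (done < n_swaps) {
      if (proposals >= max_proposals) {
        stop(sprintf(
          "rewiring stalled after %d proposals (%d of %d swaps completed)",
          proposals, done, n_swaps
        ))
      }
      if (chunk == 0L) {
        # draw proposal randomness in blocks: edge indices and the
        # orientation flips that make both swap patterns reachable
        pick1 <- sample.int(n_edges, chunk_size, replace = TRUE)
        pick2 <- sample.int(n_edges, chunk_size, replace = TRUE)
        flip <- matrix(stats::runif(2 * chunk_size) < 0.5, ncol = 2)
        chunk <- chunk_size
      }
      q <- chunk_size - chunk + 1L
      chunk <- chunk - 1L
      proposals <- proposals + 1L
      if (pick1[q] == pick2[q]) next
      e1 <- edges[pick1[q], ]
      e2 <- edges[pick2[q], ]
      if (flip[q, 1]) e1 <- e1[c(2, 1)]
      if (flip[q, 2]) e2 <- e2[c(2, 1)]
      if (e1[1] == e2[1] || e1[1] == e2[2] || e1[2] == e2[1] || e1[2] == e2[2]) next
      if (adj[e1[1], e2[2]] || adj[e2[1], e1[2]]) next
      adj[e1[1], e1[2]] <- adj[e1[2], e1[1]] <- FALSE
      adj[e2[1], e2[2]] <- adj[e2[2], e2[1]] <- FALSE
      adj[e1[1], e2[2]] <- adj[e2[2], e1[1]] <- TRUE
      adj[e2[1], e1[2]] <- adj[e1[2], e2[1]] <- TRUE
      edges[pick1[q], ] <- c(e1[1], e2[2])
      edges[pick2[q], ] <- c(e2[1], e1[2])
      done <- done + 1L
    }
    make_graph_from_edges(n, edges)
  })
}
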