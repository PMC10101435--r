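# internal helpers shared across modules

# Run `code` under a temporary RNG seed when `seed` is non-NULL, otherwise
# use the current RNG stream. Keeps all randomness caller-controllable
# without touching global state. Hand-rolled save/restore: this sits on
# the hot path of every generator call and must stay cheap.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed below 2^31, derived from a master seed and a
# small set of mixing values (used for Monte-Carlo streams keyed by
# (theta, size) and for per-restart / per-repetition streams).
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) {
    # scale so non-integer theta values (e.g. p = 0.25) mix distinctly
    v <- abs(as.numeric(p)) * 1e6
    h <- (h * 31 + (floor(v) %% 1000003)) %% 2147483629
  }
  as.integer(h %% 2147483629) + 1L
}

# All unordered vertex pairs of 1..n as a 2-column matrix (i < j).
all_pairs <- function(n) {
  if (n < 2) return(matrix(integer(0), ncol = 2))
  cbind(rep.int(seq_len(n - 1L), (n - 1L):1L),
        sequence((n - 1L):1L, from = 2:n))
}

# Dense symmetric 0/1 adjacency matrix from a canonical edge matrix.
adjacency_from_edges <- function(n, edges) {
  a <- matrix(0, n, n)
  if (!is.null(edges) && nrow(edges) > 0) {
    a[edges] <- 1
    a[edges[, c(2, 1), drop = FALSE]] <- 1
  }
  a
}

# Descending eigenvalues straight from an edge matrix — the Monte-Carlo
# model-spectrum hot path, which never needs an igraph object.
spectrum_from_edges <- function(n, edges) {
  ev <- eigen(adjacency_from_edges(n, edges), symmetric = TRUE,
              only.values = TRUE)$values
  sort(ev, decreasing = TRUE)
}

# Build an undirected simple igraph from an edge matrix, enforcing the
# package-wide graph invariants. `validated = TRUE` skips the checks for
# the package's own generators, whose edge matrices are canonical by
# construction.
make_graph_from_edges <- function(n, edges, validated = FALSE) {
  stopifnot(n >= 1)
  if (is.null(edges) || nrow(edges) == 0) {
    return(igraph::make_empty_graph(n, directed = FALSE))
  }
  if (!validated) {
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    if (anyDuplicated(edges)) stop("duplicate edges are not allowed")
    if (any(edges < 1) || any(edges > n)) stop("vertex id out of range")
  }
  igraph::graph_from_edgelist(edges, directed = FALSE) |>
    igraph::add_vertices(nv = max(0, n - max(edges)))
}

assert_simple_graph <- function(g, arg = "g") {
  if (!igraph::is_igraph(g)) stop(sprintf("`%s` must be an igraph object", arg))
  if (igraph::is_directed(g)) stop(sprintf("`%s` must be undirected", arg))
  if (any(igraph::which_loop(g)) || any(igraph::which_multiple(g))) {
    stop(sprintf("`%s` must be simple (no loops or multi-edges)", arg))
  }
  invisible(g)
}
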