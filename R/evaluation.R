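#' Pair-counting Jaccard index between two partitions
#'
#' Over all item pairs, `J = n11 / (n11 + n10 + n01)`: `n11` pairs
#' co-clustered in both partitions, `n10`/`n01` pairs co-clustered in
#' exactly one. Invariant to relabelling of either partition; equals 1
#' exactly when the partitions agree up to label names. For the package's
#' standard two-cluster design of 10 + 10 graphs, labels that are correct
#' only half the time score about 0.32 — the chance floor quoted alongside
#' clustering results.
#'
#' @param labels_true,labels_pred Equal-length label vectors (any atomic
#'   type).
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard_index <- function(labels_true, labels_pred) {
  n <- length(labels_true)
  if (length(labels_pred) != n) stop("label vectors must have equal length")
  if (n < 2) stop("need at least 2 items")
  tab <- table(labels_true, labels_pred)
  n11 <- sum(choose(tab, 2))
  same_true <- sum(choose(rowSums(tab), 2))
  same_pred <- sum(choose(colSums(tab), 2))
  denom <- same_true + same_pred - n11
  if (denom == 0) return(1)  # both partitions all-singleton: identical
  n11 / denom
}

# ---- simulation scenarios ---------------------------------------------------

scenario_catalog <- function() {
  list(
    a = list(
      label = "three Erdos-Renyi clusters, p = 0.2 / 0.25 / 0.3",
      generators = lapply(c(0.2, 0.25, 0.3), function(p) {
        function(n, seed) gen_erdos_renyi_gnp(n, p, seed)
      }),
      models = list(graph_model_spec("erdos_renyi_gnp",
                                     grid = seq(0.05, 0.5, by = 0.025)))
    ),
    b = list(
      label = "three geometric clusters, r = 0.15 / 0.25 / 0.35",
      generators = lapply(c(0.15, 0.25, 0.35), function(r) {
        function(n, seed) gen_geometric(n, r, seed)
      }),
      models = list(graph_model_spec("geometric",
                                     grid = seq(0.05, 0.5, by = 0.05)))
    ),
    c = list(
      label = "three k-regular clusters, k = 2 / 4 / 6",
      generators = lapply(c(2, 4, 6), function(k) {
        function(n, seed) gen_k_regular(n, k, seed)
      }),
      models = list(graph_model_spec("k_regular", grid = seq(2, 8, by = 2)))
    ),
    d = list(
      label = "three Watts-Strogatz clusters, p = 0.05 / 0.10 / 0.15, k = 16",
      generators = lapply(c(0.05, 0.10, 0.15), function(p) {
        function(n, seed) gen_watts_strogatz(n, 16, p, seed)
      }),
      models = list(graph_model_spec("watts_strogatz",
                                     grid = seq(0, 0.5, by = 0.025),
                                     fixed = list(k = 16)))
    ),
    e = list(
      label = "three preferential-attachment clusters, ps = 1 / 2 / 3, m = 10",
      generators = lapply(c(1, 2, 3), function(ps) {
        function(n, seed) gen_pref_attachment(n, 10, ps, seed)
      }),
      models = list(graph_model_spec("preferential_attachment",
                                     grid = seq(0.5, 3.5, by = 0.25),
                                     fixed = list(m = 10)))
    ),
    f = list(
      label = "mixed models: geometric r = 0.1, PA ps = 1.5 m = 10, k-regular k = 2",
      generators = list(
        function(n, seed) gen_geometric(n, 0.1, seed),
        function(n, seed) gen_pref_attachment(n, 10, 1.5, seed),
        function(n, seed) gen_k_regular(n, 2, seed)
      ),
      models = list(
        graph_model_spec("geometric", grid = seq(0.05, 0.5, by = 0.05)),
        graph_model_spec("preferential_attachment",
                         grid = seq(0.5, 3.5, by = 0.25), fixed = list(m = 10)),
        graph_model_spec("k_regular", grid = seq(2, 8, by = 2))
      )
    )
  )
}

#' Run one published simulation scenario
#'
#' Three families of benchmark scenarios exercise the two clustering
#' algorithms:
#'
#' * `sim1a`–`sim1f`: three clusters of 10 same-size graphs each (the five
#'   model families with parameter triplets, plus one mixed-model
#'   scenario), clustered with [kmeans_graphs()] at a fixed size
#'   `n_vertices`.
#' * `sim2a`: 10 Watts–Strogatz (`k = 20`, rewiring probability from the
#'   `sweep`) vs 10 Erdős–Rényi `G(n, m = 1000)` graphs at `n = 100` —
#'   same size and edge count; clustered with [kmeans_graphs()].
#' * `sim2b`: 10 ring lattices (`WS(p = 0, k = 20)`) perturbed with a
#'   swept number of degree-preserving edge swaps vs 10 random 20-regular
#'   graphs at `n = 100` — same size, edge count, and degree sequence.
#' * `sim3a`–`sim3f`: the `sim1` scenarios with each graph's size drawn
#'   uniformly from `size_range`, clustered with [gcem()].
#'
#' @param scenario_id One of `"sim1a"`..`"sim1f"`, `"sim2a"`, `"sim2b"`,
#'   `"sim3a"`..`"sim3f"`.
#' @param n_repetitions Independent repetitions per condition.
#' @param n_vertices Graph size for `sim1`/`sim2` scenarios.
#' @param graphs_per_cluster Graphs per true cluster (default 10).
#' @param sweep Sweep values for `sim2` (defaults: `p` in `seq(0, 1, 0.1)`
#'   for `sim2a`; swaps in `seq(0, 1000, 100)` for `sim2b`). Ignored
#'   elsewhere.
#' @param size_range Vertex-count range for `sim3` scenarios.
#' @param n_restarts K-means restarts.
#' @param n_mc Monte-Carlo replicates for `sim3`'s gCEM.
#' @param seed Master seed; every repetition derives its own stream.
#' @param n_points Density grid resolution.
#' @return A `scenario_result`: tibble of per-repetition Jaccard indices
#'   (`sweep`, `repetition`, `jaccard`) with the scenario id attached;
#'   `summary()`/[glance()] give means and normal-approximation 95%
#'   confidence half-widths.
#' @export
run_scenario <- function(scenario_id, n_repetitions = 20, n_vertices = 100,
                         graphs_per_cluster = 10, sweep = NULL,
                         size_range = c(30, 120), n_restarts = 10, n_mc = 50,
                         seed = 1, n_points = 512) {
  stopifnot(grepl("^sim[123][a-f]?$", scenario_id))
  sim <- substr(scenario_id, 1, 4)
  family <- substr(scenario_id, 5, 5)
  rows <- list()

  if (sim %in% c("sim1", "sim3")) {
    sc <- scenario_catalog()[[substr(scenario_id, 5, 5)]]
    if (is.null(sc)) stop("unknown scenario: ", scenario_id)
    k <- length(sc$generators)
    truth <- rep(seq_len(k), each = graphs_per_cluster)
    for (r in seq_len(n_repetitions)) {
      rs <- derive_seed(seed, r)
      sizes <- if (sim == "sim3") {
        with_seed_if(rs, sample(size_range[1]:size_range[2],
                                length(truth), replace = TRUE))
      } else {
        rep(n_vertices, length(truth))
      }
      graphs <- lapply(seq_along(truth), function(i) {
        sc$generators[[truth[i]]](sizes[i], derive_seed(rs, i))
      })
      fit <- if (sim == "sim1") {
        kmeans_graphs(graphs, k, n_restarts = n_restarts,
                      seed = derive_seed(rs, 999), n_points = n_points)
      } else {
        models <- if (length(sc$models) == 1) sc$models[[1]] else sc$models
        gcem(graphs, k, models, n_mc = n_mc,
             seed = derive_seed(rs, 999), n_points = n_points)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        sweep = NA_real_, repetition = r,
        jaccard = jaccard_index(truth, fit$labels)
      )
    }
  } else if (sim == "sim2") {
    stopifnot(family %in% c("a", "b"))
    if (is.null(sweep)) {
      sweep <- if (family == "a") seq(0, 1, by = 0.1) else seq(0, 1000, by = 100)
    }
    truth <- rep(1:2, each = graphs_per_cluster)
    m_edges <- n_vertices * 20 / 2
    for (s_idx in seq_along(sweep)) {
      s <- sweep[s_idx]
      for (r in seq_len(n_repetitions)) {
        rs <- derive_seed(seed, s_idx, r)
        graphs <- lapply(seq_along(truth), function(i) {
          gi_seed <- derive_seed(rs, i)
          if (truth[i] == 1) {
            if (family == "a") {
              gen_watts_strogatz(n_vertices, 20, s, gi_seed)
            } else {
              g0 <- gen_watts_strogatz(n_vertices, 20, 0, gi_seed)
              if (s > 0) markov_rewire(g0, s, derive_seed(gi_seed, 2)) else g0
            }
          } else {
            if (family == "a") {
              gen_erdos_renyi_gnm(n_vertices, m_edges, gi_seed)
            } else {
              gen_k_regular(n_vertices, 20, gi_seed)
            }
          }
        })
        fit <- kmeans_graphs(graphs, 2, n_restarts = n_restarts,
                             seed = derive_seed(rs, 999), n_points = n_points)
        rows[[length(rows) + 1]] <- tibble::tibble(
          sweep = s, repetition = r,
          jaccard = jaccard_index(truth, fit$labels)
        )
      }
    }
  } else {
    stop("unknown scenario: ", scenario_id)
  }

  out <- dplyr::bind_rows(rows)
  out$scenario <- scenario_id
  structure(out[, c("scenario", "sweep", "repetition", "jaccard")],
            class = c("scenario_result", class(out)))
}

#' @export
summary.scenario_result <- function(object, ...) {
  grp <- dplyr::group_by(tibble::as_tibble(object), .data$scenario, .data$sweep)
  dplyr::summarise(
    grp,
    n = dplyr::n(),
    mean_jaccard = mean(.data$jaccard),
    ci_half_width = 1.96 * stats::sd(.data$jaccard) / sqrt(dplyr::n()),
    .groups = "drop"
  )
}
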