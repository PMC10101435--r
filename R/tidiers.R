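# broom-style tidiers and ggplot2 autoplot methods for result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a graph k-means fit
#'
#' One row per graph: its cluster label, the square-root JS distance to
#' each centroid, and the distance to its own centroid.
#'
#' @param x A `graph_kmeans` object.
#' @param ... Unused.
#' @return A tibble with columns `graph`, `cluster`, `distance`, and one
#'   `dist_to_<k>` column per cluster.
#' @export
tidy.graph_kmeans <- function(x, ...) {
  d <- x$assignment_scores
  colnames(d) <- paste0("dist_to_", seq_len(ncol(d)))
  tibble::tibble(
    graph = seq_along(x$labels),
    cluster = x$labels,
    distance = d[cbind(seq_along(x$labels), x$labels)]
  ) |>
    dplyr::bind_cols(tibble::as_tibble(d))
}

#' @rdname tidy.graph_kmeans
#' @export
glance.graph_kmeans <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n = length(x$labels),
    silhouette = x$silhouette,
    n_iterations = x$n_iterations,
    converged = x$converged,
    objective = x$objective_trace[length(x$objective_trace)]
  )
}

#' Tidy a gCEM fit
#'
#' One row per graph: its cluster, the cluster responsibilities `t_k`, and
#' the KL divergence to the assigned cluster's model density.
#'
#' @param x A `graph_gcem` object.
#' @param ... Unused.
#' @return A tibble with columns `graph`, `cluster`, `kl`, and one
#'   `t_<k>` column per cluster.
#' @export
tidy.graph_gcem <- function(x, ...) {
  t_mat <- x$responsibilities
  colnames(t_mat) <- paste0("t_", seq_len(ncol(t_mat)))
  tibble::tibble(
    graph = seq_along(x$labels),
    cluster = x$labels,
    kl = x$kl[cbind(seq_along(x$labels), x$labels)]
  ) |>
    dplyr::bind_cols(tibble::as_tibble(t_mat))
}

#' @rdname tidy.graph_gcem
#' @export
glance.graph_gcem <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n = length(x$labels),
    n_iterations = x$n_iterations,
    converged = x$converged,
    objective = x$objective_trace[length(x$objective_trace)],
    theta = paste(vapply(x$theta, function(t) {
      paste(signif(t, 4), collapse = ",")
    }, character(1)), collapse = "; ")
  )
}

#' Tidy a parameter estimate
#'
#' @param x A `param_estimate` object.
#' @param ... Unused.
#' @return The KL profile over the search grid as a tibble
#'   (`theta`, `kl`).
#' @export
tidy.param_estimate <- function(x, ...) {
  x$grid_kl
}

#' @rdname tidy.param_estimate
#' @export
glance.param_estimate <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    theta_hat = paste(signif(x$theta_hat, 6), collapse = ","),
    kl_min = x$kl_min,
    n_mc = x$n_mc,
    size = x$size
  )
}

#' @rdname run_scenario
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @export
glance.scenario_result <- function(x, ...) {
  summary(x)
}

# ---- autoplot methods -------------------------------------------------------

#' Plot a spectral density
#'
#' @param object A `spectral_density`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectral_density <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$lambda, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(lambda), y = expression(rho(lambda))) +
    ggplot2::theme_minimal()
}

#' Plot cluster centroids of a graph k-means fit
#'
#' @param object A `graph_kmeans`.
#' @param ... Unused.
#' @return A ggplot of the centroid spectral densities.
#' @export
autoplot.graph_kmeans <- function(object, ...) {
  df <- purrr::imap_dfr(object$centroids, function(cen, k) {
    tibble::tibble(cluster = factor(k), lambda = cen$grid, density = cen$density)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda, y = .data$density,
                                   colour = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(lambda), y = expression(rho(lambda)),
                  colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot the KL profile of a parameter estimate
#'
#' @param object A `param_estimate`.
#' @param ... Unused.
#' @return A ggplot of KL against the candidate parameter, with the
#'   minimiser marked.
#' @export
autoplot.param_estimate <- function(object, ...) {
  df <- object$grid_kl
  df$theta_num <- suppressWarnings(as.numeric(df$theta))
  if (any(is.na(df$theta_num))) {
    df$theta_num <- seq_len(nrow(df))
  }
  ggplot2::ggplot(df[is.finite(df$kl), ],
                  ggplot2::aes(x = .data$theta_num, y = .data$kl)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(
      xintercept = suppressWarnings(as.numeric(paste(object$theta_hat,
                                                     collapse = ","))),
      linetype = "dashed"
    ) +
    ggplot2::labs(x = "theta", y = "KL divergence") +
    ggplot2::theme_minimal()
}

#' Plot per-condition mean Jaccard of a scenario run
#'
#' @param object A `scenario_result`.
#' @param ... Unused.
#' @return A ggplot: mean Jaccard with a 95% confidence ribbon across the
#'   sweep (or a single summary point for un-swept scenarios).
#' @export
autoplot.scenario_result <- function(object, ...) {
  s <- summary(object)
  if (all(is.na(s$sweep))) s$sweep <- 0
  ggplot2::ggplot(s, ggplot2::aes(x = .data$sweep, y = .data$mean_jaccard)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(0, .data$mean_jaccard - .data$ci_half_width),
                   ymax = pmin(1, .data$mean_jaccard + .data$ci_half_width)),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "sweep value", y = "mean Jaccard index") +
    ggplot2::theme_minimal()
}
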