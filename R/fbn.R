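# Functional-network pipeline: thresholded correlation graphs from
# windowed multichannel signals, clustering of the graph sequence, and
# moving-average state-transition detection.

#' Thresholded Pearson-correlation graph of a signal window
#'
#' One vertex per channel; an edge joins channels whose Pearson
#' correlation within the window strictly exceeds `cutoff`. The diagonal
#' is ignored (no self-loops).
#'
#' @param window Numeric matrix, channels in rows, samples in columns (at
#'   least 2 channels and 3 samples).
#' @param cutoff Correlation threshold (default 0.5, strict `>`).
#' @return A simple undirected `igraph` graph with one vertex per channel.
#' @export
correlation_graph <- function(window, cutoff = 0.5) {
  window <- as.matrix(window)
  if (nrow(window) < 2 || ncol(window) < 3) {
    stop("window needs at least 2 channels and 3 samples")
  }
  v <- apply(window, 1, stats::var)
  if (any(v == 0)) {
    stop("zero-variance channel(s): ", paste(which(v == 0), collapse = ", "))
  }
  r <- stats::cor(t(window))
  idx <- which(upper.tri(r) & r > cutoff, arr.ind = TRUE)
  make_graph_from_edges(nrow(window), idx)
}

#' Split a multichannel signal into windows
#'
#' @param signals Numeric matrix, channels in rows, samples in columns.
#' @param window_len Window length in samples.
#' @param stride Offset between consecutive window starts (default:
#'   non-overlapping, `window_len`).
#' @return A tibble with one row per window: `window` (index), `start`
#'   (first sample, 1-based), and `data` (list column of channel-by-sample
#'   matrices).
#' @export
window_stream <- function(signals, window_len, stride = window_len) {
  signals <- as.matrix(signals)
  if (window_len > ncol(signals)) stop("window_len exceeds the sample count")
  stopifnot(stride >= 1)
  starts <- seq(1, ncol(signals) - window_len + 1, by = stride)
  tibble::tibble(
    window = seq_along(starts),
    start = starts,
    data = lapply(starts, function(s) signals[, s:(s + window_len - 1), drop = FALSE])
  )
}

#' Detect a state transition in a binary label series
#'
#' Computes a centered moving average of `window` labels and reports the
#' center of the first window whose mean crosses 0.5: below 0.5 for
#' `direction = "falling"` (e.g. loss of consciousness in an
#' awake/anesthetized series) or above 0.5 for `direction = "rising"`
#' (recovery). Windows are only evaluated where they fit entirely inside
#' the series (no padding at the edges).
#'
#' @param states Numeric/integer vector of 0/1 labels.
#' @param window Moving-average width in points (default 50).
#' @param direction `"falling"` or `"rising"`.
#' @return The 1-based center index of the first crossing window, or `NA`
#'   if the average never crosses.
#' @export
detect_transition <- function(states, window = 50, direction = c("falling", "rising")) {
  direction <- match.arg(direction)
  stopifnot(all(states %in% c(0, 1)))
  n <- length(states)
  if (n < window) stop("series shorter than the moving-average window")
  # exact integer window sums: a window holding exactly window/2 ones must
  # not cross in either direction, which floating-point means can botch
  cs <- c(0, cumsum(states))
  win_sum <- cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]
  hit <- if (direction == "falling") {
    which(2 * win_sum < window)
  } else {
    which(2 * win_sum > window)
  }
  if (length(hit) == 0) return(NA_integer_)
  start <- hit[1]
  as.integer(start + floor(window / 2))
}

#' Synthetic two-state multichannel signals
#'
#' A controllable stand-in for multichannel electrophysiology recordings:
#' every channel is a shared latent signal scaled by a coupling factor
#' plus independent Gaussian noise, and the coupling switches between
#' `coupling_high` and `coupling_low` (starting high) at the given sample
#' indices. High-coupling segments produce strongly correlated channels —
#' dense correlation graphs — and low-coupling segments nearly independent
#' ones, emulating an awake-to-anesthetized connectivity change. Purely
#' synthetic: amplitudes, spectra, and artefacts of real recordings are
#' not modelled.
#'
#' @param n_channels Number of channels (rows).
#' @param n_samples Number of samples (columns).
#' @param change_points Sorted sample indices where the coupling state
#'   toggles.
#' @param coupling_high,coupling_low Coupling factors in `[0, 1]`.
#' @param noise_sd Standard deviation of the per-channel noise.
#' @param seed Optional seed.
#' @return Numeric matrix `n_channels x n_samples`, with the per-sample
#'   coupling state (1 = high) attached as attribute `"state"`.
#' @export
synthetic_two_state_signals <- function(n_channels, n_samples, change_points,
                                        coupling_high = 0.9,
                                        coupling_low = 0.1,
                                        noise_sd = 0.5, seed = NULL) {
  stopifnot(
    n_channels >= 2, n_samples >= 3,
    coupling_high >= 0, coupling_high <= 1,
    coupling_low >= 0, coupling_low <= 1,
    !is.unsorted(change_points)
  )
  if (length(change_points) > 0) {
    stopifnot(all(change_points >= 1), all(change_points <= n_samples))
  }
  with_seed_if(seed, {
    latent <- stats::rnorm(n_samples)
    state <- integer(n_samples)
    current <- 1L
    bounds <- c(1, change_points, n_samples + 1)
    for (b in seq_len(length(bounds) - 1)) {
      state[bounds[b]:(bounds[b + 1] - 1)] <- current
      current <- 1L - current
    }
    coupling <- ifelse(state == 1L, coupling_high, coupling_low)
    x <- matrix(stats::rnorm(n_channels * n_samples, sd = noise_sd),
                nrow = n_channels)
    x <- x + matrix(coupling * latent, nrow = n_channels,
                    ncol = n_samples, byrow = TRUE)
    attr(x, "state") <- state
    x
  })
}

#' Cluster a windowed signal into a binary state series
#'
#' End-to-end path from a multichannel signal to an awake/anesthetized-style
#' label series: window the signal, build one thresholded correlation
#' graph per window, cluster the graphs with [kmeans_graphs()] (`K = 2`),
#' and orient the cluster labels so that the majority state of the first
#' `orient_by` windows is called 1 (recordings are assumed to start in the
#' state labelled 1, e.g. awake).
#'
#' @param signals Numeric matrix, channels in rows.
#' @param window_len,stride Windowing parameters (see [window_stream()]).
#' @param cutoff Correlation threshold for [correlation_graph()].
#' @param n_restarts K-means restarts.
#' @param orient_by Number of leading windows used to orient the labels
#'   (default: the transition-detection window, 50).
#' @param seed Optional seed.
#' @param n_points Density grid resolution.
#' @return A tibble with one row per window: `window`, `start`, `state`
#'   (0/1), plus the `graph_kmeans` fit as attribute `"fit"`.
#' @export
fbn_state_series <- function(signals, window_len, stride = window_len,
                             cutoff = 0.5, n_restarts = 10, orient_by = 50,
                             seed = NULL, n_points = 512) {
  ws <- window_stream(signals, window_len, stride)
  graphs <- lapply(ws$data, correlation_graph, cutoff = cutoff)
  fit <- kmeans_graphs(graphs, 2, n_restarts = n_restarts, seed = seed,
                       n_points = n_points)
  head_n <- min(orient_by, nrow(ws))
  lead <- fit$labels[seq_len(head_n)]
  state1 <- as.integer(names(which.max(table(lead))))
  out <- tibble::tibble(
    window = ws$window,
    start = ws$start,
    state = as.integer(fit$labels == state1)
  )
  attr(out, "fit") <- fit
  out
}
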