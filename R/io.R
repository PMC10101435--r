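# Readers and writers for graphs and result objects.

#' Read a graph from a file
#'
#' Supported formats: `edgelist` (whitespace-separated integer pairs, one
#' edge per line, `#` comments), `adjacency` (square whitespace-separated
#' 0/1 matrix; symmetrised, self-loops dropped with a warning), `graphml`,
#' and `mtx` (Matrix Market pattern/coordinate adjacency).
#'
#' @param path File path.
#' @param format One of `"edgelist"`, `"adjacency"`, `"graphml"`, `"mtx"`;
#'   default guesses from the file extension (`.graphml`, `.mtx`,
#'   otherwise edge list).
#' @param index_base 0 or 1: the vertex-id convention of an edge-list file
#'   (default 0, the package's on-disk convention).
#' @param n_vertices Optional vertex count for edge lists whose highest id
#'   is not the last vertex (isolated trailing vertices).
#' @return A simple undirected `igraph` graph.
#' @export
read_graph_file <- function(path, format = NULL, index_base = 0,
                            n_vertices = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     graphml = "graphml", mtx = "mtx", "edgelist")
  }
  format <- match.arg(format, c("edgelist", "adjacency", "graphml", "mtx"))
  switch(format,
    edgelist = read_edgelist(path, index_base, n_vertices),
    adjacency = read_adjacency(path),
    graphml = {
      g <- igraph::read_graph(path, format = "graphml")
      igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
    },
    mtx = {
      m <- Matrix_read_mtx(path)
      graph_from_adjacency(m)
    }
  )
}

read_edgelist <- function(path, index_base, n_vertices) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(igraph::make_empty_graph(max(1, n_vertices %||% 1), directed = FALSE))
  }
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(vapply(parts, length, integer(1)) != 2)
  if (length(bad) > 0) stop("malformed edge-list line: ", bad[1])
  edges <- do.call(rbind, lapply(parts, as.integer))
  if (any(is.na(edges))) stop("non-integer vertex id in edge list")
  edges <- edges - index_base + 1L
  n <- max(edges, n_vertices %||% 0L)
  make_graph_from_edges(n, edges)
}

read_adjacency <- function(path) {
  a <- as.matrix(utils::read.table(path))
  graph_from_adjacency(a)
}

graph_from_adjacency <- function(a) {
  if (nrow(a) != ncol(a)) stop("adjacency matrix must be square")
  a <- (a != 0) | (t(a) != 0)  # symmetrise
  if (any(diag(a))) {
    warning("self-loops in adjacency input dropped")
    diag(a) <- FALSE
  }
  idx <- which(upper.tri(a) & a, arr.ind = TRUE)
  make_graph_from_edges(nrow(a), idx)
}

Matrix_read_mtx <- function(path) {
  m <- Matrix::readMM(path)
  as.matrix(m)
}

#' Write a graph to an edge-list file
#'
#' Two whitespace-separated integer columns, one edge per line, using the
#' requested vertex-id base (default 0, matching [read_graph_file()]).
#'
#' @param g A simple undirected `igraph` graph.
#' @param path Output path.
#' @param index_base 0 or 1.
#' @return Invisibly, `path`.
#' @export
write_graph_file <- function(g, path, index_base = 0) {
  assert_simple_graph(g)
  el <- igraph::as_edgelist(g, names = FALSE) - 1L + index_base
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), path)
  invisible(path)
}

#' Write a result object to JSON (+ CSV table)
#'
#' Serialises a `graph_kmeans`, `graph_gcem`, `param_estimate`, or
#' `scenario_result` to a JSON file carrying the scalar metadata (schema
#' version, package version, seed-free diagnostics) and, for clustering
#' and scenario results, a CSV table alongside (same path with a `.csv`
#' extension) holding the per-graph or per-repetition rows.
#'
#' @param result A supported result object.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_result <- function(result, path) {
  meta <- list(
    schema = "netspectra/1",
    package_version = as.character(utils::packageVersion("netspectra"))
  )
  csv_path <- sub("\\.json$", ".csv", path)
  if (identical(csv_path, path)) csv_path <- paste0(path, ".csv")
  if (inherits(result, "graph_kmeans") || inherits(result, "graph_gcem")) {
    meta$type <- class(result)[1]
    meta$k <- result$k
    meta$n_iterations <- result$n_iterations
    meta$converged <- result$converged
    if (!is.null(result$silhouette)) meta$silhouette <- result$silhouette
    if (!is.null(result$theta)) {
      meta$theta <- lapply(result$theta, as.numeric)
      meta$models <- vapply(result$models, `[[`, character(1), "model")
    }
    utils::write.csv(tidy(result), csv_path, row.names = FALSE)
    meta$table <- basename(csv_path)
  } else if (inherits(result, "param_estimate")) {
    meta$type <- "param_estimate"
    meta$model <- result$model
    meta$theta_hat <- as.numeric(result$theta_hat)
    meta$kl_min <- result$kl_min
    meta$n_mc <- result$n_mc
    meta$size <- result$size
    utils::write.csv(result$grid_kl, csv_path, row.names = FALSE)
    meta$table <- basename(csv_path)
  } else if (inherits(result, "scenario_result")) {
    meta$type <- "scenario_result"
    meta$scenario <- result$scenario[1]
    meta$n_repetitions <- length(unique(result$repetition))
    utils::write.csv(tibble::as_tibble(result), csv_path, row.names = FALSE)
    meta$table <- basename(csv_path)
  } else {
    stop("unsupported result type: ", paste(class(result), collapse = "/"))
  }
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read back a result written by [write_result()]
#'
#' @param path JSON path previously written by [write_result()].
#' @return A list with `meta` (the JSON metadata) and `table` (the CSV as
#'   a tibble, when present).
#' @export
read_result <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- NULL
  if (!is.null(meta$table)) {
    tab <- tibble::as_tibble(
      utils::read.csv(file.path(dirname(path), meta$table))
    )
  }
  list(meta = meta, table = tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
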