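# Symmetrized k-nearest-neighbour graph over feature rows (Euclidean).
# Returns an igraph; used for Leiden runs on embeddings/PCs.
knn_graph <- function(features, k = 15) {
  n <- nrow(features)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(features))
  diag(d) <- Inf
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nn <- order(d[i, ], seq_len(n))[seq_len(k)]
    adj[i, nn] <- TRUE
  }
  adj <- adj | t(adj)
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

leiden_labels <- function(graph, resolution, seed, weights = NULL) {
  with_seed(seed, {
    cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                                 resolution = resolution, weights = weights,
                                 n_iterations = 5)
    as.integer(igraph::membership(cl)) - 1L
  })
}

#' Multi-resolution clustering runs
#'
#' Produces one clustering per setting: Leiden community detection on a
#' k-nearest-neighbour graph of the feature rows (settings are resolutions),
#' or Gaussian-mixture clustering via mclust (settings are cluster counts).
#' Labels within each run are 0-based and contiguous.
#'
#' @param features Numeric matrix (typically PCA scores), spots in rows.
#' @param method `"leiden"` or `"gmm"`.
#' @param settings Numeric vector: resolutions (Leiden) or cluster counts
#'   (GMM). Default Leiden grid is `seq(0.1, 1.0, by = 0.1)`.
#' @param knn_k Neighbourhood size of the Leiden graph.
#' @param seed Integer seed (each run is seeded from `seed` + run index).
#' @return List of `clustering_run` objects (fields `labels`, `method`,
#'   `setting`).
#' @export
run_multiresolution_clustering <- function(features,
                                           method = c("leiden", "gmm"),
                                           settings = NULL,
                                           knn_k = 15, seed = 0) {
  method <- match.arg(method)
  if (is.null(settings))
    settings <- if (method == "leiden") seq(0.1, 1.0, by = 0.1) else
      stop("no-runs: cluster counts must be supplied for the gmm method",
           call. = FALSE)
  if (length(settings) == 0) stop("no-runs: empty settings", call. = FALSE)
  features <- as.matrix(features)
  graph <- if (method == "leiden") knn_graph(features, k = knn_k) else NULL
  runs <- vector("list", length(settings))
  for (t in seq_along(settings)) {
    labels <- if (method == "leiden") {
      leiden_labels(graph, settings[t], seed + t)
    } else {
      fit <- with_seed(seed + t,
        mclust::Mclust(features, G = settings[t], verbose = FALSE))
      if (is.null(fit)) stop("gmm fit failed for G=", settings[t], call. = FALSE)
      as.integer(fit$classification) - 1L
    }
    labels <- match(labels, sort(unique(labels))) - 1L  # contiguous
    runs[[t]] <- structure(list(labels = labels, method = method,
                                setting = settings[t]),
                           class = "clustering_run")
  }
  runs
}

#' Consensus (co-assignment) matrix across clustering runs
#'
#' `C[i, j]` is the fraction of runs in which spots `i` and `j` share a
#' cluster: symmetric, unit diagonal, entries multiples of `1/r` for `r` runs.
#'
#' @param runs List of `clustering_run` objects over the same spots.
#' @return Dense numeric `N x N` matrix.
#' @export
build_consensus_matrix <- function(runs) {
  stopifnot(length(runs) >= 1)
  n <- length(runs[[1]]$labels)
  if (any(vapply(runs, function(r) length(r$labels), 1L) != n))
    stop("run-mismatch: runs have differing lengths", call. = FALSE)
  C <- matrix(0, n, n)
  for (r in runs) {
    # indicator co-membership via one-hot crossproduct
    lab <- r$labels
    M <- outer(lab, lab, "==")
    C <- C + M
  }
  C / length(runs)
}

#' Initial pseudo-labels from the consensus matrix
#'
#' Leiden community detection on the weighted graph whose edge weights are the
#' positive off-diagonal consensus entries.
#'
#' @param C Consensus matrix from [build_consensus_matrix()].
#' @param resolution Leiden resolution (modularity objective).
#' @param seed Integer seed.
#' @return List with `labels` (0-based integer vector) and `n_cluster`.
#' @export
derive_initial_labels <- function(C, resolution = 1.0, seed = 0) {
  W <- C
  diag(W) <- 0
  if (all(W == 0))
    stop("degenerate-consensus: no off-diagonal consensus support",
         call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  labels <- leiden_labels(g, resolution, seed,
                          weights = igraph::E(g)$weight)
  labels <- match(labels, sort(unique(labels))) - 1L
  list(labels = labels, n_cluster = length(unique(labels)))
}
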