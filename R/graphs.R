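#' Spatial adjacency graph with consensus pruning
#'
#' Builds a k-nearest-neighbour graph on spatial coordinates, symmetrizes it
#' by element-wise maximum with its transpose, then removes edges whose
#' consensus co-assignment falls below `tau` (boundary-crossing edges rarely
#' co-cluster, so pruning trims links across tissue boundaries).
#'
#' @param coords Numeric matrix, spots x 2.
#' @param k Neighbourhood size (default 6, the Visium hexagonal
#'   neighbourhood).
#' @param C Optional consensus matrix aligned with `coords`; `NULL` skips
#'   pruning.
#' @param tau Consensus confidence threshold; edges with `C[i,j] < tau` are
#'   dropped.
#' @return Sparse binary symmetric adjacency matrix with zero diagonal.
#' @export
build_spatial_graph <- function(coords, k = 6, C = NULL, tau = 0.2) {
  n <- nrow(coords)
  if (k >= n) stop("k-too-large: k must be below the spot count", call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nn <- order(d[i, ], seq_len(n))[seq_len(k)]
    A[i, nn] <- 1
  }
  A <- pmax(A, t(A))
  if (!is.null(C)) {
    stopifnot(all(dim(C) == n))
    A[C < tau] <- 0          # C is symmetric, so symmetry is preserved
  }
  diag(A) <- 0
  Matrix::Matrix(A, sparse = TRUE)
}

#' Feature adjacency graph from consensus and cosine neighbourhoods
#'
#' For each spot `i`, the consensus neighbour set starts with all spots at
#' consensus 1 and is padded with the next-highest consensus scores until it
#' holds at least `n_neighbors` spots (ties by score then index). The feature
#' neighbour set is the `n_neighbors` most cosine-similar spots in topic
#' space. Candidate edges are the intersection of the two sets and are added
#' symmetrically, scanning spots in ascending index and candidates in
#' descending similarity, only while both endpoints have added fewer than
#' `n_neighbors` new edges. The resulting graph can link transcriptionally
#' identical regions that are spatially far apart.
#'
#' @param topic_features Spots x topics activity matrix (`Z_final` rows).
#' @param C Consensus matrix.
#' @param n_neighbors Neighbourhood size and per-node cap on added edges.
#' @return Sparse binary symmetric adjacency matrix with zero diagonal.
#' @export
build_feature_graph <- function(topic_features, C, n_neighbors = 15) {
  x <- as.matrix(topic_features)
  n <- nrow(x)
  stopifnot(all(dim(C) == n))
  norms <- sqrt(rowSums(x^2))
  zero_rows <- norms == 0
  if (any(zero_rows)) {
    warning(sum(zero_rows), " zero-norm feature row(s) excluded from cosine ranking")
    norms[zero_rows] <- 1
  }
  xn <- x / norms
  sim <- tcrossprod(xn)
  sim[zero_rows, ] <- -Inf
  sim[, zero_rows] <- -Inf
  diag(sim) <- -Inf

  cons_sets <- vector("list", n)
  feat_sets <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- C[i, ]; ci[i] <- -Inf
    ord <- order(-ci, seq_len(n))
    n_ones <- sum(ci == 1)
    take <- max(n_ones, min(n_neighbors, n - 1L))
    cons_sets[[i]] <- ord[seq_len(take)]
    feat_sets[[i]] <- order(-sim[i, ], seq_len(n))[seq_len(min(n_neighbors, n - 1L))]
  }

  A <- matrix(0, n, n)
  deg_add <- integer(n)
  for (i in seq_len(n)) {
    cand <- intersect(feat_sets[[i]], cons_sets[[i]])  # feat order = similarity rank
    for (j in cand) {
      if (i == j) next
      if (A[i, j] == 1) next
      if (deg_add[i] >= n_neighbors) break
      if (deg_add[j] >= n_neighbors) next
      A[i, j] <- 1; A[j, i] <- 1
      deg_add[i] <- deg_add[i] + 1L
      deg_add[j] <- deg_add[j] + 1L
    }
  }
  diag(A) <- 0
  Matrix::Matrix(A, sparse = TRUE)
}
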