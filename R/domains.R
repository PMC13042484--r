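#' Calinski-Harabasz score
#'
#' Between-cluster over within-cluster variance ratio scaled by
#' `(N - K) / (K - 1)`; larger is better. Undefined (NA) for a single
#' cluster.
#'
#' @param x Numeric matrix of observations.
#' @param labels Integer cluster labels.
#' @return Scalar score, or `NA` when `labels` has one level.
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  k <- length(unique(labels))
  n <- nrow(x)
  if (k < 2 || k >= n) return(NA_real_)
  gm <- colMeans(x)
  ssb <- 0; ssw <- 0
  for (lv in unique(labels)) {
    xi <- x[labels == lv, , drop = FALSE]
    ci <- colMeans(xi)
    ssb <- ssb + nrow(xi) * sum((ci - gm)^2)
    ssw <- ssw + sum(sweep(xi, 2, ci)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Cluster the fused embedding into spatial domains
#'
#' With a known target count the Gaussian-mixture route (mclust) is used;
#' otherwise Leiden on a k-nearest-neighbour graph of the embedding at the
#' given (or searched) resolution.
#'
#' @param E_att Embedding matrix (spots x dims).
#' @param n_clusters Target domain count, or `NULL` for the Leiden route.
#' @param method `"gmm"` or `"leiden"`; default picks GMM when `n_clusters`
#'   is supplied.
#' @param resolution Leiden resolution (ignored by GMM).
#' @param knn_k Neighbourhood size of the Leiden graph.
#' @param seed Integer seed.
#' @return Object of class `domain_result`: `labels` (0-based contiguous),
#'   `method`, `resolution`, `ch_score`, `refined`.
#' @export
cluster_embeddings <- function(E_att, n_clusters = NULL, method = NULL,
                               resolution = 1.0, knn_k = 15, seed = 0) {
  E_att <- as.matrix(E_att)
  if (any(!is.finite(E_att))) stop("non-finite embedding", call. = FALSE)
  if (is.null(method)) method <- if (!is.null(n_clusters)) "gmm" else "leiden"
  method <- match.arg(method, c("gmm", "leiden"))
  if (method == "gmm") {
    if (is.null(n_clusters)) stop("gmm route needs n_clusters", call. = FALSE)
    if (n_clusters > nrow(E_att))
      stop("invalid-k: more clusters than spots", call. = FALSE)
    # Shared-covariance GMM on a PCA reduction of the embedding, EM started
    # from 10 seeded k-means partitions, keeping the best log-likelihood
    # (k-means labels are the fallback if every EM run degenerates).
    n_red <- min(20L, ncol(E_att), nrow(E_att) - 1L)
    pc <- stats::prcomp(E_att, rank. = n_red)
    keep_pc <- utils::head(pc$sdev, n_red) > 1e-8 * pc$sdev[1]
    Ered <- pc$x[, keep_pc, drop = FALSE]
    best_ll <- -Inf; labels <- NULL
    best_wss <- Inf; km_labels <- NULL
    for (r in seq_len(10)) {
      km <- with_seed(seed + r,
        stats::kmeans(Ered, n_clusters, nstart = 1, iter.max = 30))
      if (km$tot.withinss < best_wss) {
        best_wss <- km$tot.withinss
        km_labels <- km$cluster - 1L
      }
      z <- outer(km$cluster, seq_len(n_clusters), "==") * 1
      em <- suppressWarnings(try(
        mclust::me(data = Ered, modelName = "EEE", z = z), silent = TRUE))
      if (!inherits(em, "try-error") && !is.null(em$loglik) &&
          is.finite(em$loglik) && em$loglik > best_ll && !anyNA(em$z)) {
        best_ll <- em$loglik
        labels <- max.col(em$z) - 1L
      }
    }
    if (is.null(labels)) labels <- km_labels
    res <- NULL
  } else {
    g <- knn_graph(E_att, k = knn_k)
    labels <- leiden_labels(g, resolution, seed)
    res <- resolution
  }
  labels <- match(labels, sort(unique(labels))) - 1L
  structure(list(labels = labels, method = method, resolution = res,
                 ch_score = calinski_harabasz(E_att, labels),
                 refined = FALSE),
            class = "domain_result")
}

#' @export
print.domain_result <- function(x, ...) {
  cat("domain_result:", length(unique(x$labels)), "domains over",
      length(x$labels), "spots (", x$method,
      if (!is.null(x$resolution)) paste0(", resolution ", x$resolution), ")\n")
  invisible(x)
}

#' Grid-search the Leiden resolution by Calinski-Harabasz score
#'
#' Evaluates Leiden clusterings of the embedding over a resolution grid and
#' returns the resolution maximizing the CH score (single-cluster partitions
#' are skipped; ties go to the lowest resolution).
#'
#' @param E_att Embedding matrix.
#' @param lo,hi,step Resolution grid bounds and spacing.
#' @param knn_k Neighbourhood size of the Leiden graph.
#' @param seed Integer seed.
#' @return List with `resolution` and the corresponding `domain_result`.
#' @export
search_resolution <- function(E_att, lo = 0.1, hi = 2.5, step = 0.001,
                              knn_k = 15, seed = 0) {
  stopifnot(lo < hi, step > 0)
  grid <- seq(lo, hi, by = step)
  g <- knn_graph(as.matrix(E_att), k = knn_k)
  best <- NULL; best_ch <- -Inf; best_res <- NA_real_
  for (r in grid) {
    labels <- leiden_labels(g, r, seed)
    labels <- match(labels, sort(unique(labels))) - 1L
    ch <- calinski_harabasz(E_att, labels)
    if (!is.na(ch) && ch > best_ch) {
      best_ch <- ch; best_res <- r
      best <- structure(list(labels = labels, method = "leiden",
                             resolution = r, ch_score = ch, refined = FALSE),
                        class = "domain_result")
    }
  }
  if (is.null(best))
    stop("no-partition-found: every resolution produced one cluster",
         call. = FALSE)
  list(resolution = best_res, result = best)
}

#' Local spatial label refinement
#'
#' Single-pass majority smoothing: each spot whose label differs from the
#' modal label among its `n` spatial nearest neighbours is reassigned to that
#' modal label (ties keep the original label). Recommended for
#' coarse-resolution spot arrays only; it can over-smooth fine structure.
#'
#' @param labels Integer label vector.
#' @param coords Spot coordinates.
#' @param n Neighbourhood size.
#' @param enabled `FALSE` returns the labels untouched.
#' @return Integer label vector.
#' @export
refine_labels_local <- function(labels, coords, n = 25, enabled = TRUE) {
  if (!enabled) return(labels)
  stopifnot(n < length(labels))
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  out <- labels
  for (i in seq_along(labels)) {
    nn <- order(d[i, ], seq_along(labels))[seq_len(n)]
    tab <- table(labels[nn])
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1 && top != as.character(labels[i]))
      out[i] <- as.integer(top)
  }
  out
}
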