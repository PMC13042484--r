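# NNDSVD initialization (Boutsidis & Gallopoulos) with the "a" variant:
# structural zeros are replaced by the matrix mean so multiplicative updates
# can move every entry.
nndsvd_init <- function(A, k) {
  s <- svd(A, nu = k, nv = k)
  m <- nrow(A); n <- ncol(A)
  W <- matrix(0, m, k); H <- matrix(0, n, k)
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[, 1] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k >= 2) for (j in 2:k) {
    x <- s$u[, j]; y <- s$v[, j]
    xp <- pmax(x, 0); xn <- pmax(-x, 0)
    yp <- pmax(y, 0); yn <- pmax(-y, 0)
    nxp <- sqrt(sum(xp^2)); nxn <- sqrt(sum(xn^2))
    nyp <- sqrt(sum(yp^2)); nyn <- sqrt(sum(yn^2))
    mp <- nxp * nyp; mn <- nxn * nyn
    if (mp >= mn && mp > 0) {
      u <- xp / nxp; v <- yp / nyp; sig <- mp
    } else if (mn > 0) {
      u <- xn / nxn; v <- yn / nyn; sig <- mn
    } else next
    W[, j] <- sqrt(s$d[j] * sig) * u
    H[, j] <- sqrt(s$d[j] * sig) * v
  }
  avg <- mean(A)
  W[W <= 0] <- avg
  H[H <= 0] <- avg
  list(W = W, H = H)
}

#' Non-negative matrix factorization of log expression into spatial topics
#'
#' Factorizes the non-negative spots x genes matrix as `Z %*% t(H)` under the
#' Frobenius objective, multiplicative updates from an NNDSVD initialization.
#' `Z` (spots x topics) is min-max normalized per column to `[0, 1]`
#' (constant columns map to zeros); `H` (genes x topics) is kept on the
#' original scale for downstream gene ranking.
#'
#' @param loggered Non-negative numeric matrix (spots x genes), typically the
#'   `loggered` layer from [normalize_log1p()].
#' @param n_topics Number of latent topics.
#' @param seed Integer seed (the solve is deterministic; kept for interface
#'   uniformity).
#' @param max_iter,tol Multiplicative-update iteration cap and relative
#'   Frobenius-objective tolerance.
#' @return Object of class `sage_topics`: `Z`, `Z_raw`, `H`, `n_topics`,
#'   `recon_error`, plus slots filled by the topic filters (`mri`,
#'   `Z_filtered`, `kept`, `importances`, `selected`, `Z_final`).
#' @export
fit_nmf <- function(loggered, n_topics = 30, seed = 0,
                    max_iter = 500, tol = 1e-4) {
  A <- as.matrix(loggered)
  if (any(A < 0)) stop("negative-input: NMF requires non-negative input",
                       call. = FALSE)
  stopifnot(n_topics < min(dim(A)))
  init <- nndsvd_init(A, n_topics)
  W <- init$W; H <- init$H            # A ~ W t(H), H is genes x topics
  eps <- 1e-10
  err_prev <- Inf
  for (it in seq_len(max_iter)) {
    W <- W * ((A %*% H) / (W %*% crossprod(H) + eps))
    H <- H * ((crossprod(A, W)) / (H %*% crossprod(W) + eps))
    if (it %% 10 == 0 || it == max_iter) {
      err <- sqrt(sum((A - W %*% t(H))^2))
      if (is.finite(err_prev) && abs(err_prev - err) <= tol * err_prev) break
      err_prev <- err
    }
  }
  err <- sqrt(sum((A - W %*% t(H))^2))
  Z <- apply(W, 2, function(col) {
    rng <- range(col)
    if (rng[2] > rng[1]) (col - rng[1]) / (rng[2] - rng[1]) else rep(0, length(col))
  })
  structure(list(Z = Z, Z_raw = W, H = H, n_topics = n_topics,
                 recon_error = err, mri = NULL, Z_filtered = NULL,
                 kept = NULL, importances = NULL, selected = NULL,
                 Z_final = NULL),
            class = "sage_topics")
}

#' @export
print.sage_topics <- function(x, ...) {
  cat("sage_topics:", nrow(x$Z), "spots,", x$n_topics, "topics",
      "(recon error", signif(x$recon_error, 4), ")\n")
  if (!is.null(x$kept))
    cat("  spatially coherent topics:", length(x$kept), "\n")
  if (!is.null(x$selected))
    cat("  selected informative topics:", length(x$selected), "\n")
  invisible(x)
}

#' Filter topics by spatial autocorrelation
#'
#' Computes Moran's I for every topic activity column and retains topics with
#' `I >= threshold`. Constant columns are treated as non-spatial and dropped.
#'
#' @param tm A `sage_topics` object.
#' @param weights A [spatial_weights()] object over the same spots.
#' @param threshold Retention threshold on Moran's I.
#' @return The `sage_topics` with `mri`, `Z_filtered`, `kept` filled.
#' @export
filter_topics_by_mri <- function(tm, weights, threshold = 0.2) {
  mri <- vapply(seq_len(ncol(tm$Z)), function(j) {
    col <- tm$Z[, j]
    if (stats::var(col) == 0) -Inf else morans_i(col, weights)
  }, numeric(1))
  keep <- which(mri >= threshold)
  if (length(keep) == 0)
    stop("no-spatial-topics: no topic reaches Moran's I >= ", threshold,
         call. = FALSE)
  tm$mri <- mri
  tm$Z_filtered <- tm$Z[, keep, drop = FALSE]
  tm$kept <- keep
  tm
}

#' Supervised topic importance via random-forest Gini impurity
#'
#' Trains a random-forest classifier of the pseudo-labels on the filtered
#' topic activities (all spots, no held-out split) and returns per-topic mean
#' decrease in Gini impurity, normalized to sum to one.
#'
#' @param Z_filtered Spots x topics activity matrix.
#' @param L_init Integer pseudo-label vector (at least two classes).
#' @param n_trees Number of trees.
#' @param seed Integer seed.
#' @return Numeric vector of normalized importances (sums to 1).
#' @export
score_topic_importance <- function(Z_filtered, L_init, n_trees = 100,
                                   seed = 0) {
  if (length(unique(L_init)) < 2)
    stop("degenerate-labels: need at least two classes", call. = FALSE)
  Z_filtered <- as.matrix(Z_filtered)
  colnames(Z_filtered) <- paste0("topic_", seq_len(ncol(Z_filtered)))
  fit <- with_seed(seed,
    randomForest::randomForest(x = Z_filtered, y = factor(L_init),
                               ntree = n_trees))
  imp <- fit$importance[, "MeanDecreaseGini"]
  imp <- pmax(imp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp) else imp[] <- 1 / length(imp)
  unname(imp)
}

#' Keep the most informative topics
#'
#' Retains the top `floor((1 - p) * N_filt)` topics by importance (ties broken
#' by topic index ascending) and stores their activities as `Z_final`.
#'
#' @param tm A `sage_topics` after [filter_topics_by_mri()].
#' @param importances Output of [score_topic_importance()] over the filtered
#'   topics.
#' @param p Fraction of (lowest-importance) topics to discard, `0 <= p < 1`.
#' @return The `sage_topics` with `importances`, `selected` (original topic
#'   indices), `Z_final` filled.
#' @export
select_informative_topics <- function(tm, importances, p = 0.2) {
  stopifnot(p >= 0, p < 1)
  n_filt <- ncol(tm$Z_filtered)
  stopifnot(length(importances) == n_filt)
  n_keep <- floor((1 - p) * n_filt)
  if (n_keep < 1)
    stop("no-topics-selected: p too large for ", n_filt, " topics",
         call. = FALSE)
  ord <- order(-importances, seq_len(n_filt))
  keep <- sort(ord[seq_len(n_keep)])
  tm$importances <- importances
  tm$selected <- tm$kept[keep]
  tm$Z_final <- tm$Z_filtered[, keep, drop = FALSE]
  tm
}
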