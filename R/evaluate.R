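entropy_of <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Label-agreement metrics against a reference annotation
#'
#' Normalized mutual information (arithmetic normalization), homogeneity,
#' completeness (entropy-based, with the degenerate conventions
#' `HOM = 1` when the reference has one class and `COM = 1` when the
#' prediction has one class), and the adjusted Rand index.
#'
#' @param pred,truth Aligned label vectors.
#' @return Named numeric vector `nmi`, `hom`, `com`, `ari`.
#' @export
accuracy_metrics <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("alignment-error: label vectors differ in length", call. = FALSE)
  n <- length(pred)
  tab <- table(truth, pred)
  pj <- unname(rowSums(tab)) / n       # reference classes
  pk <- unname(colSums(tab)) / n       # predicted clusters
  hC <- entropy_of(pj)
  hK <- entropy_of(pk)
  pij <- tab / n
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    v <- pij[i, j]
    if (v > 0) mi <- mi + v * log(v / (pj[i] * pk[j]))
  }
  nmi <- if (hC == 0 && hK == 0) 1 else if (mi == 0) 0 else mi / mean(c(hC, hK))
  hom <- if (hC == 0) 1 else mi / hC      # 1 - H(C|K)/H(C)
  com <- if (hK == 0) 1 else mi / hK
  c(nmi = nmi, hom = hom, com = com,
    ari = mclust::adjustedRandIndex(pred, truth))
}

#' Spatial-continuity metrics of a domain labeling
#'
#' CHAOS: mean same-cluster nearest-neighbour edge length on z-scaled
#' coordinates (singleton clusters skipped with a warning); lower is
#' smoother. PAS: fraction of spots whose label disagrees with more than
#' `pas_cut` of their `pas_k` spatial nearest neighbours; lower is better.
#' ASW: mean silhouette width of the labels on the coordinates.
#'
#' @param labels Integer labels.
#' @param coords Spot coordinates.
#' @param pas_k,pas_cut PAS neighbourhood size and disagreement threshold.
#' @return Named numeric vector `chaos`, `pas`, `asw`.
#' @export
continuity_metrics <- function(labels, coords, pas_k = 10, pas_cut = 6) {
  coords <- as.matrix(coords)
  zc <- scale(coords)
  d <- as.matrix(stats::dist(zc))
  diag(d) <- Inf
  # CHAOS
  edge <- numeric(0)
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    if (length(idx) < 2) {
      warning("singleton cluster ", lv, " skipped in CHAOS")
      next
    }
    dl <- d[idx, idx, drop = FALSE]
    edge <- c(edge, apply(dl, 1, min))
  }
  chaos <- mean(edge)
  # PAS on raw coordinates
  draw <- as.matrix(stats::dist(coords))
  diag(draw) <- Inf
  k <- min(pas_k, length(labels) - 1L)
  abnormal <- vapply(seq_along(labels), function(i) {
    nn <- order(draw[i, ], seq_along(labels))[seq_len(k)]
    sum(labels[nn] != labels[i]) > pas_cut
  }, logical(1))
  pas <- mean(abnormal)
  # ASW
  asw <- if (length(unique(labels)) < 2) NA_real_ else
    mean(cluster::silhouette(as.integer(factor(labels)),
                             stats::dist(coords))[, 3])
  c(chaos = chaos, pas = pas, asw = asw)
}

#' Marker-gene spatial coherence
#'
#' Moran's I and Geary's C of an expression vector under the given spatial
#' weights.
#'
#' @param expr Numeric expression vector.
#' @param weights A [spatial_weights()].
#' @return Named numeric vector `moran_i`, `geary_c`.
#' @export
marker_metrics <- function(expr, weights) {
  c(moran_i = morans_i(expr, weights), geary_c = gearys_c(expr, weights))
}

#' Normalized rank-based scores across datasets
#'
#' Per dataset (row), methods are ranked (rank 1 = best; fractional ranks on
#' ties) and normalized to `[0, 1]` via
#' `(N_method - rank) / (N_method - 1)`; per-method scores are then averaged
#' over datasets.
#'
#' @param V Datasets x methods score matrix.
#' @param higher_is_better Direction of the underlying metric.
#' @return List with matrix `R_tilde` (normalized scores) and vector
#'   `rank_m` (per-method dataset means).
#' @export
rank_based_scores <- function(V, higher_is_better = TRUE) {
  V <- as.matrix(V)
  m <- ncol(V)
  if (m < 2) stop("undefined-normalization: need at least two methods",
                  call. = FALSE)
  R <- t(apply(V, 1, function(row)
    rank(if (higher_is_better) -row else row, ties.method = "average")))
  R_tilde <- (m - R) / (m - 1)
  list(R_tilde = R_tilde, rank_m = colMeans(R_tilde))
}

#' Aggregate category-wise overall scores
#'
#' `Overall_accuracy` = mean of the NMI/HOM/COM rank scores,
#' `Overall_continuity` = mean of CHAOS/PAS/ASW, `Overall_marker` = mean of
#' Moran's I / Geary's C; `total` is their sum.
#'
#' @param rank_scores Named numeric vector with entries `nmi`, `hom`, `com`,
#'   `chaos`, `pas`, `asw`, `moran`, `geary`.
#' @return Named numeric vector `accuracy`, `continuity`, `marker`, `total`.
#' @export
overall_scores <- function(rank_scores) {
  need <- c("nmi", "hom", "com", "chaos", "pas", "asw", "moran", "geary")
  if (!all(need %in% names(rank_scores)))
    stop("incomplete-report: missing ",
         paste(setdiff(need, names(rank_scores)), collapse = ", "),
         call. = FALSE)
  acc <- mean(rank_scores[c("nmi", "hom", "com")])
  cont <- mean(rank_scores[c("chaos", "pas", "asw")])
  mark <- mean(rank_scores[c("moran", "geary")])
  c(accuracy = acc, continuity = cont, marker = mark,
    total = acc + cont + mark)
}

#' Relative improvement of one score over a baseline
#'
#' `100 (a - b) / b` for higher-is-better metrics and `100 (b - a) / b` for
#' lower-is-better ones (e.g. a Davies-Bouldin index).
#'
#' @param a Score of the method of interest.
#' @param b Baseline score (> 0).
#' @param higher_is_better Direction of the metric.
#' @return Percentage improvement.
#' @export
relative_improvement <- function(a, b, higher_is_better = TRUE) {
  if (b <= 0) stop("invalid-baseline: baseline must be positive", call. = FALSE)
  if (higher_is_better) 100 * (a - b) / b else 100 * (b - a) / b
}
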