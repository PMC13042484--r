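#' Remove rarely detected genes
#'
#' Genes detected in fewer than `min_locations` spots or with total count not
#' exceeding `min_counts` are dropped; the spot set is unchanged. Retention is
#' `n_nonzero >= min_locations` and `total > min_counts` (so a total of
#' exactly `min_counts` is removed). The filter is idempotent.
#'
#' @param ds An [st_dataset()].
#' @param min_locations Minimum number of spots with nonzero expression.
#' @param min_counts Total-count threshold; genes with totals `<= min_counts`
#'   are removed.
#' @return A filtered [st_dataset()].
#' @export
filter_genes <- function(ds, min_locations = 5, min_counts = 20) {
  n_loc <- colSums(ds$counts > 0)
  tot <- colSums(ds$counts)
  keep <- n_loc >= min_locations & tot > min_counts
  if (!any(keep)) stop("empty-after-filter: no genes pass the detection filter",
                       call. = FALSE)
  st_dataset(ds$counts[, keep, drop = FALSE], ds$coords,
             gene_ids = ds$gene_ids[keep], spot_ids = ds$spot_ids)
}

#' Library-size normalization and log transform
#'
#' Scales every spot to `target_sum` total counts and applies the natural
#' logarithm of (normalized + 1). Spots with zero total counts are dropped
#' with a warning.
#'
#' @param ds An [st_dataset()].
#' @param target_sum Per-spot library size after normalization.
#' @return An object of class `expression_layers`: list with `normalized`,
#'   `loggered` (both spots x genes), the retained `counts`/`coords`
#'   (for downstream stages), and placeholders `hvg_mask`, `pcs`.
#' @export
normalize_log1p <- function(ds, target_sum = 10000) {
  if (any(ds$counts < 0)) stop("invalid-counts: negative entries", call. = FALSE)
  tot <- rowSums(ds$counts)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " spot(s) with zero total counts dropped")
    ds <- st_dataset(ds$counts[tot > 0, , drop = FALSE],
                     ds$coords[tot > 0, , drop = FALSE],
                     gene_ids = ds$gene_ids, spot_ids = ds$spot_ids[tot > 0])
    tot <- tot[tot > 0]
  }
  normalized <- ds$counts * (target_sum / tot)
  structure(list(normalized = normalized,
                 loggered = log1p(normalized),
                 counts = ds$counts, coords = ds$coords,
                 gene_ids = ds$gene_ids, spot_ids = ds$spot_ids,
                 hvg_mask = NULL, pcs = NULL),
            class = "expression_layers")
}

# Seurat-v3-style variance-stabilized dispersion: fit a loess trend of
# log10(variance) on log10(mean) over raw counts, standardize each gene by the
# trend sd with values clipped at sqrt(N), and score genes by the variance of
# the clipped standardized values.
vst_statistic <- function(counts, loess_span = 0.3) {
  n <- nrow(counts)
  mu <- colMeans(counts)
  v <- apply(counts, 2, stats::var)
  stat <- numeric(ncol(counts))
  fit_idx <- v > 0 & mu > 0
  if (sum(fit_idx) >= 3) {
    # fit on canonically sorted points so the statistic is invariant to
    # gene order (loess's surface approximation is data-order sensitive)
    lx <- log10(mu[fit_idx]); ly <- log10(v[fit_idx])
    ord <- order(lx, ly)
    fit <- stats::loess(y ~ x, data = data.frame(x = lx[ord], y = ly[ord]),
                        span = loess_span, degree = 2)
    exp_sd <- sqrt(10^stats::predict(fit, newdata = data.frame(x = lx)))
    clip <- sqrt(n)
    z <- sweep(counts[, fit_idx, drop = FALSE], 2, mu[fit_idx], "-")
    z <- sweep(z, 2, exp_sd, "/")
    z <- pmin(z, clip)
    stat[fit_idx] <- apply(z, 2, stats::var)
  } else {
    stat[fit_idx] <- v[fit_idx]
  }
  stat
}

#' Flag highly variable genes
#'
#' Ranks genes by the mean-variance-stabilized dispersion statistic (Seurat v3
#' flavor) computed on raw counts and flags the top `n_top`. Ties are broken
#' by gene index for determinism.
#'
#' @param layers An `expression_layers` object from [normalize_log1p()].
#' @param n_top Number of genes to flag (clipped at the gene count).
#' @return The `expression_layers` with `hvg_mask` (logical vector) set.
#' @export
select_hvgs <- function(layers, n_top = 3000) {
  if (n_top <= 0) stop("invalid-parameter: n_top must be >= 1", call. = FALSE)
  g <- ncol(layers$counts)
  stat <- vst_statistic(layers$counts)
  ord <- order(-stat, seq_len(g))
  mask <- logical(g)
  mask[ord[seq_len(min(n_top, g))]] <- TRUE
  names(mask) <- layers$gene_ids
  layers$hvg_mask <- mask
  layers
}

#' Principal components of the HVG-restricted log expression
#'
#' Centered PCA on `loggered[, hvg_mask]`; scores for the leading
#' `n_comps` components are stored on the layers. `n_comps` larger than the
#' feasible rank is clipped with a warning.
#'
#' @param layers An `expression_layers` with `hvg_mask` set (all genes are
#'   used when the mask is absent).
#' @param n_comps Number of components to retain.
#' @return The `expression_layers` with `pcs` (spots x `n_comps`) set.
#' @export
reduce_pca <- function(layers, n_comps = 200) {
  x <- layers$loggered
  if (!is.null(layers$hvg_mask)) x <- x[, layers$hvg_mask, drop = FALSE]
  max_comps <- min(nrow(x) - 1L, ncol(x))
  if (n_comps > max_comps) {
    warning("n_comps clipped from ", n_comps, " to ", max_comps)
    n_comps <- max_comps
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_comps)
  layers$pcs <- p$x[, seq_len(n_comps), drop = FALSE]
  layers
}
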