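#' Column-normalize gene-topic weights over selected topics
#'
#' Restricts the gene x topic weight matrix to the selected topic columns and
#' normalizes each column to sum to one.
#'
#' @param H Non-negative gene x topic matrix (full topic set).
#' @param topics Integer indices of the selected topics.
#' @return Gene x selected-topic matrix with unit column sums.
#' @export
normalize_gene_topic_weights <- function(H, topics) {
  Ht <- H[, topics, drop = FALSE]
  cs <- colSums(Ht)
  if (any(cs <= 0)) stop("empty-topic: zero-sum topic column", call. = FALSE)
  sweep(Ht, 2, cs, "/")
}

#' Per-topic contribution ranks
#'
#' Rank 1 marks the gene with the largest contribution in a topic; larger
#' ranks mean smaller contributions. Ties break by gene index ascending.
#'
#' @param H_norm Column-normalized gene x topic matrix.
#' @return Integer matrix of the same shape; each column is a permutation of
#'   `1..G`.
#' @export
compute_rank_matrix <- function(H_norm) {
  apply(H_norm, 2, function(col) {
    r <- integer(length(col))
    r[order(-col, seq_along(col))] <- seq_along(col)
    r
  })
}

#' Cumulative-contribution rank thresholds
#'
#' For each topic, sums contributions in descending-rank order and returns the
#' smallest rank at which the running sum reaches `tau_low` (head of the
#' topic) and `tau_high` (bulk of the topic).
#'
#' @param H_norm Column-normalized gene x topic matrix.
#' @param tau_low,tau_high Quantile thresholds, `0 < tau_low < tau_high <= 1`.
#' @return List with integer vectors `r_low` and `r_high` (one per topic).
#' @export
cumulative_rank_thresholds <- function(H_norm, tau_low = 0.3, tau_high = 0.8) {
  if (!(tau_low > 0 && tau_low < tau_high && tau_high <= 1))
    stop("invalid-quantiles: need 0 < tau_low < tau_high <= 1", call. = FALSE)
  r_low <- integer(ncol(H_norm)); r_high <- integer(ncol(H_norm))
  for (t in seq_len(ncol(H_norm))) {
    cum <- cumsum(sort(H_norm[, t], decreasing = TRUE))
    r_low[t] <- which(cum >= tau_low - 1e-12)[1]
    r_high[t] <- which(cum >= tau_high - 1e-12)[1]
  }
  list(r_low = r_low, r_high = r_high)
}

#' Per-topic z-scores of gene-topic weights
#'
#' Standardizes each topic column of the (unnormalized) selected weight matrix
#' by its mean and population standard deviation (divide by `G`).
#'
#' @param H_T Gene x selected-topic weight matrix.
#' @return Matrix of z-scores; columns have mean 0 and population variance 1.
#' @export
topic_zscores <- function(H_T) {
  apply(H_T, 2, function(col) {
    mu <- mean(col)
    sd_pop <- sqrt(mean((col - mu)^2))
    if (sd_pop == 0) stop("constant-topic: zero variance column", call. = FALSE)
    (col - mu) / sd_pop
  })
}

#' Topic-specific genes
#'
#' A gene is topic-specific if, in at least one selected topic, it ranks in
#' the topic head (`rank <= r_low`) and its weight z-score strictly exceeds
#' `theta` (default 1.96, the two-sided 95% standard-normal cutoff).
#'
#' @param R Rank matrix from [compute_rank_matrix()].
#' @param zscores Matrix from [topic_zscores()].
#' @param r_low Per-topic head thresholds from [cumulative_rank_thresholds()].
#' @param gene_ids Character vector of gene identifiers (rows of `R`).
#' @param theta z-score cutoff.
#' @return Character vector of topic-specific gene ids.
#' @export
select_tsgs <- function(R, zscores, r_low, gene_ids, theta = 1.96) {
  hit <- sweep(R, 2, r_low, "<=") & (zscores > theta)
  tsg <- gene_ids[rowSums(hit) > 0]
  if (length(tsg) == 0) warning("no topic-specific genes found")
  tsg
}

#' Preliminary non-topic-specific genes
#'
#' HVGs that rank below the bulk threshold `r_high` in every selected topic.
#'
#' @param R Rank matrix.
#' @param r_high Per-topic bulk thresholds.
#' @param gene_ids Gene identifiers (rows of `R`).
#' @param hvg Character vector of highly variable gene ids.
#' @return Character vector of gene ids.
#' @export
initial_non_tsgs <- function(R, r_high, gene_ids, hvg) {
  below_all <- rowSums(sweep(R, 2, r_high, ">")) == ncol(R)
  intersect(gene_ids[below_all], hvg)
}

#' Rescue spatially autocorrelated genes from the non-specific set
#'
#' Among the preliminary non-topic-specific genes, genes with high gene-level
#' Moran's I (`> theta_mri`) despite low topic relevance (rank sum
#' `> theta_s`) are removed from the set: they are spatially informative
#' genes the decomposition under-ranked, and removing them from the
#' non-specific pool protects them from deletion. The default thresholds are
#' the 75th percentile of Moran's I and the median rank sum over the
#' preliminary set.
#'
#' @param non_tsg_init Character vector of preliminary non-TSG ids.
#' @param gene_mri Named numeric vector: per-gene Moran's I on log expression.
#' @param rank_sum Named numeric vector: per-gene rank sum over selected
#'   topics.
#' @param theta_mri,theta_s Optional explicit thresholds.
#' @return List with `rescued` (removed from the set), `non_tsg` (final set),
#'   `theta_mri`, `theta_s`.
#' @export
rescue_spatial_genes <- function(non_tsg_init, gene_mri, rank_sum,
                                 theta_mri = NULL, theta_s = NULL) {
  if (length(non_tsg_init) == 0)
    return(list(rescued = character(0), non_tsg = character(0),
                theta_mri = NA_real_, theta_s = NA_real_))
  mri0 <- gene_mri[non_tsg_init]
  s0 <- rank_sum[non_tsg_init]
  if (is.null(theta_mri)) theta_mri <- stats::quantile(mri0, 0.75, names = FALSE)
  if (is.null(theta_s)) theta_s <- stats::median(s0)
  rescued <- non_tsg_init[mri0 > theta_mri & s0 > theta_s]
  list(rescued = rescued,
       non_tsg = setdiff(non_tsg_init, rescued),
       theta_mri = theta_mri, theta_s = theta_s)
}

#' Assemble the high spatial-specificity gene set
#'
#' `Add = HVG + TSG`; removal candidates are `HVG` genes in the final
#' non-topic-specific set, ordered least-topic-relevant first (largest minimum
#' topic rank) and truncated so at most `|Add| - |HVG|` genes are removed,
#' guaranteeing a net gain: `|HSG| >= |HVG|` and `TSG` is always kept.
#'
#' @param hvg,tsg,non_tsg Character gene-id sets.
#' @param R Rank matrix with rownames = gene ids (used to order candidates).
#' @return List with `add`, `del_star`, `hsg`.
#' @export
assemble_hsgs <- function(hvg, tsg, non_tsg, R) {
  add <- union(hvg, tsg)
  cap <- length(add) - length(hvg)
  candidates <- intersect(hvg, non_tsg)
  if (cap > 0 && length(candidates) > 0) {
    min_rank <- apply(R[candidates, , drop = FALSE], 1, min)
    ord <- candidates[order(-min_rank, match(candidates, rownames(R)))]
    del_star <- ord[seq_len(min(cap, length(ord)))]
  } else del_star <- character(0)
  list(add = add, del_star = del_star, hsg = setdiff(add, del_star))
}

#' Run the full high spatial-specificity gene selection
#'
#' Orchestrates the gene-selection algebra: column normalization of the
#' selected gene-topic weights, per-topic contribution ranks, cumulative-rank
#' head/bulk thresholds, weight z-scores, the topic-specific and
#' non-topic-specific sets, the spatial rescue step, and final HSG assembly.
#'
#' @param tm A `sage_topics` with `selected` topics (see
#'   [select_informative_topics()]).
#' @param layers `expression_layers` with `hvg_mask` set.
#' @param weights [spatial_weights()] over the spots (for gene-level
#'   Moran's I).
#' @param tau_low,tau_high Cumulative-contribution thresholds.
#' @param theta z-score cutoff for topic-specific genes.
#' @param theta_mri,theta_s Optional explicit rescue thresholds.
#' @return Object of class `gene_selection` carrying the intermediate
#'   matrices (`H_norm`, `R`, `zscores`, `r_low`, `r_high`, `gene_mri`,
#'   `rank_sum`), the thresholds used, and the gene sets
#'   (`hvg`, `tsg`, `non_tsg_init`, `rescued`, `non_tsg`, `add`, `del_star`,
#'   `hsg`).
#' @export
select_hsgs <- function(tm, layers, weights, tau_low = 0.3, tau_high = 0.8,
                        theta = 1.96, theta_mri = NULL, theta_s = NULL) {
  stopifnot(!is.null(tm$selected), !is.null(layers$hvg_mask))
  gene_ids <- layers$gene_ids
  hvg <- gene_ids[layers$hvg_mask]

  H_norm <- normalize_gene_topic_weights(tm$H, tm$selected)
  rownames(H_norm) <- gene_ids
  R <- compute_rank_matrix(H_norm)
  rownames(R) <- gene_ids
  thr <- cumulative_rank_thresholds(H_norm, tau_low, tau_high)
  H_T <- tm$H[, tm$selected, drop = FALSE]
  zs <- topic_zscores(H_T)
  rownames(zs) <- gene_ids

  tsg <- suppressWarnings(select_tsgs(R, zs, thr$r_low, gene_ids, theta))
  non_tsg_init <- initial_non_tsgs(R, thr$r_high, gene_ids, hvg)

  gene_mri <- vapply(seq_along(gene_ids), function(j) {
    col <- layers$loggered[, j]
    if (stats::var(col) == 0) -Inf else morans_i(col, weights)
  }, numeric(1))
  names(gene_mri) <- gene_ids
  rank_sum <- rowSums(R)

  # rescue thresholds from the genome-wide distributions, so spatially
  # coherent genes are judged against all genes rather than only against
  # the other under-ranked ones
  if (is.null(theta_mri))
    theta_mri <- stats::quantile(gene_mri[is.finite(gene_mri)], 0.75,
                                 names = FALSE)
  if (is.null(theta_s)) theta_s <- stats::median(rank_sum)
  resc <- rescue_spatial_genes(non_tsg_init, gene_mri, rank_sum,
                               theta_mri, theta_s)
  sets <- assemble_hsgs(hvg, tsg, resc$non_tsg, R)

  structure(list(H_norm = H_norm, R = R, zscores = zs,
                 r_low = thr$r_low, r_high = thr$r_high,
                 tau_low = tau_low, tau_high = tau_high, theta = theta,
                 theta_mri = resc$theta_mri, theta_s = resc$theta_s,
                 gene_mri = gene_mri, rank_sum = rank_sum,
                 hvg = hvg, tsg = tsg, non_tsg_init = non_tsg_init,
                 rescued = resc$rescued, non_tsg = resc$non_tsg,
                 add = sets$add, del_star = sets$del_star, hsg = sets$hsg),
            class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat("gene_selection:", length(x$hsg), "HSGs",
      "(HVG:", length(x$hvg), " TSG:", length(x$tsg),
      " removed:", length(x$del_star), ")\n")
  invisible(x)
}
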