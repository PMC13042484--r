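#' Topic marker table from gene-topic z-scores
#'
#' Per selected topic, lists the genes whose weight z-score strictly exceeds
#' `theta`, ranked by descending z-score.
#'
#' @param sel A `gene_selection` from [select_hsgs()].
#' @param theta z-score cutoff (default 1.96).
#' @return data.frame with columns `gene_id`, `scope` (topic index), `score`,
#'   `rank`.
#' @export
topic_marker_table <- function(sel, theta = 1.96) {
  zs <- sel$zscores
  out <- list()
  topics <- colnames(zs)
  if (is.null(topics)) topics <- as.character(seq_len(ncol(zs)))
  for (t in seq_len(ncol(zs))) {
    idx <- which(zs[, t] > theta)
    if (length(idx) == 0) {
      warning("no marker gene passes theta for topic ", topics[t])
      next
    }
    ord <- idx[order(-zs[idx, t], idx)]
    out[[t]] <- data.frame(gene_id = rownames(zs)[ord],
                           scope = topics[t],
                           score = zs[ord, t],
                           rank = seq_along(ord),
                           row.names = NULL)
  }
  if (length(out) == 0)
    return(data.frame(gene_id = character(0), scope = character(0),
                      score = numeric(0), rank = integer(0)))
  do.call(rbind, out)
}

#' Domain markers via domain-topic-gene correlation
#'
#' For each domain: (1) the topic whose activity best correlates (Pearson)
#' with the binary domain-membership vector is selected; (2) genes whose log
#' expression correlates with that topic's activity above `r_min` are listed
#' in descending correlation.
#'
#' @param labels Integer domain labels.
#' @param Z_final Spots x selected-topics activity matrix.
#' @param loggered Spots x genes log-normalized expression.
#' @param r_min Correlation threshold for reported markers.
#' @return data.frame with `gene_id`, `scope` (domain id), `topic`, `score`
#'   (Pearson r), `rank`.
#' @export
domain_topic_correlation_markers <- function(labels, Z_final, loggered,
                                             r_min = 0.3) {
  Z_final <- as.matrix(Z_final)
  stopifnot(length(labels) == nrow(Z_final),
            nrow(Z_final) == nrow(loggered))
  topic_sd <- apply(Z_final, 2, stats::sd)
  out <- list()
  for (d in sort(unique(labels))) {
    ind <- as.numeric(labels == d)
    if (stats::sd(ind) == 0) next
    rtop <- rep(-Inf, ncol(Z_final))
    ok <- topic_sd > 0
    rtop[ok] <- as.numeric(stats::cor(ind, Z_final[, ok, drop = FALSE]))
    best <- which.max(rtop)
    act <- Z_final[, best]
    gene_sd <- apply(loggered, 2, stats::sd)
    rg <- rep(NA_real_, ncol(loggered))
    rg[gene_sd > 0] <- as.numeric(stats::cor(act,
                                             loggered[, gene_sd > 0,
                                                      drop = FALSE]))
    idx <- which(!is.na(rg) & rg > r_min)
    if (length(idx) == 0) next
    ord <- idx[order(-rg[idx], idx)]
    out[[length(out) + 1]] <-
      data.frame(gene_id = colnames(loggered)[ord], scope = d,
                 topic = best, score = rg[ord], rank = seq_along(ord),
                 row.names = NULL)
  }
  if (length(out) == 0)
    return(data.frame(gene_id = character(0), scope = integer(0),
                      topic = integer(0), score = numeric(0),
                      rank = integer(0)))
  do.call(rbind, out)
}

#' Wilcoxon differential expression between spot groups
#'
#' Two-sided Wilcoxon rank-sum test per gene with Benjamini-Hochberg
#' adjustment across genes. Fold change compares group means on the
#' natural-expression scale (`expm1` of the log layer):
#' `log2FC = log2((mean_A + eps) / (mean_B + eps))`. Reported rows satisfy
#' `|log2FC| >= min_abs_l2fc` and `p_adj < fdr`.
#'
#' @param loggered Spots x genes log-normalized expression.
#' @param labels Integer group labels per spot.
#' @param group_a,group_b Label values defining the two groups.
#' @param fdr Adjusted-p cutoff.
#' @param min_abs_l2fc Absolute log2 fold-change cutoff.
#' @return data.frame with `gene_id`, `group`, `log2fc`, `p`, `p_adj`,
#'   `direction` (`"up"` means higher in `group_a`).
#' @export
differential_expression <- function(loggered, labels, group_a, group_b,
                                    fdr = 0.001, min_abs_l2fc = 1) {
  ia <- labels == group_a
  ib <- labels == group_b
  if (!any(ia) || !any(ib)) stop("both groups must be non-empty", call. = FALSE)
  if (sum(ia) < 3 || sum(ib) < 3)
    warning("group with fewer than 3 spots: rank-sum p-values are unstable")
  eps <- 1e-9
  G <- ncol(loggered)
  p <- numeric(G); l2fc <- numeric(G)
  for (g in seq_len(G)) {
    xa <- loggered[ia, g]; xb <- loggered[ib, g]
    p[g] <- if (stats::sd(c(xa, xb)) == 0) 1 else
      suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE)$p.value)
    l2fc[g] <- log2((mean(expm1(xa)) + eps) / (mean(expm1(xb)) + eps))
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  keep <- abs(l2fc) >= min_abs_l2fc & p_adj < fdr & !is.na(p_adj)
  data.frame(gene_id = colnames(loggered)[keep],
             group = group_a,
             log2fc = l2fc[keep], p = p[keep], p_adj = p_adj[keep],
             direction = ifelse(l2fc[keep] > 0, "up", "down"),
             row.names = NULL)[order(p_adj[keep], -abs(l2fc[keep])), ]
}

#' Cluster-specific up-regulated genes
#'
#' A gene is cluster-specific when it is significantly up-regulated in the
#' cluster against every other cluster separately (the one-vs-each
#' convention).
#'
#' @inheritParams differential_expression
#' @param cluster The cluster label of interest.
#' @return Character vector of gene ids.
#' @export
cluster_specific_genes <- function(loggered, labels, cluster,
                                   fdr = 0.001, min_abs_l2fc = 1) {
  others <- setdiff(unique(labels), cluster)
  sets <- lapply(others, function(o) {
    de <- differential_expression(loggered, labels, cluster, o,
                                  fdr = fdr, min_abs_l2fc = min_abs_l2fc)
    de$gene_id[de$direction == "up"]
  })
  Reduce(intersect, sets)
}
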