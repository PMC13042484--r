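#' Pipeline configuration
#'
#' Collects every stage parameter of the domain-identification pipeline with
#' its default. Ablation switches: `use_hsg = FALSE` feeds the model plain
#' HVGs instead of the selected HSG set; `dual_view = FALSE` drops the
#' feature-graph branch.
#'
#' @param min_locations,min_counts Gene detection filter thresholds.
#' @param target_sum Library size after normalization.
#' @param n_hvgs Number of highly variable genes.
#' @param n_pcs Principal components for consensus clustering.
#' @param leiden_resolutions Resolution grid of the consensus runs.
#' @param consensus_knn Neighbourhood size of the consensus Leiden graph.
#' @param init_resolution Leiden resolution for the pseudo-labels.
#' @param n_topics NMF topic count.
#' @param mri_threshold Moran's I retention threshold for topics.
#' @param rf_trees Random-forest size for topic importance.
#' @param topic_drop_p Fraction of low-importance topics discarded.
#' @param tau_low,tau_high Cumulative-contribution thresholds of the gene
#'   selection.
#' @param theta z-score cutoff for topic-specific genes.
#' @param spatial_k Spatial k-NN graph degree (Visium hexagon default 6).
#' @param tau Consensus pruning threshold of the spatial graph.
#' @param n_neighbors Feature-graph neighbourhood size and added-degree cap.
#' @param weights_k Neighbourhood size of the Moran's I spatial weights.
#' @param refine,refine_n Local label refinement switch and neighbourhood.
#' @param use_hsg,dual_view Ablation switches (see above).
#' @param dgnn A [sage_dgnn_config()] for the embedding model.
#' @return List of class `sage_config`.
#' @export
sage_config <- function(min_locations = 5, min_counts = 20,
                        target_sum = 10000, n_hvgs = 3000, n_pcs = 200,
                        leiden_resolutions = seq(0.1, 1.0, by = 0.1),
                        consensus_knn = 15, init_resolution = 1.0,
                        n_topics = 30, mri_threshold = 0.2, rf_trees = 100,
                        topic_drop_p = 0.2,
                        tau_low = 0.3, tau_high = 0.8, theta = 1.96,
                        spatial_k = 6, tau = 0.2, n_neighbors = 15,
                        weights_k = 6, refine = TRUE, refine_n = 25,
                        use_hsg = TRUE, dual_view = TRUE,
                        dgnn = sage_dgnn_config()) {
  structure(as.list(environment()), class = "sage_config")
}

#' Fit the spatial-domain model
#'
#' Runs the full pipeline: gene filtering, normalization, HVG selection and
#' PCA; multi-resolution consensus clustering into a co-assignment matrix and
#' pseudo-labels; NMF topic modeling with Moran's I and random-forest topic
#' filtering; high spatial-specificity gene (HSG) assembly; construction of
#' the consensus-pruned spatial graph and the consensus/cosine feature graph;
#' dual-view graph autoencoder training; and domain calling on the fused
#' embedding with optional local refinement.
#'
#' @param x An [st_dataset()], or a spots x genes count matrix (then supply
#'   `coords`).
#' @param coords Spot coordinates when `x` is a matrix.
#' @param n_domains Target number of domains (`NULL` triggers the
#'   Calinski-Harabasz resolution search).
#' @param config A [sage_config()].
#' @param seed Integer master seed; all stage seeds derive from it.
#' @return Object of class `sage` with components `dataset`, `layers`,
#'   `consensus` (`C`, `L_init`, `runs`), `topics`, `selection`, `features`
#'   (gene ids fed to the model), `graphs` (`A_coord`, `A_feat`), `model`
#'   (a `sage_dgnn`), `domains` (a `domain_result`), `labels`
#'   (convenience copy), `config`, `seed`.
#' @export
sage <- function(x, coords = NULL, n_domains = NULL,
                 config = sage_config(), seed = 0) {
  ds <- if (inherits(x, "st_dataset")) x else st_dataset(x, coords)
  ds <- filter_genes(ds, config$min_locations, config$min_counts)
  layers <- normalize_log1p(ds, config$target_sum)
  layers <- select_hvgs(layers, min(config$n_hvgs, ncol(layers$counts)))
  n_pcs <- min(config$n_pcs, nrow(layers$counts) - 1L, sum(layers$hvg_mask))
  layers <- reduce_pca(layers, n_pcs)

  runs <- run_multiresolution_clustering(layers$pcs, method = "leiden",
                                         settings = config$leiden_resolutions,
                                         knn_k = config$consensus_knn,
                                         seed = seed)
  C <- build_consensus_matrix(runs)
  init <- derive_initial_labels(C, config$init_resolution, seed = seed + 100)

  weights <- spatial_weights(layers$coords, k = config$weights_k)
  n_topics <- min(config$n_topics, min(dim(layers$loggered)) - 1L)
  tm <- fit_nmf(layers$loggered, n_topics = n_topics, seed = seed + 200)
  tm <- filter_topics_by_mri(tm, weights, config$mri_threshold)
  imp <- score_topic_importance(tm$Z_filtered, init$labels,
                                n_trees = config$rf_trees, seed = seed + 300)
  # degrade gracefully when few topics survive the spatial filter
  p_eff <- if (floor((1 - config$topic_drop_p) * ncol(tm$Z_filtered)) < 1)
    0 else config$topic_drop_p
  tm <- select_informative_topics(tm, imp, p = p_eff)

  selection <- select_hsgs(tm, layers, weights,
                           tau_low = config$tau_low,
                           tau_high = config$tau_high, theta = config$theta)
  features <- if (config$use_hsg) selection$hsg else selection$hvg
  X_feat <- layers$loggered[, features, drop = FALSE]

  A_coord <- build_spatial_graph(layers$coords, k = config$spatial_k,
                                 C = C, tau = config$tau)
  A_feat <- build_feature_graph(tm$Z_final, C,
                                n_neighbors = config$n_neighbors)

  dcfg <- config$dgnn
  dcfg$seed <- seed + 400
  dcfg$dual_view <- config$dual_view
  if (is.null(dcfg$n_prototypes) && !is.null(n_domains))
    dcfg$n_prototypes <- n_domains
  model <- train_model(X_feat, A_coord, A_feat, dcfg)

  E_att <- model$embeddings$E_att
  dom <- if (!is.null(n_domains)) {
    cluster_embeddings(E_att, n_clusters = n_domains, seed = seed + 500)
  } else {
    search_resolution(E_att, step = 0.01, seed = seed + 500)$result
  }
  if (config$refine) {
    dom$labels <- refine_labels_local(dom$labels, layers$coords,
                                      n = min(config$refine_n,
                                              length(dom$labels) - 1L))
    dom$refined <- TRUE
  }

  structure(list(dataset = ds, layers = layers,
                 consensus = list(C = C, runs = runs,
                                  L_init = init$labels,
                                  n_cluster = init$n_cluster),
                 topics = tm, selection = selection, features = features,
                 graphs = list(A_coord = A_coord, A_feat = A_feat),
                 model = model, domains = dom, labels = dom$labels,
                 config = config, seed = seed),
            class = "sage")
}

#' @export
print.sage <- function(x, ...) {
  cat("sage fit:", nrow(x$layers$counts), "spots,",
      ncol(x$layers$counts), "genes,",
      length(unique(x$labels)), "domains\n")
  cat("  features:", length(x$features),
      if (x$config$use_hsg) "HSGs" else "HVGs (ablation)", "\n")
  invisible(x)
}

#' @export
summary.sage <- function(object, ...) {
  h <- object$model$history
  cat("Spatial domain model\n")
  cat("  spots:", nrow(object$layers$counts),
      " genes:", ncol(object$layers$counts), "\n")
  cat("  consensus runs:", length(object$consensus$runs),
      " pseudo-label clusters:", object$consensus$n_cluster, "\n")
  cat("  topics:", object$topics$n_topics,
      "-> spatial:", length(object$topics$kept),
      "-> selected:", length(object$topics$selected), "\n")
  cat("  gene sets: HVG", length(object$selection$hvg),
      " TSG", length(object$selection$tsg),
      " HSG", length(object$selection$hsg), "\n")
  cat("  graph edges: spatial", sum(object$graphs$A_coord) / 2,
      " feature", sum(object$graphs$A_feat) / 2, "\n")
  cat("  training:", nrow(h), "epochs, total loss",
      signif(h$total[1], 4), "->", signif(h$total[nrow(h)], 4), "\n")
  cat("  domains:", length(unique(object$labels)),
      if (object$domains$refined) "(locally refined)", "\n")
  invisible(object)
}

#' Plot called domains or the training history
#'
#' @param x A `sage` fit.
#' @param type `"domains"` (spatial map coloured by domain) or `"loss"`.
#' @param ... Passed to the underlying plot call.
#' @export
plot.sage <- function(x, type = c("domains", "loss"), ...) {
  type <- match.arg(type)
  if (type == "domains") {
    cols <- grDevices::hcl.colors(max(length(unique(x$labels)), 3), "Dark 3")
    graphics::plot(x$layers$coords, col = cols[x$labels + 1L], pch = 16,
                   xlab = "x", ylab = "y", main = "Spatial domains", ...)
  } else {
    h <- x$model$history
    graphics::plot(h$epoch, h$total, type = "l", xlab = "epoch",
                   ylab = "total loss", main = "Training loss", ...)
  }
  invisible(x)
}

#' Evaluate a fit against reference labels
#'
#' Accuracy (NMI, HOM, COM, ARI) plus spatial-continuity (CHAOS, PAS, ASW)
#' metrics of the called domains.
#'
#' @param fit A `sage` object.
#' @param truth Reference labels aligned with the retained spots.
#' @return Named numeric vector.
#' @export
sage_evaluate <- function(fit, truth) {
  stopifnot(length(truth) == length(fit$labels))
  c(accuracy_metrics(fit$labels, truth),
    continuity_metrics(fit$labels, fit$layers$coords))
}
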