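test_that("NMF recovers a planted factorization and is deterministic", {
  set.seed(6)
  # three near-orthogonal topics
  Z0 <- matrix(0, 60, 3); Z0[cbind(1:60, rep(1:3, each = 20))] <- runif(60, 1, 2)
  H0 <- matrix(0, 30, 3); H0[cbind(1:30, rep(1:3, each = 10))] <- runif(30, 1, 2)
  A <- Z0 %*% t(H0)
  tm <- fit_nmf(A, n_topics = 3, seed = 1)
  expect_lt(tm$recon_error, 0.01 * sqrt(sum(A^2)))
  expect_true(all(tm$H >= 0))
  expect_true(all(tm$Z >= 0 & tm$Z <= 1 + 1e-12))
  tm2 <- fit_nmf(A, n_topics = 3, seed = 1)
  expect_identical(tm$Z, tm2$Z)
  expect_identical(tm$H, tm2$H)
  expect_error(fit_nmf(A - 10, 3), "negative-input")
})

test_that("degenerate min-max normalization maps constant columns to zero", {
  col <- c(0.3, 0.7, 0.5)
  rng <- range(col)
  expect_equal((col - rng[1]) / diff(rng), c(0, 1, 0.5))
  # via the exported path: constant factor column cannot occur from MU with
  # NNDSVD on generic input, so exercise the guard directly
  Z <- apply(matrix(2, 4, 1), 2, function(cl) {
    r <- range(cl)
    if (r[2] > r[1]) (cl - r[1]) / (r[2] - r[1]) else rep(0, length(cl))
  })
  expect_equal(Z[, 1], rep(0, 4))
})

test_that("Moran filter keeps spatial topics and honours the >= boundary", {
  sim <- sim_default(1)
  lay <- normalize_log1p(filter_genes(sim$dataset))
  w <- spatial_weights(lay$coords, 6)
  tm <- cached("tm30", fit_nmf(lay$loggered, 30, seed = 2))
  tmf <- filter_topics_by_mri(tm, w, threshold = 0.2)
  expect_true(all(tmf$mri[tmf$kept] >= 0.2))
  expect_true(all(tmf$mri[setdiff(seq_len(30), tmf$kept)] < 0.2))
  # boundary: setting the threshold to an attained value keeps that topic
  attained <- max(tmf$mri)
  tmb <- filter_topics_by_mri(tm, w, threshold = attained)
  expect_true(which.max(tmf$mri) %in% tmb$kept)
  expect_error(filter_topics_by_mri(tm, w, threshold = 2), "no-spatial-topics")
  # spatially shuffled topic activity loses its autocorrelation
  smooth <- tmf$Z_filtered[, 1]
  set.seed(4)
  expect_gt(morans_i(smooth, w), morans_i(sample(smooth), w))
})

test_that("random-forest importance finds the predictive topic", {
  set.seed(10)
  n <- 200
  labels <- rep(0:2, length.out = n)
  Z <- matrix(runif(n * 5), n, 5)
  Z[, 3] <- labels / 2 + rnorm(n, 0, 0.05)     # topic 3 encodes the labels
  imp <- score_topic_importance(Z, labels, n_trees = 100, seed = 1)
  expect_equal(which.max(imp), 3L)
  expect_true(all(imp >= 0))
  expect_equal(sum(imp), 1)
  # permuted labels -> no topic dominates
  imp_null <- score_topic_importance(Z, sample(labels), n_trees = 100, seed = 1)
  expect_lt(max(imp_null), 0.5)
  # invariant to relabeling of the cluster ids
  imp_rl <- score_topic_importance(Z, 2 - labels, n_trees = 100, seed = 1)
  expect_equal(which.max(imp_rl), 3L)
  expect_error(score_topic_importance(Z, rep(1, n)), "degenerate-labels")
})

test_that("topic selection keeps the top (1-p) fraction with index ties", {
  tm <- structure(list(Z_filtered = matrix(runif(40), 4, 10),
                       kept = 1:10), class = "sage_topics")
  imp <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1) / 55
  sel <- select_informative_topics(tm, imp, p = 0.2)
  expect_equal(ncol(sel$Z_final), 8)           # floor(0.8 * 10)
  expect_equal(sel$selected, 1:8)
  # p = 0 is the identity
  expect_equal(ncol(select_informative_topics(tm, imp, 0)$Z_final), 10)
  # ties at the cut resolved by ascending topic index
  imp_t <- c(5, 4, 1, 1, 1, 1, 1, 1, 1, 1) / 17
  sel_t <- select_informative_topics(tm, imp_t, p = 0.5)
  expect_equal(sel_t$selected, c(1, 2, 3, 4, 5))
  expect_error(select_informative_topics(
    structure(list(Z_filtered = matrix(1, 4, 1), kept = 1),
              class = "sage_topics"), 1, p = 0.5), "no-topics-selected")
})

test_that("topic count never grows along the filtering chain", {
  sim <- sim_default(1)
  lay <- normalize_log1p(filter_genes(sim$dataset))
  w <- spatial_weights(lay$coords, 6)
  tm <- cached("tm30", fit_nmf(lay$loggered, 30, seed = 2))
  tmf <- filter_topics_by_mri(tm, w, 0.2)
  expect_lte(ncol(tmf$Z_filtered), 30)
  imp <- score_topic_importance(tmf$Z_filtered, rep(0:3, length.out = 400),
                                seed = 5)
  tms <- select_informative_topics(tmf, imp, 0.2)
  expect_lte(ncol(tms$Z_final), ncol(tmf$Z_filtered))
})
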