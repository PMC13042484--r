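test_that("gene-topic weight normalization and ranks follow the definitions", {
  H <- cbind(c(2, 2, 4), c(1, 1, 2), c(0, 0, 0))
  Hn <- normalize_gene_topic_weights(H, 1:2)
  expect_equal(Hn[, 1], c(0.25, 0.25, 0.5))
  expect_equal(colSums(Hn), c(1, 1))
  # already-normalized column is untouched
  expect_equal(normalize_gene_topic_weights(Hn, 1), Hn[, 1, drop = FALSE])
  expect_error(normalize_gene_topic_weights(H, 3), "empty-topic")

  R <- compute_rank_matrix(cbind(c(0.5, 0.3, 0.2)))
  expect_equal(R[, 1], c(1L, 2L, 3L))
  # tie broken by gene index
  expect_equal(compute_rank_matrix(cbind(c(0.4, 0.4, 0.2)))[, 1], c(1L, 2L, 3L))
  # argsort oracle on random columns
  set.seed(3)
  col <- runif(25)
  Rr <- compute_rank_matrix(cbind(col))[, 1]
  expect_equal(order(Rr), order(-col))
})

test_that("cumulative rank thresholds use descending order and >= inclusion", {
  Hn <- cbind(c(0.5, 0.3, 0.2))
  thr <- cumulative_rank_thresholds(Hn, tau_low = 0.7, tau_high = 1.0)
  expect_equal(thr$r_low, 2L)
  expect_equal(thr$r_high, 3L)          # tau_high = 1 reaches the last gene
  expect_equal(cumulative_rank_thresholds(Hn, 0.5, 0.8)$r_low, 1L)  # inclusive
  expect_error(cumulative_rank_thresholds(Hn, 0.8, 0.5), "invalid-quantiles")
  set.seed(1)
  col <- runif(30); col <- col / sum(col)
  thr2 <- cumulative_rank_thresholds(cbind(col), 0.3, 0.8)
  cum <- cumsum(sort(col, decreasing = TRUE))
  expect_equal(thr2$r_low, which(cum >= 0.3)[1])
  expect_lte(thr2$r_low, thr2$r_high)
})

test_that("topic z-scores use the population standard deviation", {
  z <- topic_zscores(cbind(c(1, 2, 3)))
  expect_equal(z[3, 1], (3 - 2) / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(z[3, 1], 1.2247, tolerance = 1e-4)
  expect_equal(mean(z[, 1]), 0, tolerance = 1e-12)
  expect_equal(mean(z[, 1]^2), 1, tolerance = 1e-12)
  expect_error(topic_zscores(cbind(c(2, 2, 2))), "constant-topic")
})

test_that("TSG membership needs head rank AND a strict z-score exceedance", {
  genes <- paste0("g", 1:4)
  R <- cbind(c(1L, 2L, 3L, 4L))
  zs <- cbind(c(2.5, 1.96, 3.0, 0.0))
  tsg <- select_tsgs(R, zs, r_low = 2L, genes, theta = 1.96)
  expect_equal(tsg, "g1")               # g2 at exactly 1.96 is excluded
  # below the head rank in all topics -> excluded regardless of z
  expect_false("g3" %in% tsg)
  expect_warning(select_tsgs(R, zs * 0, 2L, genes), "no topic-specific")
})

test_that("non-TSG sets respect the HVG domain and the rescue algebra", {
  genes <- paste0("g", 1:5)
  R <- cbind(c(1L, 4L, 5L, 3L, 2L), c(2L, 5L, 4L, 3L, 1L))
  rownames(R) <- genes
  hvg <- c("g2", "g3", "g5")
  nti <- initial_non_tsgs(R, r_high = c(3L, 3L), genes, hvg)
  expect_setequal(nti, c("g2", "g3"))   # g5 is inside r_high in topic 2
  expect_false("g1" %in% nti)           # non-HVG never included
  mri <- c(g1 = .9, g2 = .8, g3 = .1, g4 = .5, g5 = .2)
  s <- rowSums(R)
  resc <- rescue_spatial_genes(nti, mri, s, theta_mri = 0.5, theta_s = 8)
  expect_setequal(resc$rescued, "g2")   # high MRI, rank sum 9 > 8
  expect_setequal(resc$non_tsg, "g3")
  expect_true(all(resc$rescued %in% nti))
  # infinite threshold disables the rescue entirely
  none <- rescue_spatial_genes(nti, mri, s, theta_mri = Inf, theta_s = 0)
  expect_equal(none$rescued, character(0))
  expect_setequal(none$non_tsg, nti)
})

test_that("HSG assembly enforces the net-gain cap", {
  R <- matrix(c(5L, 1L, 4L, 2L, 3L), 5, 1,
              dimnames = list(paste0("g", 1:5), NULL))
  # TSG subset of HVG -> cap 0, nothing removed
  out <- assemble_hsgs(hvg = c("g1", "g2"), tsg = "g2",
                       non_tsg = "g1", R = R)
  expect_equal(out$del_star, character(0))
  expect_setequal(out$hsg, c("g1", "g2"))
  # cap limits removals to |TSG \ HVG|
  out2 <- assemble_hsgs(hvg = c("g1", "g3", "g4"), tsg = c("g2", "g5"),
                        non_tsg = c("g1", "g3", "g4"), R = R)
  expect_lte(length(out2$del_star), 2)
  expect_true(all(c("g2", "g5") %in% out2$hsg))
  # worst min-rank removed first: g1 (rank 5) before g3 (rank 4)
  expect_equal(out2$del_star, c("g1", "g3"))
})

test_that("set-algebra invariants hold over randomized inputs", {
  set.seed(99)
  for (i in 1:100) {
    G <- 40
    genes <- paste0("g", 1:G)
    K <- sample(2:4, 1)
    H <- matrix(rexp(G * K), G, K, dimnames = list(genes, NULL))
    Hn <- normalize_gene_topic_weights(H, 1:K)
    R <- compute_rank_matrix(Hn); rownames(R) <- genes
    thr <- cumulative_rank_thresholds(Hn, 0.3, 0.8)
    zs <- topic_zscores(H)
    hvg <- sample(genes, sample(5:20, 1))
    tsg <- suppressWarnings(select_tsgs(R, zs, thr$r_low, genes))
    nti <- initial_non_tsgs(R, thr$r_high, genes, hvg)
    mri <- stats::setNames(runif(G, -0.2, 0.9), genes)
    resc <- rescue_spatial_genes(nti, mri, rowSums(R))
    out <- assemble_hsgs(hvg, tsg, resc$non_tsg, R)
    expect_lte(length(out$del_star), length(out$add) - length(hvg))
    expect_true(all(tsg %in% out$hsg))
    expect_gte(length(out$hsg), length(hvg))
  }
})

test_that("full gene selection is deterministic and internally consistent", {
  fit <- fit_default(1)
  sel <- fit$selection
  expect_equal(colSums(sel$H_norm), rep(1, ncol(sel$H_norm)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(apply(sel$R, 2, sort) == seq_len(nrow(sel$R))))
  expect_setequal(sel$hsg, setdiff(sel$add, sel$del_star))
  expect_gte(length(sel$hsg), length(sel$hvg))
  expect_true(all(sel$tsg %in% sel$hsg))
  lay <- fit$layers
  w <- spatial_weights(lay$coords, 6)
  sel2 <- select_hsgs(fit$topics, lay, w)
  expect_identical(sel2$hsg, sel$hsg)
})
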