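test_that("topic marker table lists strict z-score exceedances in order", {
  fit <- fit_default(1)
  mt <- topic_marker_table(fit$selection, theta = 1.96)
  expect_true(all(mt$score > 1.96))
  # scores match a recomputation from the stored z-score matrix
  for (k in seq_len(nrow(mt))) {
    expect_equal(mt$score[k],
                 fit$selection$zscores[mt$gene_id[k],
                                       as.integer(mt$scope[k])][[1]])
  }
  # ranks descend within each scope
  for (sc in unique(mt$scope)) {
    sub <- mt[mt$scope == sc, ]
    expect_true(all(diff(sub$score) <= 1e-12))
    expect_equal(sub$rank, seq_len(nrow(sub)))
  }
  # planted high-weight gene ranks first for its topic
  zs <- matrix(c(5, 0, 1, -1), 4, 1,
               dimnames = list(paste0("g", 1:4), NULL))
  sel <- structure(list(zscores = zs), class = "gene_selection")
  mt2 <- topic_marker_table(sel)
  expect_equal(mt2$gene_id[1], "g1")
  # no gene passing -> empty with a warning
  expect_warning(out <- topic_marker_table(
    structure(list(zscores = zs * 0), class = "gene_selection")), "no marker")
  expect_equal(nrow(out), 0)
})

test_that("domain-topic correlation markers follow the Pearson chain", {
  set.seed(30)
  n <- 40
  labels <- rep(0:1, each = n / 2)
  Z <- cbind(as.numeric(labels == 0) + rnorm(n, 0, 0.01),
             runif(n))
  logg <- cbind(copycat = Z[, 1],
                noise = rnorm(n),
                anti = -Z[, 1] + rnorm(n, 0, 0.01))
  mk <- domain_topic_correlation_markers(labels, Z, logg, r_min = 0.3)
  d0 <- mk[mk$scope == 0, ]
  expect_equal(d0$topic[1], 1)                 # topic 1 matches domain 0
  expect_equal(d0$gene_id[1], "copycat")       # exact copy: r ~ 1, rank 1
  expect_gt(d0$score[1], 0.99)
  expect_false("noise" %in% d0$gene_id)
  # brute-force Pearson on a 20-spot toy
  lab2 <- rep(0:1, 10)
  Z2 <- cbind(rnorm(20))
  g2 <- cbind(gene = rnorm(20))
  mk2 <- domain_topic_correlation_markers(lab2, Z2, g2, r_min = -1.1)
  r_manual <- sum((Z2[, 1] - mean(Z2)) * (g2[, 1] - mean(g2))) /
    sqrt(sum((Z2[, 1] - mean(Z2))^2) * sum((g2[, 1] - mean(g2))^2))
  expect_equal(mk2$score[1], r_manual, tolerance = 1e-12)
  # raising r_min can only shrink marker lists
  mk_hi <- domain_topic_correlation_markers(labels, Z, logg, r_min = 0.8)
  expect_lte(nrow(mk_hi), nrow(mk))
})

test_that("Wilcoxon DEGs respect thresholds, direction and gene order", {
  set.seed(31)
  n <- 60
  labels <- rep(c("a", "b"), each = n / 2)
  logg <- cbind(null1 = rnorm(n, 1),             # same distribution
                up_a = c(rnorm(n / 2, 3), rnorm(n / 2, 0.2, 0.1)),
                dn_a = c(rnorm(n / 2, 0.2, 0.1), rnorm(n / 2, 3)))
  logg <- pmax(logg, 0)
  de <- differential_expression(logg, labels, "a", "b", fdr = 0.01)
  expect_false("null1" %in% de$gene_id)
  expect_true(all(abs(de$log2fc) >= 1))
  expect_true(all(de$p_adj < 0.01))
  expect_equal(de$direction[de$gene_id == "up_a"], "up")
  expect_equal(de$direction[de$gene_id == "dn_a"], "down")
  # invariant to gene order
  perm <- c(3, 1, 2)
  de_p <- differential_expression(logg[, perm], labels, "a", "b", fdr = 0.01)
  expect_setequal(de_p$gene_id, de$gene_id)
  expect_error(differential_expression(logg, labels, "a", "zzz"), "non-empty")
})

test_that("BH adjustment matches the brute-force step-up procedure", {
  set.seed(32)
  p <- runif(10)^2
  manual <- {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n); out[o] <- pmin(adj, 1); out
  }
  expect_equal(p.adjust(p, "BH"), manual, tolerance = 1e-12)
  # and the DEG table carries BH-adjusted values
  n <- 40
  labels <- rep(c("a", "b"), each = 20)
  logg <- matrix(rnorm(n * 6), n, 6,
                 dimnames = list(NULL, paste0("g", 1:6)))
  logg[1:20, 1] <- logg[1:20, 1] + 4
  logg <- pmax(logg, 0)
  de <- differential_expression(logg, labels, "a", "b", fdr = 1,
                                min_abs_l2fc = 0)
  praw <- sapply(colnames(logg), function(g)
    suppressWarnings(wilcox.test(logg[1:20, g], logg[21:40, g],
                                 exact = FALSE)$p.value))
  expect_equal(sort(de$p_adj), sort(unname(p.adjust(praw, "BH"))),
               tolerance = 1e-10)
})

test_that("cluster-specific genes are up against every other cluster", {
  set.seed(33)
  n <- 90
  labels <- rep(0:2, each = 30)
  logg <- matrix(abs(rnorm(n * 4)), n, 4,
                 dimnames = list(NULL, paste0("g", 1:4)))
  logg[labels == 0, 1] <- logg[labels == 0, 1] + 5   # g1 specific to 0
  logg[labels != 2, 2] <- logg[labels != 2, 2] + 5   # g2 shared by 0 and 1
  cs <- cluster_specific_genes(logg, labels, 0, fdr = 0.01)
  expect_true("g1" %in% cs)
  expect_false("g2" %in% cs || "g3" %in% cs)
})
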