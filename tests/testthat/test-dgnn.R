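test_that("encoder reduces to identity in the trivial configuration", {
  n <- 4
  X <- matrix(abs(rnorm(n * 3)), n, 3)
  params <- list(W1 = diag(3), W2 = diag(3), b2 = rep(0, 3),
                 W_omega = diag(3), u_omega = rep(1, 3))
  A0 <- matrix(0, n, n)                       # A + I = I, degrees 1
  enc <- encode_views(X, A0, A0, params)
  expect_equal(enc$E_v1, X, tolerance = 1e-12)
  expect_equal(enc$E_v1, enc$E_v2)            # shared weights, same graph
  expect_error(encode_views(X[, 1:2], A0, A0, params), "dimension-error")
})

test_that("encoder matches hand-computed message passing on a 3-node path", {
  A <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  X <- diag(3)                                # one-hot features
  params <- list(W1 = diag(3), W2 = diag(3), b2 = rep(0, 3),
                 W_omega = diag(3), u_omega = rep(1, 3))
  enc <- encode_views(X, A, A, params)
  # A_tilde = D^-1/2 (A+I) D^-1/2 with degrees (2, 3, 2)
  d <- c(2, 3, 2)
  At <- (A + diag(3)) / sqrt(outer(d, d))
  expect_equal(enc$E_v1, At %*% X, tolerance = 1e-12)
  expect_equal(enc$E_v1[1, 2], 1 / sqrt(6), tolerance = 1e-12)
})

test_that("attention fusion is a softmax-weighted convex combination", {
  set.seed(2)
  E <- matrix(rnorm(12), 4, 3)
  params <- init_model_params(3, 3, 3, seed = 1)
  # identical views -> exactly (0.5, 0.5)
  f <- fuse_attention(E, E, params)
  expect_equal(f$alpha, matrix(0.5, 4, 2), ignore_attr = TRUE)
  expect_equal(f$E_att, E, tolerance = 1e-12)
  # general views: rows on the simplex, fused row on the segment
  E2 <- matrix(rnorm(12), 4, 3)
  f2 <- fuse_attention(E, E2, params)
  expect_equal(rowSums(f2$alpha), rep(1, 4))
  expect_true(all(f2$alpha > 0 & f2$alpha < 1))
  expect_equal(f2$E_att, f2$alpha[, 1] * E + f2$alpha[, 2] * E2)
  # scalar worked example: one spot, hand-set parameters
  p1 <- list(W_omega = diag(2), u_omega = c(1, 0))
  e1 <- matrix(c(1, 0), 1, 2); e2 <- matrix(c(0, 1), 1, 2)
  s <- c(tanh(1), tanh(0))
  a <- exp(s) / sum(exp(s))
  f3 <- fuse_attention(e1, e2, p1)
  expect_equal(as.numeric(f3$alpha), a, tolerance = 1e-12)
})

test_that("decoders mirror the encoder weights", {
  set.seed(3)
  params <- init_model_params(5, 4, 3, seed = 2)
  E <- matrix(abs(rnorm(6 * 3)), 6, 3)
  dec <- decode_views(E, E, E, params)
  expect_equal(dec$v1, pmax(E %*% t(params$W2), 0) %*% t(params$W1))
  expect_equal(dec$v1, dec$att)               # identical inputs
  expect_equal(decode_views(0 * E, 0 * E, 0 * E, params)$v1,
               matrix(0, 6, 5), ignore_attr = TRUE)
  # non-negative weights and latent: ReLU passes through, so the decoder is
  # the plain matrix product E W2' W1'
  pw <- list(W1 = matrix(runif(20), 5, 4), W2 = matrix(runif(12), 4, 3),
             b2 = rep(0, 3), W_omega = diag(3), u_omega = rep(1, 3))
  Epos <- abs(matrix(rnorm(18), 6, 3))
  expect_equal(decode_views(Epos, Epos, Epos, pw)$v1,
               Epos %*% t(pw$W2) %*% t(pw$W1), tolerance = 1e-12)
})

test_that("Sinkhorn normalization attains uniform marginals", {
  set.seed(7)
  S <- matrix(rnorm(30), 10, 3)
  Q <- sinkhorn_normalize(S, n_iters = 50, epsilon = 1)
  expect_lt(max(abs(rowSums(Q) - 1 / 10)), 1e-6)
  expect_lt(max(abs(colSums(Q) - 1 / 3)), 1e-6)
  # doubly-stochastic input is (up to scale) a fixed point
  U <- matrix(1, 6, 3) / 18
  Qu <- sinkhorn_normalize(log(U), n_iters = 5, epsilon = 1)
  expect_equal(Qu, U, tolerance = 1e-12, ignore_attr = TRUE)
  # large epsilon flattens towards uniform
  Qe <- sinkhorn_normalize(S, n_iters = 50, epsilon = 1e6)
  expect_lt(max(abs(Qe - 1 / 30)), 1e-6)
})

test_that("SwAV assignments are consistent and balanced", {
  # angularly separated blobs (cosine-based assignment needs direction,
  # not magnitude, to differ)
  set.seed(8)
  b <- list(x = rbind(matrix(rnorm(80, mean = 6), 20, 4),
                      matrix(rnorm(80, mean = 6), 20, 4) *
                        matrix(c(-1, -1, 1, 1), 20, 4, byrow = TRUE)),
            labels = rep(1:2, each = 20))
  sw <- swav_assignments(b$x, b$x, b$x, n_prototypes = 2, seed = 1)
  expect_equal(sw$Q_v1, sw$Q_v2)
  expect_lt(max(abs(colSums(sw$Q_v1) - 1 / 2)), 1e-6)
  hard <- max.col(sw$Q_v1)
  expect_equal(accuracy_metrics(hard, b$labels)[["ari"]], 1)
})

test_that("loss identities hold", {
  set.seed(4)
  n <- 5; din <- 3
  X <- matrix(abs(rnorm(n * din)), n, din)
  A <- matrix(rbinom(n * n, 1, 0.5), n, n); A <- pmax(A, t(A)); diag(A) <- 0
  E <- matrix(rnorm(n * 2), n, 2)
  alpha <- matrix(0.5, n, 2)
  Q <- matrix(1 / (n * 3), n, 3)
  rec <- list(v1 = X, v2 = X, att = X)       # perfect reconstruction
  L <- compute_losses(X, rec, A, A, E, alpha, Q, Q, lambdas = c(1, 2, 3, 4))
  expect_equal(L$recon, 0)
  expect_equal(L$att, 0)                      # alpha = 1/2 everywhere
  expect_equal(L$swav, 0)                     # identical assignments
  # linearity of the total in the lambda weights
  rec2 <- list(v1 = X + 1, v2 = X, att = X)
  alpha2 <- matrix(c(0.8, 0.2), n, 2, byrow = TRUE)
  Q2 <- sinkhorn_normalize(matrix(rnorm(n * 3), n, 3), 10, 0.5)
  L1 <- compute_losses(X, rec2, A, A, E, alpha2, Q, Q2, c(1, 0, 0, 0))
  L2 <- compute_losses(X, rec2, A, A, E, alpha2, Q, Q2, c(0, 1, 0, 0))
  L3 <- compute_losses(X, rec2, A, A, E, alpha2, Q, Q2, c(0, 0, 1, 0))
  L4 <- compute_losses(X, rec2, A, A, E, alpha2, Q, Q2, c(0, 0, 0, 1))
  Lw <- compute_losses(X, rec2, A, A, E, alpha2, Q, Q2, c(10, 10, 5, 1))
  expect_equal(Lw$total,
               10 * L1$total + 10 * L2$total + 5 * L3$total + 1 * L4$total,
               tolerance = 1e-10)
  expect_true(all(c(L$recon, L$graph, L$swav, L$att) >= 0))
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  n <- 6; din <- 4; dh <- 3; dout <- 2; K <- 2
  X <- matrix(abs(rnorm(n * din)), n, din)
  mk <- function() {
    A <- matrix(rbinom(n * n, 1, .4), n, n); A <- pmax(A, t(A)); diag(A) <- 0; A
  }
  A1 <- mk(); A2 <- mk()
  params <- init_model_params(din, dh, dout, seed = 3)
  centers <- matrix(rnorm(K * dout), K, dout)
  lam <- c(10, 10, 5, 1)
  cst <- list(X = X, M1 = sagest:::normalize_adjacency(A1) %*% X,
              M2 = sagest:::normalize_adjacency(A2) %*% X,
              A1 = A1, A2 = A2, pairs = NULL, dual_view = TRUE,
              sk_iters = 3, sk_eps = 0.5)
  f <- function(p) sagest:::dgnn_forward(p, cst, lam, centers)$losses$total
  fw <- sagest:::dgnn_forward(params, cst, lam, centers)
  g <- sagest:::dgnn_backward(params, cst, fw, lam)
  eps <- 1e-6
  for (nm in names(params)) {
    num <- 0 * params[[nm]]
    for (i in seq_along(num)) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      num[i] <- (f(p1) - f(p2)) / (2 * eps)
    }
    expect_lt(max(abs(num - g[[nm]])) / max(1e-8, max(abs(num))), 1e-5)
  }
})

test_that("training reduces the loss, is symmetric and reproducible", {
  sim <- generate_synthetic_st(n_side = 8, n_domains = 2, n_genes = 60,
                               n_markers_per_domain = 5, n_noise_hvg = 5,
                               seed = 12)
  lay <- normalize_log1p(filter_genes(sim$dataset))
  X <- lay$loggered[, 1:40]
  A <- as.matrix(build_spatial_graph(lay$coords, k = 4))
  cfg <- sage_dgnn_config(d_hid = 16, d_out = 8, epochs = 60,
                          n_prototypes = 2, seed = 5)
  m <- train_model(X, A, A, cfg)
  expect_lt(m$history$total[60], m$history$total[1])
  # identical graphs + shared weights: the two views coincide throughout
  expect_equal(m$embeddings$E_v1, m$embeddings$E_v2, tolerance = 1e-10)
  # alpha rows stay on the simplex
  expect_equal(rowSums(m$embeddings$alpha), rep(1, nrow(X)))
  expect_true(all(m$embeddings$alpha >= 0))
  # bitwise reproducibility under the seed
  m2 <- train_model(X, A, A, cfg)
  expect_identical(m$history, m2$history)
  expect_identical(m$params, m2$params)
  # single-view ablation pins the attention to the spatial view
  cfg1 <- sage_dgnn_config(d_hid = 16, d_out = 8, epochs = 10,
                           dual_view = FALSE, seed = 5)
  m1 <- train_model(X, A, A, cfg1)
  expect_equal(unique(m1$embeddings$alpha[, 1]), 1)
  expect_equal(m1$embeddings$E_att, m1$embeddings$E_v1)
})
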