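#' Symmetric adjacency normalization with self-loops
#'
#' `A_tilde = D^{-1/2} (A + I) D^{-1/2}` with `D` the degree matrix of
#' `A + I`; the standard propagation operator of graph convolutions.
#'
#' @param A Square (sparse or dense) binary adjacency matrix.
#' @return Dense normalized matrix.
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  diag(A) <- diag(A) + 1
  dinv <- 1 / sqrt(rowSums(A))
  A * (dinv %o% dinv)
}

#' Training configuration for the dual-view graph autoencoder
#'
#' @param d_hid Hidden width of the GCN layer.
#' @param d_out Embedding dimension.
#' @param epochs Training epochs (full-batch gradient steps).
#' @param lr Adam learning rate.
#' @param lambdas Loss weights `(reconstruction, graph, swav, attention)`.
#' @param warmup_frac Fraction of epochs trained with the SwAV weight at 0
#'   (reconstruction warm-up); afterwards `lambdas[3]` applies.
#' @param sinkhorn_iters,sinkhorn_eps Sinkhorn-Knopp iteration count and
#'   entropic scale for the SwAV assignments.
#' @param n_prototypes Number of SwAV prototypes (defaults to the target
#'   domain count when known, else 15).
#' @param refresh_every Epoch interval at which K-means prototypes are
#'   refit on the fused embedding.
#' @param pair_limit Above this spot count the graph BCE is evaluated on all
#'   edges plus an equal number of seeded non-edges instead of all pairs.
#' @param seed Integer seed controlling initialization and prototype refits.
#' @param dual_view `FALSE` drops the feature view: the fused embedding is
#'   the spatial-view embedding, attention is pinned to `(1, 0)` and the SwAV
#'   term vanishes.
#' @return A list of class `sage_dgnn_config`.
#' @export
sage_dgnn_config <- function(d_hid = 256, d_out = 64, epochs = 600, lr = 1e-3,
                             lambdas = c(10, 10, 5, 1), warmup_frac = 0.2,
                             sinkhorn_iters = 3, sinkhorn_eps = 0.05,
                             n_prototypes = NULL, refresh_every = 20,
                             pair_limit = 5000, seed = 0, dual_view = TRUE) {
  stopifnot(length(lambdas) == 4, all(lambdas >= 0))
  structure(list(d_hid = d_hid, d_out = d_out, epochs = epochs, lr = lr,
                 lambdas = lambdas, warmup_frac = warmup_frac,
                 sinkhorn_iters = sinkhorn_iters, sinkhorn_eps = sinkhorn_eps,
                 n_prototypes = n_prototypes, refresh_every = refresh_every,
                 pair_limit = pair_limit, seed = seed, dual_view = dual_view),
            class = "sage_dgnn_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize model parameters
#'
#' Glorot-uniform weights for the shared two-layer encoder (`W1`, `W2`,
#' `b2`), the attention transform `W_omega` and context vector `u_omega`.
#'
#' @param d_in,d_hid,d_out Layer dimensions (`d_in` = number of HSGs).
#' @param seed Integer seed.
#' @return List of parameter matrices.
#' @export
init_model_params <- function(d_in, d_hid, d_out, seed = 0) {
  with_seed(seed, list(
    W1 = glorot(d_in, d_hid),
    W2 = glorot(d_hid, d_out),
    b2 = rep(0, d_out),
    W_omega = glorot(d_out, d_out),
    u_omega = glorot(d_out, 1)[, 1]
  ))
}

#' Encode both graph views with shared weights
#'
#' Per view: `H1 = ReLU(A_tilde X W1)`, `E = H1 W2 + b2`. The two views share
#' all encoder parameters; they differ only in the propagation operator.
#'
#' @param X_HSG Spots x HSG log-expression matrix.
#' @param A_coord,A_feat Binary adjacency matrices (spatial / feature view).
#' @param params Parameters from [init_model_params()].
#' @return List with `E_v1`, `E_v2`.
#' @export
encode_views <- function(X_HSG, A_coord, A_feat, params) {
  if (ncol(X_HSG) != nrow(params$W1))
    stop("dimension-error: X columns must equal nrow(W1)", call. = FALSE)
  f <- function(A) {
    Z1 <- normalize_adjacency(A) %*% X_HSG %*% params$W1
    H1 <- pmax(Z1, 0)
    sweep(H1 %*% params$W2, 2, params$b2, "+")
  }
  list(E_v1 = f(A_coord), E_v2 = f(A_feat))
}

attention_forward <- function(E1, E2, params) {
  V1 <- tanh(E1 %*% params$W_omega)
  V2 <- tanh(E2 %*% params$W_omega)
  S <- cbind(V1 %*% params$u_omega, V2 %*% params$u_omega)
  Sm <- S - apply(S, 1, max)
  eS <- exp(Sm)
  alpha <- eS / rowSums(eS)
  E_att <- alpha[, 1] * E1 + alpha[, 2] * E2
  list(E_att = E_att, alpha = alpha, V1 = V1, V2 = V2)
}

#' Fuse view embeddings by self-attention
#'
#' `v_i^(k) = tanh(E_i^(k) W_omega)`, attention scores `v_i^(k) . u_omega`,
#' per-spot softmax over the two views, and the convex fusion
#' `E_att = alpha_1 E_v1 + alpha_2 E_v2`.
#'
#' @param E_v1,E_v2 View embeddings (same shape).
#' @param params Parameters from [init_model_params()].
#' @return List with `E_att` and `alpha` (N x 2, rows on the simplex).
#' @export
fuse_attention <- function(E_v1, E_v2, params) {
  out <- attention_forward(E_v1, E_v2, params)
  list(E_att = out$E_att, alpha = out$alpha)
}

#' Decode embeddings through the transposed encoder
#'
#' `X_rec = ReLU(E W2') W1'` for each of the three embeddings; the decoders
#' mirror the encoder and own no parameters of their own.
#'
#' @param E_v1,E_v2,E_att Embedding matrices.
#' @param params Parameters from [init_model_params()].
#' @return List of reconstructions `v1`, `v2`, `att`.
#' @export
decode_views <- function(E_v1, E_v2, E_att, params) {
  dec <- function(E) pmax(E %*% t(params$W2), 0) %*% t(params$W1)
  list(v1 = dec(E_v1), v2 = dec(E_v2), att = dec(E_att))
}

#' Sinkhorn-Knopp normalization to uniform marginals
#'
#' Exponentiates `scores / epsilon` (stabilized by row-max subtraction) and
#' alternately rescales rows to sum to `1/N` and columns to `1/K`.
#'
#' @param scores Numeric N x K matrix.
#' @param n_iters Number of row/column normalization rounds.
#' @param epsilon Entropic scale; large values flatten `Q` toward uniform.
#' @return Doubly-(near-)stochastic matrix `Q` (rows `1/N`, columns `1/K`).
#' @export
sinkhorn_normalize <- function(scores, n_iters = 3, epsilon = 0.05) {
  sinkhorn_forward(scores, n_iters, epsilon)$Q
}

sinkhorn_forward <- function(scores, n_iters, epsilon) {
  n <- nrow(scores); k <- ncol(scores)
  L0 <- scores / epsilon
  L0 <- L0 - apply(L0, 1, max)
  M <- exp(L0)
  steps <- list()
  Q <- M
  for (it in seq_len(n_iters)) {
    r <- rowSums(Q)
    steps[[length(steps) + 1]] <- list(type = "row", X = Q, s = r)
    Q <- Q * ((1 / n) / r)
    cs <- colSums(Q)
    steps[[length(steps) + 1]] <- list(type = "col", X = Q, s = cs)
    Q <- sweep(Q, 2, (1 / k) / cs, "*")
  }
  list(Q = Q, M = M, steps = steps, epsilon = epsilon, n = n, k = k)
}

# Reverse-mode pass through the stored normalization steps.
# Row step Y = diag(t/r) X with r = rowSums(X):
#   dX_ij = (t/r_i) dY_ij - (t/r_i^2) sum_k dY_ik X_ik  (column step mirrored).
sinkhorn_backward <- function(cache, dQ) {
  for (st in rev(cache$steps)) {
    X <- st$X; s <- st$s
    if (st$type == "row") {
      a <- (1 / cache$n) / s
      rd <- rowSums(dQ * X)
      dQ <- a * dQ - (a / s) * rd   # length-n vectors recycle down columns
    } else {
      b <- (1 / cache$k) / s
      cd <- colSums(dQ * X)
      dQ <- sweep(dQ, 2, b, "*") - sweep(matrix(1, nrow(X), ncol(X)), 2,
                                         (b / s) * cd, "*")
    }
  }
  (dQ * cache$M) / cache$epsilon
}

cosine_to_centers <- function(E, centers) {
  norms <- sqrt(rowSums(E^2)); norms[norms == 0] <- 1
  cn <- sqrt(rowSums(centers^2)); cn[cn == 0] <- 1
  En <- E / norms
  Cn <- centers / cn
  list(cs = tcrossprod(En, Cn), En = En, Cn = Cn, norms = norms)
}

fit_prototypes <- function(E_att, n_prototypes, seed) {
  for (attempt in 0:4) {
    km <- try(with_seed(seed + attempt,
      stats::kmeans(E_att, centers = n_prototypes, nstart = 3,
                    iter.max = 50)), silent = TRUE)
    if (!inherits(km, "try-error")) return(km$centers)
  }
  stop("k-means prototype fit failed after re-seeding", call. = FALSE)
}

#' SwAV soft cluster assignments for both views
#'
#' Fits K-means prototypes on the fused embedding, scores each view's
#' embedding by cosine similarity to the prototypes, and Sinkhorn-normalizes
#' the scores into balanced soft assignment matrices.
#'
#' @param E_v1,E_v2,E_att Embedding matrices.
#' @param n_prototypes Number of prototypes (>= 2).
#' @param seed Integer seed (K-means re-seeds on degenerate fits).
#' @param n_iters,epsilon Sinkhorn parameters.
#' @return List with `Q_v1`, `Q_v2`, `centers`.
#' @export
swav_assignments <- function(E_v1, E_v2, E_att, n_prototypes = 15, seed = 0,
                             n_iters = 3, epsilon = 0.05) {
  stopifnot(n_prototypes >= 2)
  centers <- fit_prototypes(E_att, n_prototypes, seed)
  Q1 <- sinkhorn_normalize(cosine_to_centers(E_v1, centers)$cs,
                           n_iters, epsilon)
  Q2 <- sinkhorn_normalize(cosine_to_centers(E_v2, centers)$cs,
                           n_iters, epsilon)
  list(Q_v1 = Q1, Q_v2 = Q2, centers = centers)
}

softplus <- function(G) ifelse(G > 30, G, log1p(exp(pmin(G, 30))))

# Class-balanced binary cross-entropy between an adjacency and logits:
# mean over edge pairs of -log sigma(G) plus mean over non-edge pairs of
# -log(1 - sigma(G)), halved. Balancing keeps the (overwhelmingly more
# numerous) non-edges from dominating the objective.
bce_mean <- function(A, G) {
  ce <- softplus(G) - A * G
  pos <- A == 1
  n_pos <- sum(pos); n_neg <- length(A) - n_pos
  if (n_pos == 0 || n_neg == 0) return(mean(ce))
  (sum(ce[pos]) / n_pos + sum(ce[!pos]) / n_neg) / 2
}

# Gradient of bce_mean w.r.t. the logits.
bce_grad <- function(A, G) {
  P <- 1 / (1 + exp(-G))
  pos <- A == 1
  n_pos <- sum(pos); n_neg <- length(A) - n_pos
  dG <- P - A
  if (n_pos == 0 || n_neg == 0) return(dG / length(A))
  dG[pos] <- dG[pos] / (2 * n_pos)
  dG[!pos] <- dG[!pos] / (2 * n_neg)
  dG
}

kl_sum <- function(P, Q) {
  P <- pmax(P, 1e-12); Q <- pmax(Q, 1e-12)
  sum(P * (log(P) - log(Q)))
}

#' Joint loss of the dual-view autoencoder
#'
#' Reconstruction: summed MSE of the three decoders. Graph: BCE between each
#' adjacency and the sigmoid similarity of the fused embedding. SwAV:
#' symmetric KL between the two views' Sinkhorn assignments. Attention:
#' mean squared deviation of the attention weights from 1/2. The total is
#' the `lambdas`-weighted sum.
#'
#' @param X_HSG Input feature matrix.
#' @param reconstructions List `v1`, `v2`, `att` from [decode_views()].
#' @param A_coord,A_feat Adjacency matrices.
#' @param E_att Fused embedding.
#' @param alpha Attention weight matrix (N x 2).
#' @param Q_v1,Q_v2 SwAV assignment matrices.
#' @param lambdas Length-4 weights.
#' @return List of class `sage_losses`: `recon`, `graph`, `swav`, `att`,
#'   `total`, `lambdas`.
#' @export
compute_losses <- function(X_HSG, reconstructions, A_coord, A_feat, E_att,
                           alpha, Q_v1, Q_v2, lambdas = c(10, 10, 5, 1)) {
  recon <- sum(vapply(reconstructions,
                      function(R) mean(rowSums((X_HSG - R)^2)), numeric(1)))
  G <- tcrossprod(E_att)
  graph <- bce_mean(as.matrix(A_coord), G) + bce_mean(as.matrix(A_feat), G)
  swav <- kl_sum(Q_v1, Q_v2) + kl_sum(Q_v2, Q_v1)
  att <- mean((alpha - 0.5)^2)
  total <- sum(lambdas * c(recon, graph, swav, att))
  structure(list(recon = recon, graph = graph, swav = swav, att = att,
                 total = total, lambdas = lambdas),
            class = "sage_losses")
}

# ---- internal training machinery -------------------------------------------

# Full forward pass; caches every intermediate needed by dgnn_backward.
dgnn_forward <- function(params, cst, lambdas, centers = NULL) {
  with(cst, {
    Z1a <- M1 %*% params$W1; H1a <- pmax(Z1a, 0)
    Z1b <- M2 %*% params$W1; H1b <- pmax(Z1b, 0)
    E1 <- sweep(H1a %*% params$W2, 2, params$b2, "+")
    E2 <- sweep(H1b %*% params$W2, 2, params$b2, "+")

    if (cst$dual_view) {
      att <- attention_forward(E1, E2, params)
      E_att <- att$E_att; alpha <- att$alpha
    } else {
      att <- NULL
      E_att <- E1
      alpha <- cbind(rep(1, nrow(E1)), rep(0, nrow(E1)))
    }

    dec <- function(E) {
      Zd <- E %*% t(params$W2)
      Dd <- pmax(Zd, 0)
      list(Zd = Zd, Dd = Dd, R = Dd %*% t(params$W1))
    }
    d1 <- dec(E1); datt <- dec(E_att)
    d2 <- if (cst$dual_view) dec(E2) else NULL

    # MSE per spot: squared error summed over genes, averaged over spots
    recon <- mean(rowSums((X - d1$R)^2)) + mean(rowSums((X - datt$R)^2)) +
      (if (cst$dual_view) mean(rowSums((X - d2$R)^2)) else 0)

    # graph term on fused-embedding similarity
    if (is.null(cst$pairs)) {
      G <- tcrossprod(E_att)
      graph <- bce_mean(A1, G) +
        (if (cst$dual_view) bce_mean(A2, G) else 0)
      gcache <- list(G = G)
    } else {
      gv <- rowSums(E_att[cst$pairs$i, , drop = FALSE] *
                    E_att[cst$pairs$j, , drop = FALSE])
      graph <- bce_mean(cst$pairs$a1, gv) +
        (if (cst$dual_view) bce_mean(cst$pairs$a2, gv) else 0)
      gcache <- list(gv = gv)
    }

    swav <- 0; sw <- NULL
    if (cst$dual_view && !is.null(centers)) {
      c1 <- cosine_to_centers(E1, centers)
      c2 <- cosine_to_centers(E2, centers)
      s1 <- sinkhorn_forward(c1$cs, cst$sk_iters, cst$sk_eps)
      s2 <- sinkhorn_forward(c2$cs, cst$sk_iters, cst$sk_eps)
      swav <- kl_sum(s1$Q, s2$Q) + kl_sum(s2$Q, s1$Q)
      sw <- list(c1 = c1, c2 = c2, s1 = s1, s2 = s2)
    }
    att_loss <- if (cst$dual_view) mean((alpha - 0.5)^2) else 0
    total <- sum(lambdas * c(recon, graph, swav, att_loss))

    list(E1 = E1, E2 = E2, E_att = E_att, alpha = alpha, att = att,
         Z1a = Z1a, H1a = H1a, Z1b = Z1b, H1b = H1b,
         d1 = d1, d2 = d2, datt = datt, gcache = gcache, sw = sw,
         losses = list(recon = recon, graph = graph, swav = swav,
                       att = att_loss, total = total))
  })
}

dgnn_backward <- function(params, cst, fw, lambdas) {
  X <- cst$X
  n <- nrow(X); din <- ncol(X)
  g <- list(W1 = 0 * params$W1, W2 = 0 * params$W2, b2 = 0 * params$b2,
            W_omega = 0 * params$W_omega, u_omega = 0 * params$u_omega)
  dE1 <- matrix(0, n, ncol(fw$E1))
  dE2 <- matrix(0, n, ncol(fw$E1))
  dE_att <- matrix(0, n, ncol(fw$E1))

  # reconstruction decoders
  back_dec <- function(dcache, E, dR) {
    g$W1 <<- g$W1 + crossprod(dR, dcache$Dd)
    dD <- dR %*% params$W1
    dZ <- dD * (dcache$Zd > 0)
    g$W2 <<- g$W2 + crossprod(dZ, E)
    dZ %*% params$W2
  }
  sc <- lambdas[1] * 2 / n
  dE1 <- dE1 + back_dec(fw$d1, fw$E1, sc * (fw$d1$R - X))
  dE_att <- dE_att + back_dec(fw$datt, fw$E_att, sc * (fw$datt$R - X))
  if (cst$dual_view)
    dE2 <- dE2 + back_dec(fw$d2, fw$E2, sc * (fw$d2$R - X))

  # graph BCE on fused similarity
  if (lambdas[2] > 0) {
    if (is.null(cst$pairs)) {
      dG <- bce_grad(cst$A1, fw$gcache$G)
      if (cst$dual_view) dG <- dG + bce_grad(cst$A2, fw$gcache$G)
      dG <- lambdas[2] * dG
      dE_att <- dE_att + (dG + t(dG)) %*% fw$E_att
    } else {
      dgv <- bce_grad(cst$pairs$a1, fw$gcache$gv)
      if (cst$dual_view) dgv <- dgv + bce_grad(cst$pairs$a2, fw$gcache$gv)
      dgv <- lambdas[2] * dgv
      S <- Matrix::sparseMatrix(i = cst$pairs$i, j = cst$pairs$j, x = dgv,
                                dims = c(n, n))
      dE_att <- dE_att + as.matrix((S + Matrix::t(S)) %*% fw$E_att)
    }
  }

  # SwAV symmetric KL through Sinkhorn and cosine similarity
  if (cst$dual_view && !is.null(fw$sw) && lambdas[3] > 0) {
    Q1 <- pmax(fw$sw$s1$Q, 1e-12); Q2 <- pmax(fw$sw$s2$Q, 1e-12)
    dQ1 <- lambdas[3] * (log(Q1 / Q2) + 1 - Q2 / Q1)
    dQ2 <- lambdas[3] * (log(Q2 / Q1) + 1 - Q1 / Q2)
    dcs1 <- sinkhorn_backward(fw$sw$s1, dQ1)
    dcs2 <- sinkhorn_backward(fw$sw$s2, dQ2)
    back_cos <- function(cc, dcs) {
      dEn <- dcs %*% cc$Cn
      proj <- rowSums(dEn * cc$En)
      (dEn - proj * cc$En) / cc$norms
    }
    dE1 <- dE1 + back_cos(fw$sw$c1, dcs1)
    dE2 <- dE2 + back_cos(fw$sw$c2, dcs2)
  }

  # attention fusion (and its regularizer)
  if (cst$dual_view) {
    alpha <- fw$alpha
    dalpha <- lambdas[4] * 2 * (alpha - 0.5) / (2 * n)
    dalpha[, 1] <- dalpha[, 1] + rowSums(dE_att * fw$E1)
    dalpha[, 2] <- dalpha[, 2] + rowSums(dE_att * fw$E2)
    dE1 <- dE1 + alpha[, 1] * dE_att
    dE2 <- dE2 + alpha[, 2] * dE_att
    dS <- alpha * (dalpha - rowSums(dalpha * alpha))
    for (v in 1:2) {
      Vv <- if (v == 1) fw$att$V1 else fw$att$V2
      Ev <- if (v == 1) fw$E1 else fw$E2
      dVv <- dS[, v] %o% params$u_omega
      g$u_omega <- g$u_omega + as.numeric(crossprod(Vv, dS[, v]))
      dZo <- dVv * (1 - Vv^2)
      g$W_omega <- g$W_omega + crossprod(Ev, dZo)
      if (v == 1) dE1 <- dE1 + dZo %*% t(params$W_omega)
      else dE2 <- dE2 + dZo %*% t(params$W_omega)
    }
  } else {
    dE1 <- dE1 + dE_att   # fused embedding is the spatial view
  }

  # shared encoder
  back_enc <- function(dE, H1, Z1, M) {
    g$W2 <<- g$W2 + crossprod(H1, dE)
    g$b2 <<- g$b2 + colSums(dE)
    dH <- dE %*% t(params$W2)
    dZ1 <- dH * (Z1 > 0)
    g$W1 <<- g$W1 + crossprod(M, dZ1)
  }
  back_enc(dE1, fw$H1a, fw$Z1a, cst$M1)
  if (cst$dual_view) back_enc(dE2, fw$H1b, fw$Z1b, cst$M2)
  g
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the dual-view graph autoencoder
#'
#' Full-batch Adam minimization of the joint objective. The SwAV weight is
#' held at zero during the warm-up fraction of epochs (reconstruction and
#' graph terms shape the embedding first); afterwards K-means prototypes are
#' refit on the fused embedding every `refresh_every` epochs and the SwAV
#' term joins the objective. Fully reproducible under `config$seed`.
#'
#' @param X_HSG Spots x HSG log-expression matrix.
#' @param A_coord,A_feat Binary adjacency matrices from
#'   [build_spatial_graph()] / [build_feature_graph()].
#' @param config A [sage_dgnn_config()].
#' @return List of class `sage_dgnn`: `params`, `embeddings`
#'   (`E_v1`, `E_v2`, `E_att`, `alpha`), `history` (per-epoch loss
#'   data.frame), `config`.
#' @export
train_model <- function(X_HSG, A_coord, A_feat, config = sage_dgnn_config()) {
  X <- as.matrix(X_HSG)
  n <- nrow(X); din <- ncol(X)
  A1 <- as.matrix(A_coord)
  A2 <- if (config$dual_view) as.matrix(A_feat) else A1
  pairs <- NULL
  if (n > config$pair_limit) {
    pairs <- with_seed(config$seed, {
      e1 <- which(A1 == 1, arr.ind = TRUE)
      e2 <- which(A2 == 1, arr.ind = TRUE)
      epos <- unique(rbind(e1, e2))
      nneg <- nrow(epos)
      neg <- cbind(sample.int(n, nneg, TRUE), sample.int(n, nneg, TRUE))
      idx <- rbind(epos, neg)
      list(i = idx[, 1], j = idx[, 2],
           a1 = A1[idx], a2 = A2[idx])
    })
  }
  cst <- list(X = X,
              M1 = normalize_adjacency(A1) %*% X,
              M2 = normalize_adjacency(A2) %*% X,
              A1 = A1, A2 = A2, pairs = pairs,
              dual_view = config$dual_view,
              sk_iters = config$sinkhorn_iters, sk_eps = config$sinkhorn_eps)

  params <- init_model_params(din, config$d_hid, config$d_out, config$seed)
  state <- list(m = lapply(params, function(p) 0 * p),
                v = lapply(params, function(p) 0 * p))
  n_proto <- if (!is.null(config$n_prototypes)) config$n_prototypes else 15
  n_proto <- min(n_proto, n - 1L)
  warm_end <- floor(config$warmup_frac * config$epochs)
  centers <- NULL
  hist <- matrix(NA_real_, config$epochs, 5,
                 dimnames = list(NULL, c("recon", "graph", "swav", "att",
                                         "total")))
  for (ep in seq_len(config$epochs)) {
    lam <- config$lambdas
    if (ep <= warm_end) lam[3] <- 0
    if (config$dual_view && lam[3] > 0 &&
        (is.null(centers) || (ep - warm_end - 1) %% config$refresh_every == 0)) {
      fw0 <- dgnn_forward(params, cst, lam, centers = NULL)
      centers <- fit_prototypes(fw0$E_att, n_proto, config$seed + ep)
    }
    fw <- dgnn_forward(params, cst, lam,
                       centers = if (lam[3] > 0) centers else NULL)
    if (!is.finite(fw$losses$total))
      stop("divergence: non-finite loss at epoch ", ep,
           "; reduce the learning rate", call. = FALSE)
    grads <- dgnn_backward(params, cst, fw, lam)
    upd <- adam_step(params, grads, state, config$lr, ep)
    params <- upd$params; state <- upd$state
    hist[ep, ] <- c(fw$losses$recon, fw$losses$graph, fw$losses$swav,
                    fw$losses$att, fw$losses$total)
  }
  fw <- dgnn_forward(params, cst, config$lambdas, centers = centers)
  structure(list(params = params,
                 embeddings = list(E_v1 = fw$E1, E_v2 = fw$E2,
                                   E_att = fw$E_att, alpha = fw$alpha),
                 history = as.data.frame(cbind(epoch = seq_len(config$epochs),
                                               hist)),
                 config = config),
            class = "sage_dgnn")
}

#' @export
print.sage_dgnn <- function(x, ...) {
  h <- x$history
  cat("sage_dgnn: trained", nrow(h), "epochs;",
      "total loss", signif(h$total[1], 4), "->",
      signif(h$total[nrow(h)], 4), "\n")
  invisible(x)
}
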