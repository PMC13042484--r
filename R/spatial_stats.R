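#' Spatial weight matrix from coordinates
#'
#' Binary k-nearest-neighbour weights (symmetrized by union) or
#' inverse-distance weights restricted to the same neighbourhoods. The
#' default `k = 6` matches the hexagonal neighbourhood of Visium arrays.
#'
#' @param coords Numeric matrix, spots x 2.
#' @param k Neighbourhood size.
#' @param mode `"binary"` or `"idw"` (inverse distance).
#' @return An object of class `spatial_weights`: list with sparse matrix `w`
#'   (zero diagonal, non-negative) and `total_weight` (sum of all weights).
#' @export
spatial_weights <- function(coords, k = 6, mode = c("binary", "idw")) {
  mode <- match.arg(mode)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nn <- order(d[i, ], seq_len(n))[seq_len(k)]
    w[i, nn] <- if (mode == "binary") 1 else 1 / d[i, nn]
  }
  w <- pmax(w, t(w))          # symmetrize by union
  diag(w) <- 0
  w <- Matrix::Matrix(w, sparse = TRUE)
  structure(list(w = w, total_weight = sum(w)), class = "spatial_weights")
}

#' Moran's I spatial autocorrelation
#'
#' `I = (N/W) * sum_jl w_jl (z_j - zbar)(z_l - zbar) / sum_j (z_j - zbar)^2`
#' with `W` the total weight. Values near 1 indicate smooth spatial structure,
#' near 0 spatial randomness, negative values checkerboard-like alternation.
#'
#' @param values Numeric vector, one value per spot; must not be constant.
#' @param weights A [spatial_weights()] object.
#' @return Scalar Moran's I.
#' @export
morans_i <- function(values, weights) {
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) stop("constant-vector: Moran's I undefined", call. = FALSE)
  num <- as.numeric(Matrix::crossprod(z, weights$w %*% z))
  (length(values) / weights$total_weight) * num / denom
}

#' Geary's C spatial autocorrelation
#'
#' `C = (N-1) * sum_ij w_ij (x_i - x_j)^2 / (2 W sum_i (x_i - xbar)^2)`;
#' 1 under the null, below 1 for positive autocorrelation.
#'
#' @inheritParams morans_i
#' @return Scalar Geary's C.
#' @export
gearys_c <- function(values, weights) {
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) stop("constant-vector: Geary's C undefined", call. = FALSE)
  w <- weights$w
  # sum_ij w_ij (x_i - x_j)^2 = 2 x' (D - W) x with D = diag(rowsums)
  rs <- Matrix::rowSums(w)
  quad <- sum(rs * values^2) - as.numeric(Matrix::crossprod(values, w %*% values))
  num <- 2 * quad
  (length(values) - 1) * num / (2 * weights$total_weight * denom)
}
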