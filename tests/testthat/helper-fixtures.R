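# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Scaled-down pipeline profile used by end-to-end tests: 400 spots, 300
# genes, a 15% HVG budget and a compact embedding model.
test_profile <- function(...) {
  sage_config(n_hvgs = 45, n_pcs = 20,
              dgnn = sage_dgnn_config(d_hid = 64, d_out = 32, epochs = 400),
              ...)
}

sim_default <- function(seed = 1) {
  cached(paste0("sim_", seed), generate_synthetic_st(seed = seed))
}

fit_default <- function(seed = 1) {
  cached(paste0("fit_", seed),
         sage(sim_default(seed)$dataset, n_domains = 4,
              config = test_profile(), seed = seed))
}

# Small grid helper for the spatial statistics tests.
grid_coords <- function(n_side) {
  as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side)))
}

# Brute-force Moran's I straight from the double-sum definition.
moran_brute <- function(values, W) {
  W <- as.matrix(W)
  z <- values - mean(values)
  n <- length(values)
  num <- 0
  for (j in seq_len(n)) for (l in seq_len(n))
    num <- num + W[j, l] * z[j] * z[l]
  (n / sum(W)) * num / sum(z^2)
}

geary_brute <- function(values, W) {
  W <- as.matrix(W)
  n <- length(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * (values[i] - values[j])^2
  (n - 1) * num / (2 * sum(W) * sum((values - mean(values))^2))
}

make_run <- function(labels, setting = 1) {
  structure(list(labels = as.integer(labels), method = "leiden",
                 setting = setting), class = "clustering_run")
}

# Well-separated Gaussian blobs with labels.
make_blobs <- function(n_per = 30, k = 3, d = 5, sep = 8, seed = 11) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(n_per * d, mean = i * sep), n_per, d)))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}
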