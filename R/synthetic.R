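# Seed hygiene: run `code` under `seed` and restore the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic spatial transcriptomics dataset with known domains
#'
#' Spots sit on an `n_side` x `n_side` grid partitioned into contiguous
#' rectangular tiles, one transcriptional program per domain. Each program
#' has two layers, mirroring how tissue domains differ in practice: a small
#' set of planted marker genes elevated `marker_fold`-fold, and a broad
#' graded program — a random `program_frac` fraction of the remaining genes
#' modulated by modest lognormal fold effects — over a shared lognormal gene
#' baseline. Counts are negative binomial (dispersion 0.3) with lognormal
#' per-spot library-size variation, and entries are zeroed independently
#' with probability `dropout` to emulate the sparsity of sequencing-based
#' platforms.
#'
#' `layout = "disjoint"` places four vertical strips but only three
#' programs: the two outermost strips share program 1, creating a spatially
#' disconnected domain with a common expression program (the long-range
#' regime the feature graph is designed to bridge). `n_domains` is ignored
#' in that layout (truth has 3 domains).
#'
#' @param n_side Grid side length (total spots `n_side^2`).
#' @param n_domains Number of spatial domains (tiles).
#' @param n_genes Total gene count.
#' @param n_markers_per_domain Planted marker genes per domain.
#' @param dropout Per-entry zeroing probability in `[0, 1)`.
#' @param seed Integer seed; regeneration with identical parameters is
#'   bitwise identical.
#' @param layout `"tiles"` (default) or `"disjoint"`.
#' @param marker_fold Fold elevation of a marker inside its domain.
#' @param n_noise_hvg Number of background genes given strong spatially
#'   random per-spot overdispersion. These mimic the high-variance,
#'   non-spatial genes of real tissue (stress, dissociation, technical
#'   noise) that crowd variance-ranked gene lists without carrying domain
#'   information.
#' @param noise_sdlog Lognormal sdlog of the per-entry noise factors of
#'   those genes.
#' @param program_frac Fraction of non-marker genes each domain's broad
#'   program modulates.
#' @param program_meanlog,program_sdlog Lognormal parameters of the broad
#'   program fold effects.
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param lib_sdlog Lognormal sdlog of per-spot library-size factors.
#'
#' @return A list with `dataset` (an [st_dataset()]) and `truth` (list:
#'   `domain_labels` (1-based), `planted_markers` (list of gene-id vectors per
#'   domain), `tile_labels`, `params`).
#' @export
generate_synthetic_st <- function(n_side = 20, n_domains = 4, n_genes = 300,
                                  n_markers_per_domain = 10, dropout = 0.3,
                                  seed = 1, layout = c("tiles", "disjoint"),
                                  marker_fold = 5, n_noise_hvg = 30,
                                  noise_sdlog = 1.5, program_frac = 0.15,
                                  program_meanlog = log(1.8),
                                  program_sdlog = 0.3, dispersion = 0.3,
                                  lib_sdlog = 0.3) {
  layout <- match.arg(layout)
  if (layout == "tiles" && n_domains < 2)
    stop("layout-error: need at least 2 domains", call. = FALSE)
  if (n_side^2 < 4 * max(n_domains, 2))
    stop("layout-error: grid too small for requested domains", call. = FALSE)
  with_seed(seed, {
    coords <- as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side)))
    n <- nrow(coords)

    if (layout == "disjoint") {
      # four vertical strips; the two outermost share a program, so the
      # shared domain is spatially disconnected (strips 2 and 3 in between)
      n_tiles_x <- 4L; n_tiles_y <- 1L
      tile_program <- c(1L, 2L, 3L, 1L)
      n_programs <- 3L
    } else {
      n_tiles_y <- max(1L, floor(sqrt(n_domains)))
      n_tiles_x <- ceiling(n_domains / n_tiles_y)
      tile_program <- pmin(seq_len(n_tiles_x * n_tiles_y), n_domains)
      n_programs <- n_domains
    }
    tx <- pmin(ceiling(coords[, "x"] / (n_side / n_tiles_x)), n_tiles_x)
    ty <- pmin(ceiling(coords[, "y"] / (n_side / n_tiles_y)), n_tiles_y)
    tile <- (ty - 1L) * n_tiles_x + tx
    domain <- tile_program[tile]

    gene_ids <- sprintf("gene_%03d", seq_len(n_genes))
    n_marker_total <- n_programs * n_markers_per_domain
    if (n_marker_total > n_genes)
      stop("layout-error: more planted markers than genes", call. = FALSE)
    marker_of <- rep(NA_integer_, n_genes)
    marker_of[seq_len(n_marker_total)] <- rep(seq_len(n_programs),
                                              each = n_markers_per_domain)
    planted <- split(gene_ids[!is.na(marker_of)],
                     marker_of[!is.na(marker_of)])

    baseline <- stats::rlnorm(n_genes, meanlog = log(2), sdlog = 0.5)
    lib <- stats::rlnorm(n, meanlog = 0, sdlog = lib_sdlog)
    fold <- matrix(1, n, n_genes)
    nonmarker <- which(is.na(marker_of))
    # spatially random overdispersed genes (variance without domain signal)
    noise_genes <- utils::head(nonmarker, min(n_noise_hvg, length(nonmarker)))
    prog_pool <- setdiff(nonmarker, noise_genes)
    for (d in seq_len(n_programs)) {
      gidx <- which(marker_of == d)
      fold[domain == d, gidx] <- marker_fold
      # broad graded program over a random slice of background genes
      prog <- sample(prog_pool, round(program_frac * length(prog_pool)))
      eff <- stats::rlnorm(length(prog), program_meanlog, program_sdlog)
      fold[domain == d, prog] <- rep(eff, each = sum(domain == d))
    }
    if (length(noise_genes) > 0)
      fold[, noise_genes] <- fold[, noise_genes] *
        matrix(stats::rlnorm(n * length(noise_genes),
                             -noise_sdlog^2 / 2, noise_sdlog),
               n, length(noise_genes))
    mu <- (lib %o% baseline) * fold
    counts <- matrix(stats::rnbinom(n * n_genes, mu = as.vector(mu),
                                    size = 1 / dispersion), n, n_genes)
    if (dropout > 0)
      counts[stats::runif(n * n_genes) < dropout] <- 0L

    ds <- st_dataset(counts, coords, gene_ids = gene_ids,
                     spot_ids = sprintf("spot_%04d", seq_len(n)))
    list(dataset = ds,
         truth = list(domain_labels = domain,
                      tile_labels = tile,
                      planted_markers = planted,
                      params = list(n_side = n_side, n_domains = n_programs,
                                    n_genes = n_genes,
                                    n_markers_per_domain = n_markers_per_domain,
                                    dropout = dropout, seed = seed,
                                    layout = layout, marker_fold = marker_fold,
                                    dispersion = dispersion,
                                    lib_sdlog = lib_sdlog)))
  })
}

#' Generate a pair of label vectors with controlled agreement
#'
#' `pred` equals `truth` on a fixed `agreement` fraction of entries (chosen at
#' random) and is uniform over classes elsewhere. Useful for exercising
#' label-agreement metrics at known operating points.
#'
#' @param n Number of entries.
#' @param n_classes Number of classes.
#' @param agreement Fraction of entries forced equal, in `[0, 1]`.
#' @param seed Integer seed.
#' @return List with integer vectors `truth` and `pred` (values `1..n_classes`).
#' @export
generate_label_fixture <- function(n, n_classes, agreement, seed = 1) {
  stopifnot(agreement >= 0, agreement <= 1)
  with_seed(seed, {
    truth <- sample.int(n_classes, n, replace = TRUE)
    pred <- sample.int(n_classes, n, replace = TRUE)
    keep <- sample.int(n, round(agreement * n))
    pred[keep] <- truth[keep]
    list(truth = truth, pred = pred)
  })
}
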