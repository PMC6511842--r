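#' Simulation configuration for planted-bicluster profiles
#'
#' The defaults emulate the size and density of real binary MIR profiles:
#' 700 conditions by 300 genes at 20% background density, with 7 planted
#' biclusters whose row and column sizes are drawn uniformly between 20 and
#' 80, each carrying 1-3% internal zeros (noise), and pairwise cell overlap
#' below 20% of the smaller bicluster.
#'
#' @param n_rows,n_cols profile dimensions.
#' @param background_density Bernoulli rate of 1s outside all planted
#'   biclusters.
#' @param n_biclusters number of planted biclusters.
#' @param size_min,size_max bounds for planted row and column set sizes.
#' @param noise_min,noise_max bounds of the per-bicluster internal zero
#'   fraction, drawn uniformly.
#' @param max_overlap_fraction upper bound (exclusive) on pairwise shared
#'   cells relative to the smaller bicluster; enforced by rejection sampling.
#'   Overlap up to the bound is permitted but not forced.
#' @param n_replicates number of independent profiles in a benchmark run.
#' @param rng_seed master seed; replicate `i` uses `rng_seed + i`.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_rows = 700L, n_cols = 300L,
                              background_density = 0.20,
                              n_biclusters = 7L,
                              size_min = 20L, size_max = 80L,
                              noise_min = 0.01, noise_max = 0.03,
                              max_overlap_fraction = 0.20,
                              n_replicates = 50L, rng_seed = 1L) {
  stopifnot(size_max <= min(n_rows, n_cols),
            background_density > 0 || background_density == 0,
            background_density < 1,
            noise_min >= 0, noise_max >= noise_min, noise_max < 1,
            max_overlap_fraction > 0, max_overlap_fraction < 1)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 background_density = background_density,
                 n_biclusters = as.integer(n_biclusters),
                 size_min = as.integer(size_min),
                 size_max = as.integer(size_max),
                 noise_min = noise_min, noise_max = noise_max,
                 max_overlap_fraction = max_overlap_fraction,
                 n_replicates = as.integer(n_replicates),
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

#' Generate one simulated binary profile with planted biclusters
#'
#' Places `config$n_biclusters` rectangles (random row and column subsets)
#' by rejection sampling so that every pair shares fewer cells than
#' `max_overlap_fraction` times the smaller rectangle, fills the background
#' i.i.d. Bernoulli(`background_density`), sets rectangle cells to 1 and
#' flips a per-rectangle fraction `u ~ Uniform(noise_min, noise_max)` of
#' cells to 0.  Cells covered by several rectangles follow the last-placed
#' rectangle's draw; a final repair sweep restores any rectangle whose
#' realized zero fraction was pushed outside `[noise_min, noise_max]` by
#' overwrites, so the stated noise range holds exactly for every planted
#' rectangle in the returned profile.
#'
#' @param config a [simulation_config()].
#' @param replicate_seed integer seed for this profile.
#' @return An object of class `"simulated_profile"`: a list with `matrix`
#'   (binary), `truth_mask` (logical, union of planted rectangles) and
#'   `planted` (list of row/column index sets).
#' @export
generate_profile <- function(config = simulation_config(),
                             replicate_seed = config$rng_seed) {
  set.seed(replicate_seed)
  n <- config$n_rows; m <- config$n_cols
  M <- matrix(rbinom(n * m, 1L, config$background_density), n, m)

  planted <- vector("list", config$n_biclusters)
  for (i in seq_len(config$n_biclusters)) {
    placed <- FALSE
    size_range <- config$size_max - config$size_min + 1L
    for (attempt in seq_len(10000L)) {
      nr <- config$size_min + sample.int(size_range, 1L) - 1L
      nc <- config$size_min + sample.int(size_range, 1L) - 1L
      rows <- sort(sample.int(n, nr))
      cols <- sort(sample.int(m, nc))
      ok <- TRUE
      for (p in planted[seq_len(i - 1L)]) {
        ov <- length(intersect(rows, p$rows)) * length(intersect(cols, p$cols))
        lim <- config$max_overlap_fraction *
          min(nr * nc, length(p$rows) * length(p$cols))
        if (ov >= lim) { ok <- FALSE; break }
      }
      if (ok) { placed <- TRUE; break }
    }
    if (!placed)
      stop("could not place planted bicluster ", i,
           " within the overlap bound; use smaller sizes or fewer biclusters")
    planted[[i]] <- list(rows = rows, cols = cols)
  }

  # fill rectangles in placement order; later draws overwrite overlaps
  for (p in planted) {
    cells <- length(p$rows) * length(p$cols)
    M[p$rows, p$cols] <- 1L
    u <- runif(1L, config$noise_min, config$noise_max)
    nz <- min(floor(config$noise_max * cells),
              max(ceiling(config$noise_min * cells), round(u * cells)))
    if (nz > 0L) {
      idx <- sample.int(cells, nz)
      M[cbind(p$rows[(idx - 1L) %% length(p$rows) + 1L],
              p$cols[(idx - 1L) %/% length(p$rows) + 1L])] <- 0L
    }
  }

  # repair sweep: overwrites in overlap regions can leave an earlier
  # rectangle marginally outside the noise range; adjust within bounds
  for (sweep in seq_len(100L)) {
    fixed <- TRUE
    for (p in planted) {
      sub <- M[p$rows, p$cols, drop = FALSE]
      cells <- length(sub)
      zeros <- cells - sum(sub)
      lo <- ceiling(config$noise_min * cells)
      hi <- floor(config$noise_max * cells)
      if (zeros < lo) {
        ones_at <- which(sub == 1L)
        flip <- ones_at[sample.int(length(ones_at), lo - zeros)]
        sub[flip] <- 0L
        M[p$rows, p$cols] <- sub
        fixed <- FALSE
      } else if (zeros > hi) {
        zeros_at <- which(sub == 0L)
        flip <- zeros_at[sample.int(length(zeros_at), zeros - hi)]
        sub[flip] <- 1L
        M[p$rows, p$cols] <- sub
        fixed <- FALSE
      }
    }
    if (fixed) break
  }

  truth <- matrix(FALSE, n, m)
  for (p in planted) truth[p$rows, p$cols] <- TRUE
  structure(list(matrix = M, truth_mask = truth, planted = planted,
                 config = config, replicate_seed = replicate_seed),
            class = "simulated_profile")
}

#' @export
print.simulated_profile <- function(x, ...) {
  cat(sprintf("simulated profile: %d x %d, %d planted biclusters, %d truth cells\n",
              nrow(x$matrix), ncol(x$matrix), length(x$planted),
              sum(x$truth_mask)))
  invisible(x)
}

#' Element-level precision and sensitivity against planted truth
#'
#' Predicted biclusters are reduced to the union of their cells `P`.
#' Precision is the fraction of `P` inside any planted rectangle;
#' sensitivity is the fraction of planted cells covered by `P`.  An empty
#' prediction scores precision 1 and sensitivity 0.
#'
#' @param predicted list of [bicluster()] objects (or a `"pbe"` fit).
#' @param truth a [generate_profile()] result.
#' @return Named numeric vector with elements `precision` and `sensitivity`.
#' @export
element_precision_sensitivity <- function(predicted, truth) {
  if (inherits(predicted, "pbe")) predicted <- predicted$biclusters
  T <- truth$truth_mask
  P <- matrix(FALSE, nrow(T), ncol(T))
  for (b in predicted) P[b$rows, b$cols] <- TRUE
  np <- sum(P)
  hit <- sum(P & T)
  c(precision = if (np == 0L) 1 else hit / np,
    sensitivity = hit / sum(T))
}

#' Run the planted-bicluster simulation benchmark
#'
#' Generates `config$n_replicates` independent profiles (replicate `i` is
#' seeded with `config$rng_seed + i`), applies `algorithm` to each binary
#' matrix, and scores the predictions at element level against the planted
#' truth.  A replicate on which the algorithm raises an error is excluded
#' from the medians with a warning.
#'
#' @param config a [simulation_config()].
#' @param algorithm function mapping a binary matrix to a list of
#'   [bicluster()]s (or a `"pbe"` fit).  Defaults to the full PBE pipeline
#'   with `pbe_config`.
#' @param pbe_config configuration passed to the default algorithm.
#' @return An object of class `"pbe_benchmark"`: data frame of per-replicate
#'   precision/sensitivity plus medians.
#' @export
run_benchmark <- function(config = simulation_config(),
                          algorithm = NULL,
                          pbe_config = mirbic::pbe_config()) {
  if (is.null(algorithm))
    algorithm <- function(m) pbe(m, pbe_config)
  stopifnot(config$n_replicates >= 1L)
  prec <- sens <- rep(NA_real_, config$n_replicates)
  failed <- 0L
  for (i in seq_len(config$n_replicates)) {
    prof <- generate_profile(config, config$rng_seed + i)
    res <- tryCatch(algorithm(prof$matrix), error = function(e) e)
    if (inherits(res, "error")) {
      failed <- failed + 1L
      next
    }
    ps <- element_precision_sensitivity(res, prof)
    prec[i] <- ps["precision"]
    sens[i] <- ps["sensitivity"]
  }
  if (failed > 0L)
    warning(failed, " replicate(s) failed and were excluded")
  structure(list(replicates = data.frame(replicate = seq_len(config$n_replicates),
                                         precision = prec,
                                         sensitivity = sens),
                 median_precision = median(prec, na.rm = TRUE),
                 median_sensitivity = median(sens, na.rm = TRUE),
                 n_failed = failed, config = config),
            class = "pbe_benchmark")
}

#' @export
print.pbe_benchmark <- function(x, ...) {
  cat(sprintf("simulation benchmark: %d replicate(s), %d x %d profiles\n",
              x$config$n_replicates, x$config$n_rows, x$config$n_cols))
  cat(sprintf("  median precision   %.1f%%\n", 100 * x$median_precision))
  cat(sprintf("  median sensitivity %.1f%%\n", 100 * x$median_sensitivity))
  if (x$n_failed) cat("  failed replicates:", x$n_failed, "\n")
  invisible(x)
}
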