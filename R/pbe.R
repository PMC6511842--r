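#' PBE pipeline configuration
#'
#' Collects the tunable parameters of the seed-extend-merge pipeline.  The
#' defaults are the ones used throughout: seeds of at least 10 x 10, at most
#' 20 seed biclusters per profile, a zero-proportion ramp of 0.01 to 0.10 in
#' steps of 0.01 for the extension, a Meet/Min dendrogram cutoff of 0.5 for
#' merging, and trimming of rows/columns with more than 10% zeros.
#'
#' @param min_seed_rows,min_seed_cols minimum seed bicluster dimensions.
#' @param bimax_iterations maximum number of seed biclusters extracted per
#'   profile (the BIMAX iteration cap).
#' @param zero_thresholds strictly increasing vector of zero-proportion
#'   thresholds in (0, 1) for the progressive extension.
#' @param merge_cutoff Meet/Min distance below which extended biclusters are
#'   merged, in (0, 1).
#' @param trim_zero_fraction maximum tolerated per-row/per-column zero
#'   fraction in a merged bicluster.
#' @param seed_schedule seed extraction schedule, see [bimax_seeds()].
#' @return An object of class `"pbe_config"`.
#' @export
pbe_config <- function(min_seed_rows = 10L, min_seed_cols = 10L,
                       bimax_iterations = 20L,
                       zero_thresholds = seq(0.01, 0.10, by = 0.01),
                       merge_cutoff = 0.5, trim_zero_fraction = 0.10,
                       seed_schedule = c("mask", "enumerate", "depth")) {
  seed_schedule <- match.arg(seed_schedule)
  if (any(diff(zero_thresholds) <= 0) || any(zero_thresholds <= 0) ||
      any(zero_thresholds >= 1))
    stop("zero_thresholds must be strictly increasing and inside (0, 1)")
  if (merge_cutoff <= 0 || merge_cutoff >= 1)
    stop("merge_cutoff must be inside (0, 1)")
  structure(list(min_seed_rows = as.integer(min_seed_rows),
                 min_seed_cols = as.integer(min_seed_cols),
                 bimax_iterations = as.integer(bimax_iterations),
                 zero_thresholds = as.numeric(zero_thresholds),
                 merge_cutoff = merge_cutoff,
                 trim_zero_fraction = trim_zero_fraction,
                 seed_schedule = seed_schedule),
            class = "pbe_config")
}

#' @export
print.pbe_config <- function(x, ...) {
  cat("PBE configuration:\n")
  cat(sprintf("  minimum seed size     %d x %d\n",
              x$min_seed_rows, x$min_seed_cols))
  cat(sprintf("  BIMAX iterations      %d (%s schedule)\n",
              x$bimax_iterations, x$seed_schedule))
  cat(sprintf("  zero-threshold ramp   %s\n",
              paste(format(x$zero_thresholds), collapse = " ")))
  cat(sprintf("  merge cutoff          %.2f (Meet/Min, average linkage)\n",
              x$merge_cutoff))
  cat(sprintf("  trim zero fraction    %.2f\n", x$trim_zero_fraction))
  invisible(x)
}

#' Fit PBE biclusters to a binary profile
#'
#' The main fitting function: runs the full seed-extend-merge pipeline on a
#' binary profile.  Seed biclusters (inclusion-maximal all-1 submatrices of
#' at least `min_seed_rows x min_seed_cols`) are extracted with the BIMAX
#' recursion, each seed is grown by progressive extension under the ramped
#' zero-proportion threshold, and the extended biclusters are merged by
#' average-linkage clustering of Meet/Min distances and trimmed.  Every
#' emitted bicluster has per-row and per-column zero fraction at most
#' `config$trim_zero_fraction`.  Results are ordered by decreasing cell
#' count, then decreasing density, then first row index.
#'
#' @param profile a binary matrix (rows are conditions, columns genes), a
#'   [mir_profile()], or a [generate_profile()] result.
#' @param config a [pbe_config()].
#' @return An object of class `"pbe"` with components `biclusters` (list of
#'   merged [bicluster()]s), `seeds`, `extended`, `config`, `dim`, and
#'   `profile` (the binary matrix the fit was computed on).
#' @seealso [bimax_seeds()], [extend_seed()], [merge_biclusters()]
#' @examples
#' m <- matrix(0L, 30, 30)
#' m[5:25, 3:22] <- 1L
#' fit <- pbe(m)
#' fit
#' @export
pbe <- function(profile, config = pbe_config()) {
  M <- profile_matrix(profile)
  cl <- match.call()
  if (nrow(M) == 0L || ncol(M) == 0L) {
    out <- list(biclusters = list(), seeds = list(), extended = list(),
                config = config, dim = dim(M), profile = M, call = cl)
    class(out) <- "pbe"
    return(out)
  }
  seeds <- bimax_seeds(M, config$min_seed_rows, config$min_seed_cols,
                       config$bimax_iterations,
                       schedule = config$seed_schedule)
  if (length(seeds) == 0L) {
    extended <- list()
    merged <- list()
  } else {
    extended <- lapply(seeds, extend_seed, profile = M, config = config)
    merged <- merge_biclusters(extended, M, config)
    ord <- order(-vapply(merged, bicluster_cells, numeric(1)),
                 -vapply(merged, `[[`, numeric(1), "density"),
                 vapply(merged, function(b) b$rows[1L], integer(1)))
    merged <- merged[ord]
  }
  out <- list(biclusters = merged, seeds = seeds, extended = extended,
              config = config, dim = dim(M), profile = M, call = cl)
  class(out) <- "pbe"
  out
}

#' @export
print.pbe <- function(x, ...) {
  cat(sprintf("PBE fit on a %d x %d binary profile\n", x$dim[1], x$dim[2]))
  cat(sprintf("  %d seed -> %d extended -> %d merged bicluster(s)\n",
              length(x$seeds), length(x$extended), length(x$biclusters)))
  if (length(x$biclusters)) {
    df <- as.data.frame(x)
    print(head(df, 10L))
    if (nrow(df) > 10L) cat("  ...", nrow(df) - 10L, "more\n")
  }
  invisible(x)
}

#' @export
summary.pbe <- function(object, ...) {
  df <- as.data.frame(object)
  res <- list(n_seeds = length(object$seeds),
              n_merged = length(object$biclusters),
              dim = object$dim,
              table = df,
              covered_cells = n_covered_cells(object),
              config = object$config)
  class(res) <- "summary.pbe"
  res
}

#' @export
print.summary.pbe <- function(x, ...) {
  cat(sprintf("PBE fit: %d merged bicluster(s) from %d seed(s) on %d x %d\n",
              x$n_merged, x$n_seeds, x$dim[1], x$dim[2]))
  cat(sprintf("  profile cells covered: %d (%.1f%%)\n", x$covered_cells,
              100 * x$covered_cells / prod(x$dim)))
  if (nrow(x$table)) print(x$table)
  invisible(x)
}

#' @export
as.data.frame.pbe <- function(x, ...) {
  bl <- x$biclusters
  data.frame(id = seq_along(bl),
             n_rows = vapply(bl, function(b) length(b$rows), integer(1)),
             n_cols = vapply(bl, function(b) length(b$cols), integer(1)),
             cells = vapply(bl, bicluster_cells, numeric(1)),
             density = vapply(bl, `[[`, numeric(1), "density"))
}

n_covered_cells <- function(fit) {
  if (!length(fit$biclusters)) return(0L)
  P <- matrix(FALSE, fit$dim[1], fit$dim[2])
  for (b in fit$biclusters) P[b$rows, b$cols] <- TRUE
  sum(P)
}

#' Plot a PBE fit
#'
#' Displays the binary profile as an image with the merged biclusters
#' outlined.  Rows and columns are reordered so that the members of each
#' bicluster are contiguous where possible (first-bicluster-first ordering).
#'
#' @param x a `"pbe"` object.
#' @param max_biclusters outline at most this many biclusters.
#' @param ... passed to [graphics::image()].
#' @export
plot.pbe <- function(x, max_biclusters = 8L, ...) {
  M <- x$profile
  bl <- head(x$biclusters, max_biclusters)
  row_ord <- unique(c(unlist(lapply(bl, `[[`, "rows")), seq_len(nrow(M))))
  col_ord <- unique(c(unlist(lapply(bl, `[[`, "cols")), seq_len(ncol(M))))
  graphics::image(seq_len(ncol(M)), seq_len(nrow(M)),
                  t(M[row_ord, col_ord, drop = FALSE]),
                  col = c("grey92", "grey25"), xlab = "columns (genes)",
                  ylab = "rows (conditions)", useRaster = TRUE, ...)
  rpos <- match(seq_len(nrow(M)), row_ord)
  cpos <- match(seq_len(ncol(M)), col_ord)
  for (i in seq_along(bl)) {
    rr <- range(rpos[bl[[i]]$rows])
    cc <- range(cpos[bl[[i]]$cols])
    graphics::rect(cc[1] - 0.5, rr[1] - 0.5, cc[2] + 0.5, rr[2] + 0.5,
                   border = grDevices::hcl.colors(max_biclusters, "Dark 2")[i],
                   lwd = 2)
  }
  invisible(x)
}
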