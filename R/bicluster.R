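#' Bicluster objects
#'
#' A bicluster is a pair of index sets (rows, columns) into a binary profile
#' matrix, together with the pipeline stage that produced it (`"seed"`,
#' `"extended"` or `"merged"`) and its realized density, the fraction of 1s in
#' the corresponding submatrix.  Seed biclusters are all-1 by construction and
#' therefore have density exactly 1.
#'
#' @param rows integer vector of row indices (duplicate-free, non-empty).
#' @param cols integer vector of column indices (duplicate-free, non-empty).
#' @param stage one of `"seed"`, `"extended"`, `"merged"`.
#' @param density fraction of 1s of the induced submatrix, in `[0, 1]`.
#' @return An object of class `"bicluster"`.
#' @export
bicluster <- function(rows, cols, stage = c("seed", "extended", "merged"),
                      density = NA_real_) {
  stage <- match.arg(stage)
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  if (length(rows) == 0L || length(cols) == 0L)
    stop("a bicluster needs at least one row and one column")
  if (anyDuplicated(rows) || anyDuplicated(cols))
    stop("bicluster indices must be duplicate-free")
  structure(list(rows = rows, cols = cols, stage = stage,
                 density = as.numeric(density)),
            class = "bicluster")
}

#' @export
print.bicluster <- function(x, ...) {
  cat(sprintf("bicluster [%s]: %d x %d, %d cells, density %.3f\n",
              x$stage, length(x$rows), length(x$cols),
              length(x$rows) * length(x$cols), x$density))
  invisible(x)
}

#' @export
dim.bicluster <- function(x) c(length(x$rows), length(x$cols))

bicluster_cells <- function(x) length(x$rows) * length(x$cols)

bicluster_density <- function(rows, cols, profile) {
  sum(profile[rows, cols, drop = FALSE]) / (length(rows) * length(cols))
}

#' Meet/Min distance between two biclusters
#'
#' The distance used for merging redundant biclusters:
#' `1 - |A intersect B| / min(|A|, |B|)`, where the size `|A|` of a bicluster
#' is its cell count (number of rows times number of columns) and the
#' intersection counts shared cells, i.e. shared rows times shared columns.
#' It is 0 for identical biclusters and 1 for pairs sharing no row or no
#' column.
#'
#' @param a,b `bicluster` objects over the same profile.
#' @return A number in `[0, 1]`.
#' @export
meet_min_distance <- function(a, b) {
  size_a <- bicluster_cells(a)
  size_b <- bicluster_cells(b)
  overlap <- length(intersect(a$rows, b$rows)) *
    length(intersect(a$cols, b$cols))
  1 - overlap / min(size_a, size_b)
}

# Pairwise Meet/Min distance matrix, vectorized over indicator matrices.
meet_min_matrix <- function(biclusters, n_rows, n_cols) {
  k <- length(biclusters)
  R <- matrix(0L, k, n_rows)
  C <- matrix(0L, k, n_cols)
  for (i in seq_len(k)) {
    R[i, biclusters[[i]]$rows] <- 1L
    C[i, biclusters[[i]]$cols] <- 1L
  }
  shared <- (R %*% t(R)) * (C %*% t(C))
  sizes <- vapply(biclusters, bicluster_cells, numeric(1))
  1 - shared / outer(sizes, sizes, pmin)
}
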