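#' Merge redundant extended biclusters
#'
#' Extended biclusters that cover overlapping parts of the profile are grouped
#' by average-linkage hierarchical clustering of their pairwise Meet/Min
#' distances; the dendrogram is cut so that groups joined at distance below
#' `config$merge_cutoff` are merged.  Each group is merged by taking the
#' union of its members' row sets crossed with the union of their column
#' sets.  Because the union rectangle can sweep in noisy cells, it is then
#' trimmed: while any row or column of the merged submatrix has a zero
#' fraction above `config$trim_zero_fraction`, the single worst offender is
#' removed (highest zero fraction first; ties broken by fewer 1s in the full
#' profile, then rows before columns, then lowest index).  Identical results
#' collapse to one, and a group trimmed to emptiness is dropped.
#'
#' @param extended list of [bicluster()] objects (stage `"extended"`).
#' @param profile binary matrix or [mir_profile()].
#' @param config a [pbe_config()].
#' @return A list of [bicluster()] objects with stage `"merged"`, every row
#'   and column of which has zero fraction at most `config$trim_zero_fraction`.
#' @export
merge_biclusters <- function(extended, profile, config = pbe_config()) {
  M <- profile_matrix(profile)
  if (length(extended) == 0L) return(list())

  k <- length(extended)
  if (k == 1L) {
    groups <- 1L
  } else {
    D <- meet_min_matrix(extended, nrow(M), ncol(M))
    hc <- hclust(as.dist(D), method = "average")
    # join strictly below the cutoff
    groups <- cutree(hc, h = config$merge_cutoff - 1e-9)
  }

  merged <- list()
  for (g in unique(groups)) {
    members <- extended[groups == g]
    rows <- sort(unique(unlist(lapply(members, `[[`, "rows"))))
    cols <- sort(unique(unlist(lapply(members, `[[`, "cols"))))
    tr <- trim_bicluster(rows, cols, M, config$trim_zero_fraction)
    if (is.null(tr)) {
      message("merged bicluster trimmed to emptiness; dropped")
      next
    }
    merged[[length(merged) + 1L]] <-
      bicluster(tr$rows, tr$cols, "merged",
                bicluster_density(tr$rows, tr$cols, M))
  }

  # deduplicate identical row+col sets
  if (length(merged) > 1L) {
    sig <- vapply(merged, function(b)
      paste(paste(b$rows, collapse = ","), paste(b$cols, collapse = ","),
            sep = "|"), character(1))
    merged <- merged[!duplicated(sig)]
  }
  merged
}

# Iteratively remove the worst row/column until all zero fractions <= trim.
# Returns list(rows, cols) or NULL if emptied.
trim_bicluster <- function(rows, cols, M, trim) {
  storage.mode(M) <- "double"
  in_row <- logical(nrow(M)); in_row[rows] <- TRUE
  in_col <- logical(ncol(M)); in_col[cols] <- TRUE
  ones_row <- as.vector(M[, in_col, drop = FALSE] %*% rep(1, sum(in_col)))
  ones_col <- as.vector(rep(1, sum(in_row)) %*% M[in_row, , drop = FALSE])
  full_row <- rowSums(M)
  full_col <- colSums(M)
  eps <- 1e-9

  repeat {
    nr <- sum(in_row); nc <- sum(in_col)
    if (nr == 0L || nc == 0L) return(NULL)
    zf_r <- 1 - ones_row / nc
    zf_c <- 1 - ones_col / nr
    off_r <- which(in_row & zf_r > trim + eps)
    off_c <- which(in_col & zf_c > trim + eps)
    if (!length(off_r) && !length(off_c)) break
    worst_r_key <- if (length(off_r)) {
      o <- order(-zf_r[off_r], full_row[off_r], off_r)[1L]
      c(-zf_r[off_r[o]], full_row[off_r[o]], 0, off_r[o])
    }
    worst_c_key <- if (length(off_c)) {
      o <- order(-zf_c[off_c], full_col[off_c], off_c)[1L]
      c(-zf_c[off_c[o]], full_col[off_c[o]], 1, off_c[o])
    }
    take_row <- if (is.null(worst_c_key)) TRUE
      else if (is.null(worst_r_key)) FALSE
      else key_less(worst_r_key, worst_c_key)
    if (take_row) {
      r <- worst_r_key[4L]
      in_row[r] <- FALSE
      ones_col <- ones_col - M[r, ]
    } else {
      cl <- worst_c_key[4L]
      in_col[cl] <- FALSE
      ones_row <- ones_row - M[, cl]
    }
  }
  list(rows = which(in_row), cols = which(in_col))
}
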