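#' Progressively extend a seed bicluster (PBE)
#'
#' Grows an all-1 seed bicluster into a larger, noise-tolerant bicluster by
#' ramping a zero-proportion threshold from strict to lenient.  At each
#' threshold `t` of `config$zero_thresholds` (ascending):
#'
#' 1. *Addition phase*: every row not in the bicluster is scored by its
#'    fraction of zeros over the current columns, and every column not in the
#'    bicluster by its fraction of zeros over the current rows.  Among
#'    candidates with zero fraction `<= t`, the single best one is added
#'    (lowest zero fraction; ties broken by more 1s in the full profile, then
#'    rows before columns, then lowest index), scores are recomputed, and the
#'    step repeats until no candidate qualifies.
#' 2. *Removal phase*: while any member row or column has zero fraction
#'    `> t` within the bicluster, the single worst offender is removed
#'    (highest zero fraction; ties broken by fewer 1s in the full profile,
#'    then rows before columns, then lowest index) and scores are recomputed.
#'
#' Rows and columns compete in a single pool, and one element is moved per
#' step with full recomputation, which makes the procedure deterministic and
#' independent of the layout of the input.  On exit every row and column of
#' the result has zero fraction at most `max(config$zero_thresholds)`.
#' If removal ever empties the bicluster the input seed is returned unchanged.
#'
#' @param seed a [bicluster()] whose indices are valid in `profile`.
#' @param profile binary matrix or [mir_profile()].
#' @param config a [pbe_config()].
#' @return A [bicluster()] with stage `"extended"`.
#' @export
extend_seed <- function(seed, profile, config = pbe_config()) {
  M <- profile_matrix(profile)
  storage.mode(M) <- "double"
  n <- nrow(M)
  m <- ncol(M)
  if (any(seed$rows < 1L | seed$rows > n) || any(seed$cols < 1L | seed$cols > m))
    stop("seed indices out of range for profile")

  in_row <- logical(n); in_row[seed$rows] <- TRUE
  in_col <- logical(m); in_col[seed$cols] <- TRUE
  # incremental counters: 1s of every row over current columns, and of every
  # column over current rows
  ones_row <- as.vector(M[, in_col, drop = FALSE] %*% rep(1, sum(in_col)))
  ones_col <- as.vector(rep(1, sum(in_row)) %*% M[in_row, , drop = FALSE])
  full_row <- rowSums(M)
  full_col <- colSums(M)
  eps <- 1e-9

  add_row <- function(r) {
    in_row[r] <<- TRUE
    ones_col <<- ones_col + M[r, ]
  }
  add_col <- function(cl) {
    in_col[cl] <<- TRUE
    ones_row <<- ones_row + M[, cl]
  }
  drop_row <- function(r) {
    in_row[r] <<- FALSE
    ones_col <<- ones_col - M[r, ]
  }
  drop_col <- function(cl) {
    in_col[cl] <<- FALSE
    ones_row <<- ones_row - M[, cl]
  }

  for (t in config$zero_thresholds) {
    # -- addition phase --
    repeat {
      nr <- sum(in_row); nc <- sum(in_col)
      zf_r <- 1 - ones_row / nc     # all rows, over current columns
      zf_c <- 1 - ones_col / nr
      cand_r <- which(!in_row & zf_r <= t + eps)
      cand_c <- which(!in_col & zf_c <= t + eps)
      if (!length(cand_r) && !length(cand_c)) break
      best_r_key <- if (length(cand_r)) {
        o <- order(zf_r[cand_r], -full_row[cand_r], cand_r)[1L]
        c(zf_r[cand_r[o]], -full_row[cand_r[o]], 0, cand_r[o])
      }
      best_c_key <- if (length(cand_c)) {
        o <- order(zf_c[cand_c], -full_col[cand_c], cand_c)[1L]
        c(zf_c[cand_c[o]], -full_col[cand_c[o]], 1, cand_c[o])
      }
      take_row <- if (is.null(best_c_key)) TRUE
        else if (is.null(best_r_key)) FALSE
        else key_less(best_r_key, best_c_key)
      if (take_row) add_row(best_r_key[4L]) else add_col(best_c_key[4L])
    }
    # -- removal phase --
    repeat {
      nr <- sum(in_row); nc <- sum(in_col)
      if (nr == 0L || nc == 0L) {
        message("removal emptied the bicluster; returning the seed unchanged")
        return(seed)
      }
      zf_r <- 1 - ones_row / nc
      zf_c <- 1 - ones_col / nr
      off_r <- which(in_row & zf_r > t + eps)
      off_c <- which(in_col & zf_c > t + eps)
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
        drop_row(worst_r_key[4L])
        if (!any(in_row)) {
          message("removal emptied the bicluster; returning the seed unchanged")
          return(seed)
        }
      } else {
        drop_col(worst_c_key[4L])
        if (!any(in_col)) {
          message("removal emptied the bicluster; returning the seed unchanged")
          return(seed)
        }
      }
    }
  }

  rows <- which(in_row)
  cols <- which(in_col)
  bicluster(rows, cols, "extended", bicluster_density(rows, cols, M))
}

# lexicographic comparison of numeric tie-break keys
key_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - 1e-12) return(TRUE)
    if (a[i] > b[i] + 1e-12) return(FALSE)
  }
  FALSE
}
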