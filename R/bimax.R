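#' Extract all-1 seed biclusters with the BIMAX recursion
#'
#' Finds inclusion-maximal all-1 submatrices (bicliques) of a binary profile
#' that satisfy a minimum size, using the BIMAX divide-and-conquer recursion.
#' Three extraction schedules are available:
#'
#' * `"depth"`: a single run of the recursion whose number of divisions along
#'   any root-to-leaf path is capped at `max_seeds`; every maximal bicluster
#'   whose leaf is reached within that division budget is reported.  The
#'   division budget bounds the computation and the number of reported
#'   biclusters grows quickly with it.
#' * `"enumerate"`: a depth-first run that reports maximal biclusters in
#'   discovery order until `max_seeds` have been found (or all of them, if
#'   `max_seeds` is large).  This is the schedule used for exhaustive
#'   enumeration, e.g. when comparing against a brute-force oracle.
#' * `"mask"`: seed biclusters are extracted one at a time; after each
#'   extraction the cells of the found bicluster are set to 0 and the
#'   recursion restarts on the masked matrix, so successive seeds are
#'   cell-disjoint.
#'
#' Every returned bicluster is inclusion-maximal in the matrix it was
#' extracted from (the masked matrix for `"mask"`, the input otherwise) and
#' all of its cells are 1 in the input matrix, so seed density is exactly 1.
#'
#' @param profile binary matrix (0/1), or a [mir_profile()] object.
#' @param min_rows,min_cols minimum seed dimensions (default 10 x 10).
#' @param max_seeds iteration cap: the division depth for `"depth"`, the
#'   number of seeds otherwise.
#' @param schedule `"depth"`, `"enumerate"` or `"mask"`, see Details.
#' @param template_rule how the row that drives each column split is chosen:
#'   0 = first non-full row, 1 = row giving the most balanced split,
#'   2 = row with most ones, 3 = row with fewest ones.
#' @param node_budget safety cap on recursion nodes per search; when the
#'   budget is exhausted extraction stops with a warning.
#' @return A list of [bicluster()] objects with stage `"seed"`.
#' @export
bimax_seeds <- function(profile, min_rows = 10L, min_cols = 10L,
                        max_seeds = 20L,
                        schedule = c("mask", "enumerate", "depth"),
                        template_rule = 2L, node_budget = 2e6) {
  schedule <- match.arg(schedule)
  M <- profile_matrix(profile)
  stopifnot(min_rows >= 1L, min_cols >= 1L, max_seeds >= 1L)
  storage.mode(M) <- "integer"

  seeds <- list()
  if (schedule == "depth") {
    res <- bimax_enumerate_cpp(M, min_rows, min_cols, .Machine$integer.max,
                               max_seeds, template_rule, node_budget)
    if (res$budget_hit)
      warning("BIMAX node budget exhausted; seed list may be incomplete")
    for (i in seq_along(res$rows))
      seeds[[i]] <- bicluster(res$rows[[i]], res$cols[[i]], "seed", 1.0)
  } else if (schedule == "enumerate") {
    res <- bimax_enumerate_cpp(M, min_rows, min_cols, max_seeds,
                               .Machine$integer.max, template_rule,
                               node_budget)
    if (res$budget_hit)
      warning("BIMAX node budget exhausted; seed list may be incomplete")
    for (i in seq_along(res$rows))
      seeds[[i]] <- bicluster(res$rows[[i]], res$cols[[i]], "seed", 1.0)
  } else {
    W <- M
    repeat {
      if (length(seeds) >= max_seeds) break
      res <- bimax_enumerate_cpp(W, min_rows, min_cols, 1L,
                                 .Machine$integer.max, template_rule,
                                 node_budget)
      if (length(res$rows) == 0L) {
        if (res$budget_hit)
          warning("BIMAX node budget exhausted; seed list may be incomplete")
        break
      }
      r <- res$rows[[1L]]
      co <- res$cols[[1L]]
      seeds[[length(seeds) + 1L]] <- bicluster(r, co, "seed", 1.0)
      W[r, co] <- 0L
    }
  }
  seeds
}

# Accept either a raw binary matrix or a mir_profile / simulated_profile.
profile_matrix <- function(profile) {
  if (inherits(profile, "mir_profile")) return(profile$values)
  if (inherits(profile, "simulated_profile")) return(profile$matrix)
  if (is.matrix(profile)) {
    if (!all(profile %in% c(0, 1)))
      stop("profile matrix must be binary (0/1)")
    return(profile)
  }
  stop("profile must be a binary matrix, mir_profile or simulated_profile")
}
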