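#' Gold-standard target sets for one miRNA
#'
#' Holds the background (sequence-predicted) target set of a miRNA together
#' with disjoint gold-positive (GP, strong experimental evidence) and
#' gold-negative (GN, no experimental evidence) subsets.
#'
#' @param background character vector of background genes.
#' @param positives,negatives character vectors; must be disjoint, and any
#'   gene outside the background is dropped with a warning.
#' @return An object of class `"gold_standard"`.
#' @export
gold_standard <- function(background, positives, negatives) {
  background <- unique(trimws(background))
  positives <- unique(trimws(positives))
  negatives <- unique(trimws(negatives))
  if (length(background) == 0L) stop("background set is empty")
  both <- intersect(positives, negatives)
  if (length(both))
    stop("gene(s) in both GP and GN: ", paste(head(both, 5), collapse = ", "))
  out_p <- setdiff(positives, background)
  out_n <- setdiff(negatives, background)
  if (length(out_p) || length(out_n))
    warning(length(out_p) + length(out_n),
            " GP/GN gene(s) outside the background were dropped")
  structure(list(background = background,
                 positives = intersect(positives, background),
                 negatives = intersect(negatives, background)),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("gold standard: %d background, %d GP, %d GN\n",
              length(x$background), length(x$positives), length(x$negatives)))
  invisible(x)
}

#' Is a miRNA eligible for gold-standard evaluation?
#'
#' A miRNA qualifies when it has more than `min_gp` gold-positive targets
#' and the GP fraction of its background set is at least `min_gp_fraction`.
#'
#' @param gs a [gold_standard()].
#' @param min_gp strict lower bound on the GP count (default 30).
#' @param min_gp_fraction minimum `|GP| / |background|` (default 0.05).
#' @return Logical scalar.
#' @export
eligible_mirna <- function(gs, min_gp = 30L, min_gp_fraction = 0.05) {
  ngp <- length(gs$positives)
  ngp > min_gp && ngp / length(gs$background) >= min_gp_fraction
}

#' Sensitivity, specificity and gain of a target prediction
#'
#' Against a gold standard: sensitivity is the fraction of GP genes
#' predicted, specificity the fraction of GN genes not predicted, and the
#' gain in certainty is `sensitivity + specificity - 1`.  Predicting the
#' whole background (the sequence-only predictor) scores gain 0.  Predicted
#' genes outside the background are discarded with a warning.
#'
#' @param predicted character vector of predicted target genes.
#' @param gs a [gold_standard()] with non-empty GP and GN.
#' @return Named list with `sensitivity`, `specificity`, `gain`.
#' @export
score_predictions <- function(predicted, gs) {
  if (length(gs$positives) == 0L || length(gs$negatives) == 0L)
    stop("gold standard needs non-empty GP and GN sets")
  predicted <- unique(trimws(predicted))
  outside <- setdiff(predicted, gs$background)
  if (length(outside)) {
    warning(length(outside), " predicted gene(s) outside the background were discarded")
    predicted <- intersect(predicted, gs$background)
  }
  sens <- length(intersect(predicted, gs$positives)) / length(gs$positives)
  spec <- length(setdiff(gs$negatives, predicted)) / length(gs$negatives)
  list(sensitivity = sens, specificity = spec, gain = sens + spec - 1)
}

#' Filter predicted targets by interaction degree among themselves
#'
#' Induces the interaction network on the predicted genes and keeps those
#' with at least `k` interactions with other predicted targets.  `k = 0`
#' returns the input unchanged.
#'
#' @param predicted character vector of genes.
#' @param network an [read_edge_list()] result.
#' @param k minimum within-prediction degree.
#' @return Character vector (subset of `predicted`).
#' @export
network_degree_filter <- function(predicted, network, k = 0L) {
  stopifnot(k >= 0L)
  if (k == 0L) return(predicted)
  predicted <- unique(predicted)
  sub <- network[network$gene1 %in% predicted & network$gene2 %in% predicted,
                 , drop = FALSE]
  if (nrow(sub) == 0L) return(character(0))
  g <- igraph::graph_from_data_frame(sub[, c("gene1", "gene2")],
                                     directed = FALSE,
                                     vertices = predicted)
  deg <- igraph::degree(g)
  names(deg)[deg >= k]
}

#' Pooled condition-proportion curve of bicluster targets
#'
#' For a condition keyword (e.g. a cancer type), keeps the biclusters in
#' which at least `min_fraction` of the condition rows match the keyword
#' (case-insensitive substring match on the condition labels), sorts them by
#' that matching fraction in decreasing order (ties: larger bicluster first,
#' then input order), and pools their gene sets cumulatively.  After each
#' pooling step the true-positive rate `|pool & GP| / |GP|` and
#' false-positive rate `|pool & GN| / |GN|` are emitted, tracing a staircase
#' comparable to a ROC curve.
#'
#' @param biclusters list whose elements have `$conditions` and `$genes`
#'   character vectors (e.g. rows of [read_biclusters()] output, or
#'   [bicluster_members()] of a fit).
#' @param condition_labels named character vector mapping condition ids to
#'   free-text labels; every bicluster condition must be present.
#' @param keyword substring to match in the labels.
#' @param min_fraction minimum fraction of matching condition rows
#'   (default 0.30).
#' @param gs a [gold_standard()].
#' @return Data frame with one row per pooling step: `step`,
#'   `condition_fraction`, `pool_size`, `tpr`, `fpr`.  Zero qualifying
#'   biclusters give a zero-row frame.
#' @export
pooled_condition_curve <- function(biclusters, condition_labels, keyword,
                                   min_fraction = 0.30, gs) {
  fr <- vapply(biclusters, function(b) {
    labs <- condition_labels[b$conditions]
    if (anyNA(labs))
      stop("condition(s) without a label: ",
           paste(head(b$conditions[is.na(labs)], 3), collapse = ", "))
    mean(grepl(tolower(keyword), tolower(labs), fixed = TRUE))
  }, numeric(1))
  sizes <- vapply(biclusters, function(b)
    length(b$conditions) * length(b$genes), numeric(1))
  keep <- which(fr >= min_fraction)
  if (!length(keep))
    return(data.frame(step = integer(), condition_fraction = numeric(),
                      pool_size = integer(), tpr = numeric(),
                      fpr = numeric()))
  ord <- keep[order(-fr[keep], -sizes[keep], keep)]
  pool <- character(0)
  out <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    pool <- union(pool, biclusters[[ord[i]]]$genes)
    out[[i]] <- data.frame(
      step = i, condition_fraction = fr[ord[i]], pool_size = length(pool),
      tpr = length(intersect(pool, gs$positives)) / length(gs$positives),
      fpr = length(intersect(pool, gs$negatives)) / length(gs$negatives))
  }
  do.call(rbind, out)
}

#' Extract named members of fitted biclusters
#'
#' Maps the row/column index sets of a fit's biclusters to condition and
#' gene identifiers of the profile, the form consumed by
#' [pooled_condition_curve()] and the evaluation utilities.
#'
#' @param fit a `"pbe"` object (or list of [bicluster()]s).
#' @param profile the profile the fit was computed on (for dimnames).
#' @return List of lists with `conditions` and `genes` character vectors.
#' @export
bicluster_members <- function(fit, profile) {
  if (inherits(fit, "pbe")) fit <- fit$biclusters
  M <- profile_matrix(profile)
  cond_ids <- rownames(M)
  gene_ids <- colnames(M)
  if (is.null(cond_ids)) cond_ids <- paste0("r", seq_len(nrow(M)))
  if (is.null(gene_ids)) gene_ids <- paste0("c", seq_len(ncol(M)))
  lapply(fit, function(b)
    list(conditions = cond_ids[b$rows], genes = gene_ids[b$cols]))
}
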