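#' Quantize log fold changes into up/neutral/down calls
#'
#' Entries with `logFC >= fc_threshold` become `1` (up-regulated), entries
#' with `logFC <= -fc_threshold` become `-1` (down-regulated) and everything
#' else, including missing values, becomes `0` (neutral).  The boundary is
#' inclusive: a value exactly at the threshold counts as regulated.
#'
#' @param fc numeric matrix of log2 fold changes, genes x conditions, with
#'   gene row names and condition column names.
#' @param fc_threshold positive threshold on the log2 scale; a 1.3-fold
#'   change corresponds to `log2(1.3)`.
#' @return An integer matrix over `{-1, 0, 1}` with the same dimnames and a
#'   `"fc_threshold"` attribute, of class `"ternary_matrix"`.
#' @export
quantize <- function(fc, fc_threshold = log2(1.3)) {
  if (!is.numeric(fc_threshold) || length(fc_threshold) != 1L ||
      fc_threshold <= 0)
    stop("fc_threshold must be a single positive number (log2 scale)")
  v <- matrix(0L, nrow(fc), ncol(fc), dimnames = dimnames(fc))
  v[!is.na(fc) & fc >= fc_threshold] <- 1L
  v[!is.na(fc) & fc <= -fc_threshold] <- -1L
  structure(v, fc_threshold = fc_threshold,
            class = c("ternary_matrix", class(v)))
}

#' Select conditions enriched for regulated background genes
#'
#' For each condition (column) a one-sided hypergeometric upper-tail test
#' asks whether the condition's up- (or down-) regulated genes are enriched
#' in the background target set: with `N` genes in the matrix, `K` of them in
#' the background, `n` regulated in the condition and `k` of those in the
#' background, `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.  P-values
#' are Benjamini-Hochberg adjusted across all conditions of the matrix (one
#' family per direction), and conditions with adjusted `p < fdr_cutoff` are
#' returned in matrix order.  A condition with no regulated genes gets
#' `p = 1`.
#'
#' @param tern a [quantize()] result (genes x conditions).
#' @param background character vector of background gene symbols; silently
#'   intersected with the matrix genes (a message reports dropped symbols).
#' @param direction `"up"` tests enrichment of `+1` calls, `"down"` of `-1`.
#' @param fdr_cutoff BH-adjusted p-value cutoff (default 0.05).
#' @return A data frame with one row per selected condition: `condition`,
#'   `n_regulated`, `n_in_background`, `p`, `p_adjusted`.  The full
#'   per-condition table is attached as attribute `"all_conditions"`.
#' @export
enriched_conditions <- function(tern, background, direction = c("up", "down"),
                                fdr_cutoff = 0.05) {
  direction <- match.arg(direction)
  genes <- rownames(tern)
  if (is.null(genes)) stop("quantized matrix must have gene row names")
  bg <- intersect(background, genes)
  if (length(bg) < length(unique(background)))
    message(length(unique(background)) - length(bg),
            " background gene(s) absent from the matrix were dropped")
  N <- nrow(tern)
  K <- length(bg)
  target_value <- if (direction == "up") 1L else -1L
  hits <- tern == target_value
  n <- colSums(hits)
  k <- colSums(hits[genes %in% bg, , drop = FALSE])
  # upper-tail hypergeometric: P(X >= k)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p[n == 0] <- 1
  padj <- p.adjust(p, method = "BH")
  all <- data.frame(condition = colnames(tern), n_regulated = as.integer(n),
                    n_in_background = as.integer(k), p = p,
                    p_adjusted = padj, row.names = NULL)
  sel <- all[padj < fdr_cutoff, , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "all_conditions") <- all
  sel
}

#' Build a binary MIR profile for one miRNA and direction
#'
#' Restricts the quantized matrix to the background target genes and to the
#' conditions enriched for regulation in the requested direction, then
#' binarizes: a cell is 1 iff the ternary value equals `+1` (direction
#' `"up"`) or `-1` (direction `"down"`).  Rows are conditions, columns are
#' genes.  With no enriched condition an empty profile is returned with a
#' warning and downstream stages no-op.
#'
#' @inheritParams enriched_conditions
#' @return An object of class `"mir_profile"`: list with `values` (binary
#'   conditions x genes matrix), `direction`, `fc_threshold`, `fdr_cutoff`,
#'   `condition_fdr` (named adjusted p-values of the selected conditions).
#' @export
build_mir_profile <- function(tern, background, direction = c("up", "down"),
                              fdr_cutoff = 0.05) {
  direction <- match.arg(direction)
  sel <- enriched_conditions(tern, background, direction, fdr_cutoff)
  bg <- intersect(background, rownames(tern))
  target_value <- if (direction == "up") 1L else -1L
  if (nrow(sel) == 0L) {
    warning("no condition enriched at FDR < ", fdr_cutoff,
            " for direction '", direction, "'; empty profile")
    values <- matrix(0L, 0L, length(bg), dimnames = list(NULL, bg))
  } else {
    sub <- tern[bg, sel$condition, drop = FALSE]
    values <- t(sub == target_value) * 1L
    dimnames(values) <- list(sel$condition, bg)
  }
  structure(list(values = values, direction = direction,
                 fc_threshold = attr(tern, "fc_threshold"),
                 fdr_cutoff = fdr_cutoff,
                 condition_fdr = stats::setNames(sel$p_adjusted,
                                                 sel$condition)),
            class = "mir_profile")
}

#' @export
print.mir_profile <- function(x, ...) {
  cat(sprintf("MIR profile (%s, fc_threshold %.4g, FDR < %g): %d condition(s) x %d gene(s), density %.3f\n",
              x$direction, x$fc_threshold, x$fdr_cutoff,
              nrow(x$values), ncol(x$values),
              if (length(x$values)) mean(x$values) else NA_real_))
  invisible(x)
}

#' @export
dim.mir_profile <- function(x) dim(x$values)
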