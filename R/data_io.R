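#' Read a gene x condition log fold-change matrix
#'
#' Reads a delimited text matrix whose first row holds condition identifiers
#' and whose first column holds gene symbols.  Non-numeric cells become
#' missing values (treated as neutral by [quantize()]).  Duplicate gene
#' symbols and ragged rows are hard errors that name the offender.
#'
#' @param path file path.
#' @param delimiter field separator (default tab).
#' @return Numeric matrix, genes x conditions, with gene row names and
#'   condition column names, in file order.
#' @export
read_fold_change_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("no data rows in ", path)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  header <- fields[[1L]]
  conditions <- trimws(header[-1L])
  width <- length(header)
  widths <- lengths(fields)
  bad <- which(widths[-1L] != width)
  if (length(bad))
    stop("ragged row: line ", bad[1L] + 1L, " has ", widths[bad[1L] + 1L],
         " fields, expected ", width)
  genes <- trimws(vapply(fields[-1L], `[[`, character(1), 1L))
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicate gene symbol: ", dup[1L])
  values <- matrix(NA_real_, length(genes), length(conditions),
                   dimnames = list(genes, conditions))
  for (i in seq_along(genes)) {
    v <- suppressWarnings(as.numeric(fields[[i + 1L]][-1L]))
    values[i, ] <- v
  }
  if (anyDuplicated(conditions))
    stop("duplicate condition id: ", conditions[duplicated(conditions)][1L])
  values
}

#' Read a gene-set file
#'
#' One gene symbol per line; blank lines and lines starting with `#` are
#' ignored; symbols are whitespace-trimmed and matched case-sensitively.
#'
#' @param path file path.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Consensus background target set across prediction databases
#'
#' The background set of a miRNA is the set of genes predicted as targets by
#' at least `min_sources` of the supplied sequence-based databases (default:
#' at least 3 of them).
#'
#' @param target_sets named list of character vectors, one per source
#'   database.
#' @param min_sources minimum number of databases that must agree.
#' @return Character vector (sorted).  An empty consensus produces a warning
#'   and an empty vector so that the pipeline for that miRNA halts cleanly.
#' @export
consensus_background <- function(target_sets, min_sources = 3L) {
  stopifnot(is.list(target_sets), length(target_sets) >= 1L)
  if (min_sources > length(target_sets))
    stop("min_sources (", min_sources, ") exceeds the number of sources (",
         length(target_sets), ")")
  counts <- table(unlist(lapply(target_sets, function(s) unique(trimws(s)))))
  out <- sort(names(counts)[counts >= min_sources])
  if (length(out) == 0L)
    warning("empty consensus background set")
  out
}

#' Read a weighted undirected interaction edge list
#'
#' Three tab-separated columns: gene, gene, numeric score.  Self-loops are
#' dropped (a message reports how many), duplicate pairs keep the maximum
#' score, and only edges with score strictly greater than `score_threshold`
#' are retained.
#'
#' @param path file path.
#' @param score_threshold strict lower bound on edge scores (e.g. 150 for
#'   STRING-style functional scores).
#' @return An object of class `"interaction_network"`: data frame with
#'   columns `gene1`, `gene2`, `score` (pairs stored once, lexicographic
#'   order) and attribute `"score_threshold"`.
#' @export
read_edge_list <- function(path, score_threshold = 150) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("gene1", "gene2", "score"))
  df$gene1 <- trimws(df$gene1)
  df$gene2 <- trimws(df$gene2)
  loops <- df$gene1 == df$gene2
  if (any(loops)) {
    message("dropped ", sum(loops), " self-loop(s)")
    df <- df[!loops, , drop = FALSE]
  }
  a <- pmin(df$gene1, df$gene2)
  b <- pmax(df$gene1, df$gene2)
  key <- paste(a, b, sep = "\r")
  o <- order(key, -df$score)
  df <- data.frame(gene1 = a[o], gene2 = b[o], score = df$score[o])
  df <- df[!duplicated(paste(df$gene1, df$gene2, sep = "\r")), , drop = FALSE]
  df <- df[df$score > score_threshold, , drop = FALSE]
  df <- df[order(df$gene1, df$gene2), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, score_threshold = score_threshold,
            class = c("interaction_network", "data.frame"))
}

#' Write biclusters to a tab-separated file
#'
#' One record per bicluster: id, direction, FC threshold, stage, row count,
#' column count, density, semicolon-joined condition identifiers and
#' semicolon-joined gene symbols.  The paired reader [read_biclusters()]
#' round-trips the identifier sets losslessly.
#'
#' @param biclusters list of [bicluster()] objects (or a `"pbe"` fit).
#' @param profile the [mir_profile()] (or binary matrix with dimnames) the
#'   bicluster indices refer to.
#' @param path output file path.
#' @export
write_biclusters <- function(biclusters, profile, path) {
  if (inherits(biclusters, "pbe")) biclusters <- biclusters$biclusters
  M <- profile_matrix(profile)
  direction <- if (inherits(profile, "mir_profile")) profile$direction else NA
  fc <- if (inherits(profile, "mir_profile")) profile$fc_threshold else NA
  cond_ids <- rownames(M)
  gene_ids <- colnames(M)
  if (is.null(cond_ids)) cond_ids <- paste0("r", seq_len(nrow(M)))
  if (is.null(gene_ids)) gene_ids <- paste0("c", seq_len(ncol(M)))
  rec <- lapply(seq_along(biclusters), function(i) {
    b <- biclusters[[i]]
    if (any(b$rows > nrow(M)) || any(b$cols > ncol(M)))
      stop("bicluster ", i, " has indices outside the profile")
    data.frame(id = i, direction = direction, fc_threshold = fc,
               stage = b$stage, n_rows = length(b$rows),
               n_cols = length(b$cols), density = b$density,
               conditions = paste(cond_ids[b$rows], collapse = ";"),
               genes = paste(gene_ids[b$cols], collapse = ";"))
  })
  df <- if (length(rec)) do.call(rbind, rec) else
    data.frame(id = integer(), direction = character(),
               fc_threshold = numeric(), stage = character(),
               n_rows = integer(), n_cols = integer(), density = numeric(),
               conditions = character(), genes = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bicluster file written by [write_biclusters()]
#'
#' @param path file path.
#' @return Data frame with one row per bicluster; `conditions` and `genes`
#'   are list-columns of character vectors.
#' @export
read_biclusters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$conditions <- strsplit(as.character(df$conditions), ";", fixed = TRUE)
  df$genes <- strsplit(as.character(df$genes), ";", fixed = TRUE)
  df
}
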