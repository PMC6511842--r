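# Shared fixture builders: everything is generated in code at test time.

# binary matrix with a planted all-1 block on given index sets
planted_matrix <- function(n, m, rows, cols, background = 0) {
  M <- matrix(rbinom(n * m, 1L, background), n, m)
  M[rows, cols] <- 1L
  M
}

# write a genes x conditions fold-change TSV, returns path
write_fc_tsv <- function(values, genes, conditions, path = tempfile(fileext = ".tsv")) {
  header <- paste(c("gene", conditions), collapse = "\t")
  rows <- vapply(seq_along(genes), function(i)
    paste(c(genes[i], values[i, ]), collapse = "\t"), character(1))
  writeLines(c(header, rows), path)
  path
}

write_gene_set_file <- function(genes, path = tempfile(fileext = ".txt")) {
  writeLines(genes, path)
  path
}

# brute-force enumeration of inclusion-maximal all-1 submatrices meeting a
# minimum size, by closure over all column subsets (oracle for bimax_seeds)
brute_force_bicliques <- function(M, min_rows, min_cols) {
  m <- ncol(M)
  out <- list()
  seen <- character(0)
  for (mask in seq_len(2^m - 1)) {
    cols <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    if (length(cols) < min_cols) next
    rows <- which(rowSums(M[, cols, drop = FALSE]) == length(cols))
    if (length(rows) < min_rows) next
    # closure: columns full on these rows must equal cols, else not maximal
    full_cols <- which(colSums(M[rows, , drop = FALSE]) == length(rows))
    if (!identical(full_cols, cols)) next
    key <- paste(paste(rows, collapse = ","), paste(cols, collapse = ","), sep = "|")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- list(rows = rows, cols = cols)
    }
  }
  out
}

bicluster_key <- function(b) {
  paste(paste(sort(b$rows), collapse = ","),
        paste(sort(b$cols), collapse = ","), sep = "|")
}

# exhaustive-summation hypergeometric upper tail, independent of phyper
hyper_upper_tail <- function(k, N, K, n) {
  if (k <= 0) return(1)
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  if (!length(js)) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}
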