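# Independent naive oracle for the per-cell enrichment score: materializes
# P_in(i) and P_out(i) at every position of the walk by explicit summation.
# Deliberately O(N^2) and structurally unlike the package implementation.
naive_es <- function(expr, set_idx, alpha = 0.25, tie_method = "average") {
  n <- length(expr)
  r <- rank(expr, ties.method = if (tie_method == "average") "average" else "first")
  ord <- order(-r, seq_len(n))          # walk: decreasing rank, index tiebreak
  pos <- match(seq_len(n), ord)          # walk position of each gene
  in_set <- seq_len(n) %in% set_idx
  m <- sum(in_set)
  stopifnot(m > 0, m < n)
  denom_in <- sum(r[in_set]^alpha)
  es <- 0
  for (i in seq_len(n)) {
    p_in <- sum(r[in_set & pos <= i]^alpha) / denom_in
    p_out <- sum(!in_set & pos <= i) / (n - m)
    es <- es + (p_in - p_out)
  }
  es
}

# random sparse-ish count matrix with gene/cell names
random_counts <- function(n_genes, n_cells, max_count = 20) {
  m <- matrix(stats::rpois(n_genes * n_cells, lambda = 2), n_genes, n_cells)
  m[stats::runif(length(m)) < 0.3] <- 0
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("c%03d", seq_len(n_cells)))
  Matrix::Matrix(m, sparse = TRUE)
}

# small dense matrix written as CSV, returning the path
write_counts_csv <- function(m, path = tempfile(fileext = ".csv")) {
  df <- data.frame(gene = rownames(m), as.matrix(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# tiny two-major fixture used across annotator tests
two_major_fixture <- function(genes_per_set = 10) {
  make_fixture_hierarchy(n_major = 2, genes_per_set = genes_per_set)
}
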