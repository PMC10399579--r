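#' @importFrom methods as is
#' @importFrom utils read.csv write.csv
NULL

# open a text connection, transparently decompressing .gz
.open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

.read_lines <- function(path) {
  con <- .open_text(path)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Validate a genes x cells expression matrix
#'
#' Checks the input contract for count matrices: non-negative finite values,
#' unique cell barcodes, and row/column names present. Gene symbols may be
#' duplicated at read time; [collapse_duplicate_genes()] resolves them.
#'
#' @param m a matrix or sparse `Matrix` with gene symbols as rownames and
#'   cell barcodes as colnames.
#' @param require_unique_genes if `TRUE`, duplicated gene symbols are an
#'   error (the state after collapsing).
#' @return `m`, coerced to a sparse `dgCMatrix`, invisibly usable downstream.
#' @export
validate_expression_matrix <- function(m, require_unique_genes = TRUE) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must have gene symbols as rownames and cell barcodes as colnames")
  m <- as(as(m, "CsparseMatrix"), "generalMatrix")
  x <- m@x
  if (length(x) && (anyNA(x) || any(!is.finite(x))))
    stop("expression matrix contains non-finite values")
  if (length(x) && any(x < 0))
    stop("expression matrix contains negative values; counts must be >= 0")
  if (anyDuplicated(colnames(m))) {
    dup <- unique(colnames(m)[duplicated(colnames(m))])
    stop("duplicate cell barcodes: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (require_unique_genes && anyDuplicated(rownames(m))) {
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    stop("duplicate gene symbols: ", paste(utils::head(dup, 5), collapse = ", "),
         " (apply collapse_duplicate_genes first)")
  }
  m
}

#' Collapse duplicated gene symbols
#'
#' Gene symbol duplication is common after feature-id to symbol conversion.
#' The default `"sum"` policy conserves total counts per cell; `"max"` takes
#' the per-cell maximum across the duplicated rows; `"first"` keeps the first
#' occurrence. Row order of the output follows first occurrence.
#'
#' @param m genes x cells matrix (rownames = symbols).
#' @param policy one of `"sum"`, `"max"`, `"first"`.
#' @return matrix with unique rownames and unchanged columns.
#' @export
collapse_duplicate_genes <- function(m, policy = c("sum", "max", "first")) {
  policy <- match.arg(policy)
  genes <- rownames(m)
  if (is.null(genes)) stop("matrix has no rownames")
  if (!anyDuplicated(genes)) return(m)
  lev <- unique(genes)
  if (policy == "sum") {
    f <- factor(genes, levels = lev)
    ind <- Matrix::sparseMatrix(i = as.integer(f), j = seq_along(genes), x = 1,
                                dims = c(length(lev), length(genes)),
                                dimnames = list(lev, NULL))
    out <- ind %*% m
  } else if (policy == "first") {
    out <- m[!duplicated(genes), , drop = FALSE]
  } else { # max: densify only the duplicated groups (typically few)
    keep <- m[!duplicated(genes), , drop = FALSE]
    rownames(keep) <- lev
    dup_syms <- unique(genes[duplicated(genes)])
    for (g in dup_syms) {
      rows <- which(genes == g)
      block <- as.matrix(m[rows, , drop = FALSE])
      keep[g, ] <- apply(block, 2, max)
    }
    out <- keep
  }
  as(as(out, "CsparseMatrix"), "generalMatrix")
}

#' Read a 10x-style Matrix Market triplet
#'
#' Reads `matrix.mtx` (+ optional `.gz`), a features file (one gene per line;
#' if tab-separated with several columns, `feature_column` selects the symbol
#' column) and a barcodes file. Dimensions are checked against the MTX
#' header, duplicate barcodes rejected, and duplicated gene symbols collapsed.
#'
#' @param matrix_path path to the Matrix Market coordinate file.
#' @param features_path path to the features/genes file.
#' @param barcodes_path path to the barcodes file.
#' @param feature_column 1-based column of the features file holding the gene
#'   symbol. Default 2 when the file has two or more columns (10x dialect:
#'   id, symbol), otherwise 1.
#' @param collapse duplicate-symbol policy passed to
#'   [collapse_duplicate_genes()].
#' @return sparse genes x cells `dgCMatrix`.
#' @export
read_mtx_triplet <- function(matrix_path, features_path, barcodes_path,
                             feature_column = NULL,
                             collapse = c("sum", "max", "first")) {
  collapse <- match.arg(collapse)
  for (p in c(matrix_path, features_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- Matrix::readMM(matrix_path)
  feat_lines <- .read_lines(features_path)
  feat_lines <- feat_lines[nzchar(feat_lines)]
  fields <- strsplit(feat_lines, "\t", fixed = TRUE)
  ncol_feat <- if (length(fields)) length(fields[[1]]) else 1L
  if (is.null(feature_column)) feature_column <- if (ncol_feat >= 2) 2L else 1L
  if (feature_column > ncol_feat)
    stop("features file has ", ncol_feat, " columns; feature_column = ", feature_column)
  genes <- vapply(fields, `[[`, character(1), feature_column)
  barcodes <- .read_lines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (length(genes) != nrow(m))
    stop("matrix header declares ", nrow(m), " genes but features file has ",
         length(genes), " entries")
  if (length(barcodes) != ncol(m))
    stop("matrix header declares ", ncol(m), " cells but barcodes file has ",
         length(barcodes), " entries")
  dimnames(m) <- list(genes, barcodes)
  m <- validate_expression_matrix(m, require_unique_genes = FALSE)
  collapse_duplicate_genes(m, collapse)
}

#' Read a dense count table (CSV/TSV)
#'
#' @param path CSV or TSV file with a header row and label column.
#' @param genes_in `"rows"` (default) or `"columns"`; output is always
#'   genes x cells.
#' @param sep field separator; inferred from the extension when `NULL`
#'   (`.csv` comma, otherwise tab).
#' @param collapse duplicate-symbol policy.
#' @return sparse genes x cells `dgCMatrix`.
#' @export
read_dense_table <- function(path, genes_in = c("rows", "columns"), sep = NULL,
                             collapse = c("sum", "max", "first")) {
  genes_in <- match.arg(genes_in)
  collapse <- match.arg(collapse)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (nrow(df) == 0 || ncol(df) < 2) stop("empty or label-only table: ", path)
  labels <- df[[1]]
  body <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric value \"", body[bad[1, 1], bad[1, 2]], "\" at row \"",
         labels[bad[1, 1]], "\", column \"", colnames(body)[bad[1, 2]], "\"")
  }
  dimnames(num) <- list(labels, colnames(body))
  if (genes_in == "columns") num <- t(num)
  m <- as(as(Matrix::Matrix(num, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  m <- validate_expression_matrix(m, require_unique_genes = FALSE)
  collapse_duplicate_genes(m, collapse)
}

.annotation_columns <- c(
  "barcode", "prescreen_label",
  "layer1_label", "layer1_score", "layer1_margin",
  "layer2_label", "layer2_score", "layer2_margin",
  "layer3_label", "layer3_score", "layer3_margin")

#' Write per-cell annotation results to CSV
#'
#' One row per cell, in input barcode order: barcode, pre-screen label, then
#' label/score/margin for layers 1-3. Layers the cell never reached are
#' written as empty fields. The file round-trips losslessly through
#' [read_annotation_csv()].
#'
#' @param result an annotation result from [annotate_hierarchical()].
#' @param path output CSV path.
#' @export
write_annotation_csv <- function(result, path) {
  stopifnot(is.data.frame(result), nrow(result) > 0)
  missing_cols <- setdiff(.annotation_columns, names(result))
  for (col in missing_cols) result[[col]] <- NA
  utils::write.csv(result[, .annotation_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an annotation CSV written by [write_annotation_csv()]
#'
#' @param path CSV path.
#' @return data.frame with label columns as character (NA where empty) and
#'   score/margin columns numeric.
#' @export
read_annotation_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  for (col in grep("_(score|margin)$", names(df), value = TRUE))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  for (col in grep("label$|^prescreen", names(df), value = TRUE))
    df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA_character_
  class(df) <- c("annotation_result", "data.frame")
  df
}
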