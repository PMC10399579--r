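#' Parameters for single-sample enrichment scoring
#'
#' The per-cell statistic ranks all genes within a cell, walks the ranked
#' list from the highest-expressed gene down, and accumulates the difference
#' between the rank-weighted in-set ECDF and the uniform out-of-set ECDF.
#' `alpha` is the rank-weight exponent applied to the ranks of in-set genes
#' (0.25, the published default of the ssGSEA variant this mirrors; alpha = 0
#' weighs every in-set gene equally).
#'
#' @param alpha non-negative rank-weight exponent.
#' @param tie_method `"average"` (tied values share the mean rank) or
#'   `"ordinal"` (ties broken by ascending gene index, deterministic).
#' @param normalize_scores divide all scores by the global (max - min) of the
#'   score matrix. Cosmetic: a positive global scaling never changes which
#'   set attains the per-cell maximum.
#' @param min_genes_present minimum genes of a set that must be present in
#'   the matrix for the set to be scored; a warning is emitted below 3.
#' @return list of class `ssgsea_params`.
#' @export
ssgsea_params <- function(alpha = 0.25, tie_method = c("average", "ordinal"),
                          normalize_scores = FALSE, min_genes_present = 1) {
  tie_method <- match.arg(tie_method)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0,
            is.logical(normalize_scores), min_genes_present >= 1)
  if (!missing(min_genes_present) && min_genes_present < 3)
    message("min_genes_present < 3: scores from very small set overlaps are noisy")
  structure(list(alpha = alpha, tie_method = tie_method,
                 normalize_scores = normalize_scores,
                 min_genes_present = as.integer(min_genes_present)),
            class = "ssgsea_params")
}

#' Rank genes within one cell
#'
#' Largest expression receives rank N. `"average"` assigns tied values their
#' mean rank; `"ordinal"` breaks ties deterministically, the gene with the
#' lower index receiving the lower rank.
#'
#' @param x numeric vector of expression values for one cell (length >= 2).
#' @param tie_method `"average"` or `"ordinal"`.
#' @return numeric vector of ranks in 1..N.
#' @export
rank_genes <- function(x, tie_method = c("average", "ordinal")) {
  tie_method <- match.arg(tie_method)
  if (length(x) < 2) stop("need at least 2 genes to rank")
  rank(x, ties.method = if (tie_method == "average") "average" else "first")
}

# walk order: decreasing rank, ties by ascending index (deterministic)
.walk_order <- function(ranks) order(-ranks, seq_along(ranks))

#' Enrichment score of one gene set in one cell
#'
#' Walking gene positions i = 1..N in decreasing rank order, with S the set
#' genes, r the ranks and m = |S|:
#' \deqn{P_{in}(i) = \sum_{g \in S, pos(g) \le i} r_g^{\alpha} \Big/
#'       \sum_{g \in S} r_g^{\alpha}, \qquad
#'       P_{out}(i) = |\{g \notin S, pos(g) \le i\}| / (N - m)}
#' and the score is the running sum \eqn{ES = \sum_i (P_{in}(i) - P_{out}(i))}.
#'
#' @param ranks numeric rank vector over all N genes of the cell (from
#'   [rank_genes()]); may be named.
#' @param set_genes the gene set, as integer indices into `ranks`, a logical
#'   mask, or gene names (requires named `ranks`). Genes absent from the
#'   matrix must be intersected out beforehand ([score_matrix()] does this).
#' @param params an [ssgsea_params()] object.
#' @return the enrichment score (a single finite number).
#' @export
enrichment_score <- function(ranks, set_genes, params = ssgsea_params()) {
  n <- length(ranks)
  if (n < 2) stop("need at least 2 genes")
  if (is.character(set_genes)) {
    if (is.null(names(ranks))) stop("character set_genes require named ranks")
    idx <- match(set_genes, names(ranks))
    if (anyNA(idx)) stop("set gene(s) absent from ranks: ",
                         paste(set_genes[is.na(idx)], collapse = ", "))
  } else if (is.logical(set_genes)) {
    stopifnot(length(set_genes) == n)
    idx <- which(set_genes)
  } else {
    idx <- as.integer(set_genes)
  }
  m <- length(idx)
  if (m == 0) stop("empty gene set after intersection with the matrix")
  if (m >= n) stop("gene set covers every gene; out-of-set ECDF undefined")
  ord <- .walk_order(ranks)
  z <- logical(n)
  z[idx] <- TRUE
  z_ord <- z[ord]
  w <- ranks[ord]^params$alpha * z_ord
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!z_ord) / (n - m)
  sum(p_in - p_out)
}

#' Score every cell against every gene set
#'
#' Cells are ranked and scored independently of one another, so the result
#' for a cell never depends on which other cells are in the matrix, and any
#' strictly increasing per-cell transformation of the expression values
#' (library-size scaling, log1p, ...) leaves all scores unchanged.
#'
#' @param m genes x cells expression matrix (rownames = genes).
#' @param sets named list of gene sets (character vectors of gene symbols).
#' @param params an [ssgsea_params()] object.
#' @return cells x sets numeric matrix of enrichment scores, with attribute
#'   `"dropped_sets"` naming sets excluded for insufficient overlap with the
#'   matrix genes.
#' @export
score_matrix <- function(m, sets, params = ssgsea_params()) {
  stopifnot(is.list(sets), !is.null(names(sets)), nrow(m) >= 2)
  genes <- rownames(m)
  if (is.null(genes)) stop("matrix must have gene rownames")
  n <- nrow(m)
  idx_sets <- lapply(sets, function(g) {
    i <- match(g, genes)
    miss <- sum(is.na(i))
    if (miss > 0 && miss < length(g))
      warning("gene set genes absent from the matrix were ignored (",
              miss, "/", length(g), ")", call. = FALSE)
    i[!is.na(i)]
  })
  usable <- vapply(idx_sets, function(i)
    length(i) >= params$min_genes_present && length(i) < n, logical(1))
  dropped <- names(sets)[!usable]
  if (length(dropped))
    warning("gene set(s) dropped (overlap below min_genes_present or full ",
            "coverage): ", paste(dropped, collapse = ", "), call. = FALSE)
  idx_sets <- idx_sets[usable]
  if (!length(idx_sets)) stop("no scorable gene set")
  dm <- as(as(m, "CsparseMatrix"), "generalMatrix")
  ncell <- ncol(dm)
  scores <- matrix(NA_real_, nrow = ncell, ncol = length(idx_sets),
                   dimnames = list(colnames(dm), names(idx_sets)))
  sizes <- lengths(idx_sets)
  for (ci in seq_len(ncell)) {
    x <- dm[, ci]
    r <- rank(x, ties.method =
                if (params$tie_method == "average") "average" else "first")
    ord <- .walk_order(r)
    ra <- r^params$alpha
    for (si in seq_along(idx_sets)) {
      z <- logical(n)
      z[idx_sets[[si]]] <- TRUE
      z_ord <- z[ord]
      w <- ra[ord] * z_ord
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!z_ord) / (n - sizes[si])
      scores[ci, si] <- sum(p_in - p_out)
    }
  }
  if (isTRUE(params$normalize_scores)) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  attr(scores, "dropped_sets") <- dropped
  scores
}

#' Write an enrichment score table (cells x sets) to CSV
#' @param scores matrix from [score_matrix()].
#' @param path output CSV.
#' @export
write_scores_csv <- function(scores, path) {
  df <- data.frame(barcode = rownames(scores), scores, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
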