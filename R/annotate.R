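#' Pre-screen cells as immune vs non-immune
#'
#' Each cell is scored against the immune and non-immune signature pair and
#' assigned the label with the larger enrichment score. Cells with no counts
#' at all carry no ranking information and are labelled `"unassigned"`.
#'
#' @param m genes x cells matrix.
#' @param hierarchy a `signature_hierarchy` with a pre-screen pair.
#' @param params an [ssgsea_params()].
#' @return character vector of `"immune"` / `"non_immune"` / `"unassigned"`,
#'   named by barcode.
#' @export
prescreen_immune <- function(m, hierarchy, params = ssgsea_params()) {
  if (is.null(hierarchy$prescreen))
    stop("hierarchy has no pre-screen gene set pair")
  pre_sets <- hierarchy$sets[hierarchy$prescreen]
  names(pre_sets) <- names(hierarchy$prescreen)  # immune / non_immune
  nonzero <- Matrix::colSums(m) > 0
  out <- stats::setNames(rep("unassigned", ncol(m)), colnames(m))
  if (!any(nonzero)) return(out)
  sc <- tryCatch(
    score_matrix(m[, nonzero, drop = FALSE], pre_sets, params),
    error = function(e) stop("pre-screen gene sets unscorable on this matrix: ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(sc) < 2)
    stop("pre-screen gene sets unscorable on this matrix (",
         paste(attr(sc, "dropped_sets"), collapse = ", "), " dropped)")
  out[rownames(sc)] <- colnames(sc)[max.col(sc, ties.method = "first")]
  out
}

#' Score one layer of sibling gene sets for a subset of cells
#'
#' The heart of hierarchical annotation: only siblings compete. Each listed
#' cell is scored against the sibling sets and labelled by the largest
#' enrichment score; ties go to the first set in declared order with margin
#' recorded as 0.
#'
#' @param m genes x cells matrix.
#' @param sibling_sets named list of >= 2 gene sets competing at this
#'   decision.
#' @param cells barcodes to score (default: all columns of `m`).
#' @param params an [ssgsea_params()].
#' @return data.frame with columns `barcode`, `label`, `score`, `margin`
#'   (winning score minus runner-up), or `NULL` if fewer than two sets were
#'   scorable (the layer is skipped with a warning).
#' @export
annotate_layer <- function(m, sibling_sets, cells = colnames(m),
                           params = ssgsea_params()) {
  stopifnot(length(sibling_sets) >= 2, length(cells) >= 1)
  missing_cells <- setdiff(cells, colnames(m))
  if (length(missing_cells))
    stop("unknown barcode(s): ", paste(utils::head(missing_cells, 5), collapse = ", "))
  sc <- score_matrix(m[, cells, drop = FALSE], sibling_sets, params)
  if (ncol(sc) < 2) {
    warning("fewer than two scorable sibling sets; layer skipped for ",
            length(cells), " cells", call. = FALSE)
    return(NULL)
  }
  win <- max.col(sc, ties.method = "first")
  best <- sc[cbind(seq_len(nrow(sc)), win)]
  second <- vapply(seq_len(nrow(sc)), function(i) max(sc[i, -win[i]]), numeric(1))
  data.frame(barcode = rownames(sc), label = colnames(sc)[win],
             score = best, margin = best - second, row.names = NULL)
}

#' Hierarchically annotate every cell of a count matrix
#'
#' Optionally pre-screens immune vs non-immune cells, labels immune cells
#' among the major types (hierarchy roots), then re-scores the cells of each
#' labelled type against that type's subtypes only, layer by layer down to
#' `max_layer`. Leaf types simply stop deepening. All-zero cells are
#' `"unassigned"` and receive no labels.
#'
#' @param m genes x cells count matrix (raw counts or any per-cell monotone
#'   transform thereof; the ranks, and hence the labels, are identical).
#' @param hierarchy a `signature_hierarchy`.
#' @param params an [ssgsea_params()].
#' @param prescreen run the immune / non-immune pre-screen first (requires
#'   the hierarchy to carry the pair). With `FALSE` every non-empty cell is
#'   treated as immune, matching datasets from which non-immune cells were
#'   removed beforehand.
#' @param max_layer deepest layer to annotate (1-3).
#' @param min_margin optional filter: a decision whose winning margin is
#'   below this value is voided (label NA at that and deeper layers).
#'   Default 0 disables the filter.
#' @return data.frame of class `annotation_result`, one row per cell in
#'   input order: `barcode`, `prescreen_label`, and
#'   `layer<k>_label` / `_score` / `_margin` for k = 1..3.
#' @export
annotate_hierarchical <- function(m, hierarchy, params = ssgsea_params(),
                                  prescreen = TRUE, max_layer = 3,
                                  min_margin = 0) {
  stopifnot(inherits(hierarchy, "signature_hierarchy"),
            max_layer %in% 1:3, ncol(m) >= 1, min_margin >= 0)
  m <- validate_expression_matrix(m)
  barcodes <- colnames(m)
  res <- data.frame(barcode = barcodes,
                    prescreen_label = rep(NA_character_, length(barcodes)),
                    row.names = NULL)
  for (k in 1:3) {
    res[[paste0("layer", k, "_label")]] <- NA_character_
    res[[paste0("layer", k, "_score")]] <- NA_real_
    res[[paste0("layer", k, "_margin")]] <- NA_real_
  }
  nonzero <- Matrix::colSums(m) > 0
  if (prescreen) {
    pre <- prescreen_immune(m, hierarchy, params)
    res$prescreen_label <- unname(pre[barcodes])
  } else {
    res$prescreen_label <- ifelse(nonzero, "immune", "unassigned")
  }
  immune_cells <- barcodes[res$prescreen_label == "immune"]
  if (!length(immune_cells)) {
    warning("no immune cells after pre-screen; nothing to annotate")
    class(res) <- c("annotation_result", "data.frame")
    return(res)
  }
  # layer 1: majors compete among the hierarchy roots
  root_sets <- hierarchy$sets[hierarchy$roots]
  frontier <- list()  # label -> barcodes awaiting deepening
  if (length(root_sets) >= 2) {
    lay <- annotate_layer(m, root_sets, immune_cells, params)
  } else {
    lay <- data.frame(barcode = immune_cells, label = names(root_sets),
                      score = NA_real_, margin = NA_real_)
  }
  if (!is.null(lay)) {
    i <- match(lay$barcode, res$barcode)
    keep <- lay$margin >= min_margin | is.na(lay$margin)
    res$layer1_label[i[keep]] <- lay$label[keep]
    res$layer1_score[i[keep]] <- lay$score[keep]
    res$layer1_margin[i[keep]] <- lay$margin[keep]
    frontier <- split(lay$barcode[keep], lay$label[keep])
  }
  k <- 2L
  while (k <= max_layer && length(frontier)) {
    next_frontier <- list()
    for (parent in names(frontier)) {
      kids <- hierarchy_children(hierarchy, parent)
      cells <- frontier[[parent]]
      if (length(kids) < 1 || !length(cells)) next
      if (length(kids) == 1) {  # degenerate: single child inherits the cells
        lay <- data.frame(barcode = cells, label = kids,
                          score = NA_real_, margin = NA_real_)
      } else {
        lay <- annotate_layer(m, hierarchy$sets[kids], cells, params)
      }
      if (is.null(lay)) next
      i <- match(lay$barcode, res$barcode)
      keep <- lay$margin >= min_margin | is.na(lay$margin)
      res[[paste0("layer", k, "_label")]][i[keep]] <- lay$label[keep]
      res[[paste0("layer", k, "_score")]][i[keep]] <- lay$score[keep]
      res[[paste0("layer", k, "_margin")]][i[keep]] <- lay$margin[keep]
      next_frontier <- c(next_frontier, split(lay$barcode[keep], lay$label[keep]))
    }
    frontier <- next_frontier
    k <- k + 1L
  }
  class(res) <- c("annotation_result", "data.frame")
  res
}

#' Check parent-child consistency of an annotation result
#'
#' Verifies that every cell with a layer-k label has a layer-(k-1) label of
#' which it is a child in the hierarchy, and that non-immune or unassigned
#' cells carry no layer labels.
#'
#' @param result an `annotation_result`.
#' @param hierarchy the `signature_hierarchy` used to produce it.
#' @return number of violating cells (0 when fully consistent), invisibly;
#'   violations also raise a warning.
#' @export
check_hierarchical_consistency <- function(result, hierarchy) {
  bad <- logical(nrow(result))
  not_immune <- is.na(result$prescreen_label) | result$prescreen_label != "immune"
  bad <- bad | (not_immune & (!is.na(result$layer1_label) |
                              !is.na(result$layer2_label) |
                              !is.na(result$layer3_label)))
  for (k in 2:3) {
    lab <- result[[paste0("layer", k, "_label")]]
    par <- result[[paste0("layer", k - 1, "_label")]]
    has <- !is.na(lab)
    ok <- has & !is.na(par) &
      mapply(function(l, p) l %in% hierarchy_children(hierarchy, p),
             lab, ifelse(is.na(par), "", par))
    bad <- bad | (has & !ok)
  }
  n_bad <- sum(bad)
  if (n_bad > 0)
    warning(n_bad, " cell(s) violate hierarchical label consistency")
  invisible(n_bad)
}

#' Per-type cell counts at one layer
#' @param result an `annotation_result`.
#' @param layer layer index 1-3.
#' @return named integer vector of counts per label (NA cells excluded).
#' @export
type_counts <- function(result, layer = 1) {
  lab <- result[[paste0("layer", layer, "_label")]]
  table(lab[!is.na(lab)])
}

#' Types eligible for per-type graphical summaries
#'
#' Deeper-layer summaries are emitted only for types carrying at least
#' `min_cells` cells (default 50); rarer types remain in the annotation CSV
#' but get no per-type table.
#'
#' @param result an `annotation_result`.
#' @param layer layer index 1-3.
#' @param min_cells minimum cells for a type to be summarized.
#' @return character vector of type labels.
#' @export
types_for_plotting <- function(result, layer = 2, min_cells = 50) {
  cnt <- type_counts(result, layer)
  names(cnt)[cnt >= min_cells]
}
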