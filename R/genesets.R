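#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then genes. Descriptions are discarded; duplicated genes within a line are
#' de-duplicated keeping first occurrence.
#'
#' @param path GMT file (optionally gzipped).
#' @return named list of character vectors (one per set).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("gene sets file not found: ", path)
  lines <- .read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("gene sets file is empty: ", path)
  sets <- vector("list", length(lines))
  names_out <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT format error at line ", i,
           ": expected name, description and at least one gene")
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT format error at line ", i, ": no genes")
    names_out[i] <- fields[1]
    sets[[i]] <- unique(genes)
  }
  if (anyDuplicated(names_out)) {
    dup <- unique(names_out[duplicated(names_out)])
    stop("duplicate gene set names: ", paste(dup, collapse = ", "))
  }
  stats::setNames(sets, names_out)
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field written for every set.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build a validated signature hierarchy
#'
#' The annotation taxonomy is a forest whose roots are the major immune cell
#' types; children of a node are the subtypes that compete with each other
#' (and only with each other) when cells of the parent type are re-scored.
#' A separate immune / non-immune pre-screen pair sits outside the tree.
#'
#' @param sets named list of gene sets (from [read_gmt()]); must contain one
#'   set per tree label and per pre-screen label.
#' @param tree_spec named list mapping every layer-1 label and every internal
#'   node to its character vector of child labels (leaves at layer 1 map to
#'   an empty vector). Labels that never appear as children are the roots.
#' @param prescreen_labels length-2 character vector `c(immune, non_immune)`
#'   naming the pre-screen sets, or `NULL` to omit the pre-screen.
#' @return object of class `signature_hierarchy`.
#' @export
build_hierarchy <- function(sets, tree_spec, prescreen_labels = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (!is.list(tree_spec) || is.null(names(tree_spec)))
    stop("tree_spec must be a named list mapping parent label -> child labels")
  children <- lapply(tree_spec, function(x) as.character(unlist(x)))
  all_children <- unlist(children, use.names = FALSE)
  if (anyDuplicated(all_children))
    stop("label appears under more than one parent: ",
         paste(unique(all_children[duplicated(all_children)]), collapse = ", "))
  roots <- setdiff(names(children), all_children)
  if (!length(roots)) stop("tree_spec has no roots (cycle?)")
  nodes <- unique(c(names(children), all_children))
  # depth by walk from the roots; anything unreachable indicates a cycle
  depth <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  frontier <- roots
  d <- 1L
  while (length(frontier)) {
    if (d > length(nodes)) stop("cycle detected in tree_spec")
    depth[frontier] <- d
    frontier <- unlist(children[frontier], use.names = FALSE)
    frontier <- frontier[!is.na(frontier)]
    d <- d + 1L
  }
  if (anyNA(depth)) stop("cycle detected in tree_spec: unreachable labels ",
                         paste(nodes[is.na(depth)], collapse = ", "))
  needed <- nodes
  if (!is.null(prescreen_labels)) {
    if (length(prescreen_labels) != 2)
      stop("prescreen_labels must be c(immune_set, non_immune_set)")
    prescreen_labels <- as.character(prescreen_labels)
    needed <- c(needed, prescreen_labels)
  }
  missing <- setdiff(needed, names(sets))
  if (length(missing))
    stop("no gene set for label(s): ", paste(missing, collapse = ", "))
  for (lab in needed) {
    g <- sets[[lab]]
    if (!length(g) || anyDuplicated(g))
      stop("gene set '", lab, "' must be non-empty with distinct genes")
  }
  parent <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  for (p in names(children)) parent[children[[p]]] <- p
  structure(list(
    sets = sets[needed],
    children = children,
    parent = parent,
    roots = roots,
    depth = depth,
    prescreen = if (is.null(prescreen_labels)) NULL else
      stats::setNames(prescreen_labels, c("immune", "non_immune"))
  ), class = "signature_hierarchy")
}

#' @exportS3Method base::print
print.signature_hierarchy <- function(x, ...) {
  counts <- hierarchy_layer_counts(x)
  cat("signature_hierarchy:",
      paste(sprintf("layer %d: %d", seq_along(counts), counts), collapse = ", "),
      "\n")
  if (!is.null(x$prescreen))
    cat("  pre-screen sets:", paste(x$prescreen, collapse = " / "), "\n")
  cat("  roots:", paste(x$roots, collapse = ", "), "\n")
  invisible(x)
}

#' Node counts per layer of a hierarchy
#' @param hierarchy a `signature_hierarchy`.
#' @return integer vector, one entry per layer (tree depth).
#' @export
hierarchy_layer_counts <- function(hierarchy) {
  tabulate(hierarchy$depth, nbins = max(hierarchy$depth))
}

#' Children of a node (empty character vector for leaves)
#' @param hierarchy a `signature_hierarchy`.
#' @param label node label.
#' @export
hierarchy_children <- function(hierarchy, label) {
  kids <- hierarchy$children[[label]]
  if (is.null(kids)) character(0) else kids
}

#' Labels at a given layer
#' @param hierarchy a `signature_hierarchy`.
#' @param layer layer index (1 = major types).
#' @export
hierarchy_layer_labels <- function(hierarchy, layer) {
  names(hierarchy$depth)[hierarchy$depth == layer]
}

#' Read a hierarchy tree specification from JSON
#'
#' Expected shape:
#' \preformatted{
#' {"children": {"T": ["CD4_T", "CD8_T"], "mast": [], ...},
#'  "prescreen": {"immune": "immune", "non_immune": "non_immune"}}
#' }
#'
#' @param path JSON file.
#' @return list with `$children` (named list) and `$prescreen` (character
#'   vector or NULL), suitable for [build_hierarchy()].
#' @export
read_hierarchy_spec <- function(path) {
  if (!file.exists(path)) stop("hierarchy spec not found: ", path)
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(spec$children)) stop("hierarchy spec lacks a 'children' mapping")
  children <- lapply(spec$children, function(x) as.character(unlist(x)))
  prescreen <- NULL
  if (!is.null(spec$prescreen))
    prescreen <- c(spec$prescreen$immune, spec$prescreen$non_immune)
  list(children = children, prescreen = prescreen)
}

#' Load the canonical three-layer immune hierarchy
#'
#' Loads the shipped taxonomy — 9 major types (T, B, monocyte, macrophage,
#' DC, NK, ILC, mast, neutrophil), 16 second-layer subtypes, and 13 T-cell
#' subtypes under CD4 T and CD8 T — together with the illustrative example
#' signature GMT, or a user-supplied GMT covering the same labels.
#'
#' @param gmt_path optional path to a GMT providing one set per taxonomy
#'   label plus the pre-screen pair; defaults to the shipped example file.
#' @param prescreen include the immune / non-immune pre-screen pair.
#' @return a `signature_hierarchy`.
#' @export
load_canonical_hierarchy <- function(gmt_path = NULL, prescreen = TRUE) {
  spec_path <- system.file("extdata", "immune_hierarchy.json",
                           package = "scImmuRank", mustWork = TRUE)
  if (is.null(gmt_path))
    gmt_path <- system.file("extdata", "example_signatures.gmt",
                            package = "scImmuRank", mustWork = TRUE)
  spec <- read_hierarchy_spec(spec_path)
  sets <- read_gmt(gmt_path)
  build_hierarchy(sets, spec$children,
                  if (prescreen) spec$prescreen else NULL)
}

#' Screen marker genes by average expression across reference datasets
#'
#' Lowly expressed markers carry little signal in sparse scRNA-seq data and
#' are removed before scoring. Each gene's screening statistic is the
#' unweighted mean over reference matrices of its within-matrix mean
#' expression across cells (0 for matrices where the gene is absent); genes
#' with statistic below `min_mean_expression` are dropped. Sets left with
#' fewer than `min_set_size` genes are excluded with a warning.
#'
#' @param sets named list of gene sets.
#' @param reference_matrices list of genes x cells matrices.
#' @param min_mean_expression threshold on the cross-dataset mean (default 0
#'   keeps everything; the report makes any chosen threshold auditable).
#' @param min_set_size minimum genes a set must retain to survive.
#' @return list with `$sets` (screened), `$report` (data.frame: set, gene,
#'   statistic, removed) and `$excluded_sets` (character).
#' @export
screen_markers <- function(sets, reference_matrices, min_mean_expression = 0,
                           min_set_size = 1) {
  stopifnot(length(reference_matrices) >= 1, min_set_size >= 1,
            min_mean_expression >= 0)
  if (!is.list(reference_matrices) || is.null(dim(reference_matrices[[1]])))
    stopifnot(is.list(reference_matrices))
  all_genes <- unique(unlist(sets, use.names = FALSE))
  per_matrix <- vapply(reference_matrices, function(m) {
    mu <- stats::setNames(rep(0, length(all_genes)), all_genes)
    present <- intersect(all_genes, rownames(m))
    if (length(present))
      mu[present] <- Matrix::rowMeans(m[present, , drop = FALSE])
    mu
  }, numeric(length(all_genes)))
  stat <- rowMeans(matrix(per_matrix, nrow = length(all_genes),
                          dimnames = list(all_genes, NULL)))
  report <- do.call(rbind, lapply(names(sets), function(s) {
    g <- sets[[s]]
    data.frame(set = s, gene = g, statistic = unname(stat[g]),
               removed = unname(stat[g]) < min_mean_expression)
  }))
  screened <- lapply(sets, function(g) g[stat[g] >= min_mean_expression])
  keep_sizes <- lengths(screened)
  excluded <- names(screened)[keep_sizes < min_set_size]
  if (length(excluded))
    warning("gene set(s) excluded after screening (too few genes left): ",
            paste(excluded, collapse = ", "))
  list(sets = screened[keep_sizes >= min_set_size],
       report = report, excluded_sets = excluded)
}

#' Write a marker screening report to CSV
#' @param screen result of [screen_markers()].
#' @param path output CSV.
#' @export
write_screening_report <- function(screen, path) {
  utils::write.csv(screen$report, path, row.names = FALSE)
  invisible(path)
}
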