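#' Configuration for the synthetic scRNA-seq generator
#'
#' Counts are drawn from a negative binomial (the standard overdispersed
#' model for scRNA-seq counts), gene by gene and cell by cell. A cell of a
#' given leaf type overexpresses the markers of its own set and of all its
#' ancestors' sets (a CD8-naive cell is also a CD8 T cell, a T cell, and an
#' immune cell), by `marker_fold_change` over `baseline_mean`.
#'
#' @param hierarchy a `signature_hierarchy` whose leaves define the cell
#'   types to simulate.
#' @param cells_per_leaf cells drawn per leaf type.
#' @param n_background_genes genes outside every signature set.
#' @param baseline_mean negative-binomial mean of non-marker genes.
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed; variance = mu + mu^2 / dispersion).
#' @param marker_fold_change mean multiplier (>= 1) for a cell's own and
#'   ancestral marker genes; 1 produces pure noise with unrecoverable labels.
#' @param dropout_extra probability in \[0, 1) of independently forcing any
#'   count to zero, emulating extra technical dropout.
#' @param n_nonimmune cells of the non-immune compartment (overexpressing
#'   the non-immune pre-screen set); requires a pre-screen pair when > 0.
#' @param seed RNG seed; the draw is fully reproducible under it.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(hierarchy, cells_per_leaf = 200,
                              n_background_genes = 200, baseline_mean = 1,
                              dispersion = 2, marker_fold_change = 8,
                              dropout_extra = 0, n_nonimmune = 0, seed = 1) {
  stopifnot(inherits(hierarchy, "signature_hierarchy"),
            cells_per_leaf >= 1, n_background_genes >= 0, baseline_mean > 0,
            dispersion > 0, marker_fold_change >= 1,
            dropout_extra >= 0, dropout_extra < 1, n_nonimmune >= 0)
  if (n_nonimmune > 0 && is.null(hierarchy$prescreen))
    stop("n_nonimmune > 0 requires a hierarchy with a pre-screen pair")
  structure(list(hierarchy = hierarchy,
                 cells_per_leaf = as.integer(cells_per_leaf),
                 n_background_genes = as.integer(n_background_genes),
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 marker_fold_change = marker_fold_change,
                 dropout_extra = dropout_extra,
                 n_nonimmune = as.integer(n_nonimmune),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.hierarchy_leaves <- function(h) {
  nodes <- names(h$depth)
  nodes[vapply(nodes, function(x) length(hierarchy_children(h, x)) == 0,
               logical(1))]
}

.ancestors <- function(h, label) {
  out <- character(0)
  p <- h$parent[[label]]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- h$parent[[p]]
  }
  out
}

.path_to_root <- function(h, leaf) rev(c(leaf, .ancestors(h, leaf)))

#' Simulate a hierarchically labelled count matrix
#'
#' @param cfg a [simulation_config()].
#' @return list of class `simulated_dataset`: `$matrix` (sparse genes x
#'   cells counts), `$truth` (data.frame: barcode, prescreen, layer1-3) and
#'   `$config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  h <- cfg$hierarchy
  leaves <- .hierarchy_leaves(h)
  sib_overlap <- vapply(leaves, function(l) {
    p <- h$parent[[l]]
    sibs <- if (is.na(p)) setdiff(h$roots, l) else
      setdiff(hierarchy_children(h, p), l)
    any(vapply(sibs, function(s) all(h$sets[[l]] %in% h$sets[[s]]),
               logical(1)))
  }, logical(1))
  if (any(sib_overlap))
    warning("marker set(s) fully contained in a sibling's set; recovery not ",
            "guaranteed for: ", paste(leaves[sib_overlap], collapse = ", "))
  marker_genes <- unique(unlist(h$sets, use.names = FALSE))
  bg <- if (cfg$n_background_genes > 0)
    sprintf("BG%05d", seq_len(cfg$n_background_genes)) else character(0)
  genes <- c(marker_genes, bg)
  n_genes <- length(genes)
  immune_set <- if (!is.null(h$prescreen)) h$sets[[h$prescreen[["immune"]]]]
                else character(0)
  groups <- lapply(leaves, function(leaf) {
    list(label = leaf,
         up = unique(c(unlist(h$sets[c(leaf, .ancestors(h, leaf))],
                              use.names = FALSE), immune_set)),
         path = .path_to_root(h, leaf), prescreen = "immune")
  })
  if (cfg$n_nonimmune > 0) {
    groups <- c(groups, list(list(
      label = NA_character_, up = h$sets[[h$prescreen[["non_immune"]]]],
      path = character(0), prescreen = "non_immune")))
  }
  set.seed(cfg$seed)
  blocks <- vector("list", length(groups))
  truth_rows <- vector("list", length(groups))
  cell_no <- 0L
  for (gi in seq_along(groups)) {
    grp <- groups[[gi]]
    n_cells <- if (is.na(grp$label)) cfg$n_nonimmune else cfg$cells_per_leaf
    mu <- rep(cfg$baseline_mean, n_genes)
    mu[genes %in% grp$up] <- cfg$baseline_mean * cfg$marker_fold_change
    counts <- matrix(stats::rnbinom(n_genes * n_cells, size = cfg$dispersion,
                                    mu = rep(mu, times = n_cells)),
                     nrow = n_genes, ncol = n_cells)
    if (cfg$dropout_extra > 0) {
      drop <- matrix(stats::runif(n_genes * n_cells) < cfg$dropout_extra,
                     nrow = n_genes)
      counts[drop] <- 0L
    }
    barcodes <- sprintf("cell_%06d", cell_no + seq_len(n_cells))
    cell_no <- cell_no + n_cells
    colnames(counts) <- barcodes
    blocks[[gi]] <- counts
    path <- grp$path
    truth_rows[[gi]] <- data.frame(
      barcode = barcodes,
      prescreen = grp$prescreen,
      layer1 = if (length(path) >= 1) path[1] else NA_character_,
      layer2 = if (length(path) >= 2) path[2] else NA_character_,
      layer3 = if (length(path) >= 3) path[3] else NA_character_,
      row.names = NULL)
  }
  mat <- do.call(cbind, blocks)
  rownames(mat) <- genes
  sm <- as(as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix"),
           "generalMatrix")
  structure(list(matrix = sm, truth = do.call(rbind, truth_rows),
                 config = cfg),
            class = "simulated_dataset")
}

#' Build a synthetic signature hierarchy fixture
#'
#' Generates synthetic gene symbols so annotation, screening, and
#' evaluation can be exercised without any curated marker list. With
#' `disjoint = TRUE` every set gets its own genes; otherwise consecutive
#' sets share `round(overlap_fraction * genes_per_set)` genes.
#'
#' @param n_major number of major (layer-1) types, >= 2.
#' @param n_children named integer vector: children per major type
#'   (majors absent from it are leaves).
#' @param n_grandchildren named integer vector: children per layer-2 label.
#' @param genes_per_set synthetic genes per signature set, >= 1.
#' @param disjoint make all sets disjoint.
#' @param overlap_fraction fraction of shared genes between consecutive
#'   sets when `disjoint = FALSE`.
#' @param prescreen include a synthetic immune / non-immune pair.
#' @return a `signature_hierarchy`.
#' @export
make_fixture_hierarchy <- function(n_major = 2, n_children = integer(0),
                                   n_grandchildren = integer(0),
                                   genes_per_set = 10, disjoint = TRUE,
                                   overlap_fraction = 0.5, prescreen = TRUE) {
  stopifnot(n_major >= 2, genes_per_set >= 1)
  majors <- sprintf("M%d", seq_len(n_major))
  children <- stats::setNames(vector("list", n_major), majors)
  for (m in majors) {
    k <- if (m %in% names(n_children)) n_children[[m]] else 0L
    children[[m]] <- if (k > 0) sprintf("%s.%d", m, seq_len(k)) else character(0)
  }
  for (cl in unlist(children, use.names = FALSE)) {
    k <- if (cl %in% names(n_grandchildren)) n_grandchildren[[cl]] else 0L
    if (k > 0) children[[cl]] <- sprintf("%s.%d", cl, seq_len(k))
  }
  labels <- unique(c(names(children), unlist(children, use.names = FALSE)))
  if (prescreen) labels <- c(labels, "immune", "non_immune")
  sets <- .synthetic_sets(labels, genes_per_set, disjoint, overlap_fraction)
  build_hierarchy(sets, children,
                  if (prescreen) c("immune", "non_immune") else NULL)
}

#' Canonical-shape fixture hierarchy with synthetic genes
#'
#' Same labels and tree shape as the shipped canonical immune taxonomy
#' (9 major types, 16 second-layer subtypes, 13 T-cell subtypes, plus the
#' pre-screen pair), but with synthetic, by default disjoint, gene sets —
#' the standard fixture for recovery experiments.
#'
#' @inheritParams make_fixture_hierarchy
#' @return a `signature_hierarchy`.
#' @export
make_canonical_fixture <- function(genes_per_set = 10, disjoint = TRUE,
                                   overlap_fraction = 0.5) {
  spec_path <- system.file("extdata", "immune_hierarchy.json",
                           package = "scImmuRank", mustWork = TRUE)
  spec <- read_hierarchy_spec(spec_path)
  labels <- unique(c(names(spec$children),
                     unlist(spec$children, use.names = FALSE), spec$prescreen))
  sets <- .synthetic_sets(labels, genes_per_set, disjoint, overlap_fraction)
  build_hierarchy(sets, spec$children, spec$prescreen)
}

.synthetic_sets <- function(labels, genes_per_set, disjoint, overlap_fraction) {
  n_overlap <- if (disjoint) 0L else
    max(0L, min(genes_per_set - 1L, round(overlap_fraction * genes_per_set)))
  step <- genes_per_set - n_overlap
  sets <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    start <- (i - 1L) * step
    sets[[i]] <- sprintf("G%05d", start + seq_len(genes_per_set))
  }
  stats::setNames(sets, labels)
}

#' Write a simulated dataset as CLI-ready files
#'
#' Emits `matrix.mtx`, `features.tsv`, `barcodes.tsv`, `signatures.gmt`,
#' `hierarchy.json` and `truth.csv` into `dir`, so the full
#' simulate-annotate-evaluate pipeline closes over plain files.
#'
#' @param sim a `simulated_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- sim$config$hierarchy
  Matrix::writeMM(sim$matrix, file.path(dir, "matrix.mtx"))
  writeLines(rownames(sim$matrix), file.path(dir, "features.tsv"))
  writeLines(colnames(sim$matrix), file.path(dir, "barcodes.tsv"))
  write_gmt(h$sets, file.path(dir, "signatures.gmt"), description = "synthetic")
  spec <- list(children = h$children)
  if (!is.null(h$prescreen))
    spec$prescreen <- list(immune = unname(h$prescreen[["immune"]]),
                           non_immune = unname(h$prescreen[["non_immune"]]))
  jsonlite::write_json(spec, file.path(dir, "hierarchy.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, na = "")
  invisible(dir)
}
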