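make_signal_matrix <- function(sets, cell_spec, n_background = 20, value = 50) {
  # cell_spec: named list barcode -> character vector of sets to "express"
  genes <- unique(c(unlist(sets), sprintf("bg%03d", seq_len(n_background))))
  m <- matrix(0, length(genes), length(cell_spec),
              dimnames = list(genes, names(cell_spec)))
  for (bc in names(cell_spec))
    for (s in cell_spec[[bc]]) m[sets[[s]], bc] <- value
  Matrix::Matrix(m, sparse = TRUE)
}

test_that("pre-screen separates dominant immune and non-immune signals, zeros unassigned", {
  h <- two_major_fixture()
  sets <- h$sets
  m <- make_signal_matrix(sets, list(ic = "immune", nc = "non_immune",
                                     zc = character(0)))
  m[, "zc"] <- 0
  pre <- prescreen_immune(m, h)
  expect_equal(unname(pre[c("ic", "nc", "zc")]),
               c("immune", "non_immune", "unassigned"))
})

test_that("pre-screen is a hard requirement unless explicitly disabled", {
  h <- two_major_fixture()
  m <- make_signal_matrix(h$sets, list(c1 = "M1"))
  h_bad <- h
  h_bad$sets[["immune"]] <- c("absent1", "absent2")
  expect_error(suppressWarnings(prescreen_immune(m, h_bad)), "unscorable")
  # the explicit opt-out path still annotates
  res <- annotate_hierarchical(m, h, prescreen = FALSE)
  expect_equal(res$prescreen_label, "immune")
  expect_equal(res$layer1_label, "M1")
})

test_that("sibling competition labels by dominant signal with score and margin", {
  h <- make_fixture_hierarchy(n_major = 2, n_children = c(M1 = 2))
  m <- make_signal_matrix(h$sets, list(a = c("M1", "M1.1"), b = c("M1", "M1.2")))
  lay <- annotate_layer(m, h$sets[c("M1.1", "M1.2")], c("a", "b"))
  expect_equal(lay$label, c("M1.1", "M1.2"))
  expect_true(all(lay$margin > 0))
  expect_true(all(lay$score >= lay$score - lay$margin))
})

test_that("exact ties resolve to the first declared set with margin 0", {
  # positions {1,4} and {2,3} of the walk give identical scores at alpha = 0
  sets <- list(s1 = c("g1", "g4"), s2 = c("g2", "g3"))
  m <- Matrix::Matrix(matrix(c(10, 5, 2, 1), 4, 1,
                             dimnames = list(c("g1", "g2", "g3", "g4"), "c1")),
                      sparse = TRUE)
  lay <- annotate_layer(m, sets, "c1", ssgsea_params(alpha = 0))
  expect_equal(lay$label, "s1")
  expect_equal(lay$margin, 0)
})

test_that("leaves stop deepening and depth-1 hierarchies produce only layer 1", {
  h1 <- make_fixture_hierarchy(n_major = 3)  # no children anywhere
  sim <- simulate_dataset(simulation_config(h1, cells_per_leaf = 10,
                                            n_background_genes = 30, seed = 2))
  res <- annotate_hierarchical(sim$matrix, h1)
  expect_true(all(is.na(res$layer2_label)))
  expect_true(all(is.na(res$layer3_label)))
  expect_true(all(!is.na(res$layer1_label)))

  # mixed: M1 has children, M2 is a leaf like mast at layer 1
  h2 <- make_fixture_hierarchy(n_major = 2, n_children = c(M1 = 2))
  sim2 <- simulate_dataset(simulation_config(h2, cells_per_leaf = 15,
                                             n_background_genes = 30, seed = 3))
  res2 <- annotate_hierarchical(sim2$matrix, h2)
  leaf_cells <- res2$layer1_label == "M2"
  expect_true(any(leaf_cells))
  expect_true(all(is.na(res2$layer2_label[leaf_cells])))
})

test_that("max_layer truncates annotation depth", {
  h <- make_fixture_hierarchy(n_major = 2, n_children = c(M1 = 2))
  sim <- simulate_dataset(simulation_config(h, cells_per_leaf = 10,
                                            n_background_genes = 20, seed = 4))
  res <- annotate_hierarchical(sim$matrix, h, max_layer = 1)
  expect_true(all(is.na(res$layer2_label)))
})

test_that("annotating a subset of cells reproduces the full-matrix labels", {
  h <- two_major_fixture()
  sim <- simulate_dataset(simulation_config(h, cells_per_leaf = 30,
                                            n_background_genes = 50, seed = 5))
  res_full <- annotate_hierarchical(sim$matrix, h)
  pick <- sample(ncol(sim$matrix), 12)
  res_sub <- annotate_hierarchical(sim$matrix[, pick, drop = FALSE], h)
  i <- match(res_sub$barcode, res_full$barcode)
  expect_equal(res_sub$layer1_label, res_full$layer1_label[i])
  expect_equal(res_sub$prescreen_label, res_full$prescreen_label[i])
})

test_that("labels are invariant to permuting cells and gene rows", {
  h <- two_major_fixture()
  sim <- simulate_dataset(simulation_config(h, cells_per_leaf = 20,
                                            n_background_genes = 40, seed = 6))
  m <- sim$matrix
  res <- annotate_hierarchical(m, h)
  set.seed(1)
  mp <- m[sample(nrow(m)), sample(ncol(m))]
  res_p <- annotate_hierarchical(mp, h)
  i <- match(res$barcode, res_p$barcode)
  expect_equal(res_p$layer1_label[i], res$layer1_label)
})

test_that("strong synthetic signal is recovered at the subtype layer", {
  h <- make_fixture_hierarchy(n_major = 2, n_children = c(M1 = 2, M2 = 2))
  sim <- simulate_dataset(simulation_config(h, cells_per_leaf = 125,
                                            n_background_genes = 100,
                                            baseline_mean = 1, dispersion = 2,
                                            marker_fold_change = 8, seed = 7))
  res <- annotate_hierarchical(sim$matrix, h, prescreen = FALSE)
  truth2 <- sim$truth$layer2
  ok <- !is.na(truth2)
  acc <- mean(res$layer2_label[ok] == truth2[ok], na.rm = TRUE)
  expect_gte(acc, 0.95)
})

test_that("min_margin voids low-confidence decisions", {
  h <- two_major_fixture()
  sim <- simulate_dataset(simulation_config(h, cells_per_leaf = 20,
                                            n_background_genes = 40,
                                            marker_fold_change = 1, seed = 8))
  res <- annotate_hierarchical(sim$matrix, h, prescreen = FALSE,
                               min_margin = 1e6)
  expect_true(all(is.na(res$layer1_label)))
})

test_that("hierarchical consistency holds on annotated synthetic data", {
  h <- make_fixture_hierarchy(n_major = 3, n_children = c(M1 = 2, M2 = 3),
                              n_grandchildren = c(M1.1 = 2))
  sim <- simulate_dataset(simulation_config(h, cells_per_leaf = 15,
                                            n_background_genes = 40,
                                            n_nonimmune = 30, seed = 9))
  res <- annotate_hierarchical(sim$matrix, h, prescreen = TRUE)
  expect_equal(check_hierarchical_consistency(res, h), 0)
  # cells without a layer-1 label must not carry deeper labels
  no1 <- is.na(res$layer1_label)
  expect_true(all(is.na(res$layer2_label[no1])))
})

test_that("type counts and the >= 50 cells plotting rule", {
  res <- data.frame(barcode = sprintf("c%03d", 1:80),
                    prescreen_label = "immune",
                    layer1_label = "T",
                    layer1_score = 1, layer1_margin = 0.5,
                    layer2_label = rep(c("CD4_T", "CD8_T"), c(60, 20)),
                    layer2_score = 1, layer2_margin = 0.5,
                    layer3_label = NA_character_,
                    layer3_score = NA_real_, layer3_margin = NA_real_)
  class(res) <- c("annotation_result", "data.frame")
  expect_equal(as.integer(type_counts(res, 2)), c(60L, 20L))
  expect_equal(types_for_plotting(res, 2, min_cells = 50), "CD4_T")
})
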