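#' Sentinel for truth labels that must be excluded from evaluation
#' @export
DISCARD <- "DISCARD"

#' Read a label harmonization map from CSV
#'
#' Two columns: original label, standardized label. The keyword `DISCARD`
#' in the second column marks ambiguous originals (doublets, mixed labels
#' such as "NK/T") for exclusion.
#'
#' @param path CSV with columns `original`, `standardized` (header required).
#' @return named character vector: `map[original] -> standardized`.
#' @export
read_label_map <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("label map needs two columns: original, standardized")
  stats::setNames(df[[2]], df[[1]])
}

#' Harmonize ground-truth labels against a standard vocabulary
#'
#' Every distinct truth label must be covered by the map (silent
#' pass-through hides typos); labels mapped to [DISCARD] are excluded from
#' all downstream metrics and counted.
#'
#' @param truth character vector of original per-cell labels.
#' @param map named character vector from [read_label_map()].
#' @return list with `$labels` (standardized, `NA` where discarded),
#'   `$keep` (logical mask), `$n_discarded`.
#' @export
harmonize_labels <- function(truth, map) {
  truth <- as.character(truth)
  unmapped <- setdiff(unique(truth), names(map))
  if (length(unmapped))
    stop("unmapped truth label(s): ", paste(unmapped, collapse = ", "))
  std <- unname(map[truth])
  keep <- std != DISCARD
  std[!keep] <- NA_character_
  list(labels = std, keep = keep, n_discarded = sum(!keep))
}

#' Stratified subsampling of cells by truth type
#'
#' Reproduces the benchmarking sampling protocols: `"tiered"` caps very
#' abundant types (more than 50,000 cells of a type: sample 12,000; between
#' 20,000 and 50,000: sample 8,000; otherwise all cells are kept), while
#' `"capped"` samples at most `cap` cells per type (default 3,000), taking
#' all when a type has fewer. Sampling is uniform without replacement and
#' reproducible under `seed`.
#'
#' @param truth_labels per-cell type labels.
#' @param mode `"tiered"` or `"capped"`.
#' @param cap per-type cap for `"capped"` mode.
#' @param seed RNG seed.
#' @return sorted integer indices of the retained cells.
#' @export
stratified_subsample <- function(truth_labels, mode = c("tiered", "capped"),
                                 cap = 3000, seed = 1) {
  mode <- match.arg(mode)
  if (!length(truth_labels)) stop("empty label vector")
  if (mode == "capped" && cap <= 0) stop("cap must be positive")
  quota <- function(n) {
    if (mode == "capped") return(min(n, cap))
    if (n > 50000) 12000L else if (n > 20000) 8000L else n
  }
  idx_by_type <- split(seq_along(truth_labels), truth_labels)
  out <- integer(0)
  withr_seed <- seed  # one stream; per-type draws consume it in label order
  set.seed(withr_seed)
  for (type in sort(names(idx_by_type))) {
    idx <- idx_by_type[[type]]
    q <- quota(length(idx))
    out <- c(out, if (q >= length(idx)) idx else sample(idx, q))
  }
  sort(out)
}

#' Confusion-matrix metrics for predicted vs truth labels
#'
#' @param pred per-cell predicted labels.
#' @param truth per-cell truth labels, aligned with `pred`. Pairs where
#'   either is `NA` are excluded.
#' @param n_discarded optional count of cells discarded during
#'   harmonization, carried into the report.
#' @return object of class `evaluation_report`: list with `$confusion`
#'   (truth rows x predicted columns over the union vocabulary),
#'   `$accuracy` (micro, trace / total), `$per_class` (data.frame with
#'   precision, recall, f1, support per truth class), `$macro_precision`,
#'   `$macro_recall`, `$macro_f1`, `$macro_accuracy` (mean per-class
#'   recall), `$n_evaluated`, `$n_discarded`.
#' @export
evaluate_annotation <- function(pred, truth, n_discarded = 0) {
  if (length(pred) != length(truth))
    stop("pred and truth have different lengths (", length(pred), " vs ",
         length(truth), ")")
  ok <- !is.na(pred) & !is.na(truth)
  pred <- as.character(pred[ok]); truth <- as.character(truth[ok])
  if (!length(pred)) stop("no evaluable cells (all NA)")
  vocab <- sort(union(pred, truth))
  cm <- table(factor(truth, levels = vocab), factor(pred, levels = vocab))
  names(dimnames(cm)) <- c("truth", "predicted")
  diag_ <- diag(cm)
  col_sum <- colSums(cm); row_sum <- rowSums(cm)
  precision <- ifelse(col_sum > 0, diag_ / col_sum, 0)
  recall <- ifelse(row_sum > 0, diag_ / row_sum, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  present <- row_sum > 0  # macro metrics over classes present in the truth
  per_class <- data.frame(class = vocab, precision = unname(precision),
                          recall = unname(recall), f1 = unname(f1),
                          support = unname(row_sum), row.names = NULL)
  structure(list(
    confusion = cm,
    accuracy = sum(diag_) / sum(cm),
    per_class = per_class,
    macro_precision = mean(precision[present]),
    macro_recall = mean(recall[present]),
    macro_f1 = mean(f1[present]),
    macro_accuracy = mean(recall[present]),
    n_evaluated = sum(cm),
    n_discarded = n_discarded
  ), class = "evaluation_report")
}

#' @exportS3Method base::print
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %d cells (%d discarded), accuracy %.3f, macro F1 %.3f\n",
              x$n_evaluated, x$n_discarded, x$accuracy, x$macro_f1))
  print(x$per_class, digits = 3)
  invisible(x)
}

#' Per-layer evaluation of a hierarchical annotation
#'
#' Layer-k metrics are computed over the cells whose truth carries a label
#' at layer k; cells without deeper truth are excluded from deeper layers
#' only.
#'
#' @param result an `annotation_result`.
#' @param truth_df data.frame with column `barcode` and any of `layer1`,
#'   `layer2`, `layer3` truth columns (NA where truth has no label there).
#' @return named list of `evaluation_report`s, one per layer with truth.
#' @export
evaluate_layers <- function(result, truth_df) {
  stopifnot("barcode" %in% names(truth_df))
  i <- match(result$barcode, truth_df$barcode)
  if (anyNA(i))
    stop("truth table is missing barcode(s): ",
         paste(utils::head(result$barcode[is.na(i)], 5), collapse = ", "))
  out <- list()
  for (k in 1:3) {
    tcol <- paste0("layer", k)
    if (!tcol %in% names(truth_df)) next
    truth_k <- truth_df[[tcol]][i]
    if (all(is.na(truth_k))) next
    pred_k <- result[[paste0("layer", k, "_label")]]
    out[[tcol]] <- evaluate_annotation(pred_k[!is.na(truth_k)],
                                       truth_k[!is.na(truth_k)])
  }
  out
}

#' Repeated capped-subsample benchmark
#'
#' Mirrors the standard comparison protocol: per repetition, sample at most
#' `cap` cells per truth type, annotate the sample, and evaluate at layer 1;
#' the final metrics are the arithmetic means over repetitions.
#'
#' @param m genes x cells matrix.
#' @param hierarchy a `signature_hierarchy`.
#' @param truth_df truth table as in [evaluate_layers()].
#' @param reps number of repetitions (default 5).
#' @param cap per-type sampling cap (default 3000).
#' @param seed base seed; repetition r uses `seed + r - 1`.
#' @param params an [ssgsea_params()].
#' @param prescreen passed to [annotate_hierarchical()]; default `FALSE`
#'   (benchmark datasets have non-immune cells removed in advance).
#' @return list with `$reports` (per repetition), `$mean` (list:
#'   `accuracy`, `macro_precision`, `macro_recall`, `macro_f1`) and
#'   `$per_rep_accuracy`.
#' @export
replicate_benchmark <- function(m, hierarchy, truth_df, reps = 5, cap = 3000,
                                seed = 1, params = ssgsea_params(),
                                prescreen = FALSE) {
  stopifnot(reps >= 1)
  i <- match(colnames(m), truth_df$barcode)
  if (anyNA(i)) stop("truth table does not cover every cell")
  truth1 <- truth_df$layer1[i]
  reports <- vector("list", reps)
  for (r in seq_len(reps)) {
    idx <- stratified_subsample(truth1, mode = "capped", cap = cap,
                                seed = seed + r - 1)
    sub <- m[, idx, drop = FALSE]
    res <- annotate_hierarchical(sub, hierarchy, params,
                                 prescreen = prescreen, max_layer = 1)
    reports[[r]] <- evaluate_annotation(res$layer1_label, truth1[idx])
  }
  acc <- vapply(reports, `[[`, numeric(1), "accuracy")
  mean_report <- list(
    accuracy = mean(acc),
    macro_precision = mean(vapply(reports, `[[`, numeric(1), "macro_precision")),
    macro_recall = mean(vapply(reports, `[[`, numeric(1), "macro_recall")),
    macro_f1 = mean(vapply(reports, `[[`, numeric(1), "macro_f1")))
  list(reports = reports, mean = mean_report, per_rep_accuracy = acc)
}

#' Write an evaluation report (metrics + confusion matrix) to CSV
#' @param report an `evaluation_report`.
#' @param metrics_path CSV for overall + per-class metrics.
#' @param confusion_path optional CSV for the confusion matrix.
#' @export
write_evaluation_csv <- function(report, metrics_path, confusion_path = NULL) {
  overall <- data.frame(class = "__overall__",
                        precision = report$macro_precision,
                        recall = report$macro_recall,
                        f1 = report$macro_f1,
                        support = report$n_evaluated)
  overall$accuracy <- report$accuracy
  pc <- report$per_class
  pc$accuracy <- NA_real_
  utils::write.csv(rbind(overall, pc), metrics_path, row.names = FALSE)
  if (!is.null(confusion_path))
    utils::write.csv(as.data.frame.matrix(report$confusion), confusion_path)
  invisible(metrics_path)
}
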