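# Report assembly: derived deltas from method-comparison tables.
#
# These helpers operate on plain data.frames with the column schemas that
# run_method_comparison() / robustness studies emit, so the same arithmetic
# assembles reports from the package's own runs or from published benchmark
# tables (bundled reference values for two multi-modal knee/rectal MRI
# datasets ship under inst/extdata/).

#' Bundled benchmark reference tables
#'
#' Published single-modality vs fusion results, method comparisons at a 5%
#' compression ratio, and missing-modality accuracy drops on the MRNet and
#' JLURM multi-modal MRI datasets.
#'
#' @param which one of `"modality"`, `"methods"`, `"missing"`.
#' @return data.frame.
#' @export
benchmark_table <- function(which = c("modality", "methods", "missing")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("benchmark_", which, ".csv"),
                      package = "cgmdd")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

lookup_metric <- function(tbl, keycol, key, metric, dataset = NULL) {
  rows <- tbl[[keycol]] == key
  if (!is.null(dataset)) rows <- rows & tbl$dataset == dataset
  v <- tbl[[metric]][rows]
  if (length(v) != 1) {
    stopf("expected one row for %s='%s'%s, found %d", keycol, key,
          if (is.null(dataset)) "" else paste0(" in ", dataset), length(v))
  }
  v
}

#' Multi-modal fusion gain over a single modality
#'
#' Accuracy improvement (percentage points) of the multi-modal condition
#' over one single-modality condition.
#'
#' @param tbl data.frame with columns `dataset`, `condition`, `accuracy`
#'   (see [benchmark_table]`("modality")`).
#' @param dataset dataset name.
#' @param modality single-modality condition name.
#' @param fused name of the fused condition (default `"multimodal"`).
#' @export
fusion_gain <- function(tbl, dataset, modality, fused = "multimodal") {
  100 * (lookup_metric(tbl, "condition", fused, "accuracy", dataset) -
           lookup_metric(tbl, "condition", modality, "accuracy", dataset))
}

#' Gap of a method to the full-data upper bound
#'
#' `(metric[upper_bound] - metric[method]) * 100` percentage points.
#'
#' @param tbl data.frame with columns `dataset`, `method`, and the metric
#'   (see [benchmark_table]`("methods")`).
#' @param dataset dataset name.
#' @param method method name (default `"cgmdd"`).
#' @param metric `"accuracy"` or `"macro_f1"`.
#' @export
gap_to_upper_bound <- function(tbl, dataset, method = "cgmdd",
                               metric = "accuracy") {
  100 * (lookup_metric(tbl, "method", "upper_bound", metric, dataset) -
           lookup_metric(tbl, "method", method, metric, dataset))
}

#' Accuracy margin of one method over a baseline
#'
#' `(acc[method] - acc[baseline]) * 100` percentage points.
#'
#' @inheritParams gap_to_upper_bound
#' @param baseline baseline method name.
#' @export
margin_over <- function(tbl, dataset, baseline, method = "cgmdd",
                        metric = "accuracy") {
  100 * (lookup_metric(tbl, "method", method, metric, dataset) -
           lookup_metric(tbl, "method", baseline, metric, dataset))
}

#' Robustness gain from a missing-modality drop table
#'
#' `drop_only_ddg - drop_cgmdd` (percentage points) for one missing-modality
#' condition; positive values mean the contrast-guided method degrades less.
#'
#' @param tbl data.frame with columns `dataset`, `missing`,
#'   `drop_only_ddg`, `drop_cgmdd` (see [benchmark_table]`("missing")`).
#' @param dataset dataset name.
#' @param missing missing-modality condition name.
#' @export
missing_modality_gain <- function(tbl, dataset, missing) {
  lookup_metric(tbl, "missing", missing, "drop_only_ddg", dataset) -
    lookup_metric(tbl, "missing", missing, "drop_cgmdd", dataset)
}

#' Assemble a method-comparison table from evaluation runs
#'
#' Collapses the per-seed rows of [run_method_comparison()] to per-method
#' medians in the same schema the reporting helpers consume.
#'
#' @param runs data.frame from [run_method_comparison()].
#' @param dataset label for the dataset column.
#' @export
summarize_methods <- function(runs, dataset = "synthetic") {
  agg <- stats::aggregate(cbind(accuracy, macro_f1) ~ method, data = runs,
                          FUN = stats::median)
  data.frame(method = agg$method, dataset = dataset,
             accuracy = agg$accuracy, macro_f1 = agg$macro_f1)
}
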