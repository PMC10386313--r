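# Metric curves (model order vs averaged metric) and report files.

#' Construct a metric curve
#'
#' Model order (number of PCs or LVs) against a per-iteration metric, its
#' per-order mean, and the selected order (best mean; ties resolved toward
#' the smaller order).
#'
#' @param orders Integer vector of model orders.
#' @param per_iteration Numeric matrix, `length(orders)` rows x iterations.
#' @param metric_name One of `"%CC"`, `"RMSECV"`, `"R2"` (or any label).
#' @param higher_is_better Whether larger means are preferred when selecting
#'   the order (`FALSE` for RMSECV).
#' @return A list of class `metric_curve` with `orders`, `mean_metric`,
#'   `per_iteration`, `metric_name`, `selected_order`.
#' @export
metric_curve <- function(orders, per_iteration, metric_name,
                         higher_is_better = TRUE) {
  orders <- as.integer(orders)
  per_iteration <- as.matrix(per_iteration)
  if (nrow(per_iteration) != length(orders)) {
    stop("`per_iteration` must have one row per order")
  }
  mean_metric <- rowMeans(per_iteration)
  key <- if (higher_is_better) mean_metric else -mean_metric
  selected <- orders[which.max(key)]  # which.max takes the first (smallest
                                      # order) among ties
  structure(list(orders = orders, mean_metric = mean_metric,
                 per_iteration = per_iteration, metric_name = metric_name,
                 higher_is_better = higher_is_better,
                 selected_order = selected),
            class = "metric_curve")
}

#' @export
print.metric_curve <- function(x, ...) {
  cat(sprintf("metric_curve (%s over %d iterations)\n", x$metric_name,
              ncol(x$per_iteration)))
  print(data.frame(order = x$orders, mean = round(x$mean_metric, 3)))
  cat("selected order:", x$selected_order, "\n")
  invisible(x)
}

#' Write a metric curve (and optional coordinates) to report files
#'
#' Writes `<prefix>_curve.csv` (per-order mean and per-iteration values) and
#' `<prefix>_summary.json` (full-precision values, selected order, metric
#' name). Optional score/loading tables go to `<prefix>_scores.csv` /
#' `<prefix>_loadings.csv` for plotting.
#'
#' @param curve A `metric_curve`.
#' @param path_prefix Output path prefix (directories must exist).
#' @param scores,loadings Optional data frames of score / loading
#'   coordinates.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(curve, path_prefix, scores = NULL, loadings = NULL) {
  stopifnot(inherits(curve, "metric_curve"))
  files <- character(0)

  df <- data.frame(order = curve$orders, mean = curve$mean_metric)
  iter_cols <- as.data.frame(curve$per_iteration)
  names(iter_cols) <- paste0("iter_", seq_len(ncol(iter_cols)))
  csv_path <- paste0(path_prefix, "_curve.csv")
  utils::write.csv(cbind(df, iter_cols), csv_path, row.names = FALSE)
  files <- c(files, csv_path)

  json_path <- paste0(path_prefix, "_summary.json")
  jsonlite::write_json(
    list(metric_name = curve$metric_name, orders = curve$orders,
         mean_metric = curve$mean_metric,
         per_iteration = curve$per_iteration,
         higher_is_better = curve$higher_is_better,
         selected_order = curve$selected_order),
    json_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, json_path)

  if (!is.null(scores)) {
    f <- paste0(path_prefix, "_scores.csv")
    utils::write.csv(scores, f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(loadings)) {
    f <- paste0(path_prefix, "_loadings.csv")
    utils::write.csv(loadings, f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read back a written metric-curve report
#'
#' Reconstructs the `metric_curve` from `<prefix>_summary.json`; values
#' round-trip at full double precision.
#'
#' @param path_prefix The prefix passed to [write_report()].
#' @return A `metric_curve`.
#' @export
read_report <- function(path_prefix) {
  s <- jsonlite::read_json(paste0(path_prefix, "_summary.json"),
                           simplifyVector = TRUE)
  metric_curve(s$orders, s$per_iteration, s$metric_name, s$higher_is_better)
}
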