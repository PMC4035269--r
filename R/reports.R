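# Tabular report writers for downstream tooling.

#' Per-node connectivity metrics table
#'
#' Combines reachability, betweenness and tier assignment into one table.
#'
#' @param web A non-empty [protease_web()] object.
#' @return Data frame with columns `accession`, `reachability`,
#'   `betweenness`, `tier`.
#' @export
metrics_table <- function(web) {
  prof <- reachability(web)
  btw <- web_betweenness(web)
  tiers <- suppressWarnings(strongly_connected_core(web))$tiers
  acc <- names(prof$counts)
  data.frame(accession = acc,
             reachability = unname(prof$counts),
             betweenness = unname(btw[acc]),
             tier = unname(tiers[acc]),
             stringsAsFactors = FALSE)
}

#' Write connectivity metrics to TSV
#'
#' @param web A [protease_web()] object.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_metrics_report <- function(web, path) {
  utils::write.table(metrics_table(web), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a null-ensemble report to TSV
#'
#' One row per replicate: `replicate`, `model`, `mean_reachability`.
#'
#' @param summary_obj A `null_model_summary` from [null_experiment()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_ensemble_report <- function(summary_obj, path) {
  stopifnot(inherits(summary_obj, "null_model_summary"))
  df <- data.frame(replicate = seq_along(summary_obj$replicate_means),
                   model = summary_obj$model,
                   mean_reachability = summary_obj$replicate_means)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a perturbation report to TSV
#'
#' One row per result: `label`, `removed_edges`, `removed_nodes`, `auc`,
#' `auc_ratio`.
#'
#' @param results A `perturbation_result` or list of them.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_perturbation_report <- function(results, path) {
  if (inherits(results, "perturbation_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(label = r$label, removed_edges = r$removed_edge_count,
               removed_nodes = r$removed_node_count,
               auc = r$auc, auc_ratio = r$auc_ratio,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
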