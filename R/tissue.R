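#' Derive an expression threshold from negative-control intensities
#'
#' Returns the q-quantile of the negative-control A-values under the
#' nearest-rank (inverse empirical CDF) convention: the `ceiling(q * n)`-th
#' order statistic. With q = 0.95 this is the cutoff below which 95% of
#' control probe intensities fall; proteins with A-values above it are
#' called expressed.
#'
#' @param negative_controls Nonempty numeric vector of control A-values.
#' @param q Quantile in (0, 1], default 0.95.
#' @return A single threshold A-value.
#' @export
derive_threshold <- function(negative_controls, q = 0.95) {
  x <- as.numeric(negative_controls)
  x <- x[!is.na(x)]
  if (!length(x)) stop_pw("negative_controls must be a nonempty numeric vector")
  if (q <= 0 || q > 1) stop_pw("q must lie in (0, 1]")
  sort(x)[ceiling(q * length(x))]
}

#' Tissue-specific subnetwork
#'
#' Induces the subgraph on nodes whose A-value in the given tissue is
#' strictly above the threshold. Proteins absent from the expression
#' matrix are treated as not expressed and dropped (their count is
#' reported via a message).
#'
#' @param web A [protease_web()] object.
#' @param expression Numeric matrix or data frame, rows named by protein
#'   accession (or with an `accession` first column), columns named by
#'   tissue, entries log-scale A-values.
#' @param tissue Tissue (column) name.
#' @param threshold Expression cutoff, typically from [derive_threshold()].
#' @return A [protease_web()] with provenance `"tissue:<name>"`.
#' @export
tissue_subnetwork <- function(web, expression, tissue, threshold) {
  stopifnot(inherits(web, "protease_web"))
  check_string(tissue, "tissue")
  expr <- as_expression_matrix(expression)
  if (!tissue %in% colnames(expr)) stop_pw("unknown tissue: ", tissue)

  acc <- web$nodes$accession
  absent <- setdiff(acc, rownames(expr))
  if (length(absent)) {
    message(sprintf("%d node(s) absent from the expression matrix treated as not expressed",
                    length(absent)))
  }
  measured <- intersect(acc, rownames(expr))
  expressed <- measured[expr[measured, tissue] > threshold]
  induce_web(web, expressed, provenance = paste0("tissue:", tissue))
}

as_expression_matrix <- function(expression) {
  if (is.data.frame(expression)) {
    if ("accession" %in% names(expression)) {
      acc <- as.character(expression$accession)
      expression <- as.matrix(expression[setdiff(names(expression), "accession")])
      rownames(expression) <- acc
    } else {
      expression <- as.matrix(expression)
    }
  }
  if (is.null(rownames(expression)) || is.null(colnames(expression))) {
    stop_pw("expression matrix needs accession rownames and tissue colnames")
  }
  storage.mode(expression) <- "double"
  expression
}

#' Survey connectivity across tissue-specific protease webs
#'
#' For each tissue: induce the expressed subnetwork, take its largest
#' weakly connected component, compute the reachability profile and AUC,
#' and count how many of a supplied connector set are among the expressed
#' nodes. By default the AUC is normalized to each tissue's own LCC size
#' (per-tissue curves); set `reference_n` to a common count for
#' cross-tissue ratio work.
#'
#' @param web A [protease_web()] object (typically the original LCC).
#' @param expression Expression matrix as in [tissue_subnetwork()].
#' @param threshold Expression cutoff.
#' @param connector_set Accessions of key connector proteins (subset of
#'   the graph's accessions).
#' @param reference_n Optional fixed normalization node count; default
#'   each tissue's own LCC size.
#' @return Data frame with one row per tissue: `tissue`, `n_expressed`,
#'   `lcc_size`, `auc`, `connector_presence_count`.
#' @export
tissue_survey <- function(web, expression, threshold, connector_set = character(0),
                          reference_n = NULL) {
  stopifnot(inherits(web, "protease_web"))
  expr <- as_expression_matrix(expression)
  connector_set <- unique(as.character(connector_set))
  unknown <- setdiff(connector_set, web$nodes$accession)
  if (length(unknown)) stop_pw("connector(s) not in graph: ", paste(unknown, collapse = ", "))

  rows <- lapply(colnames(expr), function(tis) {
    sub <- suppressMessages(tissue_subnetwork(web, expr, tis, threshold))
    n_exp <- n_nodes(sub)
    if (n_exp == 0L) {
      return(data.frame(tissue = tis, n_expressed = 0L, lcc_size = 0L,
                        auc = NA_real_, connector_presence_count = 0L,
                        stringsAsFactors = FALSE))
    }
    lcc <- largest_connected_component(sub, mode = "weak")
    prof <- reachability(lcc, reference_n = reference_n %||% n_nodes(lcc))
    data.frame(
      tissue = tis,
      n_expressed = n_exp,
      lcc_size = n_nodes(lcc),
      auc = prof$auc,
      connector_presence_count = sum(connector_set %in% sub$nodes$accession),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
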