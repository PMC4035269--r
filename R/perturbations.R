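#' Configuration for the perturbation-robustness suite
#'
#' @param edge_removal_fractions Fractions of edges removed in the random
#'   sweep, each strictly between 0 and 1 (default 10--40%).
#' @param reps Random draws per fraction (default 200).
#' @param seed Integer seed.
#' @param connector_count Number of connectors extracted by
#'   [iterative_connector_search()] (default 6).
#' @return A list of class `perturbation_config`.
#' @export
perturbation_config <- function(edge_removal_fractions = c(0.1, 0.2, 0.3, 0.4),
                                reps = 200L, seed = 1L, connector_count = 6L) {
  if (any(edge_removal_fractions <= 0 | edge_removal_fractions >= 1)) {
    stop_pw("edge_removal_fractions must lie strictly between 0 and 1")
  }
  reps <- as.integer(reps); connector_count <- as.integer(connector_count)
  if (reps < 1L) stop_pw("reps must be >= 1")
  if (connector_count < 1L) stop_pw("connector_count must be >= 1")
  structure(list(edge_removal_fractions = edge_removal_fractions, reps = reps,
                 seed = as.integer(seed), connector_count = connector_count),
            class = "perturbation_config")
}

# Assemble a labelled perturbation result against the frozen original.
# reference_n is the ORIGINAL node count throughout a series, so removed
# nodes contribute zero and AUC ratios stay comparable.
perturbation_result <- function(label, web, reference_n, auc_original,
                                removed_edges, removed_nodes) {
  counts <- if (n_nodes(web) > 0L) reachability(web)$counts else integer(0)
  auc <- auc_frozen(counts, reference_n)
  structure(list(
    label = label,
    auc = auc,
    auc_ratio = auc / auc_original,
    removed_edge_count = as.integer(removed_edges),
    removed_node_count = as.integer(removed_nodes),
    reachability = counts,
    reference_n = reference_n,
    web = web
  ), class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("perturbation [%s]: AUC %.4f (%.1f%% of original); -%d edge(s), -%d node(s)\n",
              x$label, x$auc, 100 * x$auc_ratio,
              x$removed_edge_count, x$removed_node_count))
  invisible(x)
}

original_auc <- function(web) {
  auc_frozen(reachability(web)$counts, n_nodes(web))
}

#' High-confidence network filter ("hc" / "hc+i")
#'
#' Removes every cleavage edge whose physiological-relevance annotation is
#' not `"yes"`. Inhibition edges (which typically carry no relevance
#' annotation) are removed as well unless `keep_inhibitions = TRUE`, which
#' yields the high-confidence-plus-inhibitors variant. The node set is
#' frozen so the AUC ratio is comparable to the original.
#'
#' @param web A [protease_web()] whose cleavage edges carry relevance
#'   annotations.
#' @param keep_inhibitions Keep inhibition edges (`"hc+i"`), default `FALSE`.
#' @return A `perturbation_result`.
#' @export
high_confidence_filter <- function(web, keep_inhibitions = FALSE) {
  stopifnot(inherits(web, "protease_web"))
  ed <- web$edges
  keep <- (ed$kind == "cleavage" & !is.na(ed$relevance) & ed$relevance == "yes") |
    (ed$kind == "inhibition" & keep_inhibitions)
  pruned <- replace_edges(web, ed[keep, , drop = FALSE],
                          provenance = if (keep_inhibitions) "hc+i" else "hc")
  perturbation_result(if (keep_inhibitions) "hc+i" else "hc", pruned,
                      reference_n = n_nodes(web),
                      auc_original = original_auc(web),
                      removed_edges = sum(!keep), removed_nodes = 0L)
}

#' Remove potentially mis-directed inhibitor cleavages ("inh rm")
#'
#' Drops cleavage edges that may record an inhibitory trapping event
#' rather than an inactivating cleavage of the inhibitor: a cleavage
#' P -> I is removed iff the target I is a serine-protease inhibitor
#' (inhibitor class `S`) and the source P is a serine or cysteine protease
#' (the serpin trap is covalent only for these classes; metallo and
#' aspartic cleavage of serpins genuinely inactivates the serpin and is
#' kept), or the target is a trap inhibitor (A2M/PZP-style, which cages
#' proteases of any class). Inhibition edges are untouched.
#'
#' @param web A [protease_web()] with class and trap annotations.
#' @param broad_serine_reading If `TRUE`, rule (i) triggers on any
#'   serine-protease inhibitor annotation including `broad`-class
#'   inhibitors that cover class S targets; the default restricts it to
#'   inhibitors explicitly annotated with class `S`.
#' @return A `perturbation_result` labelled `"inh rm"`.
#' @export
remove_inhibitor_cleavages <- function(web, broad_serine_reading = FALSE) {
  stopifnot(inherits(web, "protease_web"))
  nd <- web$nodes
  cls <- split_classes(nd$inhibitor_classes)
  has_S <- vapply(cls, function(x) "S" %in% x, logical(1))
  if (broad_serine_reading) {
    has_S <- has_S | vapply(cls, function(x) "broad" %in% x, logical(1))
  }
  serine_inh <- stats::setNames(has_S, nd$accession)
  trap <- stats::setNames(nd$trap_inhibitor, nd$accession)
  catcls <- stats::setNames(nd$catalytic_class, nd$accession)

  ed <- web$edges
  drop <- ed$kind == "cleavage" &
    ((serine_inh[ed$to] & catcls[ed$from] %in% c("S", "C")) | trap[ed$to])
  pruned <- replace_edges(web, ed[!drop, , drop = FALSE], provenance = "inh rm")
  perturbation_result("inh rm", pruned,
                      reference_n = n_nodes(web),
                      auc_original = original_auc(web),
                      removed_edges = sum(drop), removed_nodes = 0L)
}

#' Single-node knockouts
#'
#' Removes each node individually (with its incident edges) and records
#' the AUC of the remainder against the original reference node count, so
#' the removed node contributes zero reachability.
#'
#' @param web A non-empty [protease_web()].
#' @return Named list of `perturbation_result`, one per node.
#' @export
single_node_knockouts <- function(web) {
  stopifnot(inherits(web, "protease_web"))
  if (n_nodes(web) == 0L) stop_pw("empty graph")
  ref <- n_nodes(web)
  auc0 <- original_auc(web)
  res <- lapply(web$nodes$accession, function(acc) {
    keep <- setdiff(web$nodes$accession, acc)
    sub <- induce_web(web, keep, provenance = paste0("1 rm:", acc))
    perturbation_result(paste0("1 rm:", acc), sub, ref, auc0,
                        removed_edges = n_edges(web) - n_edges(sub),
                        removed_nodes = 1L)
  })
  stats::setNames(res, web$nodes$accession)
}

#' Iterative search for key connector nodes
#'
#' Repeats `k` times: compute directed betweenness, remove the node with
#' the highest score (ties broken towards the lexicographically smallest
#' accession), and record the AUC of the remainder against the frozen
#' original reference. The removal order identifies the proteins that
#' tether the network together.
#'
#' @param web A [protease_web()] object.
#' @param k Number of nodes to remove (`k <= n_nodes(web)`).
#' @return A list of class `connector_search` with `order` (accessions in
#'   removal order) and `steps` (per-step `perturbation_result`).
#' @export
iterative_connector_search <- function(web, k) {
  stopifnot(inherits(web, "protease_web"))
  k <- as.integer(k)
  if (k < 1L || k > n_nodes(web)) stop_pw("k must be between 1 and the node count")
  ref <- n_nodes(web)
  auc0 <- original_auc(web)
  current <- web
  order_ <- character(0)
  steps <- vector("list", k)
  for (i in seq_len(k)) {
    b <- web_betweenness(current)
    top <- names(b)[b == max(b)]
    victim <- sort(top)[1L]
    order_ <- c(order_, victim)
    current <- induce_web(current, setdiff(current$nodes$accession, victim),
                          provenance = sprintf("connector rm %d", i))
    steps[[i]] <- perturbation_result(
      sprintf("connector rm %d (%s)", i, victim), current, ref, auc0,
      removed_edges = n_edges(web) - n_edges(current),
      removed_nodes = i)
  }
  structure(list(order = order_, steps = steps), class = "connector_search")
}

#' @export
print.connector_search <- function(x, ...) {
  cat("iterative connector search\n")
  for (i in seq_along(x$order)) {
    cat(sprintf("  %d. %s (AUC ratio %.3f)\n", i, x$order[i], x$steps[[i]]$auc_ratio))
  }
  invisible(x)
}

#' Combinatorial knockout of a connector set ("6 rm" / "5 rm")
#'
#' Removes the whole `node_set` at once, and additionally produces one
#' leave-one-in variant per member (keeping that member, removing the
#' others). All AUCs are normalized against the frozen original reference.
#'
#' @param web A [protease_web()] object.
#' @param node_set Accessions to knock out (must exist in the graph).
#' @return List with `all_removed` (a `perturbation_result`) and
#'   `leave_one_in` (named list of `perturbation_result` keyed by the kept
#'   accession).
#' @export
combinatorial_knockout <- function(web, node_set) {
  stopifnot(inherits(web, "protease_web"))
  node_set <- unique(as.character(node_set))
  unknown <- setdiff(node_set, web$nodes$accession)
  if (length(unknown)) stop_pw("unknown accession(s): ", paste(unknown, collapse = ", "))
  ref <- n_nodes(web)
  auc0 <- original_auc(web)

  ko <- function(removed, label) {
    sub <- induce_web(web, setdiff(web$nodes$accession, removed), provenance = label)
    perturbation_result(label, sub, ref, auc0,
                        removed_edges = n_edges(web) - n_edges(sub),
                        removed_nodes = length(removed))
  }
  all_removed <- ko(node_set, sprintf("%d rm", length(node_set)))
  leave_one_in <- lapply(node_set, function(kept) {
    ko(setdiff(node_set, kept),
       sprintf("%d rm (keep %s)", length(node_set) - 1L, kept))
  })
  list(all_removed = all_removed,
       leave_one_in = stats::setNames(leave_one_in, node_set))
}

#' Random edge-removal sweep
#'
#' For each fraction f in the configuration, performs `reps` seeded draws
#' removing `floor(f * |E|)` stored edges uniformly without replacement
#' (node set frozen), records the AUC of each draw, and reports the worst
#' (minimum) AUC per fraction -- the conservative summary used when
#' simulating annotation errors.
#'
#' @param web A [protease_web()] object.
#' @param config A [perturbation_config()]; rep r at fraction index fi
#'   uses the derived seed `seed + 100000 * fi + r`.
#' @return Named list (by fraction) of lists with `aucs`, `worst_auc`,
#'   `removed_edge_count`.
#' @export
random_edge_removal <- function(web, config = perturbation_config()) {
  stopifnot(inherits(web, "protease_web"), inherits(config, "perturbation_config"))
  m <- n_edges(web)
  ref <- n_nodes(web)
  out <- lapply(seq_along(config$edge_removal_fractions), function(fi) {
    f <- config$edge_removal_fractions[fi]
    k <- as.integer(floor(f * m))
    aucs <- vapply(seq_len(config$reps), function(r) {
      s <- derive_seed(config$seed, 100000 * fi + r)
      drop <- with_seed(s, sample.int(m, k))
      kept <- if (k > 0L) web$edges[-drop, , drop = FALSE] else web$edges
      pruned <- replace_edges(web, kept,
                              provenance = sprintf("random -%.0f%%", 100 * f))
      auc_frozen(reachability(pruned)$counts, ref)
    }, numeric(1))
    list(fraction = f, aucs = aucs, worst_auc = min(aucs),
         removed_edge_count = k)
  })
  stats::setNames(out, paste0("f", config$edge_removal_fractions))
}
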