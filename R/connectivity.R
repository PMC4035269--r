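#' Reachability profile of a directed network
#'
#' Reachability of node X is the number of nodes Y -- including X itself --
#' with a finite directed path from X to Y, i.e. the row sums of the
#' transitive closure. In a protease web it counts the proteins whose
#' activity a protease or inhibitor can potentially influence. An isolated
#' node therefore has reachability 1, and every node of a strongly
#' connected network has reachability equal to the node count. Self-loops
#' and parallel cleavage/inhibition edges between the same ordered pair do
#' not affect the result.
#'
#' @param web A [protease_web()] object.
#' @param reference_n Node count used to normalize the inverse cumulative
#'   curve and AUC. Defaults to the network's own node count; pass the
#'   unperturbed network's count to keep AUC ratios comparable across a
#'   perturbation series.
#' @return An object of class `reachability_profile` with elements
#'   `counts` (named integer vector), `reference_n`, `inverse_cumulative`
#'   (data frame of step-function points) and `auc`.
#' @seealso [reachability_auc()], [inverse_cumulative()]
#' @export
#' @examples
#' web <- protease_web(data.frame(accession = c("A", "B", "C")),
#'                     data.frame(from = c("A", "B"), to = c("B", "C"),
#'                                kind = "cleavage"))
#' reachability(web)$counts  # A:3 B:2 C:1
reachability <- function(web, reference_n = NULL) {
  stopifnot(inherits(web, "protease_web"))
  n <- n_nodes(web)
  if (n == 0L) stop_pw("cannot compute reachability of an empty graph")
  g <- as_igraph(web)
  d <- igraph::distances(g, mode = "out")
  counts <- as.integer(rowSums(is.finite(d)))
  names(counts) <- igraph::V(g)$name
  reference_n <- reference_n %||% n
  if (reference_n <= 0) stop_pw("reference_n must be positive")
  new_reachability_profile(counts, reference_n)
}

new_reachability_profile <- function(counts, reference_n) {
  prof <- structure(
    list(counts = counts, reference_n = reference_n,
         inverse_cumulative = NULL, auc = NULL),
    class = "reachability_profile")
  prof$inverse_cumulative <- inverse_cumulative(prof)
  prof$auc <- reachability_auc(prof)
  prof
}

#' @export
print.reachability_profile <- function(x, ...) {
  cat(sprintf("reachability profile: %d nodes, reference n = %d\n",
              length(x$counts), as.integer(x$reference_n)))
  cat(sprintf("  range [%d, %d], mean %.2f, AUC %.4f\n",
              min(x$counts), max(x$counts), mean(x$counts), x$auc))
  invisible(x)
}

#' Inverse cumulative reachability curve
#'
#' For each observed reachability value r, the fraction of nodes whose
#' reachability is at least r, as a left-closed (right-continuous between
#' observed values) step function. This is the curve whose normalized area
#' is the network's connectivity AUC.
#'
#' @param profile A `reachability_profile`.
#' @return Data frame with columns `r` (observed values, ascending) and
#'   `fraction` (non-increasing, fraction of nodes with reachability >= r).
#' @export
inverse_cumulative <- function(profile) {
  stopifnot(inherits(profile, "reachability_profile"))
  counts <- profile$counts
  if (!length(counts)) stop_pw("empty reachability profile")
  r <- sort(unique(counts))
  fraction <- vapply(r, function(v) mean(counts >= v), numeric(1))
  data.frame(r = r, fraction = fraction)
}

#' Area under the inverse cumulative reachability curve
#'
#' Exact rectangle-sum integral of the inverse cumulative step function
#' over r in `[0, reference_n]`, divided by `reference_n`. With the
#' left-closed step convention this is identically the mean reachability
#' divided by `reference_n`; both routes are computed and the closed form
#' is returned.
#'
#' @param profile A `reachability_profile`.
#' @return AUC in (0, 1] (relative to the reference node count).
#' @export
reachability_auc <- function(profile) {
  stopifnot(inherits(profile, "reachability_profile"))
  if (profile$reference_n <= 0) stop_pw("reference_n must be positive")
  mean(profile$counts) / profile$reference_n
}

# AUC with a frozen node universe: nodes removed from the network
# contribute zero reachability, so the sum runs over the surviving nodes
# but the normalization stays at reference_n for both axes.
auc_frozen <- function(counts, reference_n) {
  sum(counts) / (reference_n * reference_n)
}

#' Directed betweenness centrality
#'
#' Freeman/Brandes shortest-path betweenness on the directed graph:
#' endpoints are excluded and tied shortest paths between a pair share
#' weight equally. High-betweenness nodes tether the protease web
#' together, and iteratively removing them identifies the key connectors
#' (see [iterative_connector_search()]).
#'
#' @param web A [protease_web()] object.
#' @return Named numeric vector of betweenness scores.
#' @export
web_betweenness <- function(web) {
  stopifnot(inherits(web, "protease_web"))
  g <- as_igraph(web)
  b <- igraph::betweenness(g, directed = TRUE, weights = NA)
  stats::setNames(as.numeric(b), igraph::V(g)$name)
}

#' Strongly connected regulatory core and reachability tiers
#'
#' Returns the largest strongly connected component -- the regulatory core
#' whose members can all directly or indirectly reach each other and hence
#' share one reachability value -- and assigns every node to a tier:
#' `core`, `upstream` (reachability strictly greater than the core's;
#' these reach the core but cannot be reached from it) or `downstream`
#' (the remainder). The tier boundary is defined relative to the core's
#' shared reachability only, not to any fixed cutoff.
#'
#' @param web A non-empty [protease_web()] object.
#' @return A list of class `tier_summary` with `core` (accessions),
#'   `r_core`, `n_core`, `n_upstream`, `n_downstream`, and `tiers` (named
#'   character vector over all nodes).
#' @export
strongly_connected_core <- function(web) {
  stopifnot(inherits(web, "protease_web"))
  if (n_nodes(web) == 0L) stop_pw("cannot compute the core of an empty graph")
  g <- as_igraph(web)
  comp <- igraph::components(g, mode = "strong")
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    firsts <- vapply(best, function(ci) min(igraph::V(g)$name[comp$membership == ci]),
                     character(1))
    best <- best[order(firsts)][1L]
  }
  core <- sort(igraph::V(g)$name[comp$membership == best])
  if (length(core) == 1L) {
    warning("largest strongly connected component is a single node", call. = FALSE)
  }

  prof <- reachability(web)
  r_core_vals <- unique(prof$counts[core])
  if (length(r_core_vals) != 1L) {
    stop_pw("internal error: core members do not share one reachability value")
  }
  r_core <- r_core_vals[[1L]]
  tiers <- ifelse(names(prof$counts) %in% core, "core",
                  ifelse(prof$counts > r_core, "upstream", "downstream"))
  names(tiers) <- names(prof$counts)
  structure(list(
    core = core,
    r_core = r_core,
    n_core = length(core),
    n_upstream = sum(tiers == "upstream"),
    n_downstream = sum(tiers == "downstream"),
    tiers = tiers
  ), class = "tier_summary")
}

#' @export
print.tier_summary <- function(x, ...) {
  cat(sprintf("strongly connected core: %d nodes, shared reachability %d\n",
              x$n_core, as.integer(x$r_core)))
  cat(sprintf("  upstream %d, downstream %d\n", x$n_upstream, x$n_downstream))
  invisible(x)
}

#' Shortest-path length histogram and reachable pair count
#'
#' Over all ordered node pairs X != Y with a finite directed distance,
#' tabulates the shortest path length and counts the reachable pairs. The
#' maximum possible count is n(n-1).
#'
#' @param web A [protease_web()] object.
#' @return List with `histogram` (named integer vector, names are path
#'   lengths) and `reachable_pair_count`.
#' @export
path_length_histogram <- function(web) {
  stopifnot(inherits(web, "protease_web"))
  g <- as_igraph(web)
  d <- igraph::distances(g, mode = "out")
  diag(d) <- Inf
  finite <- d[is.finite(d)]
  tab <- table(finite)
  list(
    histogram = stats::setNames(as.integer(tab), names(tab)),
    reachable_pair_count = length(finite)
  )
}

#' Enumerate all shortest regulatory paths between two proteins
#'
#' Finds every minimal-length directed path from `source` to `target`,
#' annotating each step with the stored edge kind(s) (a step corresponds
#' to one arc, which can be backed by both a cleavage and an inhibition
#' edge). Used to propose mechanistic routes by which one protease can
#' influence another.
#'
#' @param web A [protease_web()] object.
#' @param source,target Node accessions.
#' @return A list of class `path_query_result` with `source`, `target`,
#'   `length` (`NA` if unreachable) and `paths`, a list where each element
#'   has `nodes` (accession sequence) and `kinds` (per-step
#'   semicolon-joined edge kinds).
#' @export
regulatory_paths <- function(web, source, target) {
  stopifnot(inherits(web, "protease_web"))
  check_string(source, "source"); check_string(target, "target")
  acc <- web$nodes$accession
  if (!source %in% acc) stop_pw("unknown accession: ", source)
  if (!target %in% acc) stop_pw("unknown accession: ", target)

  g <- as_igraph(web)
  d <- igraph::distances(g, v = source, mode = "out")[1L, ]
  if (!is.finite(d[[target]])) {
    return(structure(list(source = source, target = target,
                          length = NA_integer_, paths = list()),
                     class = "path_query_result"))
  }
  if (source == target) {
    return(structure(list(source = source, target = target, length = 0L,
                          paths = list(list(nodes = source, kinds = character(0)))),
                     class = "path_query_result"))
  }

  # predecessor map on the shortest-path DAG, walked back from the target
  ed <- unique(web$edges[web$edges$from != web$edges$to, c("from", "to")])
  preds <- split(ed$from, ed$to)
  walk_back <- function(v) {
    if (v == source) return(list(source))
    out <- list()
    for (u in preds[[v]]) {
      if (is.finite(d[[u]]) && d[[u]] + 1 == d[[v]]) {
        for (p in walk_back(u)) out[[length(out) + 1L]] <- c(p, v)
      }
    }
    out
  }
  node_paths <- walk_back(target)

  kind_lookup <- tapply(web$edges$kind,
                        paste(web$edges$from, web$edges$to, sep = "\r"),
                        function(k) paste(sort(unique(k)), collapse = ";"))
  paths <- lapply(node_paths, function(p) {
    steps <- paste(p[-length(p)], p[-1L], sep = "\r")
    list(nodes = p, kinds = as.character(kind_lookup[steps]))
  })
  structure(list(source = source, target = target,
                 length = as.integer(d[[target]]), paths = paths),
            class = "path_query_result")
}

#' @export
print.path_query_result <- function(x, ...) {
  if (is.na(x$length)) {
    cat(sprintf("%s -> %s: unreachable\n", x$source, x$target))
    return(invisible(x))
  }
  cat(sprintf("%s -> %s: %d shortest path(s) of length %d\n",
              x$source, x$target, length(x$paths), x$length))
  for (p in utils::head(x$paths, 10L)) {
    cat("  ", paste(p$nodes, collapse = " -> "), "\n", sep = "")
  }
  if (length(x$paths) > 10L) cat("  ...\n")
  invisible(x)
}
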