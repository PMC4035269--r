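#' Restrict a network to the protease web
#'
#' Drops every node without a MEROPS-style ID (plain substrates), keeping
#' the induced subgraph on proteases and inhibitors only. Only nodes that
#' carry a MEROPS ID and take part in a cleavage or inhibition belong to
#' the protease web; since graph nodes participate in an edge by
#' construction, membership reduces to the MEROPS ID criterion. Idempotent.
#'
#' @param web A [protease_web()] object.
#' @return A [protease_web()] restricted to MEROPS-ID-bearing nodes, with
#'   provenance `"protease web"`.
#' @export
restrict_to_protease_web <- function(web) {
  stopifnot(inherits(web, "protease_web"))
  keep <- web$nodes$accession[!is.na(web$nodes$merops_id)]
  induce_web(web, keep, provenance = "protease web")
}

#' Largest connected component
#'
#' Induced subgraph on the largest weakly (default) or strongly connected
#' component. Ties between equally-sized components are broken towards the
#' component containing the lexicographically smallest member accession.
#'
#' @param web A non-empty [protease_web()] object.
#' @param mode `"weak"` or `"strong"`.
#' @return A [protease_web()] with provenance `"LCC"` (or `"strong LCC"`).
#' @export
largest_connected_component <- function(web, mode = c("weak", "strong")) {
  stopifnot(inherits(web, "protease_web"))
  mode <- match.arg(mode)
  if (n_nodes(web) == 0L) stop_pw("cannot take the largest component of an empty graph")
  g <- as_igraph(web)
  comp <- igraph::components(g, mode = mode)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # smallest lexicographic member accession wins
    firsts <- vapply(best, function(ci) {
      min(igraph::V(g)$name[comp$membership == ci])
    }, character(1))
    best <- best[order(firsts)][1L]
  }
  keep <- igraph::V(g)$name[comp$membership == best]
  induce_web(web, keep,
             provenance = if (mode == "weak") "LCC" else "strong LCC")
}

#' Composition statistics of a protease-web graph
#'
#' Counts nodes and edges, proteases with at least one outgoing cleavage,
#' inhibitors with at least one outgoing inhibition, the size of the
#' largest weakly connected component, and the role breakdown of cleavage
#' targets (fraction of distinct cleavage targets that are proteases,
#' inhibitors, or other substrates). A target that is both protease and
#' inhibitor is counted as protease.
#'
#' @param web A [protease_web()] object.
#' @return A list of class `composition_stats`.
#' @export
composition_stats <- function(web) {
  stopifnot(inherits(web, "protease_web"))
  ed <- web$edges
  roles <- node_roles(web)
  rn <- stats::setNames(seq_len(nrow(roles)), roles$accession)

  targets <- unique(ed$to[ed$kind == "cleavage"])
  if (length(targets)) {
    tp <- roles$is_protease[rn[targets]]
    ti <- roles$is_inhibitor[rn[targets]] & !tp
    fr <- c(protease = mean(tp), inhibitor = mean(ti), other = mean(!tp & !ti))
  } else {
    fr <- c(protease = NA_real_, inhibitor = NA_real_, other = NA_real_)
  }
  lcc <- if (n_nodes(web) > 0L) {
    g <- as_igraph(web)
    max(igraph::components(g, mode = "weak")$csize)
  } else 0L

  structure(list(
    n_nodes = n_nodes(web),
    n_edges = n_edges(web),
    n_proteases_with_substrates = length(unique(ed$from[ed$kind == "cleavage"])),
    n_inhibitors_with_targets = length(unique(ed$from[ed$kind == "inhibition"])),
    lcc_size = as.integer(lcc),
    substrate_role_fractions = fr
  ), class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat("protease-web composition\n")
  cat(sprintf("  nodes %d, edges %d, largest component %d\n",
              x$n_nodes, x$n_edges, x$lcc_size))
  cat(sprintf("  proteases with substrates: %d; inhibitors with targets: %d\n",
              x$n_proteases_with_substrates, x$n_inhibitors_with_targets))
  if (!anyNA(x$substrate_role_fractions)) {
    cat(sprintf("  cleavage targets: %.0f%% proteases, %.0f%% inhibitors, %.0f%% other\n",
                100 * x$substrate_role_fractions[["protease"]],
                100 * x$substrate_role_fractions[["inhibitor"]],
                100 * x$substrate_role_fractions[["other"]]))
  }
  invisible(x)
}

# Single class label per node: proteases by catalytic class, otherwise
# inhibitors by their (possibly broad) inhibitor class. NA when unclassed.
node_class_label <- function(web) {
  nd <- web$nodes
  roles <- node_roles(web)
  inh_cls <- vapply(split_classes(nd$inhibitor_classes), function(cl) {
    cl <- cl[nzchar(cl)]
    if (!length(cl)) NA_character_
    else if (length(cl) > 1L || "broad" %in% cl) "broad"
    else cl
  }, character(1))
  lab <- ifelse(nd$catalytic_class != "none",
                paste0("protease_", nd$catalytic_class),
                ifelse(!is.na(inh_cls), paste0("inhibitor_", inh_cls), NA_character_))
  stats::setNames(lab, nd$accession)
}

#' Interaction counts between protease and inhibitor classes
#'
#' Aggregates edges by (source class, target class, kind). Protease nodes
#' are classed by catalytic class (`A`, `C`, `M`, `S`, `T`); inhibitor
#' nodes by inhibitor class, collapsing multi-class annotations to
#' `broad`. Edges with an unclassed endpoint are excluded from the
#' matrices and tallied in a per-kind remainder.
#'
#' @param web A [protease_web()] object.
#' @return A list of class `class_interaction_summary` with elements
#'   `cleavage` and `inhibition` (count matrices over class labels),
#'   `class_sizes` (members per class label) and `remainder` (excluded
#'   edge counts per kind).
#' @export
class_interaction_matrix <- function(web) {
  stopifnot(inherits(web, "protease_web"))
  labels <- node_class_label(web)
  levs <- c(paste0("protease_", CATALYTIC_CLASSES),
            paste0("inhibitor_", INHIBITOR_CLASSES))
  ed <- web$edges
  src <- labels[ed$from]
  tgt <- labels[ed$to]
  classed <- !is.na(src) & !is.na(tgt)

  one_kind <- function(kind) {
    sel <- classed & ed$kind == kind
    as.matrix(table(factor(src[sel], levels = levs),
                    factor(tgt[sel], levels = levs)))
  }
  remainder <- c(
    cleavage = sum(!classed & ed$kind == "cleavage"),
    inhibition = sum(!classed & ed$kind == "inhibition")
  )
  structure(list(
    cleavage = one_kind("cleavage"),
    inhibition = one_kind("inhibition"),
    class_sizes = table(factor(labels, levels = levs)),
    remainder = remainder
  ), class = "class_interaction_summary")
}

#' @export
print.class_interaction_summary <- function(x, ...) {
  cat("class interaction summary\n")
  cat("  classed cleavages:", sum(x$cleavage),
      " classed inhibitions:", sum(x$inhibition), "\n")
  cat("  unclassed remainder:", x$remainder[["cleavage"]], "cleavage,",
      x$remainder[["inhibition"]], "inhibition\n")
  invisible(x)
}

#' Edge overlap between two networks under an ortholog mapping
#'
#' Counts edges shared between two networks (e.g. two species) given a
#' possibly many-to-many accession mapping from graph `b` to graph `a`. An
#' edge of `b` counts as shared if any mapped (source, target) pair is an
#' edge of `a`; by default the edge kind is ignored when matching
#' (connections are compared, not mechanisms).
#'
#' @param graph_a,graph_b [protease_web()] objects.
#' @param ortholog_map Data frame whose first column holds accessions of
#'   `graph_b` and second column the corresponding accessions of `graph_a`.
#' @param kind_sensitive If `TRUE`, a match additionally requires equal
#'   edge kind.
#' @return List with `shared_b`, `shared_a` (matched edge counts),
#'   `total_a`, `total_b`, `fraction_a`, `fraction_b`.
#' @export
network_overlap <- function(graph_a, graph_b, ortholog_map,
                            kind_sensitive = FALSE) {
  stopifnot(inherits(graph_a, "protease_web"), inherits(graph_b, "protease_web"))
  map <- as.data.frame(ortholog_map)
  if (nrow(map) == 0L) {
    warning("empty ortholog map: overlap is zero by construction", call. = FALSE)
  }
  b2a <- split(as.character(map[[2L]]), as.character(map[[1L]]))

  edge_key <- function(ed) {
    if (kind_sensitive) paste(ed$from, ed$to, ed$kind, sep = "\r")
    else paste(ed$from, ed$to, sep = "\r")
  }
  a_keys <- unique(edge_key(graph_a$edges))

  ed_b <- graph_b$edges
  matched_a <- character(0)
  shared_b <- 0L
  for (i in seq_len(nrow(ed_b))) {
    srcs <- b2a[[ed_b$from[i]]]
    tgts <- b2a[[ed_b$to[i]]]
    if (is.null(srcs) || is.null(tgts)) next
    pairs <- expand.grid(srcs, tgts, stringsAsFactors = FALSE)
    keys <- if (kind_sensitive) paste(pairs[[1]], pairs[[2]], ed_b$kind[i], sep = "\r")
            else paste(pairs[[1]], pairs[[2]], sep = "\r")
    hit <- keys %in% a_keys
    if (any(hit)) {
      shared_b <- shared_b + 1L
      matched_a <- c(matched_a, keys[hit])
    }
  }
  shared_a <- sum(edge_key(graph_a$edges) %in% matched_a)
  total_a <- nrow(graph_a$edges)
  total_b <- nrow(ed_b)
  list(
    shared_a = shared_a, shared_b = shared_b,
    total_a = total_a, total_b = total_b,
    fraction_a = if (total_a) shared_a / total_a else NA_real_,
    fraction_b = if (total_b) shared_b / total_b else NA_real_
  )
}
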