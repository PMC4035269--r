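#' Directed protease-web graph
#'
#' Container for a directed multigraph of cleavage and inhibition edges
#' between annotated proteins. Nodes are proteins identified by an opaque
#' accession; edges are directed and carry a `kind` (`"cleavage"`: protease
#' to substrate; `"inhibition"`: inhibitor to inhibited protease). At most
#' one edge is stored per (source, target, kind) triple. Self-loops
#' (autolysis) may be stored but are ignored by all path-based metrics, as
#' are kind distinctions: two stored edges between the same ordered pair
#' contribute a single arc to connectivity.
#'
#' @param nodes Data frame with at least an `accession` column. Optional
#'   annotation columns: `gene_name`, `merops_id`, `catalytic_class` (one of
#'   `"A"`, `"C"`, `"M"`, `"S"`, `"T"`, `"none"`), `inhibitor_classes`
#'   (semicolon-joined subset of `"A"`, `"C"`, `"M"`, `"S"`, `"T"`,
#'   `"broad"`; empty string for none), `trap_inhibitor` (logical or 0/1,
#'   A2M/PZP-style physical trap). Missing columns are filled with
#'   unannotated defaults.
#' @param edges Data frame with columns `from`, `to`, `kind` and optional
#'   `relevance` (`"yes"`, `"no"`, `"unknown"`; cleavages only) and
#'   `source` (free-text provenance). Must not contain duplicated
#'   (from, to, kind) triples; [build_graph()] collapses duplicates first.
#' @param provenance Single string labelling the construction (e.g.
#'   `"full network"`, `"protease web"`, a perturbation label).
#'
#' @details Protein roles are derived, not stored: a node is a protease if
#'   its catalytic class is not `"none"` or it emits a cleavage edge or it
#'   is the target of an inhibition; an inhibitor if it carries inhibitor
#'   classes or emits an inhibition edge; substrate-only otherwise. This
#'   keeps minimally-annotated graphs (e.g. null-model networks or graphs
#'   imported from a bare edge list) usable by every metric, while
#'   [load_tables()] enforces the stricter annotation invariants on real
#'   input tables.
#'
#' @return An object of class `protease_web` with elements `nodes`,
#'   `edges` and `provenance`.
#' @seealso [build_graph()], [load_tables()], [reachability()]
#' @export
#' @examples
#' nodes <- data.frame(accession = c("P1", "S1"), catalytic_class = c("M", "none"))
#' edges <- data.frame(from = "P1", to = "S1", kind = "cleavage")
#' protease_web(nodes, edges, provenance = "toy")
protease_web <- function(nodes, edges, provenance = "network") {
  check_string(provenance, "provenance")
  nodes <- normalize_nodes(nodes)
  edges <- normalize_edges(edges)
  if (anyDuplicated(nodes$accession)) {
    stop_pw("duplicate accession(s): ",
            paste(unique(nodes$accession[duplicated(nodes$accession)]), collapse = ", "))
  }
  key <- paste(edges$from, edges$to, edges$kind, sep = "\r")
  if (anyDuplicated(key)) {
    stop_pw("duplicated (source, target, kind) edge triples; ",
            "use build_graph() to collapse duplicate input rows")
  }
  missing <- setdiff(c(edges$from, edges$to), nodes$accession)
  if (length(missing)) {
    stop_pw("edge endpoint(s) absent from node table: ",
            paste(utils::head(missing, 5L), collapse = ", "))
  }
  structure(
    list(nodes = nodes, edges = edges, provenance = provenance),
    class = "protease_web"
  )
}

CATALYTIC_CLASSES <- c("A", "C", "M", "S", "T")
INHIBITOR_CLASSES <- c("A", "C", "M", "S", "T", "broad")

normalize_nodes <- function(nodes) {
  if (!is.data.frame(nodes) || !"accession" %in% names(nodes)) {
    stop_pw("nodes must be a data frame with an 'accession' column")
  }
  n <- nrow(nodes)
  out <- data.frame(
    accession = as.character(nodes$accession),
    gene_name = if ("gene_name" %in% names(nodes)) as.character(nodes$gene_name) else rep(NA_character_, n),
    merops_id = if ("merops_id" %in% names(nodes)) as.character(nodes$merops_id) else rep(NA_character_, n),
    catalytic_class = if ("catalytic_class" %in% names(nodes)) as.character(nodes$catalytic_class) else rep("none", n),
    inhibitor_classes = if ("inhibitor_classes" %in% names(nodes)) as.character(nodes$inhibitor_classes) else rep("", n),
    trap_inhibitor = if ("trap_inhibitor" %in% names(nodes)) as.logical(nodes$trap_inhibitor) else rep(FALSE, n),
    stringsAsFactors = FALSE
  )
  out$merops_id[!is.na(out$merops_id) & out$merops_id == ""] <- NA_character_
  out$gene_name[!is.na(out$gene_name) & out$gene_name == ""] <- NA_character_
  out$catalytic_class[is.na(out$catalytic_class) | out$catalytic_class == ""] <- "none"
  out$inhibitor_classes[is.na(out$inhibitor_classes)] <- ""
  out$trap_inhibitor[is.na(out$trap_inhibitor)] <- FALSE
  bad <- !out$catalytic_class %in% c(CATALYTIC_CLASSES, "none")
  if (any(bad)) {
    stop_pw("invalid catalytic_class: ", paste(unique(out$catalytic_class[bad]), collapse = ", "))
  }
  for (cls in split_classes(out$inhibitor_classes)) {
    bad <- setdiff(cls, INHIBITOR_CLASSES)
    if (length(bad)) stop_pw("invalid inhibitor class: ", paste(bad, collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

normalize_edges <- function(edges) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    return(data.frame(from = character(), to = character(), kind = character(),
                      relevance = character(), source = character(),
                      stringsAsFactors = FALSE))
  }
  edges <- as.data.frame(edges)
  req <- c("from", "to", "kind")
  miss <- setdiff(req, names(edges))
  if (length(miss)) stop_pw("edge table is missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(
    from = as.character(edges$from),
    to = as.character(edges$to),
    kind = as.character(edges$kind),
    relevance = if ("relevance" %in% names(edges)) as.character(edges$relevance) else rep(NA_character_, nrow(edges)),
    source = if ("source" %in% names(edges)) as.character(edges$source) else rep(NA_character_, nrow(edges)),
    stringsAsFactors = FALSE
  )
  bad <- !out$kind %in% c("cleavage", "inhibition")
  if (any(bad)) stop_pw("edge kind must be 'cleavage' or 'inhibition'")
  badrel <- !is.na(out$relevance) & !out$relevance %in% c("yes", "no", "unknown")
  if (any(badrel)) stop_pw("physiological relevance must be 'yes', 'no' or 'unknown'")
  rownames(out) <- NULL
  out
}

split_classes <- function(x) strsplit(x, ";", fixed = TRUE)

#' @export
print.protease_web <- function(x, ...) {
  kinds <- table(factor(x$edges$kind, levels = c("cleavage", "inhibition")))
  cat("protease web [", x$provenance, "]\n", sep = "")
  cat("  nodes: ", nrow(x$nodes), "\n", sep = "")
  cat("  edges: ", nrow(x$edges),
      " (", kinds[["cleavage"]], " cleavage, ", kinds[["inhibition"]], " inhibition)\n", sep = "")
  invisible(x)
}

#' @export
summary.protease_web <- function(object, ...) {
  composition_stats(object)
}

#' Number of nodes / edges in a protease web
#'
#' @param web A [protease_web()] object.
#' @return Integer count.
#' @export
n_nodes <- function(web) {
  stopifnot(inherits(web, "protease_web"))
  nrow(web$nodes)
}

#' @rdname n_nodes
#' @export
n_edges <- function(web) {
  stopifnot(inherits(web, "protease_web"))
  nrow(web$edges)
}

#' Derived protein roles
#'
#' Roles are derived from annotations and edge participation: protease
#' (non-`"none"` catalytic class, emits a cleavage, or is inhibited),
#' inhibitor (annotated inhibitor classes or emits an inhibition),
#' substrate-only (neither).
#'
#' @param web A [protease_web()] object.
#' @return Data frame with columns `accession`, `is_protease`,
#'   `is_inhibitor`, `substrate_only`.
#' @export
node_roles <- function(web) {
  stopifnot(inherits(web, "protease_web"))
  nd <- web$nodes
  ed <- web$edges
  cleaver <- nd$accession %in% ed$from[ed$kind == "cleavage"]
  inhibited <- nd$accession %in% ed$to[ed$kind == "inhibition"]
  inhibits <- nd$accession %in% ed$from[ed$kind == "inhibition"]
  is_protease <- nd$catalytic_class != "none" | cleaver | inhibited
  is_inhibitor <- nzchar(nd$inhibitor_classes) | inhibits
  data.frame(
    accession = nd$accession,
    is_protease = is_protease,
    is_inhibitor = is_inhibitor,
    substrate_only = !is_protease & !is_inhibitor,
    stringsAsFactors = FALSE
  )
}

# igraph view of the web. collapse = TRUE drops self-loops and merges
# parallel cleavage/inhibition edges into single arcs, which is the
# representation every path/reachability metric works on.
as_igraph <- function(web, collapse = TRUE) {
  stopifnot(inherits(web, "protease_web"))
  ed <- web$edges
  if (collapse) {
    ed <- ed[ed$from != ed$to, c("from", "to"), drop = FALSE]
    ed <- unique(ed)
  }
  igraph::graph_from_data_frame(ed, directed = TRUE, vertices = web$nodes)
}

# Induced subgraph on a set of accessions; provenance relabelled.
induce_web <- function(web, keep, provenance = web$provenance) {
  keep <- unique(keep)
  nd <- web$nodes[web$nodes$accession %in% keep, , drop = FALSE]
  ed <- web$edges[web$edges$from %in% keep & web$edges$to %in% keep, , drop = FALSE]
  protease_web(nd, ed, provenance = provenance)
}

# Replace the edge set, keeping the node table fixed (node-frozen
# perturbations rely on this).
replace_edges <- function(web, edges, provenance = web$provenance) {
  protease_web(web$nodes, edges, provenance = provenance)
}
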