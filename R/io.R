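#' Export / import a protease-web graph
#'
#' Supported formats: `"graphml"` and `"gml"` (full node and edge
#' attributes plus the provenance label, via igraph's writers) and
#' `"tsv"`, a canonical edge list with columns `source`, `target`, `kind`
#' sorted lexicographically so that exports diff bit-exactly. The TSV
#' dialect stores the provenance in a leading `#provenance:` comment and
#' carries no node annotations; a graph imported from TSV has its node
#' roles derived from the edges alone.
#'
#' @param web A [protease_web()] object.
#' @param path Output (or input) file path.
#' @param format One of `"tsv"`, `"graphml"`, `"gml"`; for
#'   [import_graph()], `"auto"` guesses from the file extension.
#' @return `export_graph()` returns `path` invisibly; `import_graph()`
#'   returns a [protease_web()].
#' @export
export_graph <- function(web, path, format = c("tsv", "graphml", "gml")) {
  stopifnot(inherits(web, "protease_web"))
  format <- match.arg(format)
  if (format == "tsv") {
    ed <- web$edges[order(web$edges$from, web$edges$to, web$edges$kind,
                          method = "radix"), , drop = FALSE]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("#provenance:", web$provenance),
                 "source\ttarget\tkind"), con)
    if (nrow(ed)) {
      writeLines(paste(ed$from, ed$to, ed$kind, sep = "\t"), con)
    }
    return(invisible(path))
  }
  g <- web_to_attributed_igraph(web, gml_names = format == "gml")
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

# GML restricts attribute keys to alphanumerics, so underscores are
# dropped there and restored on import.
ATTR_MAP <- c(gene_name = "geneName", merops_id = "meropsId",
              catalytic_class = "catalyticClass",
              inhibitor_classes = "inhibitorClasses",
              trap_inhibitor = "trapInhibitor")

web_to_attributed_igraph <- function(web, gml_names = FALSE) {
  nd <- web$nodes
  nd$trap_inhibitor <- as.integer(nd$trap_inhibitor)
  nd$gene_name[is.na(nd$gene_name)] <- ""
  nd$merops_id[is.na(nd$merops_id)] <- ""
  ed <- web$edges
  ed$relevance[is.na(ed$relevance)] <- ""
  ed$source[is.na(ed$source)] <- ""
  names(ed)[names(ed) == "source"] <- "origin"  # avoid clash with endpoint column
  if (gml_names) names(nd) <- c("accession", unname(ATTR_MAP))
  g <- igraph::graph_from_data_frame(ed, directed = TRUE, vertices = nd)
  igraph::graph_attr(g, "provenance") <- web$provenance
  g
}

#' @rdname export_graph
#' @export
import_graph <- function(path, format = c("auto", "tsv", "graphml", "gml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv",
                     graphml = "graphml", gml = "gml",
                     stop_pw("cannot guess graph format from extension: ", path))
  }
  if (!file.exists(path)) stop_pw("file not found: ", path)
  if (format == "tsv") return(import_graph_tsv(path))

  g <- igraph::read_graph(path, format = format)
  va <- igraph::vertex_attr(g)
  ea <- igraph::edge_attr(g)
  pick <- function(attrs, key) attrs[[key]] %||% attrs[[unname(ATTR_MAP[key])]]
  blank_na <- function(x) { if (is.null(x)) return(NULL); x[x == ""] <- NA; x }
  nodes <- data.frame(
    accession = va$name %||% as.character(seq_len(igraph::vcount(g))),
    stringsAsFactors = FALSE)
  nodes$gene_name <- blank_na(pick(va, "gene_name"))
  nodes$merops_id <- blank_na(pick(va, "merops_id"))
  nodes$catalytic_class <- pick(va, "catalytic_class")
  nodes$inhibitor_classes <- pick(va, "inhibitor_classes")
  nodes$trap_inhibitor <- as.logical(as.integer(pick(va, "trap_inhibitor") %||% 0L))
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- data.frame(from = el[, 1L], to = el[, 2L],
                      kind = ea$kind, stringsAsFactors = FALSE)
  edges$relevance <- blank_na(ea$relevance)
  edges$source <- blank_na(ea$origin)
  prov <- igraph::graph_attr(g, "provenance") %||% "imported"
  protease_web(nodes, edges, provenance = prov)
}

import_graph_tsv <- function(path) {
  lines <- readLines(path)
  prov <- "imported"
  offset <- 1L  # file line of the header
  if (length(lines) && startsWith(lines[1L], "#provenance:")) {
    prov <- sub("^#provenance:", "", lines[1L])
    lines <- lines[-1L]
    offset <- 2L
  }
  if (!length(lines) || lines[1L] != "source\ttarget\tkind") {
    stop_pw("malformed edge-list TSV (expected 'source\\ttarget\\tkind' header): ",
            path, " line ", 1L)
  }
  body <- lines[-1L]
  keep <- which(nzchar(body))
  if (!length(keep)) {
    return(protease_web(data.frame(accession = character(0)), NULL,
                        provenance = prov))
  }
  parts <- strsplit(body[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop_pw("malformed edge-list TSV at line ", keep[bad[1L]] + offset, ": ", path)
  }
  m <- do.call(rbind, parts)
  edges <- data.frame(from = m[, 1L], to = m[, 2L], kind = m[, 3L],
                      stringsAsFactors = FALSE)
  nodes <- data.frame(accession = sort(unique(c(edges$from, edges$to))),
                      stringsAsFactors = FALSE)
  protease_web(nodes, edges, provenance = prov)
}
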