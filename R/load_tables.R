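#' Read protein, cleavage and inhibition annotation tables
#'
#' Parses the three tab-separated tables describing a protease-web dataset
#' and validates them against the record invariants. The dialect mirrors a
#' TopFIND-style export:
#'
#' * protein table: `accession`, `gene_name`, `merops_id`,
#'   `catalytic_class`, `inhibitor_classes` (semicolon-joined),
#'   `trap_inhibitor` (0/1);
#' * cleavage table: `protease_acc`, `substrate_acc`,
#'   `physiological_relevance` (`yes`/`no`/`unknown`), `source`;
#' * inhibition table: `inhibitor_acc`, `protease_acc`.
#'
#' @param protein_table,cleavage_table,inhibition_table Paths to TSV files,
#'   or data frames with the same columns.
#' @param strict If `TRUE` (default), any edge row referencing an accession
#'   absent from the protein table, a cleavage whose protease lacks a
#'   catalytic class, or an inhibition whose inhibitor lacks an inhibitor
#'   class is an error naming the offending row; if `FALSE`, such rows are
#'   dropped with a warning.
#' @return A list with validated data frames `proteins`, `cleavages`,
#'   `inhibitions`.
#' @seealso [build_graph()]
#' @export
load_tables <- function(protein_table, cleavage_table, inhibition_table,
                        strict = TRUE) {
  proteins <- read_tsv_table(protein_table, "protein table",
    c("accession", "gene_name", "merops_id", "catalytic_class",
      "inhibitor_classes", "trap_inhibitor"))
  cleavages <- read_tsv_table(cleavage_table, "cleavage table",
    c("protease_acc", "substrate_acc", "physiological_relevance", "source"))
  inhibitions <- read_tsv_table(inhibition_table, "inhibition table",
    c("inhibitor_acc", "protease_acc"))

  proteins <- normalize_nodes(
    data.frame(accession = proteins$accession, gene_name = proteins$gene_name,
               merops_id = proteins$merops_id,
               catalytic_class = proteins$catalytic_class,
               inhibitor_classes = proteins$inhibitor_classes,
               trap_inhibitor = as.logical(as.integer(proteins$trap_inhibitor)),
               stringsAsFactors = FALSE))
  if (anyDuplicated(proteins$accession)) {
    stop_pw("duplicate accession(s) in protein table: ",
            paste(unique(proteins$accession[duplicated(proteins$accession)]),
                  collapse = ", "))
  }
  # trap inhibitors must be inhibitors
  bad <- proteins$trap_inhibitor & !nzchar(proteins$inhibitor_classes)
  if (any(bad)) {
    stop_pw("trap_inhibitor set for protein(s) without inhibitor classes: ",
            paste(proteins$accession[bad], collapse = ", "))
  }

  cleavages$physiological_relevance[is.na(cleavages$physiological_relevance) |
                                      cleavages$physiological_relevance == ""] <- "unknown"
  badrel <- !cleavages$physiological_relevance %in% c("yes", "no", "unknown")
  if (any(badrel)) {
    stop_pw("invalid physiological_relevance value(s): ",
            paste(unique(cleavages$physiological_relevance[badrel]), collapse = ", "))
  }

  is_prot <- proteins$catalytic_class != "none"
  is_inh <- nzchar(proteins$inhibitor_classes)
  prot_acc <- proteins$accession[is_prot]
  inh_acc <- proteins$accession[is_inh]

  cleavages <- drop_or_fail(
    cleavages,
    ok = cleavages$protease_acc %in% prot_acc &
      cleavages$substrate_acc %in% proteins$accession,
    what = "cleavage", strict = strict)
  inhibitions <- drop_or_fail(
    inhibitions,
    ok = inhibitions$inhibitor_acc %in% inh_acc &
      inhibitions$protease_acc %in% prot_acc,
    what = "inhibition", strict = strict)

  list(proteins = proteins, cleavages = cleavages, inhibitions = inhibitions)
}

read_tsv_table <- function(x, what, required) {
  if (is.character(x)) {
    if (!file.exists(x)) stop_pw(what, ": file not found: ", x)
    x <- utils::read.delim(x, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           comment.char = "", check.names = FALSE)
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    stop_pw(what, ": missing required column(s): ", paste(miss, collapse = ", "))
  }
  for (cc in required) x[[cc]] <- as.character(x[[cc]])
  x[required]
}

drop_or_fail <- function(tab, ok, what, strict) {
  if (all(ok)) return(tab)
  rows <- which(!ok)
  if (strict) {
    stop_pw(what, " row(s) reference unknown or mis-annotated accessions: row ",
            paste(utils::head(rows, 5L), collapse = ", "))
  }
  warning(sprintf("dropping %d %s row(s) with unresolved accessions", length(rows), what),
          call. = FALSE)
  tab[ok, , drop = FALSE]
}

#' Build the directed protease-web graph from validated records
#'
#' Cleavages become directed edges protease -> substrate, inhibitions
#' inhibitor -> inhibited protease. Only proteins taking part in at least
#' one edge enter the node set (proteins performing an annotated cleavage
#' or inhibition, plus their targets). Duplicate input rows are collapsed
#' to one stored edge per (source, target, kind) with the multiplicity
#' reported via a message.
#'
#' @param proteins,cleavages,inhibitions Data frames as returned by
#'   [load_tables()] (or a single list with those elements passed as
#'   `proteins`).
#' @param provenance Construction label, default `"full network"`.
#' @return A [protease_web()] object.
#' @export
#' @examples
#' tabs <- generate_web(synthetic_web_params(seed = 1))
#' web <- build_graph(tabs$proteins, tabs$cleavages, tabs$inhibitions)
#' web
build_graph <- function(proteins, cleavages = NULL, inhibitions = NULL,
                        provenance = "full network") {
  if (is.list(proteins) && !is.data.frame(proteins) &&
      all(c("proteins", "cleavages", "inhibitions") %in% names(proteins))) {
    cleavages <- proteins$cleavages
    inhibitions <- proteins$inhibitions
    proteins <- proteins$proteins
  }
  cl <- if (NROW(cleavages)) {
    data.frame(from = as.character(cleavages$protease_acc),
               to = as.character(cleavages$substrate_acc),
               kind = "cleavage",
               relevance = as.character(cleavages$physiological_relevance %||%
                                          rep("unknown", nrow(cleavages))),
               source = if ("source" %in% names(cleavages)) as.character(cleavages$source) else NA_character_,
               stringsAsFactors = FALSE)
  } else NULL
  ih <- if (NROW(inhibitions)) {
    data.frame(from = as.character(inhibitions$inhibitor_acc),
               to = as.character(inhibitions$protease_acc),
               kind = "inhibition", relevance = NA_character_,
               source = NA_character_, stringsAsFactors = FALSE)
  } else NULL
  edges <- rbind(cl, ih)

  if (is.null(edges) || nrow(edges) == 0L) {
    warning("no cleavage or inhibition edges; returning an empty graph", call. = FALSE)
    empty <- normalize_nodes(proteins)[0, , drop = FALSE]
    return(protease_web(empty, NULL, provenance = provenance))
  }

  key <- paste(edges$from, edges$to, edges$kind, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    mult <- table(key[key %in% key[dup]])
    message(sprintf("collapsed %d duplicate edge row(s) across %d edge(s) (max multiplicity %d)",
                    sum(dup), length(mult), max(mult)))
    edges <- edges[!dup, , drop = FALSE]
  }

  participating <- unique(c(edges$from, edges$to))
  nodes <- normalize_nodes(proteins)
  nodes <- nodes[nodes$accession %in% participating, , drop = FALSE]
  missing <- setdiff(participating, nodes$accession)
  if (length(missing)) {
    stop_pw("edge(s) reference accessions absent from the protein table: ",
            paste(utils::head(missing, 5L), collapse = ", "))
  }
  protease_web(nodes, edges, provenance = provenance)
}
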