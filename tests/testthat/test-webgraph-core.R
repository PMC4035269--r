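# Table parsing, graph construction, restriction, components, composition
# and class-matrix summaries, overlap counting.

toy_tables <- function() {
  proteins <- data.frame(
    accession = c("P1", "P2", "I1", "S1"),
    gene_name = c("PRT1", "PRT2", "INH1", "SUB1"),
    merops_id = c("M10.001", "S01.001", "I04.001", NA),
    catalytic_class = c("M", "S", "none", "none"),
    inhibitor_classes = c("", "", "S", ""),
    trap_inhibitor = c(0, 0, 0, 0))
  cleavages <- data.frame(
    protease_acc = c("P1", "P1"), substrate_acc = c("P2", "S1"),
    physiological_relevance = c("yes", "unknown"), source = "curated")
  inhibitions <- data.frame(inhibitor_acc = "I1", protease_acc = "P2")
  list(proteins = proteins, cleavages = cleavages, inhibitions = inhibitions)
}

test_that("load_tables parses TSVs, validates records and honours strict mode", {
  tt <- toy_tables()
  dir <- withr::local_tempdir()
  paths <- write_web_tables(tt, dir)
  loaded <- load_tables(paths[["proteins"]], paths[["cleavages"]],
                        paths[["inhibitions"]])
  expect_equal(nrow(loaded$proteins), 4L)
  expect_equal(nrow(loaded$cleavages), 2L)
  expect_equal(nrow(loaded$inhibitions), 1L)
  expect_identical(loaded$proteins$merops_id[4], NA_character_)

  # data-frame inputs behave like files
  direct <- load_tables(tt$proteins, tt$cleavages, tt$inhibitions)
  expect_equal(direct$cleavages, loaded$cleavages)

  # missing column named in the error
  broken <- tt$cleavages[, -1]
  expect_error(load_tables(tt$proteins, broken, tt$inhibitions), "protease_acc")

  # unknown accession: strict errors with the row, lenient drops with warning
  bad <- rbind(tt$cleavages,
               data.frame(protease_acc = "PX", substrate_acc = "S1",
                          physiological_relevance = "yes", source = "x"))
  expect_error(load_tables(tt$proteins, bad, tt$inhibitions), "row 3")
  expect_warning(
    lenient <- load_tables(tt$proteins, bad, tt$inhibitions, strict = FALSE),
    "dropping")
  expect_equal(nrow(lenient$cleavages), 2L)

  # duplicate accessions rejected
  dup <- rbind(tt$proteins, tt$proteins[1, ])
  expect_error(load_tables(dup, tt$cleavages, tt$inhibitions), "duplicate")
})

test_that("build_graph collapses duplicates, orients edges and keeps participants only", {
  tt <- toy_tables()
  tt$proteins <- rbind(tt$proteins,
                       data.frame(accession = "LONER", gene_name = "L",
                                  merops_id = "M99.9", catalytic_class = "M",
                                  inhibitor_classes = "", trap_inhibitor = 0))
  tt$cleavages <- rbind(tt$cleavages, tt$cleavages[1, ])  # duplicate row
  expect_message(web <- build_graph(tt$proteins, tt$cleavages, tt$inhibitions),
                 "multiplicity 2")
  expect_equal(n_edges(web), 3L)
  expect_false("LONER" %in% web$nodes$accession)  # no edge, not added

  # P cleaves I and I inhibits P: two edges, opposite direction, distinct kind
  nodes <- data.frame(accession = c("P", "I"), catalytic_class = c("S", "none"),
                      inhibitor_classes = c("", "S"))
  cl <- data.frame(protease_acc = "P", substrate_acc = "I",
                   physiological_relevance = "yes", source = "x")
  ih <- data.frame(inhibitor_acc = "I", protease_acc = "P")
  mutual <- build_graph(nodes, cl, ih)
  expect_equal(n_edges(mutual), 2L)
  expect_setequal(paste(mutual$edges$from, mutual$edges$to, mutual$edges$kind),
                  c("P I cleavage", "I P inhibition"))

  # empty edge set: warning plus a valid empty graph
  expect_warning(empty <- build_graph(tt$proteins, NULL, NULL), "empty")
  expect_equal(n_nodes(empty), 0L)
})

test_that("synthetic tables round-trip through load_tables strictly with no warnings", {
  tabs <- generate_web(synthetic_web_params(seed = 7))
  dir <- withr::local_tempdir()
  paths <- write_web_tables(tabs, dir)
  expect_no_warning(
    loaded <- load_tables(paths[["proteins"]], paths[["cleavages"]],
                          paths[["inhibitions"]], strict = TRUE))
  expect_equal(nrow(loaded$cleavages), tabs$report$n_cleavage_rows)
  expect_equal(nrow(loaded$inhibitions), tabs$report$n_inhibition_rows)
  web <- build_graph(loaded)
  expect_lte(n_nodes(web), tabs$report$n_protein_rows)
  expect_equal(n_edges(web),
               tabs$report$n_cleavage_rows + tabs$report$n_inhibition_rows)
})

test_that("restrict_to_protease_web keeps MEROPS-ID nodes only and is idempotent", {
  tt <- toy_tables()
  web <- build_graph(tt$proteins, tt$cleavages, tt$inhibitions)
  pw <- restrict_to_protease_web(web)
  expect_setequal(pw$nodes$accession, c("P1", "P2", "I1"))  # S1 dropped
  expect_false(any(pw$edges$to == "S1"))
  again <- restrict_to_protease_web(pw)
  expect_identical(again$nodes, pw$nodes)
  expect_identical(again$edges, pw$edges)
  # monotone: never adds
  expect_lte(n_nodes(pw), n_nodes(web))
  expect_lte(n_edges(pw), n_edges(web))

  # no MEROPS IDs at all -> empty graph
  bare <- protease_web(data.frame(accession = c("A", "B")),
                       data.frame(from = "A", to = "B", kind = "cleavage"))
  expect_equal(n_nodes(restrict_to_protease_web(bare)), 0L)
})

test_that("largest_connected_component honours mode, ties and direction-reversal invariance", {
  # two disjoint chains, sizes 3 and 2
  nodes <- data.frame(accession = c("A", "B", "C", "X", "Y"))
  edges <- data.frame(from = c("A", "B", "X"), to = c("B", "C", "Y"),
                      kind = "cleavage")
  web <- protease_web(nodes, edges)
  expect_setequal(largest_connected_component(web)$nodes$accession,
                  c("A", "B", "C"))

  # strong mode on a directed 4-cycle keeps all nodes
  expect_equal(n_nodes(largest_connected_component(cycle_web(4), "strong")), 4L)
  # ...but a chain's strong components are singletons
  expect_equal(n_nodes(largest_connected_component(chain_web(), "strong")), 1L)

  # tie: two 2-chains; smallest lexicographic member wins
  tied <- protease_web(data.frame(accession = c("B1", "B2", "A1", "A2")),
                       data.frame(from = c("B1", "A1"), to = c("B2", "A2"),
                                  kind = "cleavage"))
  expect_setequal(largest_connected_component(tied)$nodes$accession,
                  c("A1", "A2"))

  # weak LCC size invariant under edge reversal
  for (s in 1:5) {
    w <- random_web(10, p = 0.12, seed = s)
    rev <- protease_web(w$nodes,
                        data.frame(from = w$edges$to, to = w$edges$from,
                                   kind = w$edges$kind))
    expect_equal(n_nodes(largest_connected_component(w)),
                 n_nodes(largest_connected_component(rev)))
  }

  expect_error(largest_connected_component(
    protease_web(data.frame(accession = character(0)), NULL)), "empty")
})

test_that("composition_stats counts roles, participants and target fractions", {
  tt <- toy_tables()
  web <- build_graph(tt$proteins, tt$cleavages, tt$inhibitions)
  st <- composition_stats(web)
  expect_equal(st$n_nodes, 4L)
  expect_equal(st$n_edges, 3L)
  expect_equal(st$n_proteases_with_substrates, 1L)  # P1 only
  expect_equal(st$n_inhibitors_with_targets, 1L)
  expect_equal(st$lcc_size, 4L)
  # targets of cleavage: P2 (protease), S1 (other)
  expect_equal(unname(st$substrate_role_fractions),
               c(0.5, 0, 0.5))
  expect_equal(sum(st$substrate_role_fractions), 1)

  # single edge P -> S
  single <- protease_web(data.frame(accession = c("P", "S"),
                                    catalytic_class = c("M", "none")),
                         data.frame(from = "P", to = "S", kind = "cleavage"))
  s1 <- composition_stats(single)
  expect_equal(s1$n_proteases_with_substrates, 1L)
  expect_equal(s1$n_inhibitors_with_targets, 0L)

  # all cleavage targets proteases -> fractions (1, 0, 0)
  allp <- protease_web(data.frame(accession = c("P", "Q"),
                                  catalytic_class = c("M", "S")),
                       data.frame(from = "P", to = "Q", kind = "cleavage"))
  expect_equal(unname(composition_stats(allp)$substrate_role_fractions),
               c(1, 0, 0))

  # totals conserved under accession relabeling
  tabs <- generate_web(synthetic_web_params(seed = 3))
  web2 <- build_graph(tabs)
  set.seed(42)
  perm <- setNames(sprintf("X%04d", sample(n_nodes(web2))), web2$nodes$accession)
  relabeled <- protease_web(
    transform(web2$nodes, accession = unname(perm[accession])),
    transform(web2$edges, from = unname(perm[from]), to = unname(perm[to])),
    provenance = "relabeled")
  a <- composition_stats(web2); b <- composition_stats(relabeled)
  expect_equal(a[names(a) != "substrate_role_fractions"],
               b[names(b) != "substrate_role_fractions"])
  expect_equal(a$substrate_role_fractions, b$substrate_role_fractions)
})

test_that("class_interaction_matrix aggregates by class pair and kind", {
  # one M-protease cleaving one S-protease
  web <- protease_web(data.frame(accession = c("P", "Q"),
                                 catalytic_class = c("M", "S")),
                      data.frame(from = "P", to = "Q", kind = "cleavage"))
  cm <- class_interaction_matrix(web)
  expect_equal(cm$cleavage["protease_M", "protease_S"], 1L)
  expect_equal(sum(cm$cleavage), 1L)
  expect_equal(unname(cm$remainder["cleavage"]), 0L)

  # no class labels at all -> everything in the remainder
  bare <- protease_web(data.frame(accession = c("A", "B")),
                       data.frame(from = "A", to = "B", kind = "cleavage"))
  cmb <- class_interaction_matrix(bare)
  expect_equal(sum(cmb$cleavage) + sum(cmb$inhibition), 0L)
  expect_equal(unname(cmb$remainder["cleavage"]), 1L)

  # random small graph: cell sums equal a direct tally of classed edges
  tabs <- generate_web(synthetic_web_params(seed = 11))
  web2 <- build_graph(tabs)
  cm2 <- class_interaction_matrix(web2)
  nd <- web2$nodes
  classed <- nd$accession[nd$catalytic_class != "none" |
                            nzchar(nd$inhibitor_classes)]
  ed <- web2$edges
  both_classed <- ed$from %in% classed & ed$to %in% classed
  expect_equal(sum(cm2$cleavage), sum(both_classed & ed$kind == "cleavage"))
  expect_equal(sum(cm2$inhibition), sum(both_classed & ed$kind == "inhibition"))
  expect_equal(sum(cm2$remainder),
               n_edges(web2) - sum(cm2$cleavage) - sum(cm2$inhibition))
})

test_that("network_overlap counts mapped shared edges, incl. many-to-one maps", {
  w <- chain_web(c("A", "B", "C"))
  idmap <- data.frame(b = c("A", "B", "C"), a = c("A", "B", "C"))
  ov <- network_overlap(w, w, idmap)
  expect_equal(ov$fraction_a, 1)
  expect_equal(ov$fraction_b, 1)

  # disjoint edge sets
  w2 <- chain_web(c("C", "B", "A"))  # reversed arcs
  ov2 <- network_overlap(w, w2, idmap)
  expect_equal(ov2$shared_b, 0L)

  # 2-to-1 ortholog mapping vs brute-force pair expansion
  a <- protease_web(data.frame(accession = c("hA", "hB")),
                    data.frame(from = "hA", to = "hB", kind = "cleavage"))
  b <- protease_web(data.frame(accession = c("m1", "m2", "m3")),
                    data.frame(from = c("m1", "m2"), to = c("m3", "m3"),
                               kind = c("cleavage", "inhibition")))
  map <- data.frame(b = c("m1", "m2", "m3"), a = c("hA", "hA", "hB"))
  ov3 <- network_overlap(a, b, map)
  expect_equal(ov3$shared_b, 2L)  # both mouse edges map onto hA->hB
  expect_equal(ov3$shared_a, 1L)
  # kind-sensitive matching drops the inhibition row
  ov4 <- network_overlap(a, b, map, kind_sensitive = TRUE)
  expect_equal(ov4$shared_b, 1L)

  expect_warning(network_overlap(a, b, map[0, ]), "empty")
})

test_that("edge deduplication is idempotent through re-serialization", {
  tabs <- generate_web(synthetic_web_params(seed = 5))
  web <- build_graph(tabs)
  # re-serialize the built edges as input rows and rebuild
  cl <- web$edges[web$edges$kind == "cleavage", ]
  ih <- web$edges[web$edges$kind == "inhibition", ]
  rebuilt <- build_graph(
    web$nodes,
    data.frame(protease_acc = cl$from, substrate_acc = cl$to,
               physiological_relevance = cl$relevance, source = cl$source),
    data.frame(inhibitor_acc = ih$from, protease_acc = ih$to))
  key <- function(w) sort(paste(w$edges$from, w$edges$to, w$edges$kind))
  expect_identical(key(rebuilt), key(web))
})
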