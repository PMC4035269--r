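# Reachability, inverse cumulative curve and AUC, betweenness, the
# strongly connected core and tiers, path-length histograms and explicit
# shortest-path queries -- each validated against brute-force oracles on
# small graphs.

test_that("reachability matches the calibration cases", {
  expect_true(all(reachability(edgeless_web(5))$counts == 1))
  expect_true(all(reachability(cycle_web(4))$counts == 4))
  expect_equal(unname(reachability(chain_web())$counts), c(3, 2, 1))
  # self-loops and parallel kinds do not change reachability
  looped <- protease_web(
    data.frame(accession = c("A", "B"), catalytic_class = c("M", "none"),
               inhibitor_classes = c("", "S")),
    rbind(data.frame(from = "A", to = "A", kind = "cleavage"),
          data.frame(from = "A", to = "B", kind = "cleavage"),
          data.frame(from = "B", to = "A", kind = "inhibition")))
  expect_true(all(reachability(looped)$counts == 2))
})

test_that("reachability equals transitive-closure row sums on random graphs", {
  for (s in 1:40) {
    w <- random_web(n = sample(3:12, 1), p = runif(1, 0.05, 0.5), seed = s)
    expect_equal(reachability(w)$counts, bf_reachability(web_adjacency(w)),
                 info = paste("seed", s))
  }
})

test_that("inverse cumulative curve matches direct counting and the step convention", {
  prof <- reachability(protease_web(
    data.frame(accession = c("A", "B", "C", "D")),
    data.frame(from = c("A", "A", "A", "B", "C", "D"),
               to = c("B", "C", "D", "A", "A", "A"), kind = "cleavage")[0, ]))
  # all values 1: single step at r = 1 with fraction 1
  expect_equal(prof$inverse_cumulative, data.frame(r = 1L, fraction = 1))

  # values {1, 1, 4, 4}
  w <- protease_web(data.frame(accession = c("A", "B", "C", "D")),
                    data.frame(from = c("A", "B", "C", "D"),
                               to = c("B", "A", "D", "C"), kind = "cleavage"))
  # A<->B and C<->D are 2-cycles: all values 2; build {1,1,4,4} directly instead
  prof2 <- structure(list(counts = c(a = 1L, b = 1L, c = 4L, d = 4L),
                          reference_n = 4), class = "reachability_profile")
  ic <- inverse_cumulative(prof2)
  expect_equal(ic$r, c(1L, 4L))
  expect_equal(ic$fraction, c(1, 0.5))

  # random profiles: fraction at every observed r equals brute-force count
  set.seed(99)
  for (i in 1:20) {
    counts <- sample.int(30, sample(3:40, 1), replace = TRUE)
    pr <- structure(list(counts = counts, reference_n = 30),
                    class = "reachability_profile")
    ic <- inverse_cumulative(pr)
    for (k in seq_len(nrow(ic))) {
      expect_equal(ic$fraction[k], mean(counts >= ic$r[k]))
    }
    expect_true(all(diff(ic$fraction) <= 0))
  }
})

test_that("AUC equals the exact step-function integral and the mean identity", {
  # edgeless N-node graph: AUC = 1/N; complete digraph: AUC = 1
  expect_equal(reachability(edgeless_web(8))$auc, 1 / 8)
  acc <- LETTERS[1:5]
  full <- expand.grid(from = acc, to = acc, stringsAsFactors = FALSE)
  full <- full[full$from != full$to, ]
  complete <- protease_web(data.frame(accession = acc),
                           cbind(full, kind = "cleavage"))
  expect_equal(reachability(complete)$auc, 1)

  # survival-integral identity, checked by independent rectangle summation
  set.seed(7)
  for (i in 1:30) {
    w <- random_web(n = sample(4:15, 1), p = runif(1, 0.05, 0.4), seed = 1000 + i)
    prof <- reachability(w)
    ic <- prof$inverse_cumulative
    r_prev <- c(0, ic$r[-nrow(ic)])
    integral <- sum(ic$fraction * (ic$r - r_prev))  # f(r) beyond max is 0
    expect_equal(prof$auc, integral / prof$reference_n, tolerance = 1e-12)
    expect_equal(prof$auc * prof$reference_n, mean(prof$counts),
                 tolerance = 1e-9)
  }
  prof <- reachability(edgeless_web(3))
  prof$reference_n <- 0
  expect_error(reachability_auc(prof), "reference_n")
})

test_that("betweenness matches Freeman brute force and closed forms", {
  # chain interior
  expect_equal(unname(web_betweenness(chain_web())), c(0, 1, 0))
  # edgeless
  expect_true(all(web_betweenness(edgeless_web(4)) == 0))
  # directed star: leaves -> center -> leaves
  leaves <- sprintf("L%d", 1:5)
  star <- protease_web(
    data.frame(accession = c("hub", leaves)),
    rbind(data.frame(from = leaves, to = "hub", kind = "cleavage"),
          data.frame(from = "hub", to = leaves, kind = "cleavage")))
  expect_equal(web_betweenness(star), bf_betweenness(web_adjacency(star)))
  # every leaf pair's unique 2-path passes the hub: 5*4 = 20
  expect_equal(unname(web_betweenness(star)["hub"]), 20)

  # directed path closed form: position i (0-based) scores i * (n-1-i)
  n <- 7
  path <- chain_web(sprintf("P%d", 1:n))
  i <- 0:(n - 1)
  expect_equal(unname(web_betweenness(path)), i * (n - 1 - i))

  # random graphs vs exhaustive path enumeration
  for (s in 1:25) {
    w <- random_web(n = sample(4:10, 1), p = runif(1, 0.1, 0.45), seed = 200 + s)
    expect_equal(web_betweenness(w), bf_betweenness(web_adjacency(w)),
                 tolerance = 1e-10, info = paste("seed", s))
  }
})

test_that("strongly_connected_core finds the core and assigns tiers", {
  # directed 4-cycle plus pendant out-edge: core = cycle, r_core = 5
  acc <- c("A", "B", "C", "D", "E")
  w <- protease_web(data.frame(accession = acc),
                    data.frame(from = c("A", "B", "C", "D", "D"),
                               to = c("B", "C", "D", "A", "E"),
                               kind = "cleavage"))
  sc <- strongly_connected_core(w)
  expect_setequal(sc$core, c("A", "B", "C", "D"))
  expect_equal(sc$r_core, 5L)
  expect_equal(sc$n_core + sc$n_upstream + sc$n_downstream, 5L)
  expect_equal(unname(sc$tiers["E"]), "downstream")

  # DAG: degenerate single-node core with warning
  expect_warning(dag <- strongly_connected_core(chain_web()), "single node")
  expect_equal(dag$n_core, 1L)
  expect_equal(dag$n_core + dag$n_upstream + dag$n_downstream, 3L)

  # upstream feeder has reachability > r_core
  w2 <- protease_web(data.frame(accession = c(acc, "U")),
                     rbind(w$edges,
                           data.frame(from = "U", to = "A", kind = "cleavage",
                                      relevance = NA, source = NA)))
  sc2 <- strongly_connected_core(w2)
  expect_equal(unname(sc2$tiers["U"]), "upstream")

  # all members of every SCC share one reachability value (random graphs)
  for (s in 1:15) {
    w3 <- random_web(n = 10, p = 0.25, seed = 300 + s)
    counts <- reachability(w3)$counts
    g <- igraph::graph_from_data_frame(
      unique(w3$edges[w3$edges$from != w3$edges$to, c("from", "to")]),
      vertices = w3$nodes$accession)
    memb <- igraph::components(g, mode = "strong")$membership
    for (grp in split(names(memb), memb)) {
      expect_length(unique(counts[grp]), 1L)
    }
  }
})

test_that("path_length_histogram matches all-pairs BFS and the pair-count identity", {
  ch <- path_length_histogram(chain_web())
  expect_equal(ch$histogram, c("1" = 2L, "2" = 1L))
  expect_equal(ch$reachable_pair_count, 3L)

  for (s in 1:10) {
    w <- random_web(n = 10, p = 0.2, seed = 400 + s)
    got <- path_length_histogram(w)
    D <- bf_distances(web_adjacency(w))
    diag(D) <- Inf
    finite <- D[is.finite(D)]
    expect_equal(got$reachable_pair_count, length(finite))
    expect_equal(got$histogram,
                 setNames(as.integer(table(finite)), names(table(finite))))
    # identity: pairs = sum(reachability) - n
    expect_equal(got$reachable_pair_count,
                 sum(reachability(w)$counts) - n_nodes(w))
    expect_lte(got$reachable_pair_count, n_nodes(w) * (n_nodes(w) - 1))
  }
})

test_that("regulatory_paths enumerates all shortest paths with edge kinds", {
  # chain: single path with kinds
  res <- regulatory_paths(chain_web(), "A", "C")
  expect_equal(res$length, 2L)
  expect_length(res$paths, 1L)
  expect_equal(res$paths[[1]]$nodes, c("A", "B", "C"))
  expect_equal(res$paths[[1]]$kinds, c("cleavage", "cleavage"))

  # unreachable
  res2 <- regulatory_paths(chain_web(), "C", "A")
  expect_true(is.na(res2$length))
  expect_length(res2$paths, 0L)

  # diamond: two tied paths of length 2
  dia <- protease_web(data.frame(accession = c("A", "B", "C", "D")),
                      data.frame(from = c("A", "A", "B", "C"),
                                 to = c("B", "C", "D", "D"), kind = "cleavage"))
  res3 <- regulatory_paths(dia, "A", "D")
  expect_equal(res3$length, 2L)
  expect_length(res3$paths, 2L)

  # kinds annotate the mechanism: inhibitor bridge route
  toy <- bridged_cascades_web()
  res4 <- regulatory_paths(toy, "P3", "Q1")
  expect_equal(res4$paths[[1]]$kinds, c("cleavage", "inhibition"))

  expect_error(regulatory_paths(chain_web(), "A", "ZZ"), "unknown accession")

  # random graphs vs brute-force enumeration
  for (s in 1:10) {
    w <- random_web(n = 8, p = 0.25, seed = 500 + s)
    A <- web_adjacency(w)
    D <- bf_distances(A)
    acc <- rownames(A)
    pair <- expand.grid(s = acc, t = acc, stringsAsFactors = FALSE)
    pair <- pair[pair$s != pair$t, ][1:10, ]
    for (k in seq_len(nrow(pair))) {
      got <- regulatory_paths(w, pair$s[k], pair$t[k])
      want <- bf_all_shortest_paths(A, D, match(pair$s[k], acc),
                                    match(pair$t[k], acc))
      if (!length(want)) {
        expect_true(is.na(got$length))
      } else {
        expect_length(got$paths, length(want))
        expect_setequal(
          vapply(got$paths, function(p) paste(p$nodes, collapse = ">"), ""),
          vapply(want, function(p) paste(acc[p], collapse = ">"), ""))
      }
    }
  }
})

test_that("removing an edge never increases any node's reachability", {
  for (s in 1:10) {
    w <- random_web(n = 9, p = 0.3, seed = 600 + s)
    if (n_edges(w) == 0) next
    base <- reachability(w)$counts
    set.seed(s)
    for (drop in sample(n_edges(w), min(4, n_edges(w)))) {
      pruned <- protease_web(w$nodes, w$edges[-drop, ], provenance = "pruned")
      expect_true(all(reachability(pruned)$counts <= base))
    }
  }
})
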