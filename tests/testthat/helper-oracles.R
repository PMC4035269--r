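# Brute-force oracles, independent of the package internals (and of
# igraph): everything here works on a plain logical adjacency matrix.

# adjacency matrix (no self-loops) of a protease_web
web_adjacency <- function(web) {
  acc <- web$nodes$accession
  n <- length(acc)
  A <- matrix(FALSE, n, n, dimnames = list(acc, acc))
  ed <- unique(web$edges[web$edges$from != web$edges$to, c("from", "to")])
  if (nrow(ed)) A[cbind(ed$from, ed$to)] <- TRUE
  A
}

# transitive closure by repeated boolean squaring; row sums (incl. self)
# are the reachability oracle
bf_reachability <- function(A) {
  R <- A | diag(TRUE, nrow(A))
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  rowSums(R)
}

# all-pairs BFS distances
bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(A[u, ])) {
          if (D[s, v] > d) { D[s, v] <- d; nxt <- c(nxt, v) }
        }
      }
      frontier <- unique(nxt)
    }
  }
  D
}

# enumerate every shortest s->t path by walking the distance-layered DAG
bf_all_shortest_paths <- function(A, D, s, t) {
  if (!is.finite(D[s, t]) || s == t) return(list())
  walk <- function(v) {
    if (v == s) return(list(s))
    out <- list()
    for (u in which(A[, v])) {
      if (is.finite(D[s, u]) && D[s, u] + 1 == D[s, v]) {
        for (p in walk(u)) out[[length(out) + 1L]] <- c(p, v)
      }
    }
    out
  }
  walk(t)
}

# Freeman betweenness by exhaustive shortest-path enumeration: interior
# nodes of each path get 1/(number of tied shortest paths)
bf_betweenness <- function(A) {
  n <- nrow(A)
  D <- bf_distances(A)
  b <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || !is.finite(D[s, t])) next
    paths <- bf_all_shortest_paths(A, D, s, t)
    if (!length(paths)) next
    w <- 1 / length(paths)
    for (p in paths) {
      interior <- p[-c(1L, length(p))]
      b[interior] <- b[interior] + w
    }
  }
  names(b) <- rownames(A)
  b
}

# random directed graph wrapped as a protease_web
random_web <- function(n, p = 0.25, seed = 1) {
  set.seed(seed)
  acc <- sprintf("N%02d", seq_len(n))
  pairs <- expand.grid(from = acc, to = acc, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pick <- runif(nrow(pairs)) < p
  protease_web(data.frame(accession = acc),
               if (any(pick)) cbind(pairs[pick, ], kind = "cleavage") else NULL,
               provenance = "random")
}

# tiny hand-built webs ------------------------------------------------------

chain_web <- function(labels = c("A", "B", "C")) {
  protease_web(data.frame(accession = labels),
               data.frame(from = labels[-length(labels)], to = labels[-1L],
                          kind = "cleavage"))
}

cycle_web <- function(n = 4L) {
  acc <- LETTERS[seq_len(n)]
  protease_web(data.frame(accession = acc),
               data.frame(from = acc, to = c(acc[-1L], acc[1L]),
                          kind = "cleavage"))
}

edgeless_web <- function(n = 5L) {
  protease_web(data.frame(accession = sprintf("Z%02d", seq_len(n))), NULL)
}

# two protease cascades joined only through a cleavable inhibitor bridge
bridged_cascades_web <- function() {
  nodes <- data.frame(
    accession = c("P1", "P2", "P3", "Q1", "Q2", "Q3", "I1"),
    merops_id = c("M1", "M2", "M3", "S1", "S2", "S3", "I04.1"),
    catalytic_class = c("M", "M", "M", "S", "S", "S", "none"),
    inhibitor_classes = c(rep("", 6), "S"))
  edges <- rbind(
    data.frame(from = c("P1", "P2"), to = c("P2", "P3"), kind = "cleavage"),
    data.frame(from = c("Q1", "Q2"), to = c("Q2", "Q3"), kind = "cleavage"),
    data.frame(from = "P3", to = "I1", kind = "cleavage"),
    data.frame(from = "I1", to = "Q1", kind = "inhibition"))
  edges$relevance <- "yes"
  protease_web(nodes, edges, provenance = "bridged toy")
}
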