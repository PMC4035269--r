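#' Configuration for a null-model experiment
#'
#' @param model One of `"ER"` (uniform random graph with matched node and
#'   edge counts), `"BA"` (sequential preferential attachment forcing the
#'   observed out-degree distribution), `"Shuffled"` (degree-preserving
#'   double-edge swaps: every node keeps its own in- and out-degree) or
#'   `"Shuffled2"` (in- and out-degree sequences independently permuted
#'   across nodes before realization: the degree multisets are preserved
#'   but decoupled from node identity).
#' @param replicates Number of replicate networks (default 500).
#' @param seed Integer seed; replicate i uses the derived seed `seed + i`.
#' @param swap_multiplier Swap attempts per edge for `"Shuffled"`
#'   (default 10).
#' @return A list of class `null_model_config`.
#' @export
null_model_config <- function(model = c("ER", "BA", "Shuffled", "Shuffled2"),
                              replicates = 500L, seed = 1L,
                              swap_multiplier = 10L) {
  model <- match.arg(model)
  replicates <- as.integer(replicates)
  swap_multiplier <- as.integer(swap_multiplier)
  if (replicates < 1L) stop_pw("replicates must be >= 1")
  if (swap_multiplier < 1L) stop_pw("swap_multiplier must be >= 1")
  structure(list(model = model, replicates = replicates,
                 seed = as.integer(seed), swap_multiplier = swap_multiplier),
            class = "null_model_config")
}

# Wrap a bare directed edge matrix (two character columns) as a web with
# unannotated nodes. Null-model arcs carry no mechanism; they are stored
# under the cleavage kind.
arcs_as_web <- function(arcs, node_names, provenance) {
  nodes <- data.frame(accession = node_names, stringsAsFactors = FALSE)
  edges <- if (nrow(arcs)) {
    data.frame(from = arcs[, 1L], to = arcs[, 2L], kind = "cleavage",
               stringsAsFactors = FALSE)
  } else NULL
  protease_web(nodes, edges, provenance = provenance)
}

#' Erdos-Renyi-style random network
#'
#' Directed simple graph on `n_nodes` nodes with exactly `n_edges` arcs
#' sampled uniformly without replacement among the n(n-1) ordered pairs;
#' no self-loops.
#'
#' @param n_nodes,n_edges Node and arc counts.
#' @param seed Integer seed; the global RNG state is left untouched.
#' @return A [protease_web()] with synthetic node names.
#' @export
null_er <- function(n_nodes, n_edges, seed) {
  n <- as.integer(n_nodes); m <- as.integer(n_edges)
  if (n < 1L) stop_pw("n_nodes must be >= 1")
  max_m <- as.numeric(n) * (n - 1)
  if (m < 0L || m > max_m) {
    stop_pw("n_edges must be between 0 and n(n-1) = ", format(max_m, scientific = FALSE))
  }
  names <- node_labels(n)
  arcs <- with_seed(seed, {
    idx <- sample(max_m, m)              # ordered non-diagonal cell index
    r <- (idx - 1) %/% (n - 1) + 1       # source
    o <- (idx - 1) %% (n - 1) + 1
    c0 <- ifelse(o >= r, o + 1, o)       # target, skipping the diagonal
    cbind(names[r], names[c0])
  })
  arcs_as_web(arcs, names, provenance = "null:ER")
}

node_labels <- function(n) sprintf("n%04d", seq_len(n))

#' Preferential-attachment-style random network
#'
#' Sequential attachment forcing a given out-degree multiset: nodes are
#' added in random order and node i emits its assigned out-degree as arcs
#' to already-present nodes, each target drawn with probability
#' proportional to its current in-degree plus one (the offset makes
#' zero-in-degree nodes reachable targets). A node's out-degree is capped
#' at the number of prior nodes; any shortfall is recorded.
#'
#' @param out_degree_sequence Nonnegative integer vector; one entry per node.
#' @param seed Integer seed.
#' @param new_to_old Direction of emitted arcs; `TRUE` (default) points
#'   arcs from the newly arrived node to earlier nodes.
#' @return A [protease_web()]; the attribute `"shortfall"` records the
#'   total out-degree lost to the cap.
#' @export
null_ba <- function(out_degree_sequence, seed, new_to_old = TRUE) {
  degs <- as.integer(out_degree_sequence)
  if (!length(degs)) stop_pw("out_degree_sequence must be nonempty")
  if (any(degs < 0L)) stop_pw("out-degrees must be nonnegative")
  n <- length(degs)
  names <- node_labels(n)
  res <- with_seed(seed, {
    order_ <- sample.int(n)
    indeg <- integer(n)
    from <- integer(0); to <- integer(0)
    shortfall <- 0L
    for (pos in seq_len(n)) {
      i <- order_[pos]
      prior <- order_[seq_len(pos - 1L)]
      k <- min(degs[i], length(prior))
      shortfall <- shortfall + (degs[i] - k)
      if (k > 0L) {
        tgt <- if (length(prior) == 1L) rep(prior, k)
               else sample(prior, k, replace = FALSE, prob = indeg[prior] + 1)
        from <- c(from, rep(i, k)); to <- c(to, tgt)
        indeg[tgt] <- indeg[tgt] + 1L
      }
    }
    list(from = from, to = to, shortfall = shortfall)
  })
  arcs <- if (new_to_old) cbind(names[res$from], names[res$to])
          else cbind(names[res$to], names[res$from])
  web <- arcs_as_web(arcs, names, provenance = "null:BA")
  attr(web, "shortfall") <- res$shortfall
  web
}

# collapsed arc matrix of a web (two character columns)
web_arcs <- function(web) {
  ed <- unique(web$edges[web$edges$from != web$edges$to, c("from", "to")])
  cbind(ed$from, ed$to)
}

#' Degree-preserving edge shuffle ("Shuffled")
#'
#' Randomizes the arc set by directed double-edge swaps: a swap replaces
#' arcs (a -> b, c -> d) with (a -> d, c -> b) and is rejected if it would
#' create a self-loop or a duplicate arc. Every node's in- and out-degree
#' are exactly preserved. The number of attempted swaps is
#' `swap_multiplier` times the arc count.
#'
#' @param web A [protease_web()] with at least 2 arcs (fewer are returned
#'   unchanged).
#' @param seed Integer seed.
#' @param swap_multiplier Attempted swaps per arc (default 10).
#' @return A [protease_web()] over the same node set.
#' @export
null_shuffled <- function(web, seed, swap_multiplier = 10L) {
  stopifnot(inherits(web, "protease_web"))
  arcs <- web_arcs(web)
  m <- nrow(arcs)
  nodes <- web$nodes$accession
  if (m < 2L) return(arcs_as_web(arcs, nodes, "null:Shuffled"))
  arcs <- with_seed(seed, {
    key <- new.env(parent = emptyenv())
    for (i in seq_len(m)) assign(paste0(arcs[i, 1L], "\r", arcs[i, 2L]), TRUE, envir = key)
    attempts <- as.integer(swap_multiplier) * m
    for (t in seq_len(attempts)) {
      ij <- sample.int(m, 2L)
      a <- arcs[ij[1L], 1L]; b <- arcs[ij[1L], 2L]
      c_ <- arcs[ij[2L], 1L]; d <- arcs[ij[2L], 2L]
      if (a == d || c_ == b) next                       # self-loop
      k1 <- paste0(a, "\r", d); k2 <- paste0(c_, "\r", b)
      if (exists(k1, envir = key, inherits = FALSE) ||
          exists(k2, envir = key, inherits = FALSE)) next  # duplicate arc
      rm(list = c(paste0(a, "\r", b), paste0(c_, "\r", d)), envir = key)
      assign(k1, TRUE, envir = key); assign(k2, TRUE, envir = key)
      arcs[ij[1L], 2L] <- d; arcs[ij[2L], 2L] <- b
    }
    arcs
  })
  arcs_as_web(arcs, nodes, "null:Shuffled")
}

#' Degree-sequence shuffle ("Shuffled2")
#'
#' Independently permutes the in-degree sequence and the out-degree
#' sequence across nodes -- preserving both degree multisets but
#' decoupling each node's in-degree from its out-degree -- and realizes
#' the permuted sequences as a simple directed graph by random stub
#' matching with rejection of self-loops and duplicate arcs. Failed
#' matchings are retried, then repaired by swapping targets with already
#' placed arcs; if residual stubs remain after the retry budget an error
#' reports them.
#'
#' @param web A [protease_web()] object.
#' @param seed Integer seed.
#' @param max_tries Full rematch attempts before constrained repair.
#' @return A [protease_web()] over the same node set.
#' @export
null_shuffled2 <- function(web, seed, max_tries = 50L) {
  stopifnot(inherits(web, "protease_web"))
  arcs <- web_arcs(web)
  nodes <- web$nodes$accession
  n <- length(nodes)
  if (nrow(arcs) == 0L) return(arcs_as_web(arcs, nodes, "null:Shuffled2"))
  idx <- stats::setNames(seq_len(n), nodes)
  outdeg0 <- tabulate(idx[arcs[, 1L]], n)
  indeg0 <- tabulate(idx[arcs[, 2L]], n)

  out <- with_seed(seed, {
    outdeg <- sample(outdeg0)   # permuted across nodes
    indeg <- sample(indeg0)
    out_stubs <- rep.int(seq_len(n), outdeg)
    realized <- NULL
    for (try in seq_len(max_tries)) {
      in_stubs <- rep.int(seq_len(n), indeg)[sample.int(sum(indeg))]
      cand <- cbind(out_stubs, in_stubs)
      ok <- cand[, 1L] != cand[, 2L] &
        !duplicated(paste(cand[, 1L], cand[, 2L]))
      if (all(ok)) { realized <- cand; break }
      if (is.null(realized) || sum(ok) > sum(attr(realized, "ok"))) {
        attr(cand, "ok") <- ok
        realized <- cand
      }
    }
    ok <- attr(realized, "ok") %||% rep(TRUE, nrow(realized))
    if (!all(ok)) {
      # constrained repair: swap each bad pairing's target with a random
      # good arc whenever both resulting arcs are legal
      good <- which(ok); bad <- which(!ok)
      key <- new.env(parent = emptyenv())
      for (i in good) assign(paste(realized[i, 1L], realized[i, 2L]), TRUE, envir = key)
      budget <- 200L * length(bad)
      while (length(bad) && budget > 0L) {
        budget <- budget - 1L
        i <- bad[[1L]]; j <- good[[sample.int(length(good), 1L)]]
        a <- realized[i, 1L]; b <- realized[i, 2L]
        c_ <- realized[j, 1L]; d <- realized[j, 2L]
        k1 <- paste(a, d); k2 <- paste(c_, b)
        if (a != d && c_ != b &&
            !exists(k1, envir = key, inherits = FALSE) &&
            !exists(k2, envir = key, inherits = FALSE)) {
          rm(list = paste(c_, d), envir = key)
          assign(k1, TRUE, envir = key); assign(k2, TRUE, envir = key)
          realized[i, 2L] <- d; realized[j, 2L] <- b
          good <- c(good, i); bad <- bad[-1L]
        }
      }
      if (length(bad)) {
        stop_pw("degree-sequence shuffle unrealizable within the retry budget; ",
                length(bad), " residual stub pair(s)")
      }
    }
    realized[, 1:2, drop = FALSE]
  })
  arcs_as_web(cbind(nodes[out[, 1L]], nodes[out[, 2L]]), nodes, "null:Shuffled2")
}

#' Compare observed mean reachability against a null ensemble
#'
#' Generates `config$replicates` null networks matched to the observed
#' graph (replicate i is seeded deterministically with `config$seed + i`),
#' computes each replicate's mean reachability, and locates the observed
#' network's mean within the ensemble. The empirical quantile uses the
#' mid-rank tie rule (strictly-below count plus half the tied count, over
#' the replicate count).
#'
#' @param web Observed [protease_web()].
#' @param config A [null_model_config()].
#' @return A list of class `null_model_summary` with `model`,
#'   `replicate_means`, `ensemble_mean`, `observed_mean`, `quantile` and
#'   `n_exceeding` (replicates strictly above the observed mean).
#' @export
null_experiment <- function(web, config) {
  stopifnot(inherits(web, "protease_web"), inherits(config, "null_model_config"))
  observed <- mean(reachability(web)$counts)
  n <- n_nodes(web)
  m <- nrow(web_arcs(web))
  outdegs <- tabulate(
    stats::setNames(seq_len(n), web$nodes$accession)[web_arcs(web)[, 1L]], n)

  means <- vapply(seq_len(config$replicates), function(i) {
    s <- derive_seed(config$seed, i)
    nullweb <- switch(config$model,
      ER = null_er(n, m, seed = s),
      BA = null_ba(outdegs, seed = s),
      Shuffled = null_shuffled(web, seed = s, swap_multiplier = config$swap_multiplier),
      Shuffled2 = null_shuffled2(web, seed = s))
    mean(reachability(nullweb)$counts)
  }, numeric(1))

  structure(list(
    model = config$model,
    replicate_means = means,
    ensemble_mean = mean(means),
    observed_mean = observed,
    quantile = (sum(means < observed) + 0.5 * sum(means == observed)) /
      length(means),
    n_exceeding = sum(means > observed)
  ), class = "null_model_summary")
}

#' @export
print.null_model_summary <- function(x, ...) {
  cat(sprintf("null ensemble [%s], %d replicates\n", x$model, length(x$replicate_means)))
  cat(sprintf("  observed mean reachability %.2f vs ensemble mean %.2f\n",
              x$observed_mean, x$ensemble_mean))
  cat(sprintf("  empirical quantile of observed: %.3f (%d replicate(s) exceed it)\n",
              x$quantile, x$n_exceeding))
  invisible(x)
}
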