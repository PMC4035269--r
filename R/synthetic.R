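#' Parameters for the synthetic protease-web generator
#'
#' The generator is scenario-based: it plants known structure (a strongly
#' connected regulatory core held together by redundant inhibitor bridges,
#' zymogen-activation cascades feeding the core from upstream, and
#' low-reachability downstream proteases) so that every pipeline stage can
#' be checked against ground truth. The defaults emulate a human-scale
#' curated snapshot: a few hundred proteins, heavy-tailed substrate
#' out-degrees, a core of a few dozen mutually reachable proteins, and a
#' bimodal reachability distribution.
#'
#' @param n_proteases,n_inhibitors,n_substrates Protein counts by role.
#' @param class_mix Named probability vector over catalytic classes
#'   `A`, `C`, `M`, `S`, `T`.
#' @param core_size Total size of the planted strongly connected core,
#'   including the bridge inhibitors (0 disables the core; otherwise at
#'   least 3).
#' @param n_bridges Number of inhibitor bridges inside the core. The core
#'   proteases are split into `n_bridges` internally cyclic groups whose
#'   only mutual connections run through the bridges: every group cleaves
#'   every bridge (serpin-bait or trap-bait cleavage) and every bridge
#'   inhibits one member of every group, so any single surviving bridge
#'   keeps the core strongly connected while removing all of them
#'   fragments it.
#' @param n_cascades,cascade_length Number and length of planted
#'   activation cascades (directed chains) feeding the core.
#' @param cross_link_rate Probability of a cleavage between each ordered
#'   pair of distinct cascades.
#' @param inhibition_rate Controls peripheral inhibitors: the chance of
#'   extra inhibition targets and of being cleaved by a cascade protease.
#' @param serpin_fraction Share of inhibitors annotated with inhibitor
#'   class `S`.
#' @param trap_count Number of A2M/PZP-style trap inhibitors (flagged,
#'   class `broad`); assigned to bridges first.
#' @param relevance_yes_fraction Probability that a cleavage row is
#'   annotated physiologically relevant (`yes`); the remainder splits
#'   evenly between `no` and `unknown`.
#' @param outdegree_tail_exponent Exponent of the truncated discrete
#'   power law (support 1..`n_substrates`) from which each protease's
#'   substrate out-degree is drawn; must exceed 1.
#' @param seed Integer master seed; topology and annotation labels use
#'   derived sub-seeds so each stage is independently reproducible.
#' @return A list of class `synthetic_web_params`.
#' @export
synthetic_web_params <- function(n_proteases = 120L, n_inhibitors = 30L,
                                 n_substrates = 150L,
                                 class_mix = c(A = 0.08, C = 0.18, M = 0.38,
                                               S = 0.28, T = 0.08),
                                 core_size = 48L, n_bridges = 6L,
                                 n_cascades = 4L, cascade_length = 8L,
                                 cross_link_rate = 0.05,
                                 inhibition_rate = 0.3,
                                 serpin_fraction = 0.5, trap_count = 2L,
                                 relevance_yes_fraction = 0.6,
                                 outdegree_tail_exponent = 1.8,
                                 seed = 1L) {
  p <- list(n_proteases = as.integer(n_proteases),
            n_inhibitors = as.integer(n_inhibitors),
            n_substrates = as.integer(n_substrates),
            class_mix = class_mix / sum(class_mix),
            core_size = as.integer(core_size),
            n_bridges = as.integer(n_bridges),
            n_cascades = as.integer(n_cascades),
            cascade_length = as.integer(cascade_length),
            cross_link_rate = cross_link_rate,
            inhibition_rate = inhibition_rate,
            serpin_fraction = serpin_fraction,
            trap_count = as.integer(trap_count),
            relevance_yes_fraction = relevance_yes_fraction,
            outdegree_tail_exponent = outdegree_tail_exponent,
            seed = as.integer(seed))
  if (!setequal(names(p$class_mix), c("A", "C", "M", "S", "T"))) {
    stop_pw("class_mix must be named over A, C, M, S, T")
  }
  if (p$core_size > 0L && p$core_size < 3L) {
    stop_pw("a planted core needs core_size >= 3 (or 0 to disable)")
  }
  if (p$core_size > p$n_proteases + p$n_inhibitors) {
    stop_pw("core_size exceeds n_proteases + n_inhibitors")
  }
  if (p$core_size > 0L) {
    if (p$n_bridges > p$n_inhibitors) stop_pw("n_bridges exceeds n_inhibitors")
    groups <- max(p$n_bridges, 1L)
    if (p$core_size - p$n_bridges < 2L * groups) {
      stop_pw("core_size too small for ", groups, " protease group(s) of >= 2")
    }
  }
  rates <- c(p$cross_link_rate, p$inhibition_rate, p$serpin_fraction,
             p$relevance_yes_fraction)
  if (any(rates < 0 | rates > 1)) stop_pw("rates/fractions must lie in [0, 1]")
  if (p$outdegree_tail_exponent <= 1) stop_pw("outdegree_tail_exponent must exceed 1")
  needed <- p$n_cascades * p$cascade_length +
    max(p$core_size - p$n_bridges, 0L)
  if (needed > p$n_proteases) {
    stop_pw("n_proteases too small for the requested cascades and core")
  }
  structure(p, class = "synthetic_web_params")
}

# truncated discrete power law on 1..kmax
rzeta_trunc <- function(n, alpha, kmax) {
  sample.int(kmax, n, replace = TRUE, prob = (seq_len(kmax))^(-alpha))
}

#' Generate synthetic protease-web annotation tables
#'
#' Emits protein, cleavage and inhibition tables in the TSV dialect read
#' by [load_tables()], together with a report of the planted structure.
#' Byte-identical output is guaranteed for identical `(params, seed)`.
#'
#' @param params A [synthetic_web_params()] object.
#' @return A list of class `synthetic_web` with data frames `proteins`,
#'   `cleavages`, `inhibitions` and a `report` list (core, group, bridge,
#'   cascade, downstream and peripheral membership; realized counts;
#'   expected tier bounds).
#' @seealso [structure_recovery_check()], [write_web_tables()]
#' @export
generate_web <- function(params = synthetic_web_params()) {
  stopifnot(inherits(params, "synthetic_web_params"))
  p <- params
  prot <- sprintf("PR%03d", seq_len(p$n_proteases))
  inh <- sprintf("IN%03d", seq_len(p$n_inhibitors))
  subs <- sprintf("SU%03d", seq_len(p$n_substrates))

  # --- allocation ---------------------------------------------------------
  n_casc_members <- p$n_cascades * p$cascade_length
  cascades <- if (n_casc_members > 0L) {
    split(prot[seq_len(n_casc_members)],
          rep(seq_len(p$n_cascades), each = p$cascade_length))
  } else list()
  n_groups <- if (p$core_size > 0L) max(p$n_bridges, 1L) else 0L
  n_core_prot <- max(p$core_size - p$n_bridges, 0L)
  core_prot <- if (n_core_prot > 0L) prot[n_casc_members + seq_len(n_core_prot)] else character(0)
  groups <- if (n_groups > 0L) {
    split(core_prot, rep(seq_len(n_groups), length.out = n_core_prot))
  } else list()
  downstream <- prot[setdiff(seq_len(p$n_proteases),
                             seq_len(n_casc_members + n_core_prot))]
  bridges <- if (p$core_size > 0L) inh[seq_len(p$n_bridges)] else character(0)
  peripheral <- setdiff(inh, bridges)

  # --- topology (sub-seed 1) ---------------------------------------------
  topo <- with_seed(derive_seed(p$seed, 1L), {
    cl_from <- character(0); cl_to <- character(0)
    ih_from <- character(0); ih_to <- character(0)
    add_cl <- function(f, t) { cl_from <<- c(cl_from, f); cl_to <<- c(cl_to, t) }
    add_ih <- function(f, t) { ih_from <<- c(ih_from, f); ih_to <<- c(ih_to, t) }

    # core protease groups: internal directed cycles
    for (g in groups) {
      if (length(g) > 1L) add_cl(g, c(g[-1L], g[1L])) else add_cl(g, g)
    }
    # redundant bridge wiring: every group cleaves every bridge (two
    # members each), every bridge inhibits one member of every group
    for (b in bridges) {
      for (g in groups) {
        src <- if (length(g) >= 2L) sample(g, 2L) else g
        add_cl(src, rep(b, length(src)))
        add_ih(b, sample(g, 1L))
      }
    }
    # core without bridges: single cycle plus a few chords
    if (p$core_size > 0L && p$n_bridges == 0L && length(core_prot) > 2L) {
      chord_n <- max(1L, length(core_prot) %/% 8L)
      for (i in seq_len(chord_n)) {
        pair <- sample(core_prot, 2L)
        add_cl(pair[1L], pair[2L])
      }
    }
    # zymogen-activation cascades feeding the core through the bridges
    for (cc in cascades) {
      if (length(cc) > 1L) add_cl(cc[-length(cc)], cc[-1L])
      terminal <- cc[length(cc)]
      if (length(bridges)) {
        hit <- bridges[stats::runif(length(bridges)) < 0.5]
        if (!length(hit)) hit <- sample(bridges, 1L)
        add_cl(rep(terminal, length(hit)), hit)
      } else if (length(core_prot)) {
        add_cl(terminal, sample(core_prot, 1L))
      }
    }
    # sparse inter-cascade cross-links
    if (length(cascades) > 1L) {
      for (i in seq_along(cascades)) for (j in seq_along(cascades)) {
        if (i != j && stats::runif(1L) < p$cross_link_rate) {
          add_cl(sample(cascades[[i]], 1L), sample(cascades[[j]], 1L))
        }
      }
    }
    # downstream proteases: activated by the core (or cascades), cleave
    # only plain substrates
    upstream_pool <- if (length(core_prot)) core_prot
                     else if (n_casc_members) prot[seq_len(n_casc_members)]
                     else character(0)
    for (d in downstream) {
      if (length(upstream_pool)) {
        k <- min(1L + (stats::runif(1L) < 0.5), length(upstream_pool))
        add_cl(sample(upstream_pool, k), rep(d, k))
      }
    }
    # peripheral inhibitors: inhibit core/downstream proteases; sometimes
    # cleaved by a cascade protease (never by the core, so they cannot
    # bypass the bridges)
    target_pool <- c(core_prot, downstream)
    if (!length(target_pool)) target_pool <- prot
    for (q in peripheral) {
      k <- min(1L + stats::rbinom(1L, 2L, p$inhibition_rate), length(target_pool))
      add_ih(rep(q, k), sample(target_pool, k))
      if (n_casc_members && stats::runif(1L) < p$inhibition_rate) {
        add_cl(sample(prot[seq_len(n_casc_members)], 1L), q)
      }
    }
    # heavy-tailed substrate repertoires
    outdeg <- rzeta_trunc(p$n_proteases, p$outdegree_tail_exponent, p$n_substrates)
    for (i in seq_len(p$n_proteases)) {
      add_cl(rep(prot[i], outdeg[i]), sample(subs, outdeg[i]))
    }
    list(cl = data.frame(from = cl_from, to = cl_to, stringsAsFactors = FALSE),
         ih = data.frame(from = ih_from, to = ih_to, stringsAsFactors = FALSE),
         outdeg = outdeg)
  })
  topo$cl <- unique(topo$cl)
  topo$ih <- unique(topo$ih)

  # --- annotation labels (sub-seed 2) ------------------------------------
  lab <- with_seed(derive_seed(p$seed, 2L), {
    catalytic <- sample(names(p$class_mix), p$n_proteases, replace = TRUE,
                        prob = p$class_mix)
    trap <- rep(FALSE, p$n_inhibitors)
    if (p$trap_count > 0L && p$n_inhibitors > 0L) {
      trap[seq_len(min(p$trap_count, p$n_inhibitors))] <- TRUE
    }
    inh_class <- rep(NA_character_, p$n_inhibitors)
    inh_class[trap] <- "broad"
    open <- which(!trap)
    n_serpin <- min(length(open), round(p$serpin_fraction * p$n_inhibitors))
    # bridges are serpins first: the planted serpin-bait cleavages should
    # carry serpin annotations
    bridge_idx <- intersect(seq_len(p$n_bridges), open)
    serp <- utils::head(unique(c(bridge_idx, sample(open))), n_serpin)
    inh_class[serp] <- "S"
    rest <- which(is.na(inh_class))
    if (length(rest)) {
      inh_class[rest] <- sample(c("C", "M", "A", "broad"), length(rest),
                                replace = TRUE, prob = c(0.35, 0.3, 0.15, 0.2))
    }
    relev <- function(n) {
      u <- stats::runif(n)
      ifelse(u < p$relevance_yes_fraction, "yes",
             ifelse(u < p$relevance_yes_fraction +
                      (1 - p$relevance_yes_fraction) / 2, "no", "unknown"))
    }
    list(catalytic = catalytic, inh_class = inh_class, trap = trap,
         relevance = relev(nrow(topo$cl)))
  })

  proteins <- data.frame(
    accession = c(prot, inh, subs),
    gene_name = c(sprintf("PRT%d", seq_len(p$n_proteases)),
                  sprintf("INH%d", seq_len(p$n_inhibitors)),
                  sprintf("SUB%d", seq_len(p$n_substrates))),
    merops_id = c(sprintf("%s%02d.%03d", lab$catalytic,
                          match(lab$catalytic, names(p$class_mix)),
                          seq_len(p$n_proteases)),
                  sprintf("I%02d.%03d", 4L + as.integer(lab$trap),
                          seq_len(p$n_inhibitors)),
                  rep(NA_character_, p$n_substrates)),
    catalytic_class = c(lab$catalytic, rep("none", p$n_inhibitors + p$n_substrates)),
    inhibitor_classes = c(rep("", p$n_proteases), lab$inh_class,
                          rep("", p$n_substrates)),
    trap_inhibitor = c(rep(FALSE, p$n_proteases), lab$trap,
                       rep(FALSE, p$n_substrates)),
    stringsAsFactors = FALSE
  )
  cleavages <- data.frame(
    protease_acc = topo$cl$from,
    substrate_acc = topo$cl$to,
    physiological_relevance = lab$relevance,
    source = "synthetic",
    stringsAsFactors = FALSE
  )
  inhibitions <- data.frame(
    inhibitor_acc = topo$ih$from,
    protease_acc = topo$ih$to,
    stringsAsFactors = FALSE
  )

  report <- list(
    params = p,
    core = sort(c(core_prot, bridges)),
    groups = groups,
    bridges = bridges,
    cascades = cascades,
    downstream = downstream,
    peripheral_inhibitors = peripheral,
    realized_out_degrees = stats::setNames(topo$outdeg, prot),
    n_protein_rows = nrow(proteins),
    n_cleavage_rows = nrow(cleavages),
    n_inhibition_rows = nrow(inhibitions),
    expected = list(
      r_core_min = p$core_size,
      n_core_min = p$core_size,
      n_upstream_min = if (length(bridges) && length(cascades)) n_casc_members else 0L
    )
  )
  structure(list(proteins = proteins, cleavages = cleavages,
                 inhibitions = inhibitions, report = report),
            class = "synthetic_web")
}

#' @export
print.synthetic_web <- function(x, ...) {
  cat(sprintf("synthetic protease-web tables: %d proteins, %d cleavages, %d inhibitions\n",
              x$report$n_protein_rows, x$report$n_cleavage_rows,
              x$report$n_inhibition_rows))
  cat(sprintf("  planted core %d (of which %d bridges), %d cascade(s)\n",
              length(x$report$core), length(x$report$bridges),
              length(x$report$cascades)))
  invisible(x)
}

#' Write synthetic tables to TSV files
#'
#' @param tables A `synthetic_web` object (or any list with `proteins`,
#'   `cleavages`, `inhibitions` data frames).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths.
#' @export
write_web_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(proteins = file.path(dir, "proteins.tsv"),
             cleavages = file.path(dir, "cleavages.tsv"),
             inhibitions = file.path(dir, "inhibitions.tsv"))
  pr <- tables$proteins
  pr$trap_inhibitor <- as.integer(pr$trap_inhibitor)
  pr$merops_id[is.na(pr$merops_id)] <- ""
  utils::write.table(pr, paths[["proteins"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(tables$cleavages, paths[["cleavages"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(tables$inhibitions, paths[["inhibitions"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  paths
}

#' Generate a synthetic tissue expression matrix with negative controls
#'
#' A-values are drawn from well-separated distributions: negative-control
#' probes from Normal(5.5, 1.2) -- whose 95% nearest-rank quantile sits
#' near the conventional cutoff of 7.5 -- expressed proteins uniformly in
#' 9--13 and silent proteins uniformly in 1--5, so a threshold derived
#' from the controls separates the two groups exactly and forced on/off
#' sets are respected deterministically.
#'
#' @param protein_table Protein data frame (uses the `accession` column).
#' @param tissue_specs List of per-tissue specifications, each a list with
#'   `name`, `p_expressed` (probability a protein is expressed), and
#'   optional accession vectors `force_on`, `force_off`.
#' @param seed Integer seed.
#' @param n_controls Number of negative-control probes (default 200).
#' @return List with `matrix` (proteins x tissues A-values) and
#'   `negative_controls`.
#' @export
generate_expression <- function(protein_table, tissue_specs, seed,
                                n_controls = 200L) {
  acc <- as.character(protein_table$accession)
  for (spec in tissue_specs) {
    forced <- c(spec$force_on, spec$force_off)
    unknown <- setdiff(forced, acc)
    if (length(unknown)) {
      stop_pw("forced accession(s) not in protein table: ",
              paste(unknown, collapse = ", "))
    }
  }
  with_seed(seed, {
    controls <- stats::rnorm(n_controls, mean = 5.5, sd = 1.2)
    mat <- vapply(tissue_specs, function(spec) {
      on <- stats::runif(length(acc)) < spec$p_expressed
      on[acc %in% spec$force_on] <- TRUE
      on[acc %in% spec$force_off] <- FALSE
      ifelse(on, stats::runif(length(acc), 9, 13), stats::runif(length(acc), 1, 5))
    }, numeric(length(acc)))
    dimnames(mat) <- list(acc, vapply(tissue_specs, `[[`, character(1), "name"))
    list(matrix = mat, negative_controls = controls)
  })
}

#' Bimodality of a reachability distribution
#'
#' A reachability distribution is called bimodal when a wide gap separates
#' a populated high-reachability mode (the regulatory core and its
#' upstream feeders) from a populated low-reachability mode: the largest
#' gap between consecutive observed values must span at least
#' `gap_fraction` of the reference node count, with at least
#' `min_side_mass` of the nodes on each side.
#'
#' @param counts Integer reachability values.
#' @param n Reference node count (defaults to `length(counts)`).
#' @param gap_fraction Minimum gap width as a fraction of `n` (default 0.25).
#' @param min_side_mass Minimum node fraction in each mode (default 0.15).
#' @return Logical.
#' @export
reachability_bimodality <- function(counts, n = length(counts),
                                    gap_fraction = 0.25,
                                    min_side_mass = 0.15) {
  if (length(counts) < 5L) return(FALSE)
  v <- sort(unique(counts))
  if (length(v) < 2L) return(FALSE)
  gaps <- diff(v)
  k <- which.max(gaps)
  if (gaps[k] < gap_fraction * n) return(FALSE)
  lo <- mean(counts <= v[k])
  hi <- mean(counts >= v[k + 1L])
  lo >= min_side_mass && hi >= min_side_mass
}

#' Run the full pipeline against the planted structure
#'
#' Builds the graph from generated tables, restricts it to the protease
#' web, takes the largest connected component, and checks that the
#' planted structure is recovered: the strongly connected core contains
#' every planted core member (which all share one reachability value),
#' tier counts respect the report's bounds, iterative connector search at
#' k = number of planted bridges returns the bridges, and the
#' reachability distribution is bimodal exactly when a core was planted
#' -- with bimodality destroyed by removing all bridges but preserved by
#' every leave-one-in variant.
#'
#' @param tables A `synthetic_web` object from [generate_web()].
#' @param report Planted-structure report; defaults to `tables$report`.
#' @return A list of diagnostics (all logical except the recovered
#'   member sets), with overall `pass`.
#' @export
structure_recovery_check <- function(tables, report = tables$report) {
  web <- suppressMessages(build_graph(tables$proteins, tables$cleavages,
                                      tables$inhibitions))
  pw <- restrict_to_protease_web(web)
  lcc <- suppressWarnings(largest_connected_component(pw, mode = "weak"))
  prof <- reachability(lcc)
  has_core <- length(report$core) > 0L

  core_recovered <- TRUE
  tier_ok <- TRUE
  bridges_found <- character(0)
  bridge_recovery <- NA
  bimodal_after_removal <- NA
  leave_one_in_bimodal <- NA
  if (has_core) {
    sc <- suppressWarnings(strongly_connected_core(lcc))
    core_recovered <- all(report$core %in% sc$core)
    tier_ok <- sc$n_core >= report$expected$n_core_min &&
      sc$n_upstream >= report$expected$n_upstream_min &&
      sc$r_core >= report$expected$r_core_min
    if (length(report$bridges)) {
      cs <- iterative_connector_search(lcc, k = length(report$bridges))
      bridges_found <- cs$order
      bridge_recovery <- setequal(cs$order, report$bridges)
      ck <- combinatorial_knockout(lcc, report$bridges)
      bimodal_after_removal <- reachability_bimodality(
        ck$all_removed$reachability, n = n_nodes(lcc))
      leave_one_in_bimodal <- all(vapply(ck$leave_one_in, function(r) {
        reachability_bimodality(r$reachability, n = n_nodes(lcc))
      }, logical(1)))
    }
  }
  bimodal <- reachability_bimodality(prof$counts, n = n_nodes(lcc))

  diagnostics <- list(
    core_recovered = core_recovered,
    tier_ok = tier_ok,
    bridges_found = bridges_found,
    bridge_recovery = bridge_recovery,
    bimodality_observed = bimodal,
    bimodality_matches_planting = bimodal == has_core,
    bimodality_after_bridge_removal = bimodal_after_removal,
    leave_one_in_bimodal = leave_one_in_bimodal
  )
  diagnostics$pass <- core_recovered && tier_ok &&
    diagnostics$bimodality_matches_planting &&
    (!isTRUE(has_core && length(report$bridges) > 0L) ||
       (isTRUE(bridge_recovery) && isFALSE(bimodal_after_removal) &&
          isTRUE(leave_one_in_bimodal)))
  diagnostics
}
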