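#' Specification of a synthetic test fixture
#'
#' Fixtures emulate the pipeline's three inputs — a signed network with a
#' known minimum feedback vertex set, a two-phenotype normalized
#' expression table with separated markers, and optional noise-injected
#' replicates — so the full pipeline builds and tests with no downloads.
#'
#' @param n_nodes total node count.
#' @param cycle_lengths lengths of the vertex-disjoint directed cycles to
#'   plant (a length of 1 is a self-loop); the minimum FVS size equals the
#'   number of planted cycles.
#' @param n_markers internal-marker nodes (chosen among the non-cycle
#'   nodes).
#' @param effect_size desired-vs-undesired marker separation in log units
#'   (default 2).
#' @param n_replicates samples per phenotype (default 3).
#' @param jitter within-phenotype replicate standard deviation in log
#'   units (default 0.05, small against the default effect size so marker
#'   checks are unambiguous).
#' @param scaffold_prob probability of each feasible acyclic scaffold edge
#'   (default 0.15).
#' @param seed RNG seed.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_nodes = 12L, cycle_lengths = 3L, n_markers = 3L,
                         effect_size = 2, n_replicates = 3L, jitter = 0.05,
                         scaffold_prob = 0.15, seed = 1L) {
  stopifnot(n_nodes >= 1, all(cycle_lengths >= 1),
            sum(cycle_lengths) <= n_nodes,
            n_markers >= 1, n_markers <= n_nodes - sum(cycle_lengths),
            effect_size >= 0, n_replicates >= 1, jitter >= 0,
            scaffold_prob >= 0, scaffold_prob <= 1)
  structure(list(n_nodes = as.integer(n_nodes),
                 cycle_lengths = as.integer(cycle_lengths),
                 n_markers = as.integer(n_markers),
                 effect_size = effect_size,
                 n_replicates = as.integer(n_replicates),
                 jitter = jitter, scaffold_prob = scaffold_prob,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a signed network with a known minimum FVS size
#'
#' Plants vertex-disjoint directed cycles of the requested lengths (all
#' activating, so signal flow around them is stable), then adds random
#' acyclic scaffolding edges that only run forward in the global node
#' order and never enter a cycle block — so the planted cycles are the
#' only cycles and the minimum FVS size equals their number. For networks
#' of at most 15 nodes the size is certified against the brute-force
#' oracle at build time and stored in `attr(, "min_fvs_size")`.
#'
#' @param spec a [fixture_spec()].
#' @return a [signed_digraph] with attributes `min_fvs_size` and
#'   `cycle_nodes` (list of planted-cycle member vectors).
#' @export
make_network <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_nodes
  nodes <- sprintf("n%02d", seq_len(n))
  local_seed(spec$seed, {
    edges <- list()
    pos <- 0L
    cycle_nodes <- list()
    for (len in spec$cycle_lengths) {
      mem <- nodes[pos + seq_len(len)]
      cyc <- if (len == 1) {
        data.frame(source = mem, sign = 1L, target = mem)
      } else {
        data.frame(source = mem, sign = 1L, target = c(mem[-1], mem[1]))
      }
      edges[[length(edges) + 1L]] <- cyc
      cycle_nodes[[length(cycle_nodes) + 1L]] <- mem
      pos <- pos + len
    }
    blk <- rep(0L, n)                      # 0 = free scaffold node
    for (b in seq_along(cycle_nodes)) {
      blk[match(cycle_nodes[[b]], nodes)] <- b
    }
    # forward scaffold edges; targets inside cycle blocks are allowed only
    # from strictly earlier nodes outside that block (still forward-only,
    # so no new cycle can form)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (blk[i] != 0L && blk[i] == blk[j]) next  # stay out of blocks
        if (stats::runif(1) < spec$scaffold_prob) {
          edges[[length(edges) + 1L]] <- data.frame(
            source = nodes[i],
            sign = if (stats::runif(1) < 0.75) 1L else -1L,
            target = nodes[j])
        }
      }
    }
    g <- signed_digraph(do.call(rbind, edges), nodes = nodes)
    size <- length(spec$cycle_lengths)
    if (n <= 15) {
      bf <- brute_force_min_fvs(g)
      stopifnot(bf$size == size)  # certify the plant
    }
    attr(g, "min_fvs_size") <- size
    attr(g, "cycle_nodes") <- cycle_nodes
    g
  })
}

#' Generate a two-phenotype expression table for a fixture network
#'
#' Baseline (undesired) values are drawn uniformly in `[0.5, 1.5]` per
#' node. Desired-phenotype samples shift the marker nodes by
#' `effect_size` (direction drawn per marker, mostly up) and additionally
#' shift the first planted-cycle node up by the same amount, so that a
#' single upregulation of that control node is a plantable reprogramming
#' scheme. Replicates add Gaussian jitter.
#'
#' @param g a network from [make_network()].
#' @param spec the [fixture_spec()] used to build `g`.
#' @return list with `expr` (an [expression_table]), `markers` (a
#'   [marker_spec()] data frame with expected directions), and
#'   `control_shift` (the non-marker node shifted between phenotypes).
#' @export
make_expression <- function(g, spec) {
  stopifnot(inherits(g, "signed_digraph"), inherits(spec, "fixture_spec"))
  nodes <- g$nodes
  cyc <- unlist(attr(g, "cycle_nodes"))
  free <- setdiff(nodes, cyc)
  local_seed(spec$seed + 1L, {
    markers <- utils::tail(free, spec$n_markers)
    dirs <- ifelse(stats::runif(spec$n_markers) < 0.8, "up", "down")
    base <- stats::setNames(stats::runif(length(nodes), 0.5, 1.5), nodes)
    des <- base
    des[markers] <- des[markers] +
      ifelse(dirs == "up", spec$effect_size, -spec$effect_size)
    ctrl <- if (length(cyc)) cyc[1] else free[1]
    des[ctrl] <- des[ctrl] + spec$effect_size
    r <- spec$n_replicates
    mk <- function(mu, tag) {
      m <- matrix(rep(mu, r), ncol = r) +
        stats::rnorm(length(mu) * r, 0, spec$jitter)
      dimnames(m) <- list(nodes, paste0(tag, "_", seq_len(r)))
      m
    }
    values <- cbind(mk(base, "undesired"), mk(des, "desired"))
    phen <- stats::setNames(rep(c("undesired", "desired"), each = r),
                            colnames(values))
    list(expr = expression_table(values, phen),
         markers = marker_spec(markers, direction = dirs),
         control_shift = ctrl)
  })
}

#' Inject Gaussian noise into initial states
#'
#' Every node with a nonzero value is perturbed by a draw from a normal
#' distribution whose mean is the value and whose standard deviation is
#' `fraction` (an absolute SD against unit-scale values, so 0.05 emulates
#' 5% noise). Zero-valued nodes are untouched; `fraction = 0` is the
#' identity.
#'
#' @param states named numeric vector or nodes x states matrix.
#' @param fraction noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return object of the same shape as `states`.
#' @export
inject_noise <- function(states, fraction, seed = 1L) {
  stopifnot(is.numeric(states), fraction >= 0)
  if (fraction == 0) return(states)
  local_seed(seed, {
    nz <- states != 0
    states[nz] <- states[nz] + stats::rnorm(sum(nz), 0, fraction)
    states
  })
}

#' The standard hand-constructed end-to-end fixture
#'
#' A 12-node network built for planted-scheme recovery: a 3-cycle
#' `A -> B -> C -> A` (the FVS candidates), three marker nodes `M1..M3`
#' activated directly by `A`, upstream inputs and downstream padding
#' nodes. The undesired phenotype has `A` and the markers low; the desired
#' phenotype has them high. Upregulating `A` (the planted scheme `A:up`)
#' drives the markers past the desired boundaries, while the all-unchanged
#' scheme stays at the undesired attractor.
#'
#' @param seed RNG seed for the replicate jitter.
#' @param n_replicates samples per phenotype (default 3).
#' @param jitter replicate standard deviation (default 0.05).
#' @return list with `g`, `expr`, `markers`, `planted_scheme` (named
#'   assignment vector), `control` (the planted control node).
#' @export
standard_fixture <- function(seed = 1L, n_replicates = 3L, jitter = 0.05) {
  edges <- data.frame(
    source = c("A", "B", "C",  "A",  "A",  "A",  "S1", "S2", "M1", "M2",
               "S1", "E1"),
    sign   = c(1,   1,   1,    1,    1,    1,    1,    -1,   1,    1,
               1,    1),
    target = c("B", "C", "A",  "M1", "M2", "M3", "A",  "B",  "D1", "D2",
               "E1", "E2")
  )
  g <- signed_digraph(edges,
                      nodes = c("A", "B", "C", "M1", "M2", "M3",
                                "S1", "S2", "D1", "D2", "E1", "E2"))
  base <- c(A = 0.5, B = 0.6, C = 0.6, M1 = 0.4, M2 = 0.5, M3 = 0.45,
            S1 = 1.0, S2 = 1.0, D1 = 0.5, D2 = 0.5, E1 = 0.8, E2 = 0.8)
  des <- base
  des[c("A", "M1", "M2", "M3")] <- des[c("A", "M1", "M2", "M3")] + 2
  local_seed(seed, {
    r <- n_replicates
    mk <- function(mu, tag) {
      m <- matrix(rep(mu, r), ncol = r) +
        stats::rnorm(length(mu) * r, 0, jitter)
      dimnames(m) <- list(names(mu), paste0(tag, "_", seq_len(r)))
      m
    }
    values <- cbind(mk(base, "undesired"), mk(des, "desired"))
    phen <- stats::setNames(rep(c("undesired", "desired"), each = r),
                            colnames(values))
    list(g = g,
         expr = expression_table(values, phen),
         markers = marker_spec(c("M1", "M2", "M3"), direction = "up"),
         planted_scheme = stats::setNames(1L, "A"),
         control = "A")
  })
}

#' Write a fixture to the pipeline's on-disk input formats
#'
#' Emits `network.tsv` (3-column edges), `expression.tsv` (nodes x
#' samples), `phenotypes.tsv` (sample, phenotype), `markers.tsv` (node,
#' direction, group) and, when given, `mutations.tsv` (gene, effect).
#'
#' @param dir output directory (created if needed).
#' @param g a [signed_digraph].
#' @param expr an [expression_table].
#' @param markers a [marker_spec()] data frame.
#' @param mutations optional [mutation_profile()].
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(dir, g, expr, markers, mutations = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network(g, file.path(dir, "network.tsv"))
  utils::write.table(cbind(node = rownames(expr$values), expr$values),
                     file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(expr$phenotype),
                                phenotype = unname(expr$phenotype)),
                     file.path(dir, "phenotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(markers, file.path(dir, "markers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(mutations)) {
    utils::write.table(mutations, file.path(dir, "mutations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
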