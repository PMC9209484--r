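#' Test whether a node set is a feedback vertex set
#'
#' A set is an FVS iff removing it leaves the directed graph without
#' cycles (self-loops count as cycles of length 1).
#'
#' @param g a [signed_digraph].
#' @param candidate character vector of nodes (may be empty).
#' @return logical.
#' @export
is_fvs <- function(g, candidate = character()) {
  !find_cycles_exists(g, removed = candidate)
}

#' Exhaustively enumerate minimum feedback vertex sets
#'
#' Enumerates node subsets by increasing size and returns every FVS of the
#' minimum size. Intended as an exact oracle for small graphs; refuses
#' graphs with more than 20 nodes.
#'
#' @param g a [signed_digraph].
#' @param size_cap largest subset size to try (default `|V|`).
#' @return list with `size` (minimum FVS size) and `fvs` (list of sorted
#'   character vectors, every minimum-size FVS). If `size_cap` is exceeded
#'   before an FVS is found, an error is raised.
#' @export
brute_force_min_fvs <- function(g, size_cap = length(g$nodes)) {
  stopifnot(inherits(g, "signed_digraph"))
  n <- length(g$nodes)
  if (n > 20) {
    stop("brute_force_min_fvs is an exact oracle for graphs with <= 20 ",
         "nodes (got ", n, "); use sa_min_fvs / enumerate_fvs instead")
  }
  ei <- edge_index(g)
  # self-loop nodes are forced members: enumerate only over the rest
  sl <- self_loop_nodes(g)
  rest <- setdiff(g$nodes, sl)
  base_keep <- rep(TRUE, n)
  if (length(sl)) base_keep[node_index(g, sl)] <- FALSE
  if (!has_cycle_cpp(n, ei$from, ei$to, base_keep)) {
    return(list(size = length(sl), fvs = list(sort(sl))))
  }
  for (k in seq_len(min(size_cap - length(sl), length(rest)))) {
    combos <- utils::combn(rest, k, simplify = FALSE)
    hits <- Filter(function(cand) {
      keep <- base_keep
      keep[node_index(g, cand)] <- FALSE
      !has_cycle_cpp(n, ei$from, ei$to, keep)
    }, combos)
    if (length(hits)) {
      return(list(size = k + length(sl),
                  fvs = lapply(hits, function(h) sort(c(sl, h)))))
    }
  }
  stop("no FVS found within size_cap = ", size_cap)
}

#' Simulated-annealing schedule for the FVS search
#'
#' @param initial_temperature starting temperature (default 0.6).
#' @param cooling_factor geometric cooling multiplier per level (0.99).
#' @param moves_per_level proposed moves per temperature level; `NULL`
#'   means `50 * |V|`, resolved at run time.
#' @param stagnation_levels stop after this many consecutive levels without
#'   improvement of the best solution (default 50).
#' @param seed RNG seed.
#' @return an `sa_schedule` list.
#' @export
sa_schedule <- function(initial_temperature = 0.6, cooling_factor = 0.99,
                        moves_per_level = NULL, stagnation_levels = 50L,
                        seed = 1L) {
  stopifnot(initial_temperature > 0,
            cooling_factor > 0, cooling_factor < 1,
            is.null(moves_per_level) || moves_per_level >= 1,
            stagnation_levels >= 1)
  structure(list(initial_temperature = initial_temperature,
                 cooling_factor = cooling_factor,
                 moves_per_level = moves_per_level,
                 stagnation_levels = as.integer(stagnation_levels),
                 seed = as.integer(seed)),
            class = "sa_schedule")
}

#' Find a minimal feedback vertex set by simulated annealing
#'
#' SA-FVSP local search: the complement of the FVS is maintained as a
#' topologically ordered acyclic induced subgraph; moves insert an outside
#' node next to its neighbours and evict order-violating ones, accepted by
#' the Metropolis rule. The returned set always passes [is_fvs()]; a
#' deterministic greedy pass then removes redundant members, so the result
#' is inclusion-minimal. Minimum *size* is only certified against
#' [brute_force_min_fvs()] on small graphs.
#'
#' @param g a [signed_digraph].
#' @param schedule an [sa_schedule()].
#' @return an `fvs_result`: list with `members` (sorted character),
#'   `size`, `verified_minimal` (inclusion-minimality, always `TRUE` after
#'   pruning), `search_seed`, `self_loop_members` (nodes forced into every
#'   FVS by a self-loop).
#' @export
sa_min_fvs <- function(g, schedule = sa_schedule()) {
  stopifnot(inherits(g, "signed_digraph"), inherits(schedule, "sa_schedule"))
  n <- length(g$nodes)
  if (n == 0) stop("empty graph")
  ei <- edge_index(g)
  mpl <- schedule$moves_per_level
  if (is.null(mpl)) mpl <- 50L * n
  inS <- local_seed(schedule$seed, {
    sa_fvsp_cpp(n, ei$from, ei$to,
                schedule$initial_temperature, schedule$cooling_factor,
                as.integer(mpl), schedule$stagnation_levels)
  })
  fvs <- g$nodes[!inS]
  # greedy inclusion-minimality pruning, deterministic in node order
  for (v in fvs) {
    cand <- setdiff(fvs, v)
    if (is_fvs(g, cand)) fvs <- cand
  }
  stopifnot(is_fvs(g, fvs))
  structure(list(members = sort(fvs), size = length(fvs),
                 verified_minimal = TRUE,
                 search_seed = schedule$seed,
                 self_loop_members = sort(intersect(self_loop_nodes(g), fvs))),
            class = "fvs_result")
}

#' @export
print.fvs_result <- function(x, ...) {
  cat("fvs_result: size", x$size, "\n  members:",
      paste(x$members, collapse = ", "), "\n")
  if (length(x$self_loop_members)) {
    cat("  forced by self-loop:", paste(x$self_loop_members, collapse = ", "),
        "\n")
  }
  invisible(x)
}

local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

#' Enumerate distinct minimal feedback vertex sets
#'
#' For graphs small enough for the exact oracle (`<= exact_limit` nodes),
#' returns the complete family of minimum-size FVSes by enumeration.
#' Larger graphs are searched by repeated randomized SA restarts; distinct
#' minimum-size sets are collected until `saturation_rounds` consecutive
#' restarts add nothing new. Saturation is a heuristic stopping rule, not
#' a completeness certificate.
#'
#' @param g a [signed_digraph].
#' @param schedule an [sa_schedule()]; restart r uses seed
#'   `schedule$seed + r`.
#' @param max_restarts restart budget for the SA path (default 200).
#' @param saturation_rounds consecutive fruitless restarts before stopping
#'   (default 25).
#' @param method `"auto"` (exact when feasible), `"exact"`, or `"sa"`.
#' @param exact_limit node-count bound for the exact path (default 12).
#' @return list with `size`, `fvs` (list of sorted member vectors),
#'   `union` (all nodes in any FVS), `method`, `restarts_used`.
#' @export
enumerate_fvs <- function(g, schedule = sa_schedule(), max_restarts = 200L,
                          saturation_rounds = 25L,
                          method = c("auto", "exact", "sa"),
                          exact_limit = 12L) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (length(g$nodes) <= exact_limit) "exact" else "sa"
  }
  if (method == "exact") {
    bf <- brute_force_min_fvs(g)
    return(list(size = bf$size, fvs = bf$fvs,
                union = sort(unique(unlist(bf$fvs))),
                method = "exact", restarts_used = 0L))
  }
  found <- list()
  keys <- character()
  best <- Inf
  stagnant <- 0L
  restarts <- 0L
  for (r in seq_len(max_restarts)) {
    restarts <- r
    res <- sa_min_fvs(g, sa_schedule(
      initial_temperature = schedule$initial_temperature,
      cooling_factor = schedule$cooling_factor,
      moves_per_level = schedule$moves_per_level,
      stagnation_levels = schedule$stagnation_levels,
      seed = schedule$seed + r))
    key <- paste(res$members, collapse = "|")
    if (res$size < best) {
      best <- res$size
      found <- list(res$members)
      keys <- key
      stagnant <- 0L
    } else if (res$size == best && !(key %in% keys)) {
      found <- c(found, list(res$members))
      keys <- c(keys, key)
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
      if (stagnant >= saturation_rounds) break
    }
  }
  ord <- order(keys)
  list(size = if (is.finite(best)) best else 0L, fvs = found[ord],
       union = sort(unique(unlist(found))), method = "sa",
       restarts_used = restarts)
}

#' Remove already-fixed nodes from a control-node set
#'
#' Nodes whose states are permanently overridden upstream (e.g. by a
#' mutation or a treatment) cannot be reassigned by a perturbation scheme
#' and are dropped from the FVS before scheme generation.
#'
#' @param fvs an `fvs_result` or a character vector of FVS members.
#' @param fixed character vector of already-overridden nodes.
#' @return character vector of controllable nodes (possibly empty, with a
#'   warning when everything was fixed).
#' @export
exclude_fixed_nodes <- function(fvs, fixed = character()) {
  members <- if (inherits(fvs, "fvs_result")) fvs$members else fvs
  control <- setdiff(members, fixed)
  dropped <- intersect(members, fixed)
  if (length(dropped)) {
    message("exclude_fixed_nodes: dropped ", length(dropped),
            " already-fixed node(s): ", paste(dropped, collapse = ", "),
            " -> ", length(control), " controllable node(s)")
  }
  if (length(control) == 0) {
    warning("all FVS members are already fixed; no controllable nodes remain")
  }
  control
}
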