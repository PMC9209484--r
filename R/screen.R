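SYMBOLS <- c("unchanged", "up", "down")

#' Generate all 3^n perturbation schemes over the control nodes
#'
#' Each scheme assigns `unchanged`, `up` (overexpression), or `down`
#' (knockout) to every control node. Schemes are produced in deterministic
#' lexicographic order (a ternary counter over the node order with symbol
#' order unchanged < up < down), so the first scheme is all-unchanged.
#'
#' @param control_nodes ordered character vector of FVS control nodes.
#' @param cap refuse more control nodes than this unless `allow_large`
#'   (default 16; 3^16 is ~43M schemes).
#' @param allow_large explicit opt-out of the cap.
#' @return a `perturbation_schemes` object: list with `nodes` and
#'   `assignment`, an integer matrix (schemes x nodes, values 0 =
#'   unchanged, 1 = up, 2 = down).
#' @examples
#' generate_schemes(c("A", "B"))  # 9 schemes
#' @export
generate_schemes <- function(control_nodes, cap = 16L, allow_large = FALSE) {
  stopifnot(is.character(control_nodes), length(control_nodes) >= 1,
            !anyDuplicated(control_nodes))
  n <- length(control_nodes)
  if (n > cap && !allow_large) {
    stop("refusing to generate 3^", n, " = ", format(3^n, big.mark = ","),
         " schemes for ", n, " control nodes (cap = ", cap,
         "); pass allow_large = TRUE to proceed")
  }
  m <- 3L^n
  assignment <- vapply(seq_len(n), function(j) {
    rep(rep(0:2, each = 3L^(n - j)), times = 3L^(j - 1L))
  }, integer(m))
  if (is.null(dim(assignment))) assignment <- matrix(assignment, nrow = m)
  colnames(assignment) <- control_nodes
  structure(list(nodes = control_nodes, assignment = assignment),
            class = "perturbation_schemes")
}

#' @export
print.perturbation_schemes <- function(x, ...) {
  cat("perturbation_schemes:", nrow(x$assignment), "schemes over",
      length(x$nodes), "control node(s):", paste(x$nodes, collapse = ", "),
      "\n")
  invisible(x)
}

#' Canonical scheme identifiers
#'
#' Format: `node:symbol|node:symbol|...` in control-node order; a
#' bijection with assignments (see [parse_scheme_id()]).
#'
#' @param schemes a `perturbation_schemes` object.
#' @param which scheme row indices (default all).
#' @return character vector of ids.
#' @export
scheme_ids <- function(schemes, which = seq_len(nrow(schemes$assignment))) {
  a <- schemes$assignment[which, , drop = FALSE]
  cols <- lapply(seq_along(schemes$nodes), function(j) {
    paste0(schemes$nodes[j], ":", SYMBOLS[a[, j] + 1L])
  })
  do.call(paste, c(cols, sep = "|"))
}

#' Parse a scheme identifier back to an assignment
#'
#' @param id a single id produced by [scheme_ids()].
#' @return named integer vector (0 unchanged, 1 up, 2 down).
#' @export
parse_scheme_id <- function(id) {
  parts <- strsplit(strsplit(id, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
  sym <- vapply(parts, `[`, "", 2)
  code <- match(sym, SYMBOLS) - 1L
  if (anyNA(code)) stop("malformed scheme id: ", id)
  stats::setNames(code, vapply(parts, `[`, "", 1))
}

#' Mutation profile (gain/loss of function)
#'
#' @param genes character vector.
#' @param effect `"gain_of_function"` or `"loss_of_function"` per gene.
#' @return a `mutation_profile` data frame.
#' @export
mutation_profile <- function(genes = character(), effect = character()) {
  stopifnot(length(genes) == length(effect),
            all(effect %in% c("gain_of_function", "loss_of_function")))
  if (anyDuplicated(genes)) stop("a gene cannot carry two mutation effects")
  structure(data.frame(gene = genes, effect = effect,
                       stringsAsFactors = FALSE),
            class = c("mutation_profile", "data.frame"))
}

# fixed override values implied by mutations and treatments, from the
# undesired-phenotype expression extrema (Eqs. of override_value)
baseline_override_set <- function(g, expr_und = NULL,
                                  mutations = NULL, treatments = NULL) {
  entries <- character(0)
  dirs <- character(0)
  if (!is.null(mutations) && nrow(mutations)) {
    entries <- c(entries, mutations$gene)
    dirs <- c(dirs, ifelse(mutations$effect == "gain_of_function",
                           "up", "down"))
  }
  if (!is.null(treatments) && length(treatments)) {
    if (is.null(names(treatments))) stop("treatments must be named by node")
    stopifnot(all(treatments %in% c("knockout", "overexpress")))
    clash <- intersect(names(treatments), entries)
    if (length(clash)) stop("node(s) with both mutation and treatment: ",
                            paste(clash, collapse = ", "))
    entries <- c(entries, names(treatments))
    dirs <- c(dirs, ifelse(treatments == "overexpress", "up", "down"))
  }
  if (length(entries) == 0) return(stats::setNames(numeric(0), character(0)))
  node_index(g, entries)
  vals <- vapply(seq_along(entries), function(i) {
    if (is.null(expr_und)) {
      override_value(direction = dirs[i], fallback = TRUE)
    } else {
      override_value(expr_und[entries[i], ], direction = dirs[i])
    }
  }, 0)
  stats::setNames(vals, entries)
}

#' Resolve a perturbation scheme into fixed override values
#'
#' Mutations and treatments are applied first, then the scheme's up/down
#' assignments, mapped through [override_value()] on the node's expression
#' across the undesired-phenotype samples (or the data-free fallback).
#' Unchanged nodes are absent from the set. A scheme reassigning a
#' mutation- or treatment-fixed node is an error (such nodes should have
#' been removed by [exclude_fixed_nodes()]).
#'
#' @param scheme named integer assignment (as from [parse_scheme_id()] or a
#'   row of `schemes$assignment`).
#' @param g a [signed_digraph].
#' @param expr an [expression_table] with undesired samples, or `NULL` for
#'   the fallback constants.
#' @param mutations a [mutation_profile()] or `NULL`.
#' @param treatments named character vector node -> `"knockout"` /
#'   `"overexpress"`, or `NULL`.
#' @return named numeric override vector.
#' @export
resolve_overrides <- function(scheme, g, expr = NULL, mutations = NULL,
                              treatments = NULL) {
  und <- undesired_values(expr)
  base <- baseline_override_set(g, und, mutations, treatments)
  active <- scheme[scheme != 0L]
  clash <- intersect(names(active), names(base))
  if (length(clash)) {
    stop("scheme reassigns already-fixed node(s): ",
         paste(clash, collapse = ", "))
  }
  sv <- vapply(seq_along(active), function(i) {
    nd <- names(active)[i]
    dir <- if (active[i] == 1L) "up" else "down"
    if (is.null(und)) override_value(direction = dir, fallback = TRUE)
    else override_value(und[nd, ], direction = dir)
  }, 0)
  c(base, stats::setNames(sv, names(active)))
}

undesired_values <- function(expr) {
  if (is.null(expr)) return(NULL)
  stopifnot(inherits(expr, "expression_table"))
  v <- expr$values[, expr$phenotype == "undesired", drop = FALSE]
  if (ncol(v) == 0) stop("expression table has no undesired samples")
  v
}

#' Run the perturbation screen
#'
#' For every undesired-phenotype replicate and every scheme, computes the
#' attractor reached from that replicate's expression profile as the
#' initial state, with the scheme's overrides (plus mutation/treatment
#' overrides) fixed. Schemes are propagated in batches.
#'
#' @param g a [signed_digraph].
#' @param schemes a `perturbation_schemes` object.
#' @param expr an [expression_table] aligned to `g`; its undesired samples
#'   are the replicates.
#' @param cfg an [sfa_config()].
#' @param mutations,treatments as in [resolve_overrides()].
#' @param chunk_size schemes propagated per batch (default 20000).
#' @return a `screen_result`: list with `scheme_ids`, `replicates`,
#'   `values` (list per replicate of nodes x schemes matrices),
#'   `converged` (list per replicate), `overrides_up`/`overrides_down`
#'   (resolved per-node override values).
#' @export
run_screen <- function(g, schemes, expr, cfg = sfa_config(),
                       mutations = NULL, treatments = NULL,
                       chunk_size = 20000L) {
  stopifnot(inherits(schemes, "perturbation_schemes"))
  if (!identical(rownames(expr$values), g$nodes)) {
    expr <- align_expression(expr, g)
  }
  und <- undesired_values(expr)
  reps <- colnames(und)
  base <- baseline_override_set(g, und, mutations, treatments)
  clash <- intersect(schemes$nodes, names(base))
  if (length(clash)) {
    stop("control node(s) already fixed by mutation/treatment: ",
         paste(clash, collapse = ", "), "; run exclude_fixed_nodes() first")
  }
  n <- length(g$nodes)
  m <- nrow(schemes$assignment)
  cn_idx <- node_index(g, schemes$nodes)
  p_up <- vapply(schemes$nodes, function(nd) override_value(und[nd, ], "up"),
                 0)
  p_down <- vapply(schemes$nodes,
                   function(nd) override_value(und[nd, ], "down"), 0)

  values <- converged <- iterations <- vector("list", length(reps))
  names(values) <- names(converged) <- names(iterations) <- reps
  for (r in seq_along(reps)) {
    vr <- matrix(NA_real_, n, m, dimnames = list(g$nodes, NULL))
    cr <- logical(m)
    ir <- integer(m)
    b <- und[, r]
    for (start in seq(1L, m, by = chunk_size)) {
      idx <- start:min(start + chunk_size - 1L, m)
      a <- schemes$assignment[idx, , drop = FALSE]
      P <- matrix(NA_real_, n, length(idx),
                  dimnames = list(g$nodes, NULL))
      if (length(base)) P[node_index(g, names(base)), ] <- base
      for (j in seq_along(cn_idx)) {
        up <- a[, j] == 1L
        dn <- a[, j] == 2L
        P[cn_idx[j], up] <- p_up[j]
        P[cn_idx[j], dn] <- p_down[j]
      }
      B <- matrix(b, n, length(idx), dimnames = list(g$nodes, NULL))
      res <- propagate_batch(g, B, overrides = P, cfg = cfg)
      vr[, idx] <- res$values
      cr[idx] <- res$converged
      ir[idx] <- res$iterations
    }
    if (any(!cr)) {
      warning("replicate ", reps[r], ": ", sum(!cr),
              " scheme(s) did not converge; recorded, not fatal")
    }
    values[[r]] <- vr
    converged[[r]] <- cr
    iterations[[r]] <- ir
  }
  structure(list(scheme_ids = scheme_ids(schemes), schemes = schemes,
                 replicates = reps, values = values, converged = converged,
                 iterations = iterations,
                 overrides_up = p_up, overrides_down = p_down,
                 baseline_overrides = base),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result:", length(x$scheme_ids), "schemes x",
      length(x$replicates), "replicate(s) =",
      length(x$scheme_ids) * length(x$replicates), "attractors\n")
  invisible(x)
}
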