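#' Signal-flow analysis settings
#'
#' @param alpha weight of the network term in the propagation update,
#'   in `[0, 1)`. The default 0.9 gives greater weight to network topology
#'   than to a node's own initial activity.
#' @param tolerance convergence threshold on the max-norm change between
#'   successive states; default `1e-6`.
#' @param max_iterations iteration cap; non-convergence is flagged, never
#'   silent.
#' @return an `sfa_config` list.
#' @export
sfa_config <- function(alpha = 0.9, tolerance = 1e-6, max_iterations = 1000L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0, alpha < 1,
            is.numeric(tolerance), tolerance > 0,
            max_iterations >= 1)
  structure(list(alpha = alpha, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations)),
            class = "sfa_config")
}

#' Degree-normalized signed weight matrix
#'
#' For each edge j -> i, `W[i, j] = sign(ij) / sqrt(D_out(j) * D_in(i))`;
#' zero elsewhere. Rows are targets, columns sources, both in graph node
#' order.
#'
#' @param g a [signed_digraph].
#' @return a dense numeric matrix with node dimnames.
#' @export
weight_matrix <- function(g) {
  stopifnot(inherits(g, "signed_digraph"))
  n <- length(g$nodes)
  if (n == 0) stop("empty graph")
  deg <- degrees(g)
  W <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges)) {
    si <- match(g$edges$source, g$nodes)
    ti <- match(g$edges$target, g$nodes)
    W[cbind(ti, si)] <- g$edges$sign /
      sqrt(deg$out_degree[si] * deg$in_degree[ti])
  }
  W
}

as_override_set <- function(overrides, g) {
  if (is.null(overrides) || length(overrides) == 0) {
    return(structure(numeric(0), names = character(0)))
  }
  v <- unlist(overrides)
  if (is.null(names(v)) || any(names(v) == "")) {
    stop("overrides must be a named numeric vector (node -> fixed value)")
  }
  if (!all(is.finite(v))) stop("override values must be finite")
  node_index(g, names(v)) # validates membership
  v
}

#' Propagate signal flow to a fixed-point attractor
#'
#' Iterates `x_i(t+1) = alpha * sum_j W[i,j] x_j(t) + (1 - alpha) * b_i` for
#' every free node synchronously; overridden nodes are held at their fixed
#' value `p_i` at all times (they still feed that value to their targets).
#' The initial iterate is `b` with overrides applied. Iteration stops when
#' the max-norm change drops below `tolerance`, or at `max_iterations` with
#' `converged = FALSE`.
#'
#' @param g a [signed_digraph].
#' @param init named numeric vector covering every node: the (log-scale)
#'   initial activities `b`. Values are used as given, never re-logged.
#' @param overrides named numeric vector of permanently fixed node values,
#'   or `NULL`.
#' @param cfg an [sfa_config()].
#' @param label optional provenance tag stored on the result.
#' @return an `sfa_attractor`: list with `values` (named numeric),
#'   `converged`, `iterations`, `residual`, `overrides`, `label`.
#' @examples
#' g <- signed_digraph(data.frame(source = "A", sign = 1, target = "B"))
#' a <- propagate(g, c(A = 1, B = 0))
#' a$values  # A: (1-alpha)*b = 0.1; B: alpha*W*0.1 = 0.09
#' @export
propagate <- function(g, init, overrides = NULL, cfg = sfa_config(),
                      label = NULL) {
  b <- init_vector(g, init)
  res <- propagate_batch(g, matrix(b, ncol = 1, dimnames = list(g$nodes, label)),
                         overrides = overrides, cfg = cfg)
  structure(list(values = res$values[, 1],
                 converged = res$converged[1],
                 iterations = res$iterations[1],
                 residual = res$residual[1],
                 overrides = as_override_set(overrides, g),
                 label = label),
            class = "sfa_attractor")
}

#' @export
print.sfa_attractor <- function(x, ...) {
  cat("sfa_attractor (", length(x$values), " nodes): ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " iterations, residual ",
      format(x$residual, digits = 3), "\n", sep = "")
  if (length(x$overrides)) {
    cat("  overrides:", paste(names(x$overrides),
                              format(x$overrides, digits = 4),
                              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

init_vector <- function(g, init) {
  v <- unlist(init)
  if (is.null(names(v))) stop("initial state must be a named numeric vector")
  idx <- match(g$nodes, names(v))
  if (anyNA(idx)) {
    stop("initial state missing node(s): ",
         paste(g$nodes[is.na(idx)], collapse = ", "))
  }
  v <- as.numeric(v[idx])
  if (!all(is.finite(v))) stop("initial state values must be finite")
  names(v) <- g$nodes
  v
}

#' Batched signal-flow propagation
#'
#' Runs [propagate()] simultaneously for many initial states (columns of
#' `B`). Overrides may be shared (a single named vector) or per-column
#' (a matrix `P` of fixed values, `NA` where a node is free in that
#' column). All columns iterate synchronously; per-column convergence
#' iteration counts are recorded at the first time each column's max-norm
#' change falls below tolerance.
#'
#' @param g a [signed_digraph].
#' @param B numeric matrix, nodes x states, rownames = node names (graph
#'   order enforced).
#' @param overrides `NULL`, a named numeric vector applied to all columns,
#'   or a nodes x states matrix with `NA` for free entries.
#' @param cfg an [sfa_config()].
#' @return list with `values` (nodes x states), `converged`, `iterations`,
#'   `residual` (per state).
#' @export
propagate_batch <- function(g, B, overrides = NULL, cfg = sfa_config()) {
  stopifnot(inherits(g, "signed_digraph"), is.matrix(B))
  n <- length(g$nodes)
  if (is.null(rownames(B))) {
    if (nrow(B) != n) stop("B must have one row per node")
    rownames(B) <- g$nodes
  } else {
    B <- B[match(g$nodes, rownames(B)), , drop = FALSE]
    if (anyNA(rownames(B))) stop("B rownames must cover all nodes")
  }
  if (!all(is.finite(B))) stop("initial states must be finite")
  m <- ncol(B)
  W <- cfg$alpha * weight_matrix(g)
  bterm <- (1 - cfg$alpha) * B

  if (is.matrix(overrides)) {
    P <- overrides[match(g$nodes, rownames(overrides)), , drop = FALSE]
    if (ncol(P) != m) stop("override matrix must match ncol(B)")
    mask <- !is.na(P)
  } else {
    ov <- as_override_set(overrides, g)
    P <- matrix(NA_real_, n, m)
    mask <- matrix(FALSE, n, m)
    if (length(ov)) {
      ridx <- node_index(g, names(ov))
      P[ridx, ] <- ov
      mask[ridx, ] <- TRUE
    }
  }
  any_mask <- any(mask)

  X <- B
  if (any_mask) X[mask] <- P[mask]
  iterations <- rep(NA_integer_, m)
  residual <- rep(Inf, m)
  for (it in seq_len(cfg$max_iterations)) {
    Xn <- W %*% X + bterm
    if (any_mask) Xn[mask] <- P[mask]
    if (!all(is.finite(Xn))) {
      stop("signal-flow propagation diverged (non-finite state) at iteration ",
           it)
    }
    cm <- col_max_abs_diff_cpp(Xn, X)
    newly <- is.na(iterations) & cm < cfg$tolerance
    iterations[newly] <- it
    residual <- cm
    X <- Xn
    if (all(!is.na(iterations))) break
  }
  converged <- !is.na(iterations)
  iterations[!converged] <- cfg$max_iterations
  dimnames(X) <- list(g$nodes, colnames(B))
  list(values = X, converged = converged, iterations = iterations,
       residual = residual)
}

#' Compare two attractors node by node
#'
#' The per-node difference of the (log-scale) steady-state values is read
#' analogously to a log fold-change: a positive difference means the first
#' attractor has higher activity at that node. The magnitude is reported
#' but is not a quantitative effect size.
#'
#' @param a,b `sfa_attractor` objects (or named numeric vectors) over the
#'   same node set.
#' @param tolerance absolute difference below which a node is called
#'   `unchanged` (guards float noise); default `1e-9`.
#' @return data frame with columns `node`, `difference`,
#'   `call` (`"up"`, `"down"`, `"unchanged"`).
#' @export
compare_attractors <- function(a, b, tolerance = 1e-9) {
  va <- if (inherits(a, "sfa_attractor")) a$values else a
  vb <- if (inherits(b, "sfa_attractor")) b$values else b
  if (is.null(names(va)) || is.null(names(vb)) ||
      !setequal(names(va), names(vb))) {
    stop("attractors must cover the same node set")
  }
  vb <- vb[names(va)]
  d <- va - vb
  call <- ifelse(abs(d) <= tolerance, "unchanged",
                 ifelse(d > 0, "up", "down"))
  data.frame(node = names(va), difference = unname(d), call = unname(call),
             stringsAsFactors = FALSE)
}

#' Override value for an up- or down-regulated control node
#'
#' Upregulation fixes the node at `max(normexp) + 2.5 * max(normexp)`;
#' downregulation at `min(normexp) - 2.5 * min(normexp)`, where the
#' extrema are taken across the experimental samples of the undesired
#' phenotype. When no expression data exist (`fallback = TRUE`), the
#' fixed values are +2.5 and -2.5 respectively. Note the downregulation
#' formula yields a value above the minimum when `min(normexp) < 0`
#' (possible on log-scale data); a warning is emitted in that case and
#' the formula applied verbatim.
#'
#' @param expr numeric vector of the node's normalized expression values
#'   across undesired-phenotype samples (ignored when `fallback = TRUE`).
#' @param direction `"up"` or `"down"`.
#' @param fallback use the data-free constants +/-2.5.
#' @return the fixed override value `p`.
#' @export
override_value <- function(expr, direction = c("up", "down"),
                           fallback = FALSE) {
  direction <- match.arg(direction)
  if (fallback) return(if (direction == "up") 2.5 else -2.5)
  if (length(expr) == 0 || !all(is.finite(expr))) {
    stop("no finite expression values supplied; use fallback = TRUE ",
         "when expression data are unavailable")
  }
  if (direction == "up") {
    mx <- max(expr)
    mx + 2.5 * mx
  } else {
    mn <- min(expr)
    p <- mn - 2.5 * mn
    if (p > mn) {
      warning("downregulation override (", format(p, digits = 4),
              ") exceeds the observed minimum (", format(mn, digits = 4),
              "); this happens when min(normexp) < 0")
    }
    p
  }
}
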