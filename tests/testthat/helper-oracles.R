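# Independent oracles and generators used across the suite.

# Random signed digraph: every ordered pair (i != j) becomes an edge with
# probability p; optional self-loops with probability p_loop.
rand_digraph <- function(n, p = 0.25, seed = 1, p_loop = 0) {
  set.seed(seed)
  nodes <- sprintf("v%02d", seq_len(n))
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- stats::runif(nrow(pairs)) < p
  e <- pairs[keep, ]
  if (p_loop > 0) {
    lp <- nodes[stats::runif(n) < p_loop]
    if (length(lp)) e <- rbind(e, data.frame(source = lp, target = lp))
  }
  if (nrow(e) == 0) e <- data.frame(source = nodes[1], target = nodes[min(2, n)])
  e$sign <- ifelse(stats::runif(nrow(e)) < 0.7, 1, -1)
  signed_digraph(e, nodes = nodes)
}

# DFS three-colour cycle detection, independent of the package's Kahn check.
dfs_has_cycle <- function(g, removed = character()) {
  nodes <- setdiff(g$nodes, removed)
  keep <- g$edges$source %in% nodes & g$edges$target %in% nodes
  adj <- split(g$edges$target[keep], factor(g$edges$source[keep],
                                            levels = nodes))
  colour <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 white 1 grey 2 black
  found <- FALSE
  visit <- function(v) {
    colour[v] <<- 1L
    for (w in adj[[v]]) {
      if (colour[w] == 1L) found <<- TRUE
      else if (colour[w] == 0L && !found) visit(w)
    }
    colour[v] <<- 2L
  }
  for (v in nodes) if (colour[v] == 0L && !found) visit(v)
  found
}

# Direct linear-solve oracle for the signal-flow fixed point with optional
# overridden (pinned) rows: free rows satisfy (I - aW) x = (1-a) b, pinned
# rows satisfy x_i = p_i.
linear_solve_attractor <- function(g, b, overrides = NULL,
                                   alpha = 0.9) {
  W <- weight_matrix(g)
  n <- length(g$nodes)
  A <- diag(n) - alpha * W
  rhs <- (1 - alpha) * b[g$nodes]
  if (!is.null(overrides)) {
    idx <- match(names(overrides), g$nodes)
    A[idx, ] <- 0
    A[cbind(idx, idx)] <- 1
    rhs[idx] <- overrides
  }
  stats::setNames(as.numeric(solve(A, rhs)), g$nodes)
}

tiny_cycle <- function() {
  signed_digraph(data.frame(source = c("A", "B", "C"), sign = 1,
                            target = c("B", "C", "A")))
}

two_two_cycles <- function() {
  signed_digraph(data.frame(source = c("A", "B", "C", "D"), sign = 1,
                            target = c("B", "A", "D", "C")))
}

tiny_dag <- function() {
  signed_digraph(data.frame(source = c("A", "A", "B"), sign = c(1, -1, 1),
                            target = c("B", "C", "C")))
}
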