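#' Construct a signed directed network
#'
#' A signed digraph is the substrate of every computation in this package:
#' nodes are genes or signalling activities, edges carry a sign (+1
#' activation, -1 inhibition). Node order is fixed at first appearance so
#' that matrices derived from the graph are reproducible.
#'
#' @param edges data frame with columns `source`, `sign`, `target` (any
#'   order accepted by name). Signs may be given as `1`, `-1`, `"+"`,
#'   `"-"`, `"activate"`, `"inhibit"` (case-insensitive).
#' @param nodes optional character vector of node names; nodes appearing in
#'   edges are appended in order of first appearance. Allows isolated nodes.
#' @return an object of class `signed_digraph` with elements `nodes`
#'   (character), `edges` (data frame `source`, `target`, `sign`).
#' @examples
#' g <- signed_digraph(data.frame(source = c("A", "B", "C"),
#'                                sign   = c("+", "-", "+"),
#'                                target = c("B", "C", "A")))
#' g
#' @export
signed_digraph <- function(edges, nodes = character()) {
  stopifnot(is.data.frame(edges))
  need <- c("source", "sign", "target")
  if (!all(need %in% names(edges))) {
    stop("edges must have columns 'source', 'sign', 'target'")
  }
  src <- as.character(edges$source)
  tgt <- as.character(edges$target)
  sgn <- normalize_sign(edges$sign)
  if (nrow(edges) > 0 && (any(is.na(src)) || any(is.na(tgt)) ||
                          any(src == "") || any(tgt == ""))) {
    stop("edge endpoints must be non-empty strings")
  }
  key <- paste(src, tgt, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    for (k in unique(dup)) {
      s <- unique(sgn[key == k])
      if (length(s) > 1) {
        stop("contradictory duplicate edge (opposite signs): ",
             gsub("\r", " -> ", k))
      }
    }
    keep <- !duplicated(key)
    src <- src[keep]; tgt <- tgt[keep]; sgn <- sgn[keep]
  }
  all_nodes <- unique(c(as.character(nodes), rbind(src, tgt)[TRUE]))
  # rbind trick interleaves source/target per edge => first-appearance order
  g <- structure(list(
    nodes = all_nodes,
    edges = data.frame(source = src, target = tgt, sign = sgn,
                       stringsAsFactors = FALSE)
  ), class = "signed_digraph")
  g
}

normalize_sign <- function(x) {
  tok <- tolower(trimws(as.character(x)))
  out <- ifelse(tok %in% c("1", "+1", "+", "activate", "activates"), 1L,
         ifelse(tok %in% c("-1", "−1", "-", "inhibit", "inhibits"), -1L,
                NA_integer_))
  if (anyNA(out)) {
    bad <- unique(tok[is.na(out)])
    stop("unrecognized edge sign token(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' @export
print.signed_digraph <- function(x, ...) {
  cat("signed_digraph:", length(x$nodes), "nodes,", nrow(x$edges), "edges (",
      sum(x$edges$sign == 1), "activating /", sum(x$edges$sign == -1),
      "inhibiting )\n")
  sl <- self_loop_nodes(x)
  if (length(sl)) cat("  self-loops on:", paste(sl, collapse = ", "), "\n")
  invisible(x)
}

node_index <- function(g, nodes) {
  idx <- match(nodes, g$nodes)
  if (anyNA(idx)) {
    stop("unknown node(s): ", paste(nodes[is.na(idx)], collapse = ", "))
  }
  idx
}

self_loop_nodes <- function(g) {
  unique(g$edges$source[g$edges$source == g$edges$target])
}

#' Read a signed network from a 3-column edge file
#'
#' Expects one edge per line, `source<TAB>sign<TAB>target` (dialect
#' `"three_column"`) or the SIF-like `source sign target` with any
#' whitespace (dialect `"sif_sign"`). Lines starting with `#` and blank
#' lines are ignored. Sign tokens `1`, `-1`, `+`, `-`, `activate`,
#' `inhibit` (case-insensitive) are normalized to +/-1. Opposite-sign
#' duplicates of the same (source, target) pair are rejected.
#'
#' @param path file path.
#' @param dialect `"three_column"` (strict tabs) or `"sif_sign"`.
#' @return a [signed_digraph].
#' @export
read_network <- function(path, dialect = c("three_column", "sif_sign")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("network file has no edge records: ", path)
  split_re <- if (dialect == "three_column") "\t" else "[ \t]+"
  parts <- strsplit(lines, split_re)
  nf <- lengths(parts)
  if (any(nf != 3)) {
    bad <- lineno[which(nf != 3)[1]]
    stop("malformed network record at line ", bad,
         ": expected 3 fields, got ", nf[which(nf != 3)[1]])
  }
  rec <- do.call(rbind, parts)
  g <- signed_digraph(data.frame(source = rec[, 1], sign = rec[, 2],
                                 target = rec[, 3]))
  message("read_network: ", length(g$nodes), " nodes, ", nrow(g$edges),
          " edges from ", path)
  g
}

#' Write a signed network to a 3-column edge file
#'
#' Emits `source<TAB>sign<TAB>target` with signs as `1`/`-1`; the inverse
#' of [read_network()] on normalized records.
#'
#' @param g a [signed_digraph].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path) {
  stopifnot(inherits(g, "signed_digraph"))
  writeLines(paste(g$edges$source, g$edges$sign, g$edges$target, sep = "\t"),
             path)
  invisible(path)
}

#' In- and out-degrees of every node
#'
#' Self-loops count once in the in-degree and once in the out-degree of
#' the looping node, matching the degree normalization used by the
#' signal-flow weight matrix.
#'
#' @param g a [signed_digraph].
#' @return data frame with columns `node`, `in_degree`, `out_degree`.
#' @export
degrees <- function(g) {
  stopifnot(inherits(g, "signed_digraph"))
  si <- match(g$edges$source, g$nodes)
  ti <- match(g$edges$target, g$nodes)
  n <- length(g$nodes)
  data.frame(
    node = g$nodes,
    in_degree = tabulate(ti, nbins = n),
    out_degree = tabulate(si, nbins = n),
    stringsAsFactors = FALSE
  )
}

edge_index <- function(g) {
  list(from = match(g$edges$source, g$nodes) - 1L,
       to   = match(g$edges$target, g$nodes) - 1L)
}

#' Test whether removing a node set leaves a directed cycle
#'
#' Self-loops count as cycles of length 1.
#'
#' @param g a [signed_digraph].
#' @param removed character vector of nodes to remove (may be empty).
#' @return `TRUE` iff the induced subgraph on the remaining nodes contains
#'   a directed cycle.
#' @export
find_cycles_exists <- function(g, removed = character()) {
  stopifnot(inherits(g, "signed_digraph"))
  keep <- rep(TRUE, length(g$nodes))
  if (length(removed)) keep[node_index(g, removed)] <- FALSE
  ei <- edge_index(g)
  has_cycle_cpp(length(g$nodes), ei$from, ei$to, keep)
}
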