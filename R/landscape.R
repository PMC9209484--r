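#' Normalized expression table with phenotype labels
#'
#' @param values numeric matrix, nodes x samples, finite, rownames = node
#'   names, colnames = sample names.
#' @param phenotype named character vector mapping each sample to
#'   `"undesired"`, `"desired"`, or `"other"`.
#' @return an `expression_table`.
#' @export
expression_table <- function(values, phenotype) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have node rownames and sample colnames")
  }
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (is.null(names(phenotype))) {
    if (length(phenotype) != ncol(values)) {
      stop("phenotype must be named by sample or match the sample count")
    }
    names(phenotype) <- colnames(values)
  }
  miss <- setdiff(colnames(values), names(phenotype))
  if (length(miss)) stop("samples without phenotype: ",
                         paste(miss, collapse = ", "))
  phenotype <- phenotype[colnames(values)]
  bad <- setdiff(unique(phenotype), c("undesired", "desired", "other"))
  if (length(bad)) stop("unknown phenotype label(s): ",
                        paste(bad, collapse = ", "))
  structure(list(values = values, phenotype = phenotype),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table:", nrow(x$values), "nodes x", ncol(x$values),
      "samples (", paste(names(table(x$phenotype)), table(x$phenotype),
                         sep = ":", collapse = ", "), ")\n")
  invisible(x)
}

#' Read an expression table and phenotype map from TSV files
#'
#' The expression file is nodes x samples with a header row of sample
#' names and node names in the first column. The phenotype file has two
#' tab-separated columns `sample<TAB>phenotype` without a header.
#'
#' @param expr_path,phenotype_path file paths.
#' @return an [expression_table].
#' @export
read_expression <- function(expr_path, phenotype_path) {
  m <- as.matrix(utils::read.delim(expr_path, row.names = 1,
                                   check.names = FALSE))
  ph <- utils::read.delim(phenotype_path, header = FALSE,
                          col.names = c("sample", "phenotype"),
                          colClasses = "character")
  expression_table(m, stats::setNames(ph$phenotype, ph$sample))
}

#' Align an expression table to a network's node set
#'
#' Rows absent from the network are dropped with a message. Network nodes
#' absent from the table are an error unless `fill` is given, in which
#' case they are filled with that constant (logged).
#'
#' @param expr an [expression_table].
#' @param g a [signed_digraph].
#' @param fill optional constant for missing nodes (e.g. 0).
#' @return an [expression_table] whose rows are exactly `g$nodes`.
#' @export
align_expression <- function(expr, g, fill = NULL) {
  stopifnot(inherits(expr, "expression_table"), inherits(g, "signed_digraph"))
  extra <- setdiff(rownames(expr$values), g$nodes)
  if (length(extra)) {
    message("align_expression: ignoring ", length(extra),
            " expression row(s) not in the network")
  }
  missing <- setdiff(g$nodes, rownames(expr$values))
  v <- expr$values
  if (length(missing)) {
    if (is.null(fill)) {
      stop("network node(s) missing from expression table: ",
           paste(missing, collapse = ", "),
           " (supply fill= to default-fill)")
    }
    message("align_expression: filling ", length(missing),
            " missing node(s) with ", fill)
    v <- rbind(v, matrix(fill, length(missing), ncol(v),
                         dimnames = list(missing, colnames(v))))
  }
  expression_table(v[g$nodes, , drop = FALSE], expr$phenotype)
}

#' Sample random initial states within observed expression ranges
#'
#' For each node, values are drawn uniformly from the `[min, max]` range of
#' that node's expression across the selected phenotypes' samples (pooled
#' by default over all supplied phenotypes). Constant nodes always get
#' their constant.
#'
#' @param expr an [expression_table].
#' @param n number of random states.
#' @param seed RNG seed.
#' @param phenotypes phenotype labels whose samples define the ranges
#'   (default: all samples pooled).
#' @param stratify if `TRUE`, states are split evenly across the selected
#'   phenotypes, each drawn from that phenotype's own ranges.
#' @return numeric matrix nodes x n with columns `random_1..n`.
#' @export
sample_initial_states <- function(expr, n, seed = 1L,
                                  phenotypes = NULL, stratify = FALSE) {
  stopifnot(inherits(expr, "expression_table"), n >= 1)
  if (is.null(phenotypes)) phenotypes <- unique(expr$phenotype)
  sel <- expr$phenotype %in% phenotypes
  if (!any(sel)) stop("no samples for phenotype(s): ",
                      paste(phenotypes, collapse = ", "))
  draw <- function(v, k) {
    lo <- apply(v, 1, min)
    hi <- apply(v, 1, max)
    matrix(stats::runif(nrow(v) * k, rep(lo, k), rep(hi, k)),
           nrow = nrow(v), dimnames = list(rownames(v), NULL))
  }
  out <- local_seed(seed, {
    if (!stratify) {
      draw(expr$values[, sel, drop = FALSE], n)
    } else {
      per <- diff(round(seq(0, n, length.out = length(phenotypes) + 1)))
      do.call(cbind, Map(function(ph, k) {
        if (k == 0) return(NULL)
        draw(expr$values[, expr$phenotype == ph, drop = FALSE], k)
      }, phenotypes, per))
    }
  })
  colnames(out) <- paste0("random_", seq_len(ncol(out)))
  out
}

#' Estimate the attractor landscape
#'
#' Computes one attractor per experimental sample and one per random
#' initial state (drawn within the observed expression ranges), all under
#' the same baseline overrides (e.g. mutation-fixed nodes). Non-converged
#' states are flagged and excluded from downstream clustering.
#'
#' @param g a [signed_digraph].
#' @param expr an [expression_table] aligned to `g` (see
#'   [align_expression()]).
#' @param cfg an [sfa_config()].
#' @param n_random number of random initial states (default 100000).
#' @param seed RNG seed for the random states.
#' @param baseline_overrides named numeric vector applied to every state,
#'   or `NULL`.
#' @param stratify passed to [sample_initial_states()].
#' @return an `attractor_landscape`: list with `values` (nodes x states),
#'   `provenance` (`"experimental"`/`"random"`), `phenotype` (per state;
#'   `NA` for random), `converged`, `iterations`, `n_excluded`.
#' @export
build_landscape <- function(g, expr, cfg = sfa_config(), n_random = 100000L,
                            seed = 1L, baseline_overrides = NULL,
                            stratify = FALSE) {
  stopifnot(inherits(g, "signed_digraph"), inherits(expr, "expression_table"))
  if (!identical(rownames(expr$values), g$nodes)) {
    expr <- align_expression(expr, g)
  }
  B <- expr$values
  prov <- rep("experimental", ncol(B))
  phen <- unname(expr$phenotype)
  if (n_random > 0) {
    R <- sample_initial_states(expr, n_random, seed = seed,
                               stratify = stratify)
    B <- cbind(B, R)
    prov <- c(prov, rep("random", ncol(R)))
    phen <- c(phen, rep(NA_character_, ncol(R)))
  }
  res <- propagate_batch(g, B, overrides = baseline_overrides, cfg = cfg)
  n_exc <- sum(!res$converged)
  if (n_exc > 0) {
    warning(n_exc, " state(s) did not converge within ", cfg$max_iterations,
            " iterations; they are excluded from clustering")
  }
  structure(list(values = res$values, provenance = prov, phenotype = phen,
                 converged = res$converged, iterations = res$iterations,
                 baseline_overrides = as_override_set(baseline_overrides, g),
                 n_excluded = n_exc),
            class = "attractor_landscape")
}

#' @export
print.attractor_landscape <- function(x, ...) {
  cat("attractor_landscape:", ncol(x$values), "attractors (",
      sum(x$provenance == "experimental"), "experimental +",
      sum(x$provenance == "random"), "random ),",
      x$n_excluded, "non-converged\n")
  invisible(x)
}

#' Write an attractor table as TSV
#'
#' Rows are states, columns the node steady-state values plus `converged`
#' and `iterations`.
#'
#' @param landscape an `attractor_landscape` (or the list returned by
#'   [propagate_batch()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_attractors <- function(landscape, path) {
  df <- as.data.frame(t(landscape$values))
  df$converged <- landscape$converged
  df$iterations <- landscape$iterations
  utils::write.table(cbind(state = rownames(df), df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cluster the attractor landscape and choose k
#'
#' Fits k-means for each candidate `k` (10 seeded random starts each) and
#' derives two optima: the elbow of the within-cluster sum-of-squares
#' curve (maximum discrete curvature) and the maximum mean silhouette
#' width. If the two metrics agree and that `k` separates the undesired-
#' and desired-sample attractors into disjoint clusters, it is chosen;
#' otherwise the smallest candidate that separates them is taken. A `k`
#' that co-clusters the two phenotypes is never returned; if no candidate
#' separates them, an error advises revising the network, markers, or
#' simulation settings.
#'
#' Mean silhouette width is computed on a seeded subsample of at most
#' `silhouette_cap` attractors (pairwise distances on the full landscape
#' are quadratic in its size).
#'
#' @param landscape an `attractor_landscape` with both phenotypes present.
#' @param k_range candidate cluster counts (default `2:10`).
#' @param seed RNG seed for k-means initialization and the silhouette
#'   subsample.
#' @param nstart k-means random starts per k (default 10).
#' @param silhouette_cap subsample cap for the silhouette metric.
#' @return a `cluster_model`: list with `k`, `centroids`, `assignment`,
#'   `wcss`, `silhouette`, `k_elbow`, `k_silhouette`, `rationale`,
#'   `cluster_phenotype` (map cluster -> phenotype label or `NA`),
#'   `desired_clusters`, `undesired_clusters`, `kept` (indices of the
#'   converged attractors that were clustered).
#' @export
choose_k <- function(landscape, k_range = 2:10, seed = 1L, nstart = 10L,
                     silhouette_cap = 5000L) {
  stopifnot(inherits(landscape, "attractor_landscape"))
  kept <- which(landscape$converged)
  X <- t(landscape$values[, kept, drop = FALSE])
  if (nrow(X) < 2) stop("need at least 2 converged attractors")
  k_range <- k_range[k_range >= 2 & k_range < nrow(X)]
  if (length(k_range) == 0) stop("k_range has no feasible values")
  exp_idx <- which(landscape$provenance[kept] == "experimental")
  phen <- landscape$phenotype[kept]

  fits <- vector("list", length(k_range))
  wcss <- sil <- numeric(length(k_range))
  sub <- local_seed(seed, {
    if (nrow(X) > silhouette_cap) {
      sort(unique(c(exp_idx, sample.int(nrow(X), silhouette_cap))))
    } else seq_len(nrow(X))
  })
  dsub <- stats::dist(X[sub, , drop = FALSE])
  for (i in seq_along(k_range)) {
    fits[[i]] <- local_seed(seed + i, {
      stats::kmeans(X, centers = k_range[i], nstart = nstart,
                    iter.max = 100)
    })
    wcss[i] <- fits[[i]]$tot.withinss
    sw <- cluster::silhouette(fits[[i]]$cluster[sub], dsub)
    sil[i] <- mean(sw[, "sil_width"])
  }

  # elbow: maximum discrete curvature (second difference) of the WCSS curve
  k_elbow <- if (length(k_range) >= 3) {
    curv <- diff(diff(wcss))
    k_range[which.max(curv) + 1L]
  } else k_range[1]
  k_sil <- k_range[which.max(sil)]

  separates <- function(i) {
    cl <- fits[[i]]$cluster
    und <- unique(cl[exp_idx[phen[exp_idx] == "undesired"]])
    des <- unique(cl[exp_idx[phen[exp_idx] == "desired"]])
    length(und) > 0 && length(des) > 0 && length(intersect(und, des)) == 0
  }
  candidates <- sort(unique(c(k_elbow, k_sil)))
  chosen <- NA_integer_
  rationale <- NULL
  if (k_elbow == k_sil && separates(match(k_elbow, k_range))) {
    chosen <- k_elbow
    rationale <- "elbow and silhouette agree and separate the phenotypes"
  } else {
    for (k in candidates) {
      if (separates(match(k, k_range))) {
        chosen <- k
        rationale <- paste0("metrics disagree (elbow k=", k_elbow,
                            ", silhouette k=", k_sil, "); smallest ",
                            "candidate separating the phenotypes")
        break
      }
    }
  }
  if (is.na(chosen)) {
    stop("no candidate k (elbow k=", k_elbow, ", silhouette k=", k_sil,
         ") separates the undesired- and desired-sample attractors; ",
         "consider revising the network structure, the internal-marker ",
         "set, or the simulation settings")
  }
  fit <- fits[[match(chosen, k_range)]]
  cl <- fit$cluster
  cluster_phenotype <- rep(NA_character_, chosen)
  for (ph in c("undesired", "desired")) {
    cluster_phenotype[unique(cl[exp_idx[phen[exp_idx] == ph]])] <- ph
  }
  structure(list(
    k = chosen, centroids = fit$centers, assignment = cl,
    wcss = stats::setNames(wcss, k_range),
    silhouette = stats::setNames(sil, k_range),
    k_elbow = k_elbow, k_silhouette = k_sil, rationale = rationale,
    cluster_phenotype = cluster_phenotype,
    desired_clusters = which(cluster_phenotype == "desired"),
    undesired_clusters = which(cluster_phenotype == "undesired"),
    kept = kept, seed = seed
  ), class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("cluster_model: k =", x$k, "( elbow", x$k_elbow, ", silhouette",
      x$k_silhouette, ")\n  ", x$rationale, "\n  desired cluster(s):",
      paste(x$desired_clusters, collapse = ", "), "; undesired:",
      paste(x$undesired_clusters, collapse = ", "), "\n")
  invisible(x)
}

#' Check internal-marker consistency between phenotype attractors
#'
#' For each marker node, verifies that the sign of (mean desired-attractor
#' value - mean undesired-attractor value) matches the expected direction,
#' and, when replicates exist, flags markers whose undesired-attractor
#' value range overlaps the desired range as unreliable readouts.
#'
#' @param landscape an `attractor_landscape`.
#' @param markers data frame with columns `node` and `direction`
#'   (`"up"`/`"down"`, desired relative to undesired).
#' @return data frame per marker: `node`, `expected`, `observed`
#'   (`up`/`down`/`unchanged`), `sign_ok`, `overlap`, `reliable`.
#' @export
check_marker_consistency <- function(landscape, markers) {
  stopifnot(inherits(landscape, "attractor_landscape"),
            is.data.frame(markers), all(c("node", "direction") %in%
                                        names(markers)))
  bad <- setdiff(markers$node, rownames(landscape$values))
  if (length(bad)) stop("marker(s) not in network: ",
                        paste(bad, collapse = ", "))
  kept <- landscape$converged
  des <- landscape$values[, kept & !is.na(landscape$phenotype) &
                            landscape$phenotype == "desired", drop = FALSE]
  und <- landscape$values[, kept & !is.na(landscape$phenotype) &
                            landscape$phenotype == "undesired", drop = FALSE]
  if (ncol(des) == 0 || ncol(und) == 0) {
    stop("both desired and undesired experimental attractors are required")
  }
  out <- lapply(seq_len(nrow(markers)), function(i) {
    nd <- markers$node[i]
    d <- mean(des[nd, ]) - mean(und[nd, ])
    observed <- if (abs(d) <= 1e-9) "unchanged" else if (d > 0) "up" else "down"
    overlap <- max(min(des[nd, ]), min(und[nd, ])) <=
      min(max(des[nd, ]), max(und[nd, ]))
    data.frame(node = nd, expected = markers$direction[i],
               observed = observed,
               sign_ok = observed == markers$direction[i],
               overlap = overlap,
               reliable = observed == markers$direction[i] && !overlap,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
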