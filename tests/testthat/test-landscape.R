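make_expr <- function(g, n_rep = 3, seed = 1, effect = 2, jitter = 0.05) {
  set.seed(seed)
  n <- length(g$nodes)
  base <- stats::runif(n, 0.5, 1.5)
  und <- matrix(rep(base, n_rep), ncol = n_rep) +
    stats::rnorm(n * n_rep, 0, jitter)
  des <- matrix(rep(base + effect, n_rep), ncol = n_rep) +
    stats::rnorm(n * n_rep, 0, jitter)
  v <- cbind(und, des)
  dimnames(v) <- list(g$nodes, c(paste0("u", 1:n_rep), paste0("d", 1:n_rep)))
  expression_table(v, stats::setNames(rep(c("undesired", "desired"),
                                          each = n_rep), colnames(v)))
}

test_that("random initial states stay within per-node observed ranges", {
  g <- rand_digraph(8, 0.25, seed = 11)
  expr <- make_expr(g)
  S <- sample_initial_states(expr, 500, seed = 4)
  expect_equal(dim(S), c(8, 500))
  lo <- apply(expr$values, 1, min)
  hi <- apply(expr$values, 1, max)
  expect_true(all(S >= lo & S <= hi))

  # constant node always gets its constant
  v <- expr$values
  v["v01", ] <- 0.7
  e2 <- expression_table(v, expr$phenotype)
  S2 <- sample_initial_states(e2, 50, seed = 4)
  expect_true(all(S2["v01", ] == 0.7))

  # stratified mode draws within each phenotype's own range
  S3 <- sample_initial_states(expr, 100, seed = 4,
                              phenotypes = c("undesired", "desired"),
                              stratify = TRUE)
  expect_equal(ncol(S3), 100)
})

test_that("landscape has one attractor per initial state, deterministically", {
  g <- rand_digraph(8, 0.25, seed = 11)
  expr <- make_expr(g)
  l1 <- build_landscape(g, expr, n_random = 200, seed = 9)
  expect_equal(ncol(l1$values), ncol(expr$values) + 200)
  expect_equal(sum(l1$provenance == "experimental"), 6)
  expect_equal(ncol(l1$values) - l1$n_excluded + l1$n_excluded,
               ncol(expr$values) + 200)  # count conservation
  l2 <- build_landscape(g, expr, n_random = 200, seed = 9)
  expect_identical(l1$values, l2$values)
  l0 <- build_landscape(g, expr, n_random = 0)
  expect_equal(ncol(l0$values), ncol(expr$values))
})

test_that("choose_k finds two well-separated phenotype blobs", {
  g <- rand_digraph(10, 0.2, seed = 21)
  expr <- make_expr(g, effect = 10, seed = 2)   # centers far apart
  l <- build_landscape(g, expr, n_random = 300, seed = 3)
  m <- choose_k(l, k_range = 2:6, seed = 5)
  expect_equal(m$k, 2)
  expect_equal(m$k_silhouette, 2)
  expect_length(intersect(m$desired_clusters, m$undesired_clusters), 0)
  # determinism
  m2 <- choose_k(l, k_range = 2:6, seed = 5)
  expect_identical(m$assignment, m2$assignment)
})

test_that("inseparable phenotypes raise a separation failure", {
  g <- rand_digraph(10, 0.2, seed = 21)
  # desired replicates are exact copies of the undesired ones: their
  # attractors coincide pairwise, so no k can put them in disjoint clusters
  expr <- make_expr(g, effect = 0, seed = 2)
  v <- expr$values
  v[, expr$phenotype == "desired"] <- v[, expr$phenotype == "undesired"]
  expr <- expression_table(v, expr$phenotype)
  l <- build_landscape(g, expr, n_random = 300, seed = 3)
  expect_error(choose_k(l, k_range = 2:4, seed = 5), "revis")
})

test_that("chosen k never co-clusters the two phenotypes", {
  for (seed in 1:5) {
    g <- rand_digraph(9, 0.25, seed = 400 + seed)
    expr <- make_expr(g, effect = 4, seed = seed)
    l <- build_landscape(g, expr, n_random = 250, seed = seed)
    m <- tryCatch(choose_k(l, k_range = 2:6, seed = seed),
                  error = function(e) NULL)
    if (is.null(m)) next
    cl <- m$assignment
    kept_ph <- l$phenotype[m$kept]
    expect_length(intersect(unique(cl[which(kept_ph == "undesired")]),
                            unique(cl[which(kept_ph == "desired")])), 0)
  }
})

test_that("marker consistency checks sign and replicate-range overlap", {
  fx <- standard_fixture(seed = 1)
  l <- build_landscape(fx$g, fx$expr, n_random = 100, seed = 1)
  rep1 <- check_marker_consistency(l, fx$markers)
  expect_true(all(rep1$sign_ok))
  expect_true(all(rep1$reliable))

  # wrong expected direction is flagged
  bad <- fx$markers
  bad$direction <- "down"
  rep2 <- check_marker_consistency(l, bad)
  expect_false(any(rep2$sign_ok))

  # flags are invariant to marker order
  shuf <- fx$markers[c(3, 1, 2), ]
  rep3 <- check_marker_consistency(l, shuf)
  expect_identical(rep3[order(rep3$node), ], rep1[order(rep1$node), ],
                   ignore_attr = TRUE)

  expect_error(check_marker_consistency(l, marker_spec("nope", "up")),
               "not in network")
})

test_that("expression alignment drops extras and fills or rejects missing", {
  g <- tiny_cycle()
  v <- matrix(1, 4, 2, dimnames = list(c("A", "B", "C", "X"), c("s1", "s2")))
  expr <- expression_table(v, c(s1 = "undesired", s2 = "desired"))
  al <- suppressMessages(align_expression(expr, g))
  expect_identical(rownames(al$values), g$nodes)

  v2 <- v[1:2, , drop = FALSE]
  e2 <- expression_table(v2, c(s1 = "undesired", s2 = "desired"))
  expect_error(align_expression(e2, g), "missing")
  al2 <- suppressMessages(align_expression(e2, g, fill = 0))
  expect_equal(unname(al2$values["C", ]), c(0, 0))
})
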