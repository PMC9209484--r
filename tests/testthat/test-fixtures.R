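test_that("planted-cycle networks have the promised minimum FVS size", {
  spec2 <- fixture_spec(n_nodes = 12, cycle_lengths = c(3, 2), n_markers = 3,
                        seed = 4)
  g <- make_network(spec2)
  expect_equal(attr(g, "min_fvs_size"), 2)
  expect_equal(brute_force_min_fvs(g)$size, 2)

  # 0 planted cycles -> DAG
  spec0 <- fixture_spec(n_nodes = 8, cycle_lengths = integer(0),
                        n_markers = 2, seed = 4)
  g0 <- make_network(spec0)
  expect_false(find_cycles_exists(g0))
  expect_equal(brute_force_min_fvs(g0)$size, 0)

  # a cycle of length 1 plants a self-loop
  spec1 <- fixture_spec(n_nodes = 6, cycle_lengths = 1, n_markers = 2,
                        seed = 4)
  g1 <- make_network(spec1)
  expect_equal(brute_force_min_fvs(g1)$size, 1)

  # reproducible under seed
  expect_identical(make_network(spec2)$edges, g$edges)

  expect_error(fixture_spec(n_nodes = 4, cycle_lengths = c(3, 3)),
               "cycle_lengths")
})

test_that("min FVS size matches the oracle across a small spec matrix", {
  for (seed in 1:6) {
    for (cycles in list(2L, c(3L, 2L), c(4L, 3L))) {
      spec <- fixture_spec(n_nodes = 12, cycle_lengths = cycles,
                           n_markers = 2, seed = seed,
                           scaffold_prob = 0.2)
      g <- make_network(spec)
      expect_equal(brute_force_min_fvs(g)$size, length(cycles),
                   info = paste("seed", seed))
    }
  }
})

test_that("expression fixtures separate markers by the requested effect", {
  spec <- fixture_spec(n_nodes = 12, cycle_lengths = 3, n_markers = 3,
                       effect_size = 2, n_replicates = 3, seed = 9)
  g <- make_network(spec)
  fx <- make_expression(g, spec)
  expect_equal(ncol(fx$expr$values), 6)
  expect_equal(sum(fx$expr$phenotype == "desired"), 3)
  v <- fx$expr$values
  for (i in seq_len(nrow(fx$markers))) {
    nd <- fx$markers$node[i]
    gap <- mean(v[nd, fx$expr$phenotype == "desired"]) -
      mean(v[nd, fx$expr$phenotype == "undesired"])
    expected <- if (fx$markers$direction[i] == "up") 2 else -2
    expect_equal(gap, expected, tolerance = 3 * spec$jitter)
  }
  # zero effect size leaves every marker inseparable
  spec0 <- fixture_spec(n_nodes = 12, cycle_lengths = 3, n_markers = 3,
                        effect_size = 0, n_replicates = 3, seed = 9)
  fx0 <- make_expression(g, spec0)
  l0 <- build_landscape(g, fx0$expr, n_random = 50, seed = 1)
  rep0 <- check_marker_consistency(l0, fx0$markers)
  expect_false(any(rep0$reliable))
})

test_that("noise injection is the identity at zero and spares zero nodes", {
  x <- c(a = 1, b = 0, c = -0.5)
  expect_identical(inject_noise(x, 0), x)
  y <- inject_noise(x, 0.3, seed = 2)
  expect_identical(unname(y["b"]), 0)
  expect_false(y["a"] == x["a"])
  # sample mean of repeated draws concentrates on the original value
  draws <- vapply(1:1000, function(s) inject_noise(c(v = 1), 0.5, seed = s)["v"],
                  0)
  expect_lt(abs(mean(draws) - 1), 0.05)
  # matrix input keeps shape
  m <- matrix(1:6 / 6, 2, 3, dimnames = list(c("a", "b"), NULL))
  nm <- inject_noise(m, 0.1, seed = 1)
  expect_identical(dim(nm), dim(m))
})

test_that("fixtures round-trip through the on-disk formats", {
  fx <- standard_fixture(seed = 1)
  d <- withr::local_tempdir()
  write_fixture(d, fx$g, fx$expr, fx$markers,
                mutations = mutation_profile("S1", "gain_of_function"))
  g2 <- suppressMessages(read_network(file.path(d, "network.tsv")))
  expect_identical(g2$edges, fx$g$edges)
  e2 <- read_expression(file.path(d, "expression.tsv"),
                        file.path(d, "phenotypes.tsv"))
  expect_equal(e2$values, fx$expr$values, tolerance = 1e-12)
  expect_identical(e2$phenotype, fx$expr$phenotype)
})
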