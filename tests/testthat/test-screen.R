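test_that("scheme generation yields 3^n schemes in ternary-counter order", {
  s2 <- generate_schemes(c("A", "B"))
  expect_equal(nrow(s2$assignment), 9)
  ids <- scheme_ids(s2)
  expect_equal(ids[1], "A:unchanged|B:unchanged")
  expect_equal(ids[2], "A:unchanged|B:up")
  expect_equal(ids[4], "A:up|B:unchanged")
  expect_false(anyDuplicated(ids) > 0)

  s6 <- generate_schemes(letters[1:6])
  expect_equal(nrow(s6$assignment), 729)

  expect_error(generate_schemes(letters[1:17]), "allow_large")
  s17_ok <- generate_schemes(letters[1:6], cap = 3, allow_large = TRUE)
  expect_equal(nrow(s17_ok$assignment), 729)
})

test_that("scheme ids are a bijection with assignments", {
  s <- generate_schemes(c("N1", "N2", "N3"))
  ids <- scheme_ids(s)
  for (i in c(1, 5, 14, 27)) {
    back <- parse_scheme_id(ids[i])
    expect_identical(unname(back), unname(s$assignment[i, ]))
    expect_identical(names(back), s$nodes)
  }
  expect_error(parse_scheme_id("A:sideways"), "malformed")
})

test_that("override resolution merges mutations, treatments and the scheme", {
  fx <- standard_fixture(seed = 1, jitter = 0)
  g <- fx$g
  expr <- fx$expr
  # scheme {A: up}: undesired max for A is 0.5 -> 0.5 + 2.5*0.5 = 1.75
  ov <- resolve_overrides(c(A = 1L), g, expr)
  expect_equal(unname(ov["A"]), 3.5 * 0.5)
  # gain-of-function mutation present in every resolved set
  mut <- mutation_profile("S1", "gain_of_function")   # S1 max = 1.0 -> 3.5
  ov2 <- resolve_overrides(c(A = 1L), g, expr, mutations = mut)
  expect_equal(unname(ov2["S1"]), 3.5)
  # all-unchanged scheme, no mutations -> empty set
  expect_length(resolve_overrides(c(A = 0L), g, expr), 0)
  # fallback constants without expression data
  ov3 <- resolve_overrides(c(A = 1L, B = 2L), g, expr = NULL)
  expect_equal(unname(ov3), c(2.5, -2.5))
  # conflicts are defensive errors
  expect_error(resolve_overrides(c(S1 = 1L), g, expr, mutations = mut),
               "already-fixed")
  expect_error(mutation_profile(c("X", "X"),
                                c("gain_of_function", "loss_of_function")),
               "two mutation effects")
})

test_that("the screen produces replicates x schemes attractors with pinned nodes", {
  fx <- standard_fixture(seed = 2)
  schemes <- generate_schemes(fx$control)
  scr <- run_screen(fx$g, schemes, fx$expr)
  expect_equal(length(scr$scheme_ids), 3)
  expect_equal(length(scr$replicates), 3)
  expect_equal(sum(vapply(scr$values, ncol, 0L)), 9)

  # all-unchanged scheme equals the baseline undesired attractor
  und <- fx$expr$values[, fx$expr$phenotype == "undesired", drop = FALSE]
  for (r in seq_along(scr$replicates)) {
    base <- propagate(fx$g, und[, r])
    # batches iterate until every column converges, so allow slack of the
    # order of the convergence tolerance
    expect_equal(scr$values[[r]][, 1], base$values, tolerance = 1e-4)
  }
  # overridden control nodes sit exactly at their p value
  up_col <- which(schemes$assignment[, "A"] == 1L)
  expect_identical(unname(scr$values[[1]]["A", up_col]),
                   unname(scr$overrides_up["A"]))
  dn_col <- which(schemes$assignment[, "A"] == 2L)
  expect_identical(unname(scr$values[[1]]["A", dn_col]),
                   unname(scr$overrides_down["A"]))
})

test_that("screen results do not depend on batch boundaries", {
  fx <- standard_fixture(seed = 3)
  schemes <- generate_schemes(c("A", "B"))
  s1 <- run_screen(fx$g, schemes, fx$expr, chunk_size = 2L)
  s2 <- run_screen(fx$g, schemes, fx$expr, chunk_size = 9L)
  expect_identical(s1$values, s2$values)
})

test_that("control nodes already fixed upstream are refused", {
  fx <- standard_fixture(seed = 1)
  mut <- mutation_profile("A", "gain_of_function")
  schemes <- generate_schemes("A")
  expect_error(run_screen(fx$g, schemes, fx$expr, mutations = mut),
               "exclude_fixed_nodes")
})
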