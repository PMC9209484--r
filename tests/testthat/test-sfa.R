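test_that("weight matrix implements degree-normalized signed influence", {
  # single activating edge, both degrees 1
  g1 <- signed_digraph(data.frame(source = "J", sign = 1, target = "I"))
  expect_equal(weight_matrix(g1)["I", "J"], 1.0)

  # inhibiting edge with D_out = D_in = 4 -> -1/sqrt(16)
  e <- data.frame(
    source = c("J", "J", "J", "J", "K", "L", "M"),
    sign   = c(-1, 1, 1, 1, 1, 1, 1),
    target = c("I", "X", "Y", "Z", "I", "I", "I"))
  g4 <- signed_digraph(e)
  expect_equal(weight_matrix(g4)["I", "J"], -0.25)

  # activating edge with D_out = 2, D_in = 3 -> 1/sqrt(6)
  e <- data.frame(source = c("J", "J", "K", "L"), sign = 1,
                  target = c("I", "X", "I", "I"))
  g6 <- signed_digraph(e)
  expect_equal(weight_matrix(g6)["I", "J"], 1 / sqrt(6), tolerance = 1e-12)
})

test_that("propagation closed forms: isolated node and two-node chain", {
  g <- signed_digraph(data.frame(source = "J", sign = 1, target = "I"),
                      nodes = c("J", "I", "Z"))
  a <- propagate(g, c(J = 1, I = 0, Z = 1))
  expect_true(a$converged)
  expect_equal(unname(a$values["Z"]), 0.1, tolerance = 1e-6)  # (1-alpha)*b
  expect_equal(unname(a$values["J"]), 0.1, tolerance = 1e-6)
  expect_equal(unname(a$values["I"]), 0.09, tolerance = 1e-6) # alpha*W*x_j
})

test_that("overridden nodes hold their value exactly and feed neighbours", {
  g <- tiny_cycle()
  a <- propagate(g, c(A = 1, B = 0, C = 0), overrides = c(B = 2.5))
  expect_identical(unname(a$values["B"]), 2.5)
  # C is driven by the pinned B: reduced linear solve oracle
  oracle <- linear_solve_attractor(g, c(A = 1, B = 0, C = 0), c(B = 2.5))
  expect_equal(a$values, oracle, tolerance = 1e-5)
})

test_that("converged attractors match the direct linear solve on random graphs", {
  cfg <- sfa_config()
  for (seed in 1:25) {
    g <- rand_digraph(sample(5:30, 1), 0.15, seed = 100 + seed)
    W <- weight_matrix(g)
    if (max(abs(eigen(0.9 * W, only.values = TRUE)$values)) >= 1) next
    set.seed(seed)
    b <- stats::setNames(stats::rnorm(length(g$nodes)), g$nodes)
    a <- propagate(g, b, cfg = cfg)
    expect_true(a$converged)
    expect_lt(max(abs(a$values - linear_solve_attractor(g, b))),
              10 * cfg$tolerance)
    # with two pinned nodes
    ov <- stats::setNames(c(2.5, -1), sample(g$nodes, 2))
    ao <- propagate(g, b, overrides = ov, cfg = cfg)
    expect_lt(max(abs(ao$values - linear_solve_attractor(g, b, ov))),
              10 * cfg$tolerance)
  }
})

test_that("propagation is deterministic and flags non-convergence", {
  g <- rand_digraph(10, 0.3, seed = 3)
  b <- stats::setNames(seq_len(10) / 10, g$nodes)
  a1 <- propagate(g, b)
  a2 <- propagate(g, b)
  expect_identical(a1$values, a2$values)

  # alpha close to 1 on a cycle with an asymmetric start cannot settle in
  # a handful of iterations
  g2 <- tiny_cycle()
  slow <- propagate(g2, c(A = 1, B = 0, C = 0),
                    cfg = sfa_config(alpha = 0.99, tolerance = 1e-12,
                                     max_iterations = 3))
  expect_false(slow$converged)
  expect_equal(slow$iterations, 3)
})

test_that("attractor comparison calls up/down/unchanged with a float guard", {
  a <- c(A = 0.3, B = -0.2, C = 1)
  b <- c(A = 0.1, B = 0.1, C = 1 + 1e-12)
  cmp <- compare_attractors(a, b)
  expect_equal(cmp$call, c("up", "down", "unchanged"))
  expect_equal(cmp$difference[1], 0.2, tolerance = 1e-12)
  expect_equal(cmp$difference[2], -0.3, tolerance = 1e-12)
  same <- compare_attractors(a, a)
  expect_true(all(same$call == "unchanged") && all(same$difference == 0))
  expect_error(compare_attractors(a, c(A = 1, B = 2, D = 3)), "node set")
})

test_that("override values follow the up/down formulas and the fallback", {
  expect_equal(override_value(c(1, 2), "up"), 7)        # max + 2.5*max
  expect_equal(override_value(c(1, 2), "down"), -1.5)   # min - 2.5*min
  expect_equal(override_value(direction = "up", fallback = TRUE), 2.5)
  expect_equal(override_value(direction = "down", fallback = TRUE), -2.5)
  expect_error(override_value(numeric(0), "up"), "fallback")
  # negative minimum: formula verbatim, but warn that p > min
  expect_warning(p <- override_value(c(-0.4, 1), "down"), "minimum")
  expect_equal(p, 0.6)
})
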