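# shared fixture pipeline pieces, computed once per file
fx <- standard_fixture(seed = 1)
res <- screen_and_filter(fx$g, fx$expr, fx$markers, control = fx$control,
                         n_random = 600, seed = 7)

test_that("classifiers separate the landscape clusters and are deterministic", {
  expect_true(all(res$clfs$training_accuracy >= 0.9))
  clfs2 <- train_classifiers(res$landscape, res$model, seed = 7, ntree = 200)
  v1 <- fvscreen:::classifier_votes(res$clfs, t(res$screen$values[[1]]))
  v2 <- fvscreen:::classifier_votes(clfs2, t(res$screen$values[[1]]))
  expect_identical(v1, v2)
  # single-cluster labels are rejected
  m1 <- res$model
  m1$assignment[] <- 1L
  expect_error(train_classifiers(res$landscape, m1), ">= 2 clusters")
})

test_that("shuffled labels give near-chance held-out accuracy", {
  X <- t(res$landscape$values[, res$model$kept, drop = FALSE])
  set.seed(3)
  y <- factor(sample(res$model$assignment))      # destroy the signal
  tr <- sample(nrow(X), floor(0.7 * nrow(X)))
  nb <- e1071::naiveBayes(as.data.frame(X[tr, ]), y[tr])
  acc <- mean(stats::predict(nb, as.data.frame(X[-tr, ])) == y[-tr])
  base <- max(table(y)) / length(y)
  expect_lt(acc, base + 0.1)
})

test_that("criterion 1 applies the 2-of-3 vote and the all-replicates rule", {
  c1 <- res$c1
  # vote arithmetic: pass iff >= 2 desired predictions
  expect_identical(unname(c1$votes$pass),
                   unname(c1$votes$n_desired >= 2 &
                            c1$votes$n_desired <= 3))
  # overall verdict is the conjunction across replicates
  per <- c1$per_replicate
  expect_identical(unname(c1$verdict), unname(rowSums(!per) == 0))
  # a scheme passing on only 2 of 3 replicates fails overall
  scr <- res$screen
  fake <- scr
  fake$values[[3]][, 2] <- res$landscape$values[, 1]  # undesired-side attractor
  c1f <- criterion1(res$clfs, fake, res$model$desired_clusters)
  expect_true(c1f$per_replicate[2, 1] || c1f$per_replicate[2, 2])
  expect_false(c1f$per_replicate[2, 3])
  expect_false(c1f$verdict[2])
})

test_that("feature importance ranks a planted informative node first", {
  # two clusters differing in a single coordinate
  set.seed(5)
  n <- 400
  X <- matrix(stats::rnorm(n * 10, 0, 0.3), n, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  X[, "f4"] <- X[, "f4"] + rep(c(0, 5), each = n / 2)
  X[, "f7"] <- 1  # constant feature
  fake_land <- structure(list(
    values = t(X), provenance = rep("random", n),
    phenotype = rep(NA_character_, n), converged = rep(TRUE, n),
    iterations = rep(1L, n), n_excluded = 0L), class = "attractor_landscape")
  fake_model <- structure(list(kept = seq_len(n),
                               assignment = rep(1:2, each = n / 2)),
                          class = "cluster_model")
  clfs <- train_classifiers(fake_land, fake_model, seed = 1, ntree = 100)
  fi <- feature_importance(clfs, top_frac = 0.1, seed = 1)
  expect_equal(fi$top_n, 1)
  expect_true(all(vapply(fi$top, function(t) t[1] == "f4", TRUE)))
  expect_equal(fi$importance$naive_bayes[fi$importance$feature == "f7"], 0)
  # a 36-feature problem reports ceiling(3.6) = 4 per classifier
  expect_equal(feature_importance(res$clfs, top_frac = 0.1)$top_n,
               ceiling(0.1 * length(res$clfs$features)))
})

test_that("criterion 2 applies strict/relaxed boundaries and the threshold", {
  # single marker, constructed values: desired 2.0, undesired 1.0
  des <- matrix(2, 1, 2, dimnames = list("M1", NULL))
  und <- matrix(1, 1, 2, dimnames = list("M1", NULL))
  mk_screen <- function(vals) {
    schemes <- generate_schemes("A")
    structure(list(
      scheme_ids = scheme_ids(schemes), schemes = schemes,
      replicates = "r1",
      values = list(r1 = matrix(rep(vals, each = 3), nrow = length(vals),
                                byrow = TRUE,
                                dimnames = list(names(vals), NULL))),
      converged = list(r1 = rep(TRUE, 3))), class = "screen_result")
  }
  scr <- mk_screen(c(M1 = 2.3, A = 0))
  c2s <- criterion2(scr, marker_spec("M1"), des, und, mode = "strict")
  expect_true(all(c2s$verdict))                     # 2.3 > 2.0
  scr15 <- mk_screen(c(M1 = 1.5, A = 0))
  expect_false(any(criterion2(scr15, marker_spec("M1"), des, und,
                              mode = "strict")$verdict))   # fails strict
  expect_true(all(criterion2(scr15, marker_spec("M1"), des, und,
                             mode = "relaxed")$verdict))   # 1.5 > 1.0
})

test_that("the passing-marker fraction threshold is exact", {
  nodes <- paste0("M", 1:10)
  mk <- marker_spec(nodes)
  des <- matrix(2, 10, 2, dimnames = list(nodes, NULL))
  und <- matrix(1, 10, 2, dimnames = list(nodes, NULL))
  schemes <- generate_schemes("A")
  vals9 <- c(stats::setNames(rep(2.5, 9), nodes[1:9]), M10 = 1.2, A = 0)
  vals8 <- c(stats::setNames(rep(2.5, 8), nodes[1:8]), M9 = 1.2, M10 = 1.2,
             A = 0)
  mk_screen <- function(vals) {
    structure(list(
      scheme_ids = scheme_ids(schemes), schemes = schemes,
      replicates = "r1",
      values = list(r1 = matrix(rep(vals, 3), nrow = length(vals),
                                dimnames = list(names(vals), NULL))),
      converged = list(r1 = rep(TRUE, 3))), class = "screen_result")
  }
  expect_true(all(criterion2(mk_screen(vals9), mk, des, und,
                             threshold = 0.9)$verdict))  # 9/10 passes
  expect_false(any(criterion2(mk_screen(vals8), mk, des, und,
                              threshold = 0.9)$verdict)) # 8/10 fails
})

test_that("unresolvable markers leave the denominator with a warning", {
  nodes <- c("M1", "M2")
  des <- matrix(c(2, 1), 2, 2, dimnames = list(nodes, NULL))
  und <- matrix(c(1, 1), 2, 2, dimnames = list(nodes, NULL))  # M2 flat
  schemes <- generate_schemes("A")
  scr <- structure(list(
    scheme_ids = scheme_ids(schemes), schemes = schemes, replicates = "r1",
    values = list(r1 = matrix(rep(c(2.5, 0, 0), 3), nrow = 3,
                              dimnames = list(c(nodes, "A"), NULL))),
    converged = list(r1 = rep(TRUE, 3))), class = "screen_result")
  expect_warning(c2 <- criterion2(scr, marker_spec(nodes), des, und),
                 "unresolvable")
  expect_identical(c2$excluded_markers, "M2")
  expect_true(all(c2$fractions == 1))   # denominator is the single M1
})

test_that("marker groups are thresholded independently", {
  nodes <- paste0("M", 1:4)
  mk <- marker_spec(nodes, group = c("apoptosis", "apoptosis",
                                     "proliferation", "proliferation"))
  des <- matrix(2, 4, 1, dimnames = list(nodes, NULL))
  und <- matrix(1, 4, 1, dimnames = list(nodes, NULL))
  schemes <- generate_schemes("A")
  # both apoptosis markers pass, both proliferation fail: overall 50% but
  # group-wise 100%/0% -> fails; ungrouped 50% also fails at 0.5+
  vals <- c(M1 = 2.5, M2 = 2.5, M3 = 1.1, M4 = 1.1, A = 0)
  scr <- structure(list(
    scheme_ids = scheme_ids(schemes), schemes = schemes, replicates = "r1",
    values = list(r1 = matrix(rep(vals, 3), nrow = 5,
                              dimnames = list(names(vals), NULL))),
    converged = list(r1 = rep(TRUE, 3))), class = "screen_result")
  grouped <- criterion2(scr, mk, des, und, threshold = 0.5)
  expect_false(any(grouped$verdict))            # proliferation group at 0
  ungrouped <- criterion2(scr, marker_spec(nodes), des, und, threshold = 0.5)
  expect_true(all(ungrouped$verdict))           # pooled fraction is 0.5
  # verdicts invariant to marker order
  reord <- criterion2(scr, mk[c(3, 1, 4, 2), ], des, und, threshold = 0.5)
  expect_identical(grouped$verdict, reord$verdict)
})

test_that("strict survivors are a subset of relaxed survivors", {
  des_u <- which(res$landscape$phenotype[res$model$kept] == "desired" &
                   res$landscape$provenance[res$model$kept] == "experimental")
  und_u <- which(res$landscape$phenotype[res$model$kept] == "undesired" &
                   res$landscape$provenance[res$model$kept] == "experimental")
  vals <- res$landscape$values[, res$model$kept, drop = FALSE]
  strict <- criterion2(res$screen, fx$markers, vals[, des_u, drop = FALSE],
                       vals[, und_u, drop = FALSE], mode = "strict")
  relaxed <- criterion2(res$screen, fx$markers, vals[, des_u, drop = FALSE],
                        vals[, und_u, drop = FALSE], mode = "relaxed")
  expect_true(all(names(strict$verdict)[strict$verdict] %in%
                    names(relaxed$verdict)[relaxed$verdict]))
  # survivors shrink monotonically in the threshold
  counts <- vapply(seq(0.5, 1.0, by = 0.1), function(th) {
    sum(criterion2(res$screen, fx$markers, vals[, des_u, drop = FALSE],
                   vals[, und_u, drop = FALSE], threshold = th)$verdict)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("survivor ranking prefers the smallest perturbation sets", {
  schemes <- generate_schemes(c("A", "B"))
  scr <- structure(list(scheme_ids = scheme_ids(schemes), schemes = schemes,
                        replicates = "r1"), class = "screen_result")
  ids <- scheme_ids(schemes)
  mkv <- function(pass_ids) {
    stats::setNames(ids %in% pass_ids, ids)
  }
  pass <- c("A:up|B:up", "A:up|B:unchanged")
  rep <- summarize_survivors(scr, list(verdict = mkv(pass)),
                             list(verdict = mkv(pass)))
  expect_equal(rep$survivors$scheme_id[1], "A:up|B:unchanged")
  expect_equal(rep$survivors$n_perturbed, c(1, 2))
  # A:up occurs in every survivor
  expect_equal(rep$recurrence$frequency[rep$recurrence$assignment == "A:up"],
               1.0)
  empty <- summarize_survivors(scr, list(verdict = mkv(character())),
                               list(verdict = mkv(character())))
  expect_equal(nrow(empty$survivors), 0)
  expect_match(empty$note, "no scheme")
})
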