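test_that("kNN affinity matches hand-enumerated collinear example", {
  # points 0, 1, 10 on the line; t = 1, sigma = 1.
  # 0 picks 1; 1 picks 0; 10 picks 1 -> union keeps edges (1,2) and (2,3).
  g <- affinity_graph(matrix(c(0, 1, 10), ncol = 1), neighbors = 1, bandwidth = 1)
  expect_equal(g$weights[1, 2], exp(-1))
  expect_equal(g$weights[2, 3], exp(-81))
  expect_equal(g$weights[1, 3], 0)
  expect_equal(g$weights, t(g$weights))
  expect_equal(diag(g$weights), rep(0, 3))
  expect_equal(g$degrees, rowSums(g$weights))
})

test_that("duplicate points connect with weight one and precondition checks fire", {
  g <- affinity_graph(matrix(c(1, 1), ncol = 1), neighbors = 1, bandwidth = 1)
  expect_equal(g$weights[1, 2], 1)
  expect_error(affinity_graph(matrix(1, 1, 1), neighbors = 1), "at least 2")
  expect_error(affinity_graph(matrix(1:4, 2), neighbors = 2), "< n")
})

test_that("affinity weights are symmetric and zero-diagonal for random inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(30 * 4), 30, 4)
    g <- affinity_graph(x, neighbors = 3)
    expect_identical(g$weights, t(g$weights))
    expect_true(all(diag(g$weights) == 0))
    expect_true(all(g$weights >= 0))
  }
})

test_that("empty graph gives the diagonal solution Y / (1 + lambda)", {
  d <- fixture_random(n = 8, n_lab = 4, seed = 2)
  g <- affinity_graph(d, neighbors = 2)
  g$weights[] <- 0
  g$degrees[] <- 0
  p <- propagate_labels(g, d, lambda = 3)
  expect_equal(p$scores, label_matrix(d) / 4)
})

test_that("propagation recovers cluster labels from one label per cluster", {
  d <- fixture_two_clusters(n = 50, seed = 6)
  p <- propagate_labels(affinity_graph(d, neighbors = 5), d, lambda = 99)
  expect_equal(mean(p$pseudo[p$unlabeled] == d$hidden[p$unlabeled]), 1)
})

test_that("weak regularization pins scores to the label matrix", {
  d <- fixture_random(n = 15, n_lab = 6, seed = 5)
  g <- affinity_graph(d, neighbors = 3)
  p <- propagate_labels(g, d, lambda = 1e-6)
  lab <- labeled_rows(d)
  expect_equal(max(abs(p$scores - label_matrix(d))), 0, tolerance = 1e-5)
  expect_equal(p$pseudo[lab], d$label[lab])
})

test_that("closed-form and fixed-point propagation agree", {
  for (seed in 1:5) {
    d <- fixture_random(n = 40, d = 3, K = 3, n_lab = 10, seed = seed)
    g <- affinity_graph(d, neighbors = 4)
    p <- propagate_labels(g, d, lambda = 99)
    it <- propagate_labels_iterative(g, d, lambda = 99)
    expect_lt(max(abs(p$scores - it)), 1e-8)
  }
})

test_that("the closed form is a stationary point of the objective", {
  d <- fixture_random(n = 30, d = 2, K = 2, n_lab = 8, seed = 9)
  g <- affinity_graph(d, neighbors = 3)
  Y <- label_matrix(d)
  p <- propagate_labels(g, d, lambda = 50)
  expect_lt(max(abs(propagation_gradient(p$scores, Y, g, 50))), 1e-6)
  # and a local minimum: random unit-norm-1e-3 perturbations never improve it
  base <- propagation_objective(p$scores, Y, g, 50)
  set.seed(1)
  for (i in 1:100) {
    delta <- matrix(rnorm(length(Y)), nrow(Y))
    delta <- delta / sqrt(sum(delta^2)) * 1e-3
    expect_gte(propagation_objective(p$scores + delta, Y, g, 50), base)
  }
})

test_that("objective vanishes at F = Y on an empty graph and is permutation-invariant", {
  d <- fixture_random(n = 10, n_lab = 4, seed = 3)
  g <- affinity_graph(d, neighbors = 2)
  Y <- label_matrix(d)
  g0 <- g
  g0$weights[] <- 0
  g0$degrees[] <- 0
  expect_equal(propagation_objective(Y, Y, g0, 5), 0)

  set.seed(2)
  Fm <- matrix(rnorm(length(Y)), nrow(Y))
  perm <- sample(nrow(Y))
  gp <- g
  gp$weights <- g$weights[perm, perm]
  gp$degrees <- g$degrees[perm]
  expect_equal(propagation_objective(Fm[perm, ], Y[perm, ], gp, 5),
               propagation_objective(Fm, Y, g, 5))
})

test_that("rescaling features and bandwidth together leaves propagation unchanged", {
  d <- fixture_random(n = 25, n_lab = 6, seed = 11)
  g1 <- affinity_graph(d$x, neighbors = 4, bandwidth = 2)
  g2 <- affinity_graph(d$x * 10, neighbors = 4, bandwidth = 20)
  expect_equal(g1$weights, g2$weights)
  p1 <- propagate_labels(g1, label_matrix(d), lambda = 9)
  p2 <- propagate_labels(g2, label_matrix(d), lambda = 9)
  expect_equal(p1$scores, p2$scores)
})

test_that("propagation ties break toward the lowest class index", {
  # two symmetric labeled points, one unlabeled exactly between them
  x <- matrix(c(-1, 1, 0), ncol = 1)
  d <- pl_dataset(x, c("a", "b", NA), levels = c("a", "b"))
  g <- affinity_graph(d, neighbors = 2, bandwidth = 1)
  p <- propagate_labels(g, d, lambda = 99)
  expect_equal(p$scores[3, 1], p$scores[3, 2], tolerance = 1e-12)
  expect_equal(p$pseudo[3], 1L)
})

test_that("tidy exports one scored row per instance", {
  d <- fixture_random(n = 12, n_lab = 5, seed = 8)
  p <- propagate_labels(affinity_graph(d, neighbors = 3), d)
  td <- tidy(p, d)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 12)
  expect_true(all(c("id", "pseudo_label", "labeled") %in% names(td)))
})
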