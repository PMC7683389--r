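test_that("candidate generation is deterministic and structurally correct", {
  set.seed(3)
  W1 <- generate_candidates(5, count = 20, oblique_nonzeros = 2)
  set.seed(3)
  W2 <- generate_candidates(5, count = 20, oblique_nonzeros = 2)
  expect_identical(W1, W2)
  for (j in seq_len(ncol(W1))) {
    nz <- which(W1[, j] != 0)
    if (length(nz) == 1 && W1[nz, j] == 1) {
      succeed() # axis-aligned: one-hot
    } else {
      expect_lte(length(nz), 2)
      expect_true(all(abs(W1[nz, j]) <= 1))
    }
  }
})

test_that("stage-2 threshold search finds the separating midpoint", {
  x <- matrix(c(0, 1, 9, 10), ncol = 1)
  d <- pl_dataset(x, c("a", "a", "b", "b"), levels = c("a", "b"))
  pop <- node_population(labeled = 1:4)
  bt <- optimal_threshold(1, pop, d, d$label)
  expect_equal(bt$tau, 5)
  expect_equal(bt$gain, 0.5)
  # single-class node -> invalid candidate
  expect_null(optimal_threshold(1, node_population(labeled = 1:2), d, d$label))
  # duplicate projections leave one midpoint
  d2 <- pl_dataset(matrix(c(0, 0, 1), ncol = 1), c("a", "a", "b"),
                   levels = c("a", "b"))
  bt2 <- optimal_threshold(1, node_population(labeled = 1:3), d2, d2$label)
  expect_equal(bt2$tau, 0.5)
  # constant projections -> no threshold at all
  d3 <- pl_dataset(matrix(c(1, 1, 1), ncol = 1), c("a", "a", "b"),
                   levels = c("a", "b"))
  expect_null(optimal_threshold(1, node_population(labeled = 1:3), d3, d3$label))
})

test_that("threshold ties resolve toward the smallest tau", {
  # both gaps give the same (perfect) gain; the lower midpoint must win
  d <- pl_dataset(matrix(c(0, 2, 10), ncol = 1), c("a", "b", "b"),
                  levels = c("a", "b"))
  bt <- optimal_threshold(1, node_population(labeled = 1:3), d, d$label)
  expect_equal(bt$tau, 1)
})

test_that("pseudo-label structure can reverse the stage-3 candidate ranking", {
  # four ambiguous labeled points separable both horizontally and vertically;
  # two unlabeled clusters make only the vertical cut structure-respecting
  x <- rbind(
    c(0.0, 0.0), c(0.0, 0.2),   # labeled class a, left column
    c(1.0, 1.0), c(0.8, 0.8),   # labeled class b, right column
    cbind(runif(10, 0, 0.2), runif(10, 0.6, 0.9)),  # pseudo a, upper left
    cbind(runif(10, 0.8, 1.0), runif(10, 0.1, 0.4)) # pseudo b, lower right
  )
  d <- pl_dataset(x, c("a", "a", "b", "b", rep(NA, 20)), levels = c("a", "b"))
  pseudo <- c(rep(NA, 4), rep(1L, 10), rep(2L, 10))
  pop <- node_population(labeled = 1:4, unlabeled = 5:24)
  horizontal <- split_function(c(0, 1), 0.5)
  vertical <- split_function(c(1, 0), 0.5)
  cands <- list(horizontal, vertical)
  std <- select_split(cands, pop, d, d$label, pseudo, 2, variant = "standard")
  grf <- select_split(cands, pop, d, d$label, pseudo, 2, variant = "graph")
  expect_equal(std$index, 1L) # supervised gains tie; first candidate wins
  expect_equal(grf$index, 2L) # pseudo-labels break the tie toward structure
  expect_equal(grf$score, 0.5)
})

test_that("with no unlabeled data the graph forest is node-for-node standard", {
  d <- make_moons(n_per_class = 40, seed = 21) # fully labeled
  f_graph <- graph_forest(d, variant = "graph", trees = 4, seed = 5)
  f_std <- graph_forest(d, variant = "standard", trees = 4, seed = 5)
  expect_identical(f_graph$trees, f_std$trees)
})

test_that("training is reproducible from the master seed", {
  d <- make_moons(n_per_class = 30, labeled_per_class = 5, seed = 2)
  f1 <- graph_forest(d, trees = 3, seed = 11)
  f2 <- graph_forest(d, trees = 3, seed = 11)
  f3 <- graph_forest(d, trees = 3, seed = 12)
  expect_identical(f1$trees, f2$trees)
  expect_false(identical(f1$trees, f3$trees))
})

test_that("separable data grows pure trees that memorize the training labels", {
  d <- fixture_two_clusters(n = 30, seed = 8)
  full <- pl_dataset(d$x, d$levels[d$hidden], levels = d$levels)
  f <- graph_forest(full, variant = "standard", trees = 1, bootstrap = FALSE,
                    max_depth = 10, min_labeled_split = 2, seed = 1)
  expect_equal(forest_accuracy(f, full), 1)
})

test_that("max_depth zero yields a single root leaf with the class prior", {
  d <- fixture_1d()
  f <- graph_forest(d, variant = "standard", trees = 1, max_depth = 0,
                    bootstrap = FALSE, seed = 1)
  expect_null(f$trees[[1]]$split)
  expect_equal(f$trees[[1]]$dist, c(0.5, 0.5)) # 3+1 vs 3+1 after smoothing
})

test_that("deeper trees never lose training accuracy (no bootstrap)", {
  d <- make_moons(n_per_class = 60, seed = 31)
  accs <- vapply(c(1, 2, 4, 8), function(md) {
    f <- graph_forest(d, variant = "standard", trees = 1, bootstrap = FALSE,
                      max_depth = md, min_labeled_split = 2, seed = 9)
    forest_accuracy(f, d)
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("ensemble predictions are proper distributions with shared paths", {
  d <- make_moons(n_per_class = 40, labeled_per_class = 10, seed = 14)
  f <- graph_forest(d, trees = 5, seed = 3)
  q <- matrix(rnorm(40), 20, 2)
  pr <- predict(f, q)
  expect_s3_class(pr, "tbl_df")
  expect_equal(unname(rowSums(as.matrix(pr))), rep(1, 20), tolerance = 1e-12)
  cl <- predict(f, q, type = "class")
  expect_equal(cl$.pred_class,
               f$levels[max.col(as.matrix(pr), ties.method = "first")])
  expect_error(predict(f, matrix(0, 2, 5)), "features")
})

test_that("forests round-trip through the model file byte-stably", {
  d <- make_moons(n_per_class = 30, labeled_per_class = 5, seed = 2)
  f <- graph_forest(d, trees = 3, seed = 11)
  path <- withr::local_tempfile(fileext = ".json")
  save_forest(f, path)
  g <- load_forest(path)
  q <- matrix(rnorm(30), 15, 2)
  expect_identical(as.matrix(predict(f, q)), as.matrix(predict(g, q)))
  # load -> save is byte-stable
  path2 <- withr::local_tempfile(fileext = ".json")
  save_forest(g, path2)
  expect_identical(readLines(path), readLines(path2))
  # schema and corruption errors
  writeLines(substr(paste(readLines(path), collapse = ""), 1, 50), path2)
  expect_error(load_forest(path2))
  bad <- jsonlite::read_json(path)
  bad$schema <- 99
  jsonlite::write_json(bad, path2, auto_unbox = TRUE)
  expect_error(load_forest(path2), "schema")
})

test_that("tidy and glance summarize a fitted forest", {
  d <- make_moons(n_per_class = 30, labeled_per_class = 8, seed = 5)
  f <- graph_forest(d, trees = 4, seed = 2)
  td <- tidy(f)
  expect_equal(nrow(td), 4)
  expect_true(all(td$nodes == 2 * td$leaves - 1)) # binary trees
  gl <- glance(f)
  expect_equal(gl$variant, "graph")
  expect_equal(gl$trees, 4L)
})
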