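test_that("LIBSVM sparse records densify and labels remap in sorted order", {
  path <- withr::local_tempfile(fileext = ".libsvm")
  writeLines(c("+1 1:0.5 3:-1", "-1 2:2"), path)
  d <- read_libsvm(path)
  expect_equal(unname(d$x), matrix(c(0.5, 0, 0, 2, -1, 0), 2, 3))
  expect_equal(d$levels, c("-1", "1")) # sorted originals -> codes 1..K
  expect_equal(d$label, c(2L, 1L))
})

test_that("LIBSVM reader rejects empty and malformed input with line numbers", {
  path <- withr::local_tempfile(fileext = ".libsvm")
  writeLines(character(0), path)
  expect_error(read_libsvm(path), "no records")
  writeLines(c("+1 1:0.5", "-1 2:abc"), path)
  expect_error(read_libsvm(path), "line 2")
  writeLines(c("+1 1:0.5", "xx 2:1"), path)
  expect_error(read_libsvm(path), "line 2")
  # single-class files read fine but refuse to train
  writeLines(c("1 1:1", "1 1:1"), path)
  d <- read_libsvm(path)
  expect_equal(d$K, 1L)
  expect_error(graph_forest(d, trees = 1), "2 distinct classes")
})

test_that("LIBSVM read -> write -> read is identity", {
  path <- withr::local_tempfile(fileext = ".libsvm")
  writeLines(c("+1 1:0.5 3:-1.25", "-1 2:2", "+1 3:0.125"), path)
  d1 <- read_libsvm(path)
  path2 <- withr::local_tempfile(fileext = ".libsvm")
  write_libsvm(d1, path2)
  d2 <- read_libsvm(path2)
  expect_equal(d2$x, d1$x)
  expect_equal(d2$label, d1$label)
  expect_equal(d2$levels, d1$levels)
})

test_that("CSV tables split labeled/unlabeled rows by empty label cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x1,x2,label", "0,1,a", "2,3,", "4,5,b", "6,7,"), path)
  d <- read_csv_dataset(path)
  expect_equal(n_labeled(d), 2L)
  expect_equal(n_unlabeled(d), 2L)
  expect_equal(d$levels, c("a", "b"))
  expect_equal(unlabeled_rows(d), c(2L, 4L))

  # round trip preserves the in-memory representation
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_csv_dataset(d, path2)
  d2 <- read_csv_dataset(path2)
  expect_equal(d2$x, d$x, ignore_attr = TRUE)
  expect_equal(d2$label, d$label)
})

test_that("CSV reader flags non-numeric features and all-unlabeled tables", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x1,label", "oops,a", "1,b"), path)
  expect_error(read_csv_dataset(path), "row 1.*x1")
  writeLines(c("x1,label", "1,", "2,"), path)
  expect_error(read_csv_dataset(path), "unlabeled")
  # prediction-only table is fine when asked for explicitly
  writeLines(c("x1,x2", "1,2", "3,4"), path)
  d <- read_csv_dataset(path, label_col = NULL)
  expect_equal(n_unlabeled(d), 2L)
})

test_that("split_labeled_subset is seed-reproducible and seed-sensitive", {
  d <- make_clusters(n_per_class = 50, seed = 4)
  a <- split_labeled_subset(d, 10, seed = 1)
  b <- split_labeled_subset(d, 10, seed = 1)
  expect_identical(labeled_rows(a), labeled_rows(b))
  expect_equal(n_labeled(a), 10L)
  expect_equal(n_unlabeled(a), 90L)
  # ground truth rides along for oracle use
  expect_equal(a$hidden[unlabeled_rows(a)], d$label[unlabeled_rows(a)])
  cc <- split_labeled_subset(d, 10, seed = 2)
  expect_false(identical(sort(labeled_rows(a)), sort(labeled_rows(cc))))
})

test_that("split_labeled_subset edge cases: full retention, tiny n, quotas", {
  d <- make_clusters(n_per_class = 10, seed = 4)
  expect_equal(n_unlabeled(split_labeled_subset(d, 20, seed = 1)), 0L)
  expect_error(split_labeled_subset(d, 1, seed = 1), "at least 2")
  q <- split_labeled_subset(d, 3, seed = 1, per_class = TRUE)
  expect_equal(as.vector(table(q$label[labeled_rows(q)])), c(3L, 3L))
  expect_error(split_labeled_subset(d, 11, seed = 1, per_class = TRUE), "quota")
  # stratification always keeps every class represented
  s <- split_labeled_subset(d, 2, seed = 7)
  expect_equal(sort(unique(s$label[labeled_rows(s)])), c(1L, 2L))
})

test_that("label_matrix rows are one-hot for labeled, zero for unlabeled", {
  d <- fixture_random(n = 12, n_lab = 5, seed = 3)
  Y <- label_matrix(d)
  expect_equal(rowSums(Y)[labeled_rows(d)], rep(1, 5), ignore_attr = TRUE)
  expect_equal(rowSums(Y)[unlabeled_rows(d)], rep(0, 7), ignore_attr = TRUE)
  expect_equal(Y[cbind(labeled_rows(d), d$label[labeled_rows(d)])], rep(1, 5))
})

test_that("data frames convert to datasets and back", {
  df <- tibble::tibble(x1 = 1:4 / 2, x2 = c(0, 1, 0, 1),
                       label = c("v", NA, "bg", NA))
  d <- as_pl_dataset(df)
  expect_equal(n_labeled(d), 2L)
  back <- as_tibble(d)
  expect_equal(back$label, df$label)
  expect_equal(back$x1, df$x1)
})
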