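#' Partially labeled dataset
#'
#' The canonical in-memory container for semi-supervised training data: a
#' numeric feature matrix over all instances together with an integer class
#' code per row (`NA` marks an unlabeled row). Class codes are contiguous
#' `1..K` and map back to the original labels through `levels`. Withheld
#' ground-truth labels (from [split_labeled_subset()] or a synthetic
#' generator) may ride along in `hidden`; they are read only by oracle forest
#' variants and by evaluation code, never by the semi-supervised learner.
#'
#' @param x Numeric matrix, one row per instance.
#' @param label Integer vector (length `nrow(x)`) of class codes in `1..K`,
#'   `NA` for unlabeled rows. A factor or character/numeric vector is encoded
#'   against `levels` (or its own sorted unique values).
#' @param levels Character vector of original class labels, in code order.
#'   Defaults to the sorted unique values of `label` (and `hidden`).
#' @param hidden Optional vector of ground-truth labels for every row, same
#'   encoding as `label`. `NULL` if unknown.
#' @param row_order Optional integer vector recording the original file row
#'   for each instance, for round-tripping predictions.
#' @return An object of class `pl_dataset` with elements `x`, `label`
#'   (integer codes, `NA` = unlabeled), `levels`, `K`, and optionally
#'   `hidden` and `row_order`.
#' @examples
#' x <- matrix(rnorm(20), 10, 2)
#' d <- pl_dataset(x, c(1, 2, rep(NA, 8)), levels = c("bg", "vessel"))
#' n_labeled(d)
#' @export
pl_dataset <- function(x, label, levels = NULL, hidden = NULL, row_order = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (length(label) != nrow(x)) {
    stopf("`label` has length %d but `x` has %d rows", length(label), nrow(x))
  }
  enc <- encode_labels(label, hidden, levels)
  structure(
    list(
      x = x,
      label = enc$label,
      levels = enc$levels,
      K = length(enc$levels),
      hidden = enc$hidden,
      row_order = row_order
    ),
    class = "pl_dataset"
  )
}

encode_labels <- function(label, hidden = NULL, levels = NULL) {
  pool <- c(label, hidden)
  pool <- pool[!is.na(pool)]
  if (is.null(levels)) {
    levels <- as.character(sort(unique(pool)))
  }
  code <- function(v) {
    if (is.null(v)) return(NULL)
    out <- match(as.character(v), levels)
    if (any(is.na(out) & !is.na(v))) {
      bad <- unique(v[is.na(out) & !is.na(v)])
      stopf("labels not in `levels`: %s", paste(bad, collapse = ", "))
    }
    as.integer(out)
  }
  list(label = code(label), hidden = code(hidden), levels = levels)
}

#' @export
print.pl_dataset <- function(x, ...) {
  cat(sprintf(
    "<pl_dataset> %d instances x %d features | %d labeled, %d unlabeled, K = %d (%s)%s\n",
    nrow(x$x), ncol(x$x), n_labeled(x), n_unlabeled(x), x$K,
    paste(x$levels, collapse = ", "),
    if (!is.null(x$hidden)) " | ground truth retained" else ""
  ))
  invisible(x)
}

#' @rdname pl_dataset
#' @param data A data frame whose numeric columns are features.
#' @param label_col Name of the label column, or `NULL` for a prediction-only
#'   dataset in which every row is unlabeled. Empty strings and `NA` in the
#'   label column mark unlabeled rows.
#' @param unlabeled_rows Optional integer vector of row numbers to force into
#'   the unlabeled block (their labels, if present, are moved to `hidden`).
#' @export
as_pl_dataset <- function(data, label_col = "label", hidden = NULL,
                          unlabeled_rows = NULL) {
  data <- as.data.frame(data)
  if (!is.null(label_col) && !label_col %in% names(data)) {
    if (identical(label_col, "label")) {
      label_col <- NULL # tolerate default on prediction-only tables
    } else {
      stopf("label column '%s' not found", label_col)
    }
  }
  if (is.null(label_col)) {
    lab <- rep(NA_character_, nrow(data))
    feat <- data
  } else {
    lab <- as.character(data[[label_col]])
    lab[!is.na(lab) & lab == ""] <- NA_character_
    feat <- data[setdiff(names(data), label_col)]
  }
  bad <- !vapply(feat, is.numeric, logical(1))
  if (any(bad)) {
    stopf("non-numeric feature column(s): %s", paste(names(feat)[bad], collapse = ", "))
  }
  if (!is.null(unlabeled_rows)) {
    if (is.null(hidden)) hidden <- lab
    lab[unlabeled_rows] <- NA_character_
  }
  x <- as.matrix(feat)
  pl_dataset(x, lab, hidden = hidden, row_order = seq_len(nrow(x)))
}

#' @rdname pl_dataset
#' @param d A `pl_dataset`.
#' @export
n_labeled <- function(d) sum(!is.na(d$label))

#' @rdname pl_dataset
#' @export
n_unlabeled <- function(d) sum(is.na(d$label))

#' @rdname pl_dataset
#' @export
labeled_rows <- function(d) which(!is.na(d$label))

#' @rdname pl_dataset
#' @export
unlabeled_rows <- function(d) which(is.na(d$label))

#' @method as_tibble pl_dataset
#' @export
as_tibble.pl_dataset <- function(x, ...) {
  feat <- x$x
  if (is.null(colnames(feat))) {
    colnames(feat) <- paste0("x", seq_len(ncol(feat)))
  }
  out <- tibble::as_tibble(as.data.frame(feat))
  out$label <- ifelse(is.na(x$label), NA_character_, x$levels[x$label])
  out
}

# training preconditions shared by the forest and propagation entry points
check_trainable <- function(d) {
  l <- n_labeled(d)
  if (l < 1) stopf("dataset has no labeled rows")
  classes <- unique(d$label[!is.na(d$label)])
  if (length(classes) < 2) {
    stopf("training requires >= 2 distinct classes among the labeled rows (found %d)",
          length(classes))
  }
  invisible(d)
}

#' Withhold labels from all but a random subset of rows
#'
#' Starting from a fully labeled dataset, keep the labels of `n` randomly
#' chosen rows and move every other row to the unlabeled block. The withheld
#' labels are retained in `hidden` so oracle variants and evaluation code can
#' still see the ground truth. Sampling is stratified by class so every class
#' keeps at least one labeled representative whenever `n >= K`; stratification
#' can be disabled for exact uniform draws.
#'
#' @param d A fully labeled `pl_dataset`.
#' @param n Number of rows that keep their labels (`n >= 2`).
#' @param seed Integer seed; the same seed reproduces the same subset.
#' @param stratify Guarantee at least one labeled row per class (default `TRUE`).
#' @param per_class Interpret `n` as an exact per-class quota instead of a
#'   total: `n` rows of EVERY class keep their labels (balanced draw).
#' @return A `pl_dataset` with `n` labeled rows (or `n * K` under
#'   `per_class`), the rest unlabeled, and ground truth in `hidden`.
#' @examples
#' d <- make_clusters(n_per_class = 20, seed = 1)
#' d10 <- split_labeled_subset(d, 10, seed = 1)
#' c(n_labeled(d10), n_unlabeled(d10))
#' @export
split_labeled_subset <- function(d, n, seed, stratify = TRUE, per_class = FALSE) {
  stopifnot(inherits(d, "pl_dataset"))
  if (any(is.na(d$label))) stopf("`d` must be fully labeled")
  total <- nrow(d$x)
  classes <- sort(unique(d$label))
  if (!per_class) {
    if (n > total) stopf("n = %d exceeds the %d available rows", n, total)
    if (n < 2) stopf("n must be at least 2")
    if (stratify && n < length(classes)) {
      stopf("cannot stratify: n = %d < %d classes", n, length(classes))
    }
  }
  keep <- with_local_seed(seed, {
    if (per_class) {
      # exact per-class quota draw
      unlist(lapply(classes, function(k) {
        idx <- which(d$label == k)
        if (length(idx) < n) {
          stopf("class %s has only %d rows, quota %d requested",
                d$levels[k], length(idx), n)
        }
        idx[sample.int(length(idx), n)]
      }))
    } else if (stratify) {
      # one guaranteed draw per class, remainder uniform over the rest
      first <- vapply(classes, function(k) {
        idx <- which(d$label == k)
        idx[sample.int(length(idx), 1)]
      }, integer(1))
      rest <- setdiff(seq_len(total), first)
      c(first, if (n > length(first)) rest[sample.int(length(rest), n - length(first))])
    } else {
      sample.int(total, n)
    }
  })
  lab <- rep(NA_integer_, total)
  lab[keep] <- d$label[keep]
  structure(
    list(
      x = d$x, label = lab, levels = d$levels, K = d$K,
      hidden = d$label, row_order = d$row_order
    ),
    class = "pl_dataset"
  )
}

#' One-hot label matrix
#'
#' The (l+u) x K matrix Y with a one-hot row for every labeled instance and an
#' all-zero row for every unlabeled instance — the right-hand side of the
#' label-propagation linear system.
#'
#' @param d A `pl_dataset`.
#' @return A numeric matrix, `nrow(d$x)` x `d$K`.
#' @export
label_matrix <- function(d) {
  Y <- matrix(0, nrow(d$x), d$K)
  lab <- labeled_rows(d)
  Y[cbind(lab, d$label[lab])] <- 1
  Y
}
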