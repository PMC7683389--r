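# Readers/writers for the two dataset formats and the forest model file.

#' Read a LIBSVM sparse file
#'
#' Lines follow the `label index:value ...` convention with 1-based feature
#' indices; absent indices densify to zero. Original labels (e.g. `-1`/`+1`)
#' are remapped to contiguous class codes preserving sorted order, and the
#' mapping is kept in the dataset's `levels` so reports can show the original
#' labels.
#'
#' @param path Path to a LIBSVM-format text file.
#' @return A fully labeled [pl_dataset()].
#' @export
read_libsvm <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stopf("no records in %s", path)
  parsed <- lapply(seq_along(lines), function(i) {
    toks <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
    lab <- suppressWarnings(as.numeric(toks[1]))
    if (is.na(lab)) stopf("line %d: label '%s' is not numeric", i, toks[1])
    feats <- toks[-1]
    if (length(feats) == 0) {
      return(list(lab = lab, idx = integer(0), val = numeric(0)))
    }
    parts <- strsplit(feats, ":", fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad)) stopf("line %d: malformed feature token '%s'", i, feats[bad][1])
    idx <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
    val <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
    if (any(is.na(idx)) || any(idx < 1)) stopf("line %d: bad feature index", i)
    if (any(is.na(val))) stopf("line %d: non-numeric feature value", i)
    list(lab = lab, idx = idx, val = val)
  })
  d <- max(c(1L, unlist(lapply(parsed, `[[`, "idx"))))
  x <- matrix(0, length(parsed), d)
  for (i in seq_along(parsed)) {
    x[i, parsed[[i]]$idx] <- parsed[[i]]$val
  }
  labs <- vapply(parsed, `[[`, 0, "lab")
  # sorted-unique numeric order, then printed without scientific notation
  lev <- format(sort(unique(labs)), trim = TRUE, scientific = FALSE)
  pl_dataset(x, format(labs, trim = TRUE, scientific = FALSE), levels = lev,
             row_order = seq_along(labs))
}

#' @rdname read_libsvm
#' @param d A `pl_dataset`; unlabeled rows are not representable in LIBSVM and
#'   cause an error.
#' @export
write_libsvm <- function(d, path) {
  stopifnot(inherits(d, "pl_dataset"))
  if (any(is.na(d$label))) stopf("LIBSVM format has no unlabeled-row convention")
  lines <- vapply(seq_len(nrow(d$x)), function(i) {
    v <- d$x[i, ]
    nz <- which(v != 0)
    paste(c(d$levels[d$label[i]],
            sprintf("%d:%s", nz, format(v[nz], digits = 17, trim = TRUE, scientific = FALSE))),
          collapse = " ")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a dense CSV/TSV feature table
#'
#' A rectangular table with a header row; the label column may contain empty
#' cells, which mark unlabeled rows. All remaining columns must be numeric
#' features.
#'
#' @param path Path to a CSV or TSV file (delimiter inferred from extension).
#' @param label_col Label column name, or `NULL` for a prediction-only table.
#' @param unlabeled_rows Optional explicit row numbers to treat as unlabeled.
#' @return A [pl_dataset()]; original row order is recorded for round-tripping
#'   predictions.
#' @export
read_csv_dataset <- function(path, label_col = "label", unlabeled_rows = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  if (nrow(tab) == 0) stopf("no records in %s", path)
  if (!is.null(label_col) && !label_col %in% names(tab)) label_col <- NULL
  feat_cols <- setdiff(names(tab), label_col)
  for (cn in feat_cols) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    if (any(is.na(v) & !is.na(tab[[cn]]) & tab[[cn]] != "")) {
      row <- which(is.na(v) & !is.na(tab[[cn]]))[1]
      stopf("non-numeric value '%s' at row %d, column '%s'", tab[[cn]][row], row, cn)
    }
    tab[[cn]] <- v
  }
  out <- as_pl_dataset(tab, label_col = label_col, unlabeled_rows = unlabeled_rows)
  if (!is.null(label_col) && n_labeled(out) == 0) {
    stopf("all rows are unlabeled; pass label_col = NULL for a prediction-only table")
  }
  out
}

#' @rdname read_csv_dataset
#' @param d A `pl_dataset`.
#' @export
write_csv_dataset <- function(d, path) {
  stopifnot(inherits(d, "pl_dataset"))
  tab <- as_tibble.pl_dataset(d)
  readr::write_csv(tab, path, na = "")
  invisible(path)
}

# ---- forest model file -------------------------------------------------------
# Self-describing JSON: schema version, config snapshot, per-tree flat node
# lists (w, tau, child ids, leaf distributions). Canonical key order and full
# float precision make save -> load -> save byte-stable.

FOREST_SCHEMA <- 1L

flatten_tree <- function(node) {
  nodes <- list()
  walk <- function(nd) {
    id <- length(nodes) + 1L
    nodes[id] <<- list(NULL) # reserve the slot before descending
    if (is.null(nd$split)) {
      nodes[[id]] <<- list(leaf = TRUE, dist = as.numeric(nd$dist))
    } else {
      left <- walk(nd$left)
      right <- walk(nd$right)
      nodes[[id]] <<- list(leaf = FALSE, w = as.numeric(nd$split$w),
                           tau = nd$split$tau, left = left, right = right)
    }
    id
  }
  walk(node)
  nodes
}

unflatten_tree <- function(nodes, id = 1L) {
  nd <- nodes[[id]]
  if (isTRUE(nd$leaf)) {
    list(dist = as.numeric(nd$dist))
  } else {
    list(
      split = list(w = as.numeric(nd$w), tau = as.numeric(nd$tau)),
      left = unflatten_tree(nodes, nd$left),
      right = unflatten_tree(nodes, nd$right)
    )
  }
}

#' Save / load a trained forest
#'
#' Forests serialize to a self-describing JSON model file (schema version,
#' configuration snapshot, per-tree node lists with split weights, thresholds,
#' child ids and leaf class distributions). A load followed by a save is
#' byte-stable, and a loaded forest predicts identically to the original.
#'
#' @param forest A fitted [graph_forest()] object.
#' @param path Destination file path.
#' @export
save_forest <- function(forest, path) {
  stopifnot(inherits(forest, "graph_forest"))
  obj <- list(
    schema = FOREST_SCHEMA,
    levels = forest$levels,
    K = forest$K,
    d = forest$d,
    config = forest$config,
    trees = lapply(forest$trees, flatten_tree)
  )
  # I(17) significant digits: doubles round-trip exactly through JSON
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = FALSE)
  invisible(path)
}

#' @rdname save_forest
#' @export
load_forest <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE),
    error = function(e) stopf("cannot parse model file %s: %s", path, conditionMessage(e))
  )
  if (is.null(obj$schema) || obj$schema != FOREST_SCHEMA) {
    stopf("model schema version %s not supported (expected %d)",
          obj$schema %||% "<missing>", FOREST_SCHEMA)
  }
  structure(
    list(
      trees = lapply(obj$trees, unflatten_tree),
      levels = as.character(obj$levels),
      K = as.integer(obj$K),
      d = as.integer(obj$d),
      config = obj$config
    ),
    class = "graph_forest"
  )
}
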