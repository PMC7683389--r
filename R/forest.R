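# Oblique random forests with three-stage node construction:
#   Stage 1  draw random split-direction candidates {w_j}
#   Stage 2  per candidate, pick the threshold tau_j maximizing supervised
#            gain over the node's stage-2 members
#   Stage 3  across candidates, pick the (w, tau) maximizing the stage-3
#            score — the supervised gain for the standard forest, the
#            graph-embedded gain over labeled + pseudo-labeled members for
#            the semi-supervised forest, the true-label gain for oracles.
# All variants share one growth and one prediction code path; they differ
# only in which label vector each stage consults. Prediction is untouched by
# the semi-supervision: leaves carry empirical distributions of the labeled
# training members and the ensemble averages them.

#' Generate random split-direction candidates
#'
#' The default candidate scheme mixes axis-aligned directions (one-hot `w`)
#' with sparse oblique ones (`oblique_nonzeros` entries drawn uniformly from
#' `[-1, 1]`). Consumes the current RNG stream, so results are deterministic
#' under [set.seed()].
#'
#' @param d Feature dimension.
#' @param count Number of candidates M.
#' @param oblique_nonzeros Nonzero entries per oblique candidate.
#' @param axis_fraction Probability that a candidate is axis-aligned.
#' @return A `d x count` matrix, one candidate per column.
#' @export
generate_candidates <- function(d, count = 50, oblique_nonzeros = 2,
                                axis_fraction = 0.5) {
  stopifnot(count >= 1)
  W <- matrix(0, d, count)
  s <- min(oblique_nonzeros, d)
  for (j in seq_len(count)) {
    if (stats::runif(1) < axis_fraction || d == 1) {
      W[sample.int(d, 1), j] <- 1
    } else {
      W[sample.int(d, s), j] <- stats::runif(s, -1, 1)
    }
  }
  W
}

# Best threshold for projections p with class codes y (no NAs): midpoints
# between consecutive distinct sorted projections, vectorized gain.
# Returns list(tau, gain) or NULL when no valid threshold exists.
best_threshold <- function(p, y, K, criterion = "gini") {
  n <- length(p)
  if (n < 2) return(NULL)
  ord <- order(p)
  ps <- p[ord]
  ys <- y[ord]
  bnd <- which(diff(ps) > 0)
  if (length(bnd) == 0) return(NULL)
  C <- vapply(seq_len(K), function(k) cumsum(ys == k), numeric(n))
  L <- C[bnd, , drop = FALSE]
  total <- C[n, ]
  R <- rep(1, length(bnd)) %o% total - L
  nl <- rowSums(L)
  nr <- n - nl
  if (criterion == "gini") {
    node_imp <- function(M, sz) ifelse(sz > 0, 1 - rowSums(M^2) / sz^2, 0)
    parent_imp <- 1 - sum((total / n)^2)
  } else {
    xlx <- function(q) ifelse(q > 0, q * log2(q), 0)
    node_imp <- function(M, sz) {
      q <- M / pmax(sz, 1)
      -rowSums(xlx(q))
    }
    parent_imp <- -sum(xlx(total[total > 0] / n))
  }
  gains <- parent_imp - (nl * node_imp(L, nl) + nr * node_imp(R, nr)) / n
  best <- which.max(gains) # first max = smallest tau on ties
  list(tau = (ps[bnd[best]] + ps[bnd[best] + 1]) / 2, gain = gains[best])
}

#' Per-candidate optimal threshold (stage 2)
#'
#' Projects the node's labeled members onto `w`, sorts the projections, and
#' evaluates every midpoint between consecutive distinct values, returning
#' the threshold maximizing the supervised gain (ties resolved toward the
#' smallest threshold). A candidate whose projections are all identical is
#' invalid (`NULL`).
#'
#' @param w Weight vector.
#' @param pop A [node_population()].
#' @param d A [pl_dataset()].
#' @param labels Class codes indexed by dataset row.
#' @param criterion `"gini"` or `"entropy"`.
#' @return `list(tau, gain)` or `NULL` if no valid threshold exists.
#' @export
optimal_threshold <- function(w, pop, d, labels, criterion = "gini") {
  idx <- pop$labeled[!is.na(labels[pop$labeled])]
  if (length(idx) < 2 || length(unique(labels[idx])) < 2) return(NULL)
  p <- drop(d$x[idx, , drop = FALSE] %*% w)
  best_threshold(p, labels[idx], max(labels, na.rm = TRUE), criterion)
}

#' Cross-candidate split selection (stage 3)
#'
#' Scores each thresholded candidate and returns the argmax (ties to the
#' first candidate in generation order). The `"graph"` variant scores with
#' the graph-embedded gain, routing labeled and unlabeled members alike; the
#' `"standard"` variant scores with the supervised gain over labeled members
#' only.
#'
#' @param candidates List of [split_function()] objects (already thresholded).
#' @param pop A [node_population()].
#' @param d A [pl_dataset()].
#' @param labels,pseudo Class-code vectors indexed by dataset row.
#' @param K Class count.
#' @param variant `"graph"` or `"standard"`.
#' @param criterion Impurity for the supervised variant.
#' @return `list(index, split, score)`, or `NULL` if no candidate is valid.
#' @export
select_split <- function(candidates, pop, d, labels, pseudo = NULL, K,
                         variant = c("graph", "standard"), criterion = "gini") {
  variant <- match.arg(variant)
  if (length(candidates) == 0) return(NULL)
  scores <- vapply(candidates, function(sp) {
    if (is.null(sp)) return(-Inf)
    s <- if (variant == "graph") {
      graph_gain(pop, sp, d, labels, pseudo, K)
    } else {
      supervised_gain(pop, sp, d, labels, K, criterion)
    }
    if (is.na(s)) -Inf else s
  }, numeric(1))
  if (all(!is.finite(scores))) return(NULL)
  i <- which.max(scores)
  list(index = i, split = candidates[[i]], score = scores[i])
}

# ---- internal growth ---------------------------------------------------------

# ctx: x, K, stage2_lab, stage3_lab, leaf_lab, stage3_imp ("gini"/"entropy"),
#      config (candidates, oblique_nonzeros, axis_fraction, max_depth,
#      min_labeled_split, criterion, leaves_use_pseudo)
leaf_node <- function(ctx, labeled, unlabeled, parent_dist) {
  counts <- tabulate(ctx$leaf_lab[labeled], nbins = ctx$K)
  if (isTRUE(ctx$config$leaves_use_pseudo)) {
    counts <- counts + tabulate(ctx$stage3_lab[unlabeled], nbins = ctx$K)
  }
  if (sum(counts) == 0) {
    list(dist = parent_dist)
  } else {
    list(dist = (counts + 1) / (sum(counts) + ctx$K)) # +1 Laplace smoothing
  }
}

grow_node <- function(ctx, labeled, unlabeled, depth, parent_dist) {
  cfg <- ctx$config
  ylab <- ctx$leaf_lab[labeled]
  this_dist <- leaf_node(ctx, labeled, unlabeled, parent_dist)$dist
  if (depth >= cfg$max_depth ||
      length(labeled) < cfg$min_labeled_split ||
      length(unique(ylab)) < 2) {
    return(list(dist = this_dist))
  }
  rows <- c(labeled, unlabeled)
  Wc <- generate_candidates(ncol(ctx$x), cfg$candidates, cfg$oblique_nonzeros,
                            cfg$axis_fraction)
  P <- ctx$x[rows, , drop = FALSE] %*% Wc
  n_lab <- length(labeled)

  # stage 2: threshold each candidate on the stage-2 members
  s2 <- !is.na(ctx$stage2_lab[rows])
  y2 <- ctx$stage2_lab[rows[s2]]
  taus <- rep(NA_real_, ncol(Wc))
  if (length(unique(y2)) >= 2) {
    for (j in seq_len(ncol(Wc))) {
      bt <- best_threshold(P[s2, j], y2, ctx$K, cfg$criterion)
      if (!is.null(bt)) taus[j] <- bt$tau
    }
  }
  valid <- which(!is.na(taus))
  if (length(valid) == 0) {
    return(list(dist = this_dist))
  }

  # stage 3: score valid candidates over the stage-3 members
  s3 <- !is.na(ctx$stage3_lab[rows])
  y3 <- ctx$stage3_lab[rows[s3]]
  parent_counts <- tabulate(y3, nbins = ctx$K)
  imp <- impurity_fun(ctx$stage3_imp)
  best_j <- NA_integer_
  best_score <- -Inf
  for (j in valid) {
    left_all <- P[, j] < taus[j]
    if (!any(left_all) || all(left_all)) next # degenerate routing
    score <- gain_from_counts(parent_counts,
                              tabulate(y3[left_all[s3]], nbins = ctx$K), imp)
    if (score > best_score) { # strict: ties keep first in generation order
      best_score <- score
      best_j <- j
    }
  }
  if (is.na(best_j)) {
    return(list(dist = this_dist))
  }
  left_all <- P[, best_j] < taus[best_j]
  ll <- left_all[seq_len(n_lab)]
  lu <- left_all[-seq_len(n_lab)]
  list(
    split = split_function(Wc[, best_j], taus[best_j]),
    left = grow_node(ctx, labeled[ll], unlabeled[lu], depth + 1, this_dist),
    right = grow_node(ctx, labeled[!ll], unlabeled[!lu], depth + 1, this_dist)
  )
}

# label vectors each stage consults, per variant
variant_stages <- function(variant, d, pseudo) {
  n <- nrow(d$x)
  y <- d$label
  need_oracle <- variant %in% c("perfect_stage3", "perfect_splitting", "optimal")
  if (need_oracle) {
    if (is.null(d$hidden) || anyNA(d$hidden)) {
      stopf("variant '%s' needs withheld ground-truth labels in `hidden`", variant)
    }
  }
  switch(variant,
    standard = ,
    control = list(stage2 = y, stage3 = y, route_unlabeled = FALSE),
    graph = {
      s3 <- y
      s3[is.na(s3)] <- pseudo[is.na(s3)]
      list(stage2 = y, stage3 = s3, route_unlabeled = TRUE)
    },
    perfect_stage3 = ,
    optimal = list(stage2 = y, stage3 = d$hidden, route_unlabeled = TRUE),
    perfect_splitting = list(stage2 = d$hidden, stage3 = d$hidden,
                             route_unlabeled = TRUE),
    stopf("unknown variant '%s'", variant)
  )
}

#' Train a (semi-supervised) oblique random forest
#'
#' Grows `trees` oblique decision trees with three-stage node construction.
#' For the `"graph"` variant, labels are first propagated once over a kNN
#' Gaussian affinity graph of all labeled and unlabeled points; the resulting
#' pseudo-labels replace the stage-3 split-selection gain with a
#' graph-embedded Gini gain, while stage 2 (thresholding) and the leaves use
#' labeled data only and the prediction path is exactly that of a standard
#' forest. `"standard"` (alias `"control"`) ignores the unlabeled block.
#' Oracle variants consult the withheld ground-truth labels of the unlabeled
#' block and bound what semi-supervision could achieve. `"optimal"` (alias
#' `"perfect_stage3"`) is trained on the labeled data exactly like a standard
#' forest but its stage-3 selection gain is computed from the true labels of
#' every routed member — the exact oracle counterpart of the `"graph"`
#' variant, which uses propagated pseudo-labels there, and hence the upper
#' bound a perfect propagation could attain. `"perfect_splitting"`
#' additionally proposes and scores the stage-2 thresholds on all members
#' with true labels; it exists for the bottleneck diagnostic, where its
#' near-identity with `"perfect_stage3"` shows stage 3 is what matters.
#'
#' @param d A [pl_dataset()] (or a data frame with a `label` column; `NA`
#'   labels mark unlabeled rows).
#' @param variant One of `"graph"`, `"standard"`, `"control"`,
#'   `"perfect_stage3"`, `"perfect_splitting"`, `"optimal"`.
#' @param trees Ensemble size T.
#' @param candidates Split-direction candidates per node (M).
#' @param oblique_nonzeros,axis_fraction Candidate scheme, see
#'   [generate_candidates()].
#' @param max_depth,min_labeled_split Stopping rules: maximum node depth and
#'   minimum labeled members required to attempt a split.
#' @param bootstrap Bootstrap the labeled block per tree (the unlabeled block
#'   is always shared in full).
#' @param criterion Impurity for supervised gains (stages 2 and supervised
#'   stage 3): `"gini"` or `"entropy"`. The graph-embedded stage-3 gain is
#'   always Gini.
#' @param neighbors,bandwidth,lambda Propagation hyperparameters, see
#'   [affinity_graph()] and [propagate_labels()].
#' @param leaves_use_pseudo Ablation flag: include pseudo-labeled members in
#'   leaf distributions (default `FALSE`; leaves use labeled members only).
#' @param seed Master seed; per-tree streams are derived from it.
#' @param propagation Optional precomputed [propagate_labels()] result to
#'   reuse across variants.
#' @return An object of class `graph_forest`.
#' @examples
#' d <- make_moons(n_per_class = 50, labeled_per_class = 5, seed = 1)
#' f <- graph_forest(d, trees = 5, seed = 1)
#' predict(f, make_moons(n_per_class = 10, seed = 2), type = "class")
#' @export
graph_forest <- function(d,
                         variant = c("graph", "standard", "control",
                                     "perfect_stage3", "perfect_splitting",
                                     "optimal"),
                         trees = 100, candidates = 50, oblique_nonzeros = 2,
                         axis_fraction = 0.5, max_depth = 20,
                         min_labeled_split = 4, bootstrap = TRUE,
                         criterion = c("gini", "entropy"),
                         neighbors = 10, bandwidth = NULL, lambda = 99,
                         leaves_use_pseudo = FALSE, seed = 1,
                         propagation = NULL) {
  variant <- match.arg(variant)
  criterion <- match.arg(criterion)
  if (is.data.frame(d)) d <- as_pl_dataset(d)
  stopifnot(inherits(d, "pl_dataset"))
  check_trainable(d)
  n <- nrow(d$x)
  unlab <- unlabeled_rows(d)

  pseudo <- rep(NA_integer_, n)
  if (variant == "graph" && length(unlab) > 0) {
    if (is.null(propagation)) {
      g <- affinity_graph(d, neighbors = neighbors, bandwidth = bandwidth)
      bandwidth <- g$bandwidth
      propagation <- propagate_labels(g, d, lambda = lambda)
    }
    pseudo[unlab] <- propagation$pseudo[unlab]
  }
  stages <- variant_stages(variant, d, pseudo)
  route_unlab <- if (stages$route_unlabeled) unlab else integer(0)

  config <- list(
    variant = variant, trees = trees, candidates = candidates,
    oblique_nonzeros = oblique_nonzeros, axis_fraction = axis_fraction,
    max_depth = max_depth, min_labeled_split = min_labeled_split,
    bootstrap = bootstrap, criterion = criterion, neighbors = neighbors,
    bandwidth = bandwidth, lambda = lambda,
    leaves_use_pseudo = leaves_use_pseudo, seed = seed
  )
  ctx <- list(
    x = d$x, K = d$K,
    stage2_lab = stages$stage2, stage3_lab = stages$stage3,
    leaf_lab = d$label,
    stage3_imp = if (variant == "graph") "gini" else criterion,
    config = config
  )
  lab_ids <- labeled_rows(d)
  root_counts <- tabulate(d$label[lab_ids], nbins = d$K)
  root_dist <- (root_counts + 1) / (sum(root_counts) + d$K)

  tree_list <- lapply(seq_len(trees), function(b) {
    with_local_seed(derive_seed(seed, "tree", b), {
      members <- if (bootstrap) {
        lab_ids[sample.int(length(lab_ids), length(lab_ids), replace = TRUE)]
      } else {
        lab_ids
      }
      grow_node(ctx, members, route_unlab, depth = 0, parent_dist = root_dist)
    })
  })

  structure(
    list(trees = tree_list, levels = d$levels, K = d$K, d = ncol(d$x),
         config = config, propagation = propagation),
    class = "graph_forest"
  )
}

#' @export
print.graph_forest <- function(x, ...) {
  cat(sprintf("<graph_forest> variant '%s', %d trees, %d classes (%s), %d features\n",
              x$config$variant, length(x$trees), x$K,
              paste(x$levels, collapse = ", "), x$d))
  invisible(x)
}

tree_leaf_matrix <- function(node, X, K) {
  out <- matrix(0, nrow(X), K)
  rec <- function(nd, idx) {
    if (length(idx) == 0) return(invisible(NULL))
    if (is.null(nd$split)) {
      out[idx, ] <<- matrix(nd$dist, length(idx), K, byrow = TRUE)
    } else {
      left <- drop(X[idx, , drop = FALSE] %*% nd$split$w) < nd$split$tau
      rec(nd$left, idx[left])
      rec(nd$right, idx[!left])
    }
    invisible(NULL)
  }
  rec(node, seq_len(nrow(X)))
  out
}

predict_matrix <- function(object, X) {
  if (ncol(X) != object$d) {
    stopf("newdata has %d features, forest expects %d", ncol(X), object$d)
  }
  acc <- matrix(0, nrow(X), object$K)
  for (tr in object$trees) {
    acc <- acc + tree_leaf_matrix(tr, X, object$K)
  }
  probs <- acc / length(object$trees)
  probs / rowSums(probs)
}

as_feature_matrix <- function(newdata, forest = NULL) {
  if (inherits(newdata, "pl_dataset")) return(newdata$x)
  if (is.data.frame(newdata)) {
    newdata <- newdata[setdiff(names(newdata), "label")]
    num <- vapply(newdata, is.numeric, logical(1))
    return(as.matrix(newdata[num]))
  }
  as.matrix(newdata)
}

#' Predict from a trained forest
#'
#' Routes each query through every tree and averages the reached leaf
#' distributions; identical for every training variant.
#'
#' @param object A `graph_forest`.
#' @param newdata A matrix, data frame or [pl_dataset()] of query rows.
#' @param type `"prob"` for per-class probabilities (one `.pred_<class>`
#'   column each, rows sum to 1), `"class"` for hard labels (`.pred_class`,
#'   argmax with ties to the lowest class index).
#' @param ... Unused.
#' @return A tibble with one row per query.
#' @export
predict.graph_forest <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  probs <- predict_matrix(object, as_feature_matrix(newdata, object))
  if (type == "class") {
    return(tibble::tibble(.pred_class = object$levels[row_argmax(probs)]))
  }
  colnames(probs) <- paste0(".pred_", object$levels)
  tibble::as_tibble(as.data.frame(probs))
}

tree_stats <- function(node) {
  if (is.null(node$split)) {
    c(nodes = 1, leaves = 1, depth = 0)
  } else {
    l <- tree_stats(node$left)
    r <- tree_stats(node$right)
    c(nodes = 1 + l[["nodes"]] + r[["nodes"]],
      leaves = l[["leaves"]] + r[["leaves"]],
      depth = 1 + max(l[["depth"]], r[["depth"]]))
  }
}

#' Broom-style summaries of a fitted forest
#'
#' `tidy()` returns one row per tree (node, leaf and depth counts);
#' `glance()` returns a one-row model summary.
#'
#' @param x A `graph_forest`.
#' @param ... Unused.
#' @method tidy graph_forest
#' @export
tidy.graph_forest <- function(x, ...) {
  st <- t(vapply(x$trees, tree_stats, numeric(3)))
  tibble::tibble(
    tree = seq_len(nrow(st)),
    nodes = as.integer(st[, "nodes"]),
    leaves = as.integer(st[, "leaves"]),
    depth = as.integer(st[, "depth"])
  )
}

#' @rdname tidy.graph_forest
#' @method glance graph_forest
#' @export
glance.graph_forest <- function(x, ...) {
  st <- tidy.graph_forest(x)
  tibble::tibble(
    variant = x$config$variant,
    trees = length(x$trees),
    classes = x$K,
    features = x$d,
    mean_depth = mean(st$depth),
    mean_leaves = mean(st$leaves),
    lambda = x$config$lambda,
    neighbors = x$config$neighbors
  )
}
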