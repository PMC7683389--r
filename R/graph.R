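# kNN Gaussian affinity graph and closed-form label propagation.
#
# All l+u training points enter one graph; labels spread by minimizing a
# graph-regularized least-squares objective whose unique minimizer is
#   F* = ((1+lambda) I - lambda S)^{-1} Y,    S = D^{-1/2} W D^{-1/2}.
# The spectrum of S lies in [-1, 1], so the system matrix is symmetric
# positive definite for every lambda > 0.

#' Build a kNN Gaussian affinity graph
#'
#' For each point the `neighbors` nearest other points are found; an edge is
#' kept when either endpoint selects the other (union symmetrization), and
#' carries weight `exp(-dist^2 / sigma^2)`. With `bandwidth = NULL` the
#' bandwidth sigma is set by the median heuristic: the median of all retained
#' neighbor distances.
#'
#' @param d A [pl_dataset()] (labeled and unlabeled rows all participate), or
#'   a plain numeric matrix.
#' @param neighbors Neighbor count t (`1 <= t < n`).
#' @param bandwidth Gaussian bandwidth sigma, or `NULL` for the median
#'   heuristic.
#' @return An object of class `affinity_graph`: dense symmetric `weights`
#'   with zero diagonal, `degrees` (row sums), `neighbors`, `bandwidth`.
#' @examples
#' g <- affinity_graph(make_moons(seed = 1), neighbors = 10)
#' all(g$weights == t(g$weights))
#' @export
affinity_graph <- function(d, neighbors = 10, bandwidth = NULL) {
  x <- if (inherits(d, "pl_dataset")) d$x else as.matrix(d)
  n <- nrow(x)
  if (n < 2) stopf("graph construction needs at least 2 points")
  if (neighbors < 1) stopf("`neighbors` must be >= 1")
  if (neighbors >= n) stopf("`neighbors` = %d must be < n = %d", neighbors, n)
  dm <- as.matrix(stats::dist(x))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    # ties broken by lowest index (order() is stable)
    nn <- order(dm[i, -i])[seq_len(neighbors)]
    nn <- seq_len(n)[-i][nn]
    adj[i, nn] <- TRUE
  }
  adj <- adj | t(adj) # union rule
  if (is.null(bandwidth)) {
    retained <- dm[adj & upper.tri(adj)]
    bandwidth <- stats::median(retained)
    if (!is.finite(bandwidth) || bandwidth <= 0) {
      pos <- retained[retained > 0]
      bandwidth <- if (length(pos)) min(pos) else 1
    }
  }
  if (bandwidth <= 0) stopf("`bandwidth` must be positive")
  W <- ifelse(adj, exp(-dm^2 / bandwidth^2), 0)
  diag(W) <- 0
  structure(
    list(weights = W, degrees = rowSums(W),
         neighbors = neighbors, bandwidth = bandwidth),
    class = "affinity_graph"
  )
}

#' @export
print.affinity_graph <- function(x, ...) {
  cat(sprintf("<affinity_graph> %d nodes, %d edges, t = %d, sigma = %.4g\n",
              nrow(x$weights), sum(x$weights > 0) / 2, x$neighbors, x$bandwidth))
  invisible(x)
}

# D^{-1/2} W D^{-1/2} with rows/cols of isolated nodes (degree 0) set to zero
normalized_affinity <- function(graph) {
  dd <- graph$degrees
  inv_sqrt <- ifelse(dd > 0, 1 / sqrt(dd), 0)
  graph$weights * tcrossprod(inv_sqrt)
}

#' Propagate labels over an affinity graph
#'
#' Solves the graph-regularized least-squares problem whose data term anchors
#' labeled rows at their one-hot targets and whose smoothness term penalizes
#' degree-normalized score differences along edges, weighted by `lambda`.
#' The closed-form minimizer `((1+lambda) I - lambda S)^{-1} Y` is computed by
#' a direct symmetric solve; unlabeled rows get pseudo-labels by row argmax
#' (ties to the lowest class index). Isolated nodes fall back to
#' `Y/(1+lambda)` scores.
#'
#' @param graph An [affinity_graph()] over all rows of `d`.
#' @param d The [pl_dataset()] the graph was built from (supplies the label
#'   matrix), or a pre-built label matrix.
#' @param lambda Regularization weight (> 0). The default 99 corresponds to
#'   the classical propagation mixing rate alpha = lambda/(1+lambda) = 0.99.
#' @return An object of class `propagation`: `scores` ((l+u) x K matrix F*),
#'   `pseudo` (integer codes for ALL rows, by row argmax), `unlabeled`
#'   (row indices of the unlabeled block), `lambda`.
#' @examples
#' d <- make_moons(n_per_class = 100, labeled_per_class = 1, seed = 1)
#' g <- affinity_graph(d, neighbors = 10)
#' p <- propagate_labels(g, d)
#' table(p$pseudo[p$unlabeled], d$hidden[p$unlabeled])
#' @export
propagate_labels <- function(graph, d, lambda = 99) {
  if (lambda <= 0) stopf("`lambda` must be > 0")
  if (inherits(d, "pl_dataset")) {
    Y <- label_matrix(d)
    unlab <- unlabeled_rows(d)
  } else {
    Y <- as.matrix(d)
    unlab <- which(rowSums(Y) == 0)
  }
  n <- nrow(graph$weights)
  if (nrow(Y) != n) stopf("label matrix has %d rows, graph has %d nodes", nrow(Y), n)
  S <- normalized_affinity(graph)
  A <- -lambda * S
  diag(A) <- diag(A) + (1 + lambda)
  F_star <- solve(A, Y)
  res <- max(abs(A %*% F_star - Y))
  if (!is.finite(res) || res > 1e-6 * max(1, max(abs(Y)))) {
    stopf("propagation solve failed (residual %g)", res)
  }
  structure(
    list(scores = F_star, pseudo = row_argmax(F_star), unlabeled = unlab,
         lambda = lambda),
    class = "propagation"
  )
}

#' @export
print.propagation <- function(x, ...) {
  cat(sprintf("<propagation> %d instances x %d classes, lambda = %g, %d pseudo-labeled\n",
              nrow(x$scores), ncol(x$scores), x$lambda, length(x$unlabeled)))
  invisible(x)
}

#' Propagation objective and its gradient
#'
#' The loss whose minimizer the closed-form propagation computes:
#' `1/2 * sum_i ||f_i - y_i||^2 + (lambda/2) * sum_{edges (i,j)} W_ij *
#' ||f_i/sqrt(D_ii) - f_j/sqrt(D_jj)||^2`, with each unordered edge counted
#' once so that the stated closed form is its exact stationary point. Used to
#' test optimality; `propagation_gradient()` returns the dense analytic
#' gradient.
#'
#' @param scores Candidate score matrix F, (l+u) x K.
#' @param Y One-hot label matrix (see [label_matrix()]).
#' @param graph An [affinity_graph()].
#' @param lambda Regularization weight.
#' @return `propagation_objective()`: a nonnegative scalar.
#'   `propagation_gradient()`: a matrix the shape of `scores`.
#' @export
propagation_objective <- function(scores, Y, graph, lambda) {
  scores <- as.matrix(scores)
  stopifnot(all(dim(scores) == dim(Y)), nrow(scores) == nrow(graph$weights))
  fit <- 0.5 * sum((scores - Y)^2)
  dd <- graph$degrees
  inv_sqrt <- ifelse(dd > 0, 1 / sqrt(dd), 0)
  Fn <- scores * inv_sqrt # rows scaled by D^{-1/2}
  W <- graph$weights
  edges <- which(W > 0 & upper.tri(W), arr.ind = TRUE)
  smooth <- if (nrow(edges)) {
    sum(W[edges] * rowSums((Fn[edges[, 1], , drop = FALSE] -
                              Fn[edges[, 2], , drop = FALSE])^2))
  } else {
    0
  }
  fit + 0.5 * lambda * smooth
}

#' @rdname propagation_objective
#' @export
propagation_gradient <- function(scores, Y, graph, lambda) {
  scores <- as.matrix(scores)
  S <- normalized_affinity(graph)
  # J masks isolated nodes out of the smoothness term entirely
  J <- as.numeric(graph$degrees > 0)
  (scores - Y) + lambda * (J * scores - S %*% scores)
}

#' Fixed-point label propagation (iterative reference)
#'
#' Iterates `F <- alpha S F + (1-alpha) Y` with `alpha = lambda/(1+lambda)`
#' from `F = Y` until the relative change drops below `tol`. Converges to the
#' same fixed point as the closed-form solve; retained as an independent
#' route for validation and for very large graphs.
#'
#' @inheritParams propagate_labels
#' @param tol Relative-change stopping tolerance.
#' @param max_iter Iteration cap.
#' @return A score matrix the shape of the label matrix.
#' @export
propagate_labels_iterative <- function(graph, d, lambda = 99, tol = 1e-10,
                                       max_iter = 100000) {
  Y <- if (inherits(d, "pl_dataset")) label_matrix(d) else as.matrix(d)
  S <- normalized_affinity(graph)
  alpha <- lambda / (1 + lambda)
  F_cur <- Y
  for (it in seq_len(max_iter)) {
    F_new <- alpha * (S %*% F_cur) + (1 - alpha) * Y
    delta <- max(abs(F_new - F_cur)) / max(1e-300, max(abs(F_cur)))
    F_cur <- F_new
    if (delta < tol) break
  }
  F_cur
}

#' Tidy export of a propagation result
#'
#' @param x A `propagation` object.
#' @param d Optional originating [pl_dataset()] for class names and
#'   labeled/unlabeled status.
#' @param ... Unused.
#' @return A tibble with one row per instance: id, per-class scores,
#'   pseudo-label, and (if `d` is given) whether the row was labeled.
#' @method tidy propagation
#' @export
tidy.propagation <- function(x, d = NULL, ...) {
  scores <- x$scores
  lev <- if (!is.null(d)) d$levels else paste0("class", seq_len(ncol(scores)))
  colnames(scores) <- paste0("score_", lev)
  out <- tibble::as_tibble(as.data.frame(scores))
  out <- dplyr::mutate(out,
    id = dplyr::row_number(),
    pseudo_label = lev[x$pseudo],
    .before = 1
  )
  if (!is.null(d)) out$labeled <- !is.na(d$label)
  out
}
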