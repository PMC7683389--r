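# Node impurities and split gains over mixed labeled/pseudo-labeled
# populations. A node population is a pair of index lists into the labeled
# and unlabeled blocks; class proportions count labeled members by their true
# label and unlabeled members by their propagated pseudo-label. The naming
# here is strictly left/right for children — the labeled/unlabeled blocks are
# a different axis entirely.

#' Node population
#'
#' @param labeled Integer indices of labeled members (rows of the dataset).
#'   May contain repeats when the labeled block is bootstrapped.
#' @param unlabeled Integer indices of unlabeled members.
#' @return A list with elements `labeled` and `unlabeled`.
#' @export
node_population <- function(labeled = integer(0), unlabeled = integer(0)) {
  list(labeled = as.integer(labeled), unlabeled = as.integer(unlabeled))
}

pop_size <- function(pop) length(pop$labeled) + length(pop$unlabeled)

# class counts of a population: labeled members by `labels`, unlabeled by
# `pseudo`; either vector is indexed by dataset row
pop_counts <- function(pop, labels, pseudo, K) {
  cl <- c(labels[pop$labeled], pseudo[pop$unlabeled])
  cl <- cl[!is.na(cl)]
  tabulate(cl, nbins = K)
}

gini_from_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0) # vacuous node is pure by convention
  p <- counts / n
  sum(p * (1 - p))
}

entropy_from_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

impurity_fun <- function(criterion = c("gini", "entropy")) {
  switch(match.arg(criterion), gini = gini_from_counts, entropy = entropy_from_counts)
}

#' Gini impurity of a node population
#'
#' Class proportions `p_k` count labeled members through their labels and
#' unlabeled members through their pseudo-labels:
#' `p_k = (#labeled with label k + #unlabeled with pseudo-label k) / |S|`,
#' and the impurity is `sum_k p_k (1 - p_k)`. An empty population has
#' impurity 0.
#'
#' @param pop A [node_population()].
#' @param labels Integer class codes (`1..K`) indexed by dataset row; `NA`
#'   allowed off the labeled block.
#' @param pseudo Integer pseudo-label codes indexed by dataset row; ignored
#'   when the population has no unlabeled members.
#' @param K Number of classes.
#' @return A number in `[0, 1 - 1/K]`.
#' @examples
#' node_gini(node_population(labeled = 1:3, unlabeled = 4), c(1, 1, 1, NA), c(NA, NA, NA, 2), 2)
#' @export
node_gini <- function(pop, labels, pseudo = NULL, K) {
  gini_from_counts(pop_counts(pop, labels, pseudo %||% rep(NA_integer_, length(labels)), K))
}

#' Oblique split function
#'
#' The binary test `h(x; w, tau) = [<w, x> < tau]`: a strictly smaller
#' projection routes LEFT.
#'
#' @param w Numeric weight vector (length d).
#' @param tau Scalar threshold.
#' @export
split_function <- function(w, tau) {
  list(w = as.numeric(w), tau = as.numeric(tau))
}

# route a population through a split; returns list(left=, right=) populations
route_population <- function(pop, split, x) {
  goes_left <- function(idx) {
    if (length(idx) == 0) return(logical(0))
    drop(x[idx, , drop = FALSE] %*% split$w) < split$tau
  }
  ll <- goes_left(pop$labeled)
  lu <- goes_left(pop$unlabeled)
  list(
    left = node_population(pop$labeled[ll], pop$unlabeled[lu]),
    right = node_population(pop$labeled[!ll], pop$unlabeled[!lu])
  )
}

gain_from_counts <- function(parent_counts, left_counts, impurity = gini_from_counts) {
  n <- sum(parent_counts)
  if (n == 0) return(0)
  right_counts <- parent_counts - left_counts
  nl <- sum(left_counts)
  impurity(parent_counts) -
    (nl * impurity(left_counts) + (n - nl) * impurity(right_counts)) / n
}

#' Graph-embedded information gain
#'
#' Parent impurity minus size-weighted child impurity, where EVERY member —
#' labeled and unlabeled alike — is routed through the split and counted in
#' the class proportions (labeled members by label, unlabeled by
#' pseudo-label):
#' `G(S) - (|S_left| G(S_left) + |S_right| G(S_right)) / |S|`.
#' A degenerate split that sends all members one way has gain exactly 0.
#'
#' @inheritParams node_gini
#' @param split A [split_function()].
#' @param d The [pl_dataset()] supplying feature rows.
#' @param weighting `"all"` (default) weights children by their full
#'   labeled+unlabeled size as the gain formula states; `"labeled"` is an
#'   ablation that weights by labeled counts only.
#' @return The gain, in `[0, G(S)]`.
#' @export
graph_gain <- function(pop, split, d, labels, pseudo, K,
                       weighting = c("all", "labeled")) {
  weighting <- match.arg(weighting)
  kids <- route_population(pop, split, d$x)
  if (weighting == "all") {
    parent <- pop_counts(pop, labels, pseudo, K)
    left <- pop_counts(kids$left, labels, pseudo, K)
    gain_from_counts(parent, left)
  } else {
    no_pseudo <- rep(NA_integer_, length(labels))
    parent <- pop_counts(pop, labels, no_pseudo, K)
    left <- pop_counts(kids$left, labels, no_pseudo, K)
    mixed <- function(p) gini_from_counts(pop_counts(p, labels, pseudo, K))
    n <- sum(parent)
    if (n == 0) return(0)
    mixed(pop) - (sum(left) * mixed(kids$left) +
                    (n - sum(left)) * mixed(kids$right)) / n
  }
}

#' Supervised information gain
#'
#' Identical in form to [graph_gain()] but counting ONLY labeled members; the
#' unlabeled members of the node do not enter the proportions or the child
#' weights. Undefined (returns `NA`) when the node has no labeled members —
#' callers must treat such a candidate as invalid.
#'
#' @inheritParams graph_gain
#' @param criterion Impurity: `"gini"` (default) or `"entropy"`.
#' @export
supervised_gain <- function(pop, split, d, labels, K,
                            criterion = c("gini", "entropy")) {
  imp <- impurity_fun(criterion)
  if (length(pop$labeled) == 0) return(NA_real_)
  pl <- drop(d$x[pop$labeled, , drop = FALSE] %*% split$w) < split$tau
  parent <- tabulate(labels[pop$labeled], nbins = K)
  left <- tabulate(labels[pop$labeled[pl]], nbins = K)
  gain_from_counts(parent, left, imp)
}
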