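# Shared fixture builders; everything is generated in code at test time.

# tiny fully labeled 1-D dataset: class 1 at 0,1,2 and class 2 at 8,9,10
fixture_1d <- function() {
  pl_dataset(matrix(c(0, 1, 2, 8, 9, 10), ncol = 1),
             rep(c("a", "b"), each = 3), levels = c("a", "b"))
}

# two tight, well-separated Gaussian clusters with one label per cluster
fixture_two_clusters <- function(n = 50, seed = 1) {
  make_clusters(n_per_class = n, noise_scale = 0.5, separation = sqrt(200),
                labeled_per_class = 1, seed = seed)
}

# random partially labeled dataset for property checks
fixture_random <- function(n = 20, d = 3, K = 2, n_lab = 8, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d)
  lab <- rep(NA_character_, n)
  lab[seq_len(n_lab)] <- as.character(sample.int(K, n_lab, replace = TRUE))
  hidden <- as.character(sample.int(K, n, replace = TRUE))
  hidden[seq_len(n_lab)] <- lab[seq_len(n_lab)]
  pl_dataset(x, lab, levels = as.character(seq_len(K)), hidden = hidden)
}

# brute-force graph-embedded gain: explicit membership recount, no shared
# code with the implementation beyond the split definition
oracle_graph_gain <- function(pop, split, d, labels, pseudo, K) {
  cls <- function(p) {
    c(labels[p$labeled], pseudo[p$unlabeled])
  }
  gini <- function(v) {
    if (length(v) == 0) return(0)
    p <- as.vector(table(factor(v, levels = seq_len(K)))) / length(v)
    sum(p * (1 - p))
  }
  side <- function(idx) drop(d$x[idx, , drop = FALSE] %*% split$w) < split$tau
  lp <- list(labeled = pop$labeled[side(pop$labeled)],
             unlabeled = pop$unlabeled[side(pop$unlabeled)])
  rp <- list(labeled = pop$labeled[!side(pop$labeled)],
             unlabeled = pop$unlabeled[!side(pop$unlabeled)])
  sz <- function(p) length(p$labeled) + length(p$unlabeled)
  gini(cls(pop)) - (sz(lp) * gini(cls(lp)) + sz(rp) * gini(cls(rp))) / sz(pop)
}
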