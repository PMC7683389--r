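# Experiment harness: forest variants side by side, accuracy curves over the
# number of labeled samples, and the stage-3 bottleneck comparison.

#' Train one named forest variant
#'
#' Thin wrapper over [graph_forest()] that validates variant requirements
#' (oracle variants need withheld ground truth) and applies harness defaults.
#'
#' @param d A [pl_dataset()].
#' @param variant Variant name, see [graph_forest()].
#' @param ... Passed to [graph_forest()].
#' @return A `graph_forest`.
#' @export
run_variant <- function(d, variant, ...) {
  graph_forest(d, variant = variant, ...)
}

#' Classification accuracy of a forest on a labeled dataset
#'
#' @param forest A `graph_forest`.
#' @param test A fully labeled [pl_dataset()] (or matrix plus `truth` codes).
#' @param truth Optional integer class codes overriding `test$label`.
#' @return Fraction of correctly classified rows.
#' @export
forest_accuracy <- function(forest, test, truth = NULL) {
  X <- as_feature_matrix(test)
  truth <- truth %||% test$label
  pred <- row_argmax(predict_matrix(forest, X))
  mean(pred == truth)
}

#' Compare forest variants over repeated labeled-subset draws
#'
#' For every repeat, a fresh labeled subset of size `labeled_size` is drawn
#' from the fully labeled `train` pool (the rest becomes unlabeled with
#' ground truth withheld into `hidden`), every requested variant is trained
#' on the SAME partially labeled dataset, and accuracy is measured on the
#' held-out `test` set — so comparisons are paired by draw.
#'
#' @param train A fully labeled [pl_dataset()] training pool.
#' @param test A fully labeled [pl_dataset()] evaluation set.
#' @param variants Character vector of variant names.
#' @param labeled_size Number of rows keeping their labels per repeat (a
#'   per-class quota when `per_class = TRUE`).
#' @param per_class Draw `labeled_size` rows of EVERY class instead of
#'   `labeled_size` rows in total.
#' @param repeats Number of paired repeats.
#' @param seed Master seed; repeat r uses the derived sub-stream
#'   `derive_seed(seed, "rep", r)`.
#' @param ... Forest parameters passed to [graph_forest()].
#' @return A tibble: `variant`, `repeat`, `labeled_size`, `accuracy`.
#' @export
compare_variants <- function(train, test, variants, labeled_size,
                             repeats = 20, seed = 1, per_class = FALSE, ...) {
  purrr::map_dfr(seq_len(repeats), function(r) {
    rep_seed <- derive_seed(seed, "rep", r)
    d <- split_labeled_subset(train, labeled_size, seed = rep_seed,
                              per_class = per_class)
    forest_seed <- derive_seed(rep_seed, "forest")
    purrr::map_dfr(variants, function(v) {
      # all variants share one forest seed: identical bootstraps and
      # candidate streams, so the comparison isolates the split criterion
      f <- graph_forest(d, variant = v, seed = forest_seed, ...)
      tibble::tibble(
        variant = v, `repeat` = r, labeled_size = labeled_size,
        accuracy = forest_accuracy(f, test)
      )
    })
  })
}

#' Accuracy versus number of labeled samples
#'
#' The quantitative-analysis protocol: for each labeled-subset size and each
#' repeat, draw the subset, train every variant on it, and score accuracy on
#' a held-out labeled test set.
#'
#' @inheritParams compare_variants
#' @param labeled_sizes Integer vector of labeled-subset sizes (each >= the
#'   class count).
#' @return A tibble of class `accuracy_curve` with columns `variant`,
#'   `labeled_size`, `repeat`, `accuracy`.
#' @export
accuracy_curve <- function(train, test, variants = c("standard", "graph", "optimal"),
                           labeled_sizes, repeats = 5, seed = 1, ...) {
  if (nrow(test$x) == 0) stopf("test set is empty")
  out <- purrr::map_dfr(labeled_sizes, function(n) {
    compare_variants(train, test, variants, labeled_size = n,
                     repeats = repeats, seed = derive_seed(seed, "size", n), ...)
  })
  class(out) <- c("accuracy_curve", class(out))
  out
}

#' Per-cell summary of an accuracy curve
#'
#' @param x An [accuracy_curve()] result.
#' @param ... Unused.
#' @return A tibble with mean and standard deviation of accuracy per
#'   (variant, labeled_size) cell.
#' @export
summarize_curve <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x, .data$variant, .data$labeled_size),
    mean_accuracy = mean(.data$accuracy),
    sd_accuracy = stats::sd(.data$accuracy),
    repeats = dplyr::n(),
    .groups = "drop"
  )
}

#' Plot an accuracy curve
#'
#' Mean accuracy (± one standard deviation ribbon) against the number of
#' labeled samples, one line per variant.
#'
#' @param object An [accuracy_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot accuracy_curve
#' @export
autoplot.accuracy_curve <- function(object, ...) {
  s <- summarize_curve(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$labeled_size, y = .data$mean_accuracy,
                                  colour = .data$variant, fill = .data$variant)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_accuracy - .data$sd_accuracy,
                                      ymax = .data$mean_accuracy + .data$sd_accuracy),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "labeled samples", y = "accuracy",
                  colour = "variant", fill = "variant") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.accuracy_curve
#' @export
plot_accuracy_curve <- function(object, ...) autoplot.accuracy_curve(object, ...)

#' Stage-3 bottleneck experiment
#'
#' Reproduces the three-forest comparison that locates the performance
#' bottleneck of a random forest under scarce labels: a `control` forest
#' trained on a small labeled set S1 alone; a `perfect_stage3` forest that
#' additionally consults the true labels of a large extra pool S2 — but only
#' inside the stage-3 candidate selection; and a `perfect_splitting` forest
#' that consults S2 in stages 2 and 3. A large `perfect_stage3 - control`
#' gap combined with a small further `perfect_splitting - perfect_stage3`
#' gap indicates that stage-3 gain estimation is the bottleneck.
#'
#' Splitting criterion defaults to entropy for all three forests, matching
#' the original protocol of this experiment.
#'
#' @param train Fully labeled [pl_dataset()] pool (supplies S1 and S2).
#' @param test Fully labeled [pl_dataset()] evaluation set.
#' @param s1 Size of the small labeled set S1.
#' @param repeats Paired repeats.
#' @param seed Master seed.
#' @param criterion Impurity for the supervised gains (entropy by default
#'   here, unlike [graph_forest()]).
#' @param ... Forest parameters passed to [graph_forest()].
#' @return A tibble: `variant`, `repeat`, `labeled_size`, `accuracy`.
#' @export
bottleneck_experiment <- function(train, test, s1 = 20, repeats = 20, seed = 1,
                                  criterion = "entropy", ...) {
  compare_variants(train, test,
                   variants = c("control", "perfect_stage3", "perfect_splitting"),
                   labeled_size = s1, repeats = repeats, seed = seed,
                   criterion = criterion, ...)
}
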