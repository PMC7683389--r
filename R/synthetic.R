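# Synthetic manifold-structured generators. Every generator is a pure
# function of its arguments (bit-reproducible per seed) and returns ground
# truth for all points, so oracle variants and evaluation always have access
# to the withheld labels.

# optional random orthonormal embedding of 2-D data into `dimension`;
# the embedding has its own seed so train/test draws can share one map
embed_dims <- function(x, dimension, embed_seed) {
  if (is.null(dimension) || dimension <= ncol(x)) {
    return(x)
  }
  Q <- with_local_seed(derive_seed(embed_seed, "embed"), {
    m <- matrix(stats::rnorm(dimension * ncol(x)), dimension, ncol(x))
    qr.Q(qr(m))
  })
  x %*% t(Q)
}

finish_dataset <- function(x, y, labeled_per_class, seed, levels = c("0", "1")) {
  d <- pl_dataset(x, levels[y + 1L], levels = levels, hidden = levels[y + 1L])
  if (!is.null(labeled_per_class)) {
    d <- split_labeled_subset(d, labeled_per_class,
                              seed = derive_seed(seed, "subset"),
                              per_class = TRUE)
  }
  d
}

#' Two Gaussian clusters
#'
#' Two isotropic Gaussian clusters with centre separation `separation` and
#' per-coordinate spread `noise_scale`, optionally embedded into a
#' higher-dimensional space by a random orthonormal map. The default
#' separation of `20 * noise_scale` gives well-separated clusters; pass
#' `separation` explicitly for overlapping ones.
#'
#' @param n_per_class Points per class.
#' @param noise_scale Isotropic standard deviation of each cluster.
#' @param separation Distance between the two cluster centres.
#' @param dimension Ambient dimension after random orthonormal embedding
#'   (`NULL` or `2` keeps the plane).
#' @param labeled_per_class If non-`NULL`, labels are withheld from all but
#'   exactly this many points per class (a per-class quota draw via
#'   [split_labeled_subset()]).
#' @param seed Integer seed.
#' @param embed_seed Seed for the random embedding map only (defaults to
#'   `seed`); pass the same value for train and test draws so they share one
#'   embedding.
#' @return A [pl_dataset()] with ground truth in `hidden`.
#' @examples
#' d <- make_clusters(n_per_class = 50, labeled_per_class = 1, seed = 1)
#' @export
make_clusters <- function(n_per_class = 100, noise_scale = 1,
                          separation = 20 * noise_scale, dimension = 2,
                          labeled_per_class = NULL, seed = 1,
                          embed_seed = seed) {
  x <- with_local_seed(derive_seed(seed, "clusters"), {
    n <- n_per_class
    rbind(
      cbind(stats::rnorm(n, 0, noise_scale), stats::rnorm(n, 0, noise_scale)),
      cbind(stats::rnorm(n, separation, noise_scale), stats::rnorm(n, 0, noise_scale))
    )
  })
  y <- rep(0:1, each = n_per_class)
  finish_dataset(embed_dims(x, dimension, embed_seed), y, labeled_per_class, seed)
}

#' Two interleaving moons
#'
#' The canonical manifold-structured semi-supervised fixture: two interleaving
#' half-circles of radius 1 with isotropic Gaussian jitter.
#'
#' @inheritParams make_clusters
#' @param noise_scale Standard deviation of the Gaussian jitter.
#' @export
make_moons <- function(n_per_class = 100, noise_scale = 0.05, dimension = 2,
                       labeled_per_class = NULL, seed = 1,
                       embed_seed = seed) {
  x <- with_local_seed(derive_seed(seed, "moons"), {
    n <- n_per_class
    t1 <- stats::runif(n, 0, pi)
    t2 <- stats::runif(n, 0, pi)
    pts <- rbind(
      cbind(cos(t1), sin(t1)),
      cbind(1 - cos(t2), 0.5 - sin(t2))
    )
    pts + matrix(stats::rnorm(2 * 2 * n, 0, noise_scale), 2 * n, 2)
  })
  y <- rep(0:1, each = n_per_class)
  finish_dataset(embed_dims(x, dimension, embed_seed), y, labeled_per_class, seed)
}

#' Synthetic vessel phantom image
#'
#' A dark noisy background crossed by bright curvilinear tubes: random cubic
#' Bezier centrelines rendered with a Gaussian cross-section profile. Stands
#' in for retinal-vessel imagery in feature-extraction tests, with a binary
#' ground-truth mask on the tube pixels.
#'
#' @param height,width Image size in pixels.
#' @param n_tubes Number of tubes.
#' @param width_range Tube half-width range in pixels (uniform per tube).
#' @param snr Tube peak amplitude divided by background noise standard
#'   deviation.
#' @param seed Integer seed.
#' @return A list with `image` (numeric matrix in `[0,1]`) and `mask`
#'   (logical matrix, `TRUE` on tube pixels).
#' @examples
#' v <- make_vessel_image(seed = 1)
#' mean(v$image[v$mask]) > mean(v$image[!v$mask])
#' @export
make_vessel_image <- function(height = 128, width = 128, n_tubes = 3,
                              width_range = c(2, 5), snr = 8, seed = 1) {
  with_local_seed(derive_seed(seed, "vessel"), {
    noise_sd <- 1 / snr
    img <- matrix(stats::rnorm(height * width, 0.1, noise_sd), height, width)
    tube <- matrix(0, height, width)
    for (i in seq_len(n_tubes)) {
      # cubic Bezier with control points spread across the frame
      ctrl <- cbind(stats::runif(4, 1, height), stats::runif(4, 1, width))
      tt <- seq(0, 1, length.out = 4 * max(height, width))
      b <- outer(tt, 0:3, function(t, k) choose(3, k) * t^k * (1 - t)^(3 - k))
      path <- b %*% ctrl
      w <- stats::runif(1, width_range[1], width_range[2])
      rad <- ceiling(3 * w)
      for (p in seq_len(nrow(path))) {
        r0 <- round(path[p, 1]); c0 <- round(path[p, 2])
        rs <- max(1, r0 - rad):min(height, r0 + rad)
        cs <- max(1, c0 - rad):min(width, c0 + rad)
        if (length(rs) == 0 || length(cs) == 0) next
        d2 <- outer((rs - path[p, 1])^2, (cs - path[p, 2])^2, `+`)
        tube[rs, cs] <- pmax(tube[rs, cs], exp(-d2 / (2 * (w / 2)^2)))
      }
    }
    img <- img + tube
    img <- pmin(pmax(img, 0), 1)
    list(image = img, mask = tube > exp(-1 / 2)) # within one half-width sigma
  })
}
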