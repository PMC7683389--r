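# Image feature extraction: raw local patches and Gabor-wavelet responses at
# sampled pixel locations. Images are numeric arrays in [0, 1]: H x W
# (grayscale), H x W x C (multi-channel), or H x W x D cubes for 3-D data.

#' Read a PNG/TIFF image into a numeric array
#'
#' @param path Image path; format chosen by extension. Multi-page TIFFs load
#'   as H x W x D arrays.
#' @return A numeric array with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) == 1) pages[[1]] else simplify2array(pages)
  } else {
    stopf("unsupported image format: %s", path)
  }
}

#' @rdname read_image
#' @param image Numeric array in `[0, 1]`.
#' @export
write_image <- function(image, path) {
  image <- pmin(pmax(image, 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(image, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(image, path)
  } else {
    stopf("unsupported image format: %s", path)
  }
  invisible(path)
}

# reflect-padded index lookup: maps any integer to [1, n] by mirroring
reflect_index <- function(idx, n) {
  if (n == 1) return(rep(1L, length(idx)))
  period <- 2L * (n - 1L)
  m <- (idx - 1L) %% period
  m <- ifelse(m < 0, m + period, m)
  as.integer(ifelse(m < n, m + 1L, period - m + 1L))
}

#' Extract local patches around sampled pixels
#'
#' Cuts an odd-sized window centred on each sampled pixel and flattens it in
#' (row, column, channel-or-slice) order — the last axis varying fastest.
#' Borders are handled by reflect padding; values are clamped to `[0, 1]`.
#'
#' @param image Numeric array: H x W, H x W x C, or H x W x D.
#' @param points Data frame or matrix with columns `row`, `col` (and `slice`
#'   for 3-D cubes with `depth > 1`), 1-based pixel coordinates.
#' @param height,width Odd patch height and width (pixels).
#' @param depth Slices for 3-D cubes (odd; 1 extracts from a single 2-D
#'   plane or from every channel of a 2-D colour image).
#' @return A numeric matrix, one flattened patch per row
#'   (`height * width * depth * channels` columns).
#' @examples
#' img <- matrix(0.5, 32, 32)
#' extract_patches(img, data.frame(row = 16, col = 16), height = 5, width = 5)[1, 1:3]
#' @export
extract_patches <- function(image, points, height = 15, width = 15, depth = 1) {
  if (height %% 2 == 0 || width %% 2 == 0 || depth %% 2 == 0) {
    stopf("patch height/width/depth must be odd")
  }
  dims <- dim(image)
  if (is.null(dims)) stopf("`image` must be a matrix or array")
  if (length(dims) == 2) dims <- c(dims, 1L)
  img <- array(as.numeric(image), dim = dims)
  points <- as.data.frame(points)
  if (!all(c("row", "col") %in% names(points))) {
    stopf("`points` needs `row` and `col` columns")
  }
  if (any(points$row < 1 | points$row > dims[1] |
            points$col < 1 | points$col > dims[2])) {
    stopf("sample point outside image bounds")
  }
  third <- if (depth > 1) {
    if (!"slice" %in% names(points)) stopf("3-D patches need a `slice` column")
    if (any(points$slice < 1 | points$slice > dims[3])) {
      stopf("sample point outside image bounds")
    }
    points$slice
  } else {
    rep(1L, nrow(points)) # channel axis taken whole below
  }
  hr <- (height - 1L) / 2L
  hc <- (width - 1L) / 2L
  hd <- (depth - 1L) / 2L
  chans <- if (depth > 1) 1L else dims[3]
  out <- matrix(0, nrow(points), height * width * depth * chans)
  for (i in seq_len(nrow(points))) {
    rs <- reflect_index(points$row[i] + (-hr:hr), dims[1])
    cs <- reflect_index(points$col[i] + (-hc:hc), dims[2])
    zs <- if (depth > 1) {
      reflect_index(third[i] + (-hd:hd), dims[3])
    } else {
      seq_len(dims[3])
    }
    patch <- img[rs, cs, zs, drop = FALSE] # height x width x (depth|channels)
    # flatten with the last axis fastest: (row, col, channel/slice) order
    out[i, ] <- as.vector(aperm(patch, c(3, 2, 1)))
  }
  pmin(pmax(out, 0), 1)
}

#' Gabor filter kernel
#'
#' A 2-D Gabor wavelet: Gaussian envelope times a complex sinusoid with wave
#' vector at angle `theta` and wavelength `wavelength` (pixels). The real
#' (cosine) part is mean-subtracted so the filter has no DC response; the
#' envelope is isotropic with `sigma = 0.56 * wavelength`.
#'
#' @param wavelength Sinusoid wavelength in pixels (> 0).
#' @param theta Wave-vector orientation in radians.
#' @param sigma Gaussian envelope standard deviation (default
#'   `0.56 * wavelength`).
#' @param half Kernel half-size in pixels (default three envelope standard
#'   deviations; capped by callers so the kernel fits the image).
#' @return A list with odd-sized matrices `real` and `imag`.
#' @export
gabor_kernel <- function(wavelength, theta, sigma = 0.56 * wavelength,
                         half = max(3L, ceiling(3 * sigma))) {
  if (wavelength <= 0) stopf("`wavelength` must be positive")
  g <- seq(-half, half)
  X <- outer(rep(1, length(g)), g) # column offsets (x)
  Y <- outer(g, rep(1, length(g))) # row offsets (y)
  xr <- X * cos(theta) + Y * sin(theta)
  yr <- -X * sin(theta) + Y * cos(theta)
  env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
  re <- env * cos(2 * pi * xr / wavelength)
  im <- env * sin(2 * pi * xr / wavelength)
  list(real = re - mean(re), imag = im - mean(im))
}

#' Gabor-wavelet features at sampled pixels
#'
#' Filters the image with a bank of 2-D Gabor wavelets — every combination of
#' `wavelengths` and `n_orientations` evenly spaced orientations in `[0, pi)`
#' — and records the response modulus at each sampled pixel, per channel.
#' Features are flattened in (scale, orientation, channel) order, channel
#' fastest. For 3-D cubes the filters are applied to each point's central
#' slice.
#'
#' @inheritParams extract_patches
#' @param wavelengths Numeric vector of sinusoid wavelengths (pixels).
#' @param n_orientations Number of evenly spaced orientations in `[0, pi)`.
#' @return A numeric matrix, one row per point,
#'   `length(wavelengths) * n_orientations * channels` columns.
#' @export
gabor_features <- function(image, points, wavelengths = c(2, 4, 8, 16),
                           n_orientations = 7) {
  if (any(wavelengths <= 0)) stopf("wavelengths must be positive")
  dims <- dim(image)
  if (is.null(dims)) stopf("`image` must be a matrix or array")
  if (length(dims) == 2) dims <- c(dims, 1L)
  img <- array(as.numeric(image), dim = dims)
  points <- as.data.frame(points)
  is_cube <- "slice" %in% names(points) && dims[3] > 1 && !is.null(points$slice)
  thetas <- (seq_len(n_orientations) - 1) * pi / n_orientations
  n_chan <- if (is_cube) 1L else dims[3]
  out <- matrix(0, nrow(points), length(wavelengths) * n_orientations * n_chan)
  pidx <- cbind(points$row, points$col)
  col_of <- function(s, o, ch) ((s - 1) * n_orientations + (o - 1)) * n_chan + ch
  max_half <- (min(dims[1:2]) - 1L) %/% 2L # kernel must fit the image
  for (s in seq_along(wavelengths)) {
    for (o in seq_len(n_orientations)) {
      sg <- 0.56 * wavelengths[s]
      k <- gabor_kernel(wavelengths[s], thetas[o], sigma = sg,
                        half = min(max(3L, ceiling(3 * sg)), max_half))
      for (ch in seq_len(n_chan)) {
        if (is_cube) {
          # response computed per distinct slice actually sampled
          for (sl in unique(points$slice)) {
            sel <- points$slice == sl
            re <- EBImage::filter2(img[, , sl], k$real, boundary = "replicate")
            im <- EBImage::filter2(img[, , sl], k$imag, boundary = "replicate")
            mod <- sqrt(re^2 + im^2)
            out[sel, col_of(s, o, ch)] <- mod[pidx[sel, , drop = FALSE]]
          }
        } else {
          re <- EBImage::filter2(img[, , ch], k$real, boundary = "replicate")
          im <- EBImage::filter2(img[, , ch], k$imag, boundary = "replicate")
          mod <- sqrt(re^2 + im^2)
          out[, col_of(s, o, ch)] <- mod[pidx]
        }
      }
    }
  }
  out
}

#' Sample labeled pixels from a ground-truth mask
#'
#' Uniform without-replacement draws of positive (mask `TRUE`) and negative
#' pixels, deterministic per seed.
#'
#' @param mask Logical matrix.
#' @param n_pos,n_neg Number of positive / negative pixels to draw.
#' @param seed Integer seed.
#' @return A tibble with `row`, `col` and `label` (`1` positive, `0`
#'   negative).
#' @export
sample_pixels <- function(mask, n_pos, n_neg, seed = 1) {
  pos <- which(mask)
  neg <- which(!mask)
  if (length(pos) < n_pos) {
    stopf("mask has only %d positive pixels, %d requested", length(pos), n_pos)
  }
  if (length(neg) < n_neg) {
    stopf("mask has only %d negative pixels, %d requested", length(neg), n_neg)
  }
  sel <- with_local_seed(derive_seed(seed, "pixels"), {
    c(pos[sample.int(length(pos), n_pos)], neg[sample.int(length(neg), n_neg)])
  })
  rc <- arrayInd(sel, dim(mask))
  tibble::tibble(
    row = rc[, 1], col = rc[, 2],
    label = rep(c(1L, 0L), c(n_pos, n_neg))
  )
}
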