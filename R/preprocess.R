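# Preprocessing and augmentation for fundus images and OCT volumes:
# grayscale conversion, bilinear resizing, ordered uniform slice subsampling,
# image/volume-wise intensity normalization, and the SimCLR-style view
# augmentations (center crop, horizontal flip, Gaussian blur, contrast).

#' Preprocessing configuration
#'
#' @param target_size `c(rows, cols)` both modalities are resized to
#'   (default 224 x 224).
#' @param n_keep_slices number of B-scans retained per volume by ordered
#'   uniform subsampling (default 20).
#' @param grayscale_weights RGB channel weights (default ITU-R 601).
#' @param normalize_eps standard-deviation floor in [normalize()].
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(target_size = c(224, 224),
                              n_keep_slices = 20,
                              grayscale_weights = c(0.2989, 0.5870, 0.1140),
                              normalize_eps = 1e-8) {
  stopifnot(all(target_size >= 1), n_keep_slices >= 1,
            length(grayscale_weights) == 3, normalize_eps > 0)
  structure(list(target_size = as.integer(target_size),
                 n_keep_slices = as.integer(n_keep_slices),
                 grayscale_weights = grayscale_weights,
                 normalize_eps = normalize_eps),
            class = "preprocess_config")
}

#' Augmentation policy for self-supervised views
#'
#' Center crop and horizontal flip are applied with probability 0.5 each;
#' Gaussian blur and contrast adjustment with probability 0.3 each. Ranges
#' follow the SimCLR convention and are exposed here.
#'
#' @param p_crop,p_hflip,p_blur,p_contrast application probabilities.
#' @param crop_scale `c(lo, hi)` retained center fraction.
#' @param blur_sigma `c(lo, hi)` blur standard deviation in pixels.
#' @param contrast_factor `c(lo, hi)` contrast multiplier about the mean.
#' @return an `augmentation_policy` list.
#' @export
augmentation_policy <- function(p_crop = 0.5, p_hflip = 0.5,
                                p_blur = 0.3, p_contrast = 0.3,
                                crop_scale = c(0.8, 1.0),
                                blur_sigma = c(0.1, 2.0),
                                contrast_factor = c(0.6, 1.4)) {
  probs <- c(p_crop, p_hflip, p_blur, p_contrast)
  stopifnot(all(probs >= 0 & probs <= 1),
            crop_scale[1] <= crop_scale[2], crop_scale[1] > 0,
            blur_sigma[1] <= blur_sigma[2],
            contrast_factor[1] <= contrast_factor[2])
  structure(list(p_crop = p_crop, p_hflip = p_hflip, p_blur = p_blur,
                 p_contrast = p_contrast, crop_scale = crop_scale,
                 blur_sigma = blur_sigma, contrast_factor = contrast_factor),
            class = "augmentation_policy")
}

#' Convert an image to grayscale
#'
#' Weighted channel sum for 3-channel input; grayscale input is returned
#' unchanged (idempotent).
#'
#' @param image 2D matrix or rows x cols x 3 array.
#' @param weights channel weights summing to 1 (default ITU-R 601).
#' @return 2D matrix.
#' @export
to_grayscale <- function(image, weights = c(0.2989, 0.5870, 0.1140)) {
  if (is.matrix(image)) return(image)
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) {
    stop("to_grayscale: input must have 1 or 3 channels")
  }
  image[, , 1] * weights[1] + image[, , 2] * weights[2] + image[, , 3] * weights[3]
}

# interpolation weight matrix mapping n_in samples onto n_out, align-corners
# convention: output pixel i sits at source coordinate (i-1)(n_in-1)/(n_out-1)
bilinear_weights <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  src <- if (n_out == 1L) (n_in - 1) / 2 else (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  lo <- pmin(floor(src), n_in - 2)
  lo <- pmax(lo, 0)
  frac <- src - lo
  if (n_in == 1L) { W[, 1] <- 1; return(W) }
  for (i in seq_len(n_out)) {
    W[i, lo[i] + 1] <- W[i, lo[i] + 1] + (1 - frac[i])
    W[i, lo[i] + 2] <- W[i, lo[i] + 2] + frac[i]
  }
  W
}

#' Bilinear resize of a 2D grid
#'
#' Separable bilinear interpolation with the align-corners pixel mapping, so
#' an input already at the target size is returned unchanged and endpoints
#' map exactly.
#'
#' @param image 2D matrix.
#' @param target_size `c(rows, cols)`.
#' @return resized matrix.
#' @export
resize_image <- function(image, target_size) {
  stopifnot(is.matrix(image), nrow(image) >= 1, ncol(image) >= 1)
  if (any(target_size < 1)) stop("resize_image: target size must be positive")
  if (nrow(image) == target_size[1] && ncol(image) == target_size[2]) return(image)
  Wr <- bilinear_weights(nrow(image), target_size[1])
  Wc <- bilinear_weights(ncol(image), target_size[2])
  Wr %*% image %*% t(Wc)
}

#' Ordered uniform slice subsampling indices
#'
#' `floor(linspace(0, n_slices - 1, n_keep) + 0.5) + 1`: a non-decreasing
#' index vector of length `n_keep` (1-based) that always includes the first
#' and last slice. When `n_slices < n_keep`, indices repeat.
#'
#' @param n_slices number of available slices (>= 1).
#' @param n_keep number of slices to keep (>= 1, default 20).
#' @return integer vector of length `n_keep`.
#' @export
subsample_slices <- function(n_slices, n_keep = 20) {
  stopifnot(n_slices >= 1, n_keep >= 1)
  if (n_keep == 1L) return(as.integer(ceiling(n_slices / 2)))
  pos <- (seq_len(n_keep) - 1) * (n_slices - 1) / (n_keep - 1)
  as.integer(floor(pos + 0.5)) + 1L
}

#' Image/volume-wise intensity normalization
#'
#' `(x - mean(x)) / max(sd(x), eps)` over all elements; a constant input
#' maps to all zeros.
#'
#' @param x numeric array of any dimension.
#' @param eps standard-deviation floor.
#' @return array of the same shape with mean 0 and sd 1 (non-constant input).
#' @export
normalize <- function(x, eps = 1e-8) {
  stopifnot(all(is.finite(x)))
  (x - mean(x)) / max(stats::sd(as.vector(x)), eps)
}

# Gaussian blur via separable convolution with reflected boundaries
gauss_blur <- function(image, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_1d <- function(M, kern) {
    n <- nrow(M)
    idx <- seq_len(n)
    out <- matrix(0, n, ncol(M))
    for (j in seq_along(kern)) {
      off <- j - r - 1L
      src <- idx + off
      src[src < 1] <- 2 - src[src < 1]          # reflect
      src[src > n] <- 2 * n - src[src > n]
      out <- out + kern[j] * M[src, , drop = FALSE]
    }
    out
  }
  t(blur_1d(t(blur_1d(image, k)), k))
}

apply_augment_2d <- function(image, draws, policy, target_size) {
  if (draws$do_hflip) image <- image[, rev(seq_len(ncol(image))), drop = FALSE]
  if (draws$do_crop) {
    cr <- pmax(1L, round(draws$crop_s * c(nrow(image), ncol(image))))
    r0 <- floor((nrow(image) - cr[1]) / 2) + 1L
    c0 <- floor((ncol(image) - cr[2]) / 2) + 1L
    image <- image[r0:(r0 + cr[1] - 1L), c0:(c0 + cr[2] - 1L), drop = FALSE]
    image <- resize_image(image, target_size)
  }
  if (draws$do_blur) image <- gauss_blur(image, draws$sigma)
  if (draws$do_contrast) image <- mean(image) + draws$factor * (image - mean(image))
  image
}

#' Apply the stochastic view augmentation
#'
#' Draws each transform independently with its policy probability and applies
#' center crop (resized back), horizontal flip, Gaussian blur and contrast
#' adjustment. For a 3D volume the same 2D transform parameters are applied
#' to every slice, so the through-plane structure is kept coherent.
#'
#' @param sample 2D matrix or slices x rows x cols array.
#' @param policy an [augmentation_policy()].
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the augmented view is bit-reproducible.
#' @return array of the same shape as the input.
#' @export
augment <- function(sample, policy = augmentation_policy(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draws <- list(
    do_crop = stats::runif(1) < policy$p_crop,
    crop_s = stats::runif(1, policy$crop_scale[1], policy$crop_scale[2]),
    do_hflip = stats::runif(1) < policy$p_hflip,
    do_blur = stats::runif(1) < policy$p_blur,
    sigma = stats::runif(1, policy$blur_sigma[1], policy$blur_sigma[2]),
    do_contrast = stats::runif(1) < policy$p_contrast,
    factor = stats::runif(1, policy$contrast_factor[1], policy$contrast_factor[2])
  )
  if (is.matrix(sample)) {
    return(apply_augment_2d(sample, draws, policy, dim(sample)))
  }
  d <- dim(sample)
  stopifnot(length(d) == 3L)
  out <- array(0, d)
  for (s in seq_len(d[1])) {
    out[s, , ] <- apply_augment_2d(sample[s, , ], draws, policy, d[2:3])
  }
  out
}

#' Preprocess a fundus image: grayscale, resize, normalize
#'
#' @param image 2D matrix or RGB array.
#' @param config a [preprocess_config()].
#' @return target-size matrix with mean 0, sd 1.
#' @export
preprocess_fundus <- function(image, config = preprocess_config()) {
  g <- to_grayscale(image, config$grayscale_weights)
  normalize(resize_image(g, config$target_size), config$normalize_eps)
}

#' Preprocess an OCT volume: subsample slices, resize, normalize
#'
#' @param vol slices x rows x cols array.
#' @param config a [preprocess_config()].
#' @return `n_keep_slices` x target rows x target cols array, normalized
#'   volume-wise.
#' @export
preprocess_volume <- function(vol, config = preprocess_config()) {
  d <- dim(vol)
  stopifnot(length(d) == 3L)
  idx <- subsample_slices(d[1], config$n_keep_slices)
  out <- array(0, c(length(idx), config$target_size))
  for (i in seq_along(idx)) {
    out[i, , ] <- resize_image(vol[idx[i], , ], config$target_size)
  }
  normalize(out, config$normalize_eps)
}

#' Preprocess every scan of a cohort into flat feature matrices
#'
#' Applies [preprocess_fundus()] and [preprocess_volume()] to each record and
#' flattens the results row-wise, the input form the encoders consume.
#'
#' @param cohort a `retina_cohort` (or list of `paired_scan`).
#' @param config a [preprocess_config()].
#' @return list with `X` (n x fundus features), `Y` (n x volume features) and
#'   the `manifest` data frame aligned to the rows.
#' @export
preprocess_cohort <- function(cohort, config = preprocess_config()) {
  n <- length(cohort)
  px <- prod(config$target_size)
  X <- matrix(0, n, px)
  Y <- matrix(0, n, config$n_keep_slices * px)
  for (i in seq_len(n)) {
    X[i, ] <- as.numeric(preprocess_fundus(cohort[[i]]$fundus, config))
    Y[i, ] <- as.numeric(preprocess_volume(cohort[[i]]$oct, config))
  }
  list(X = X, Y = Y, manifest = cohort_manifest(cohort))
}
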