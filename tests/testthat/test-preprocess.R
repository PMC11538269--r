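# Preprocessing stack: grayscale weights, bilinear resize against a
# brute-force oracle, ordered slice subsampling, normalization, and the
# seeded view augmentations.

test_that("grayscale conversion is idempotent and uses the channel weights", {
  g <- matrix(runif(12), 3, 4)
  expect_identical(to_grayscale(g), g)
  white <- array(1, c(2, 2, 3))
  # ITU-R 601 weights sum to 0.9999 at printed precision
  expect_equal(to_grayscale(white), matrix(1, 2, 2), tolerance = 1e-3)
  red <- array(0, c(1, 1, 3)); red[1, 1, 1] <- 1
  expect_equal(as.numeric(to_grayscale(red)), 0.2989)
  expect_error(to_grayscale(array(1, c(2, 2, 2))), "channels")
})

# independent per-pixel bilinear oracle with the align-corners mapping
brute_bilinear <- function(img, out) {
  res <- matrix(0, out[1], out[2])
  src_pos <- function(i, n_out, n_in) {
    if (n_out == 1) (n_in - 1) / 2 else (i - 1) * (n_in - 1) / (n_out - 1)
  }
  for (i in seq_len(out[1])) for (j in seq_len(out[2])) {
    sy <- src_pos(i, out[1], nrow(img)); sx <- src_pos(j, out[2], ncol(img))
    y0 <- min(floor(sy), nrow(img) - 2); x0 <- min(floor(sx), ncol(img) - 2)
    y0 <- max(y0, 0); x0 <- max(x0, 0)
    fy <- sy - y0; fx <- sx - x0
    res[i, j] <- (1 - fy) * (1 - fx) * img[y0 + 1, x0 + 1] +
      (1 - fy) * fx * img[y0 + 1, x0 + 2] +
      fy * (1 - fx) * img[y0 + 2, x0 + 1] +
      fy * fx * img[y0 + 2, x0 + 2]
  }
  res
}

test_that("bilinear resize matches the brute-force oracle and its edge cases", {
  img <- matrix(runif(224 * 224), 224, 224)
  expect_identical(resize_image(img, c(224, 224)), img)
  expect_equal(resize_image(matrix(3.7, 10, 12), c(5, 7)),
               matrix(3.7, 5, 7), tolerance = 1e-12)
  checker <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expect_equal(resize_image(checker, c(4, 4)), brute_bilinear(checker, c(4, 4)),
               tolerance = 1e-12)
  set.seed(3)
  r <- matrix(rnorm(37 * 23), 37, 23)
  expect_equal(resize_image(r, c(17, 31)), brute_bilinear(r, c(17, 31)),
               tolerance = 1e-12)
  # interpolation cannot expand the intensity range
  out <- resize_image(r, c(17, 31))
  expect_gte(min(out), min(r) - 1e-12)
  expect_lte(max(out), max(r) + 1e-12)
  expect_error(resize_image(r, c(0, 10)), "positive")
})

test_that("slice subsampling is ordered, endpoint-inclusive, and matches linspace", {
  expect_equal(subsample_slices(20, 20), 1:20)
  expect_equal(subsample_slices(39, 20), seq(1, 39, by = 2))
  s <- subsample_slices(256, 20)
  expect_length(s, 20)
  expect_equal(s[1], 1)
  expect_equal(s[20], 256)
  for (n in c(21, 64, 100, 199, 256)) {
    s <- subsample_slices(n, 20)
    expect_length(s, 20)
    expect_true(all(diff(s) >= 0))
    expect_equal(s[c(1, 20)], c(1, n))
  }
  # fewer slices than requested: repeated indices by the same formula
  s <- subsample_slices(5, 9)
  expect_length(s, 9)
  expect_true(all(diff(s) >= 0))
  expect_equal(range(s), c(1, 5))
})

test_that("normalization yields mean 0 / sd 1 and is affine-invariant", {
  expect_equal(normalize(matrix(7, 4, 4)), matrix(0, 4, 4))
  set.seed(4)
  x <- array(rnorm(4 * 5 * 6, 3, 2), c(4, 5, 6))
  nx <- normalize(x)
  expect_lt(abs(mean(nx)), 1e-6)
  expect_lt(abs(sd(as.vector(nx)) - 1), 1e-4)
  expect_equal(normalize(2.5 * x + 11), nx, tolerance = 1e-10)
})

test_that("augmentation honors probabilities, involution and slice coherence", {
  img <- matrix(runif(32 * 32), 32, 32)
  none <- augmentation_policy(p_crop = 0, p_hflip = 0, p_blur = 0, p_contrast = 0)
  expect_identical(augment(img, none, seed = 1), img)
  flip_only <- augmentation_policy(p_crop = 0, p_hflip = 1, p_blur = 0, p_contrast = 0)
  flipped <- augment(img, flip_only, seed = 1)
  expect_identical(flipped, img[, 32:1])
  expect_identical(augment(flipped, flip_only, seed = 2), img)
  crop_only <- augmentation_policy(p_crop = 1, p_hflip = 0, p_blur = 0, p_contrast = 0)
  a1 <- augment(img, crop_only, seed = 5)
  a2 <- augment(img, crop_only, seed = 5)
  expect_identical(a1, a2)
  expect_equal(dim(a1), c(32, 32))
  expect_false(identical(a1, img))
  # volumes: the same transform parameters apply to every slice
  vol <- array(runif(4 * 16 * 16), c(4, 16, 16))
  fv <- augment(vol, flip_only, seed = 1)
  for (s in 1:4) expect_equal(fv[s, , ], vol[s, , 16:1])
  # two views under different seeds differ when any probability is positive
  pol <- augmentation_policy()
  diffs <- vapply(1:60, function(i) {
    !identical(augment(img, pol, seed = 2 * i), augment(img, pol, seed = 2 * i + 1))
  }, logical(1))
  expect_gt(mean(diffs), 0.5)
})

test_that("the default pipeline yields 20 x 224 x 224 normalized volumes", {
  set.seed(6)
  vol <- array(runif(31 * 60 * 64), c(31, 60, 64))
  out <- preprocess_volume(vol, preprocess_config())
  expect_equal(dim(out), c(20, 224, 224))
  expect_lt(abs(mean(out)), 1e-6)
  expect_lt(abs(sd(as.vector(out)) - 1), 1e-4)
  img <- array(runif(50 * 40 * 3), c(50, 40, 3))
  fo <- preprocess_fundus(img, preprocess_config())
  expect_equal(dim(fo), c(224, 224))
})
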