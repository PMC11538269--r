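# Synthetic paired-cohort generator: determinism, label rules, and the
# constructed mutual information between the two modalities.

test_that("cohort generation is deterministic and respects the config", {
  cfg <- tiny_config(n_patients = 6, visits = 1)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_length(c1, 6)
  expect_identical(lapply(c1, function(s) s$fundus),
                   lapply(c2, function(s) s$fundus))
  expect_identical(lapply(c1, function(s) s$oct),
                   lapply(c2, function(s) s$oct))
  expect_identical(lapply(c1, function(s) s$labels),
                   lapply(c2, function(s) s$labels))
  for (s in c1) {
    expect_true(all(dim(s$fundus) == cfg$fundus_size))
    d <- dim(s$oct)
    expect_gte(d[1], cfg$oct_slice_range[1])
    expect_lte(d[1], cfg$oct_slice_range[2])
    expect_true(all(s$fundus >= 0) && all(s$oct >= 0))
  }
  expect_error(generate_cohort(synth_config(n_patients = 0, seed = 1)),
               "invalid config")
})

test_that("multi-visit cohorts produce one record per (patient, visit)", {
  cfg <- tiny_config(n_patients = 5, visits = c(2, 3))
  ch <- generate_cohort(cfg)
  man <- cohort_manifest(ch)
  per <- table(man$patient_id)
  expect_length(per, 5)
  expect_true(all(per >= 2 & per <= 3))
  expect_true(all(tapply(man$visit, man$patient_id,
                         function(v) identical(sort(v), seq_along(v)))))
})

test_that("treatment-need categories follow the injection-count thresholds", {
  expect_equal(categorize_treatment_need(16), "high")
  expect_equal(categorize_treatment_need(5), "low")
  expect_equal(categorize_treatment_need(10), "excluded")
  expect_equal(categorize_treatment_need(c(0, 5, 6, 15, 16, 30)),
               c("low", "low", "excluded", "excluded", "high", "high"))
  expect_error(categorize_treatment_need(-1), "non-negative")
  # every generated record is self-consistent
  man <- cohort_manifest(tiny_cohort())
  expect_equal(man$treatment_need, categorize_treatment_need(man$n_inj))
  expect_true(all(man$y_cst > 0))
})

test_that("rendered central-band thickness equals y_cst within one voxel (noiseless)", {
  cfg <- tiny_config(n_patients = 1, noise_sd = 0)
  set.seed(7)
  for (i in 1:12) {
    z <- rnorm(8)
    labels <- list(fluid = 0, y_cst = NULL)
    t_true <- retinapair:::cst_thickness(z[1], cfg$oct_rows)
    vol <- render_oct(z, labels, cfg, n_slices = 21, noise_sd = 0)
    expect_lte(abs(measure_cst(vol) - t_true), 1)
  }
})

test_that("the fluid blob strictly darkens the carved region at equal latents", {
  cfg <- tiny_config(noise_sd = 0)
  set.seed(8)
  z <- rnorm(8)
  v0 <- render_oct(z, list(fluid = 0), cfg, n_slices = 22, noise_sd = 0)
  v1 <- render_oct(z, list(fluid = 1), cfg, n_slices = 22, noise_sd = 0)
  blob <- which(v1 != v0)
  expect_gt(length(blob), 0)
  expect_lt(mean(v1[blob]), mean(v0[blob]))
  # the measurement column is untouched by the blob
  expect_equal(measure_cst(v1), measure_cst(v0))
})

test_that("a latent amplitude change concentrates pixel differences in that blob", {
  cfg <- tiny_config(noise_sd = 0)
  z1 <- rep(0, 8)
  z2 <- z1; z2[3] <- 1.5
  f1 <- render_fundus(z1, cfg, noise_sd = 0)
  f2 <- render_fundus(z2, cfg, noise_sd = 0)
  d <- abs(f2 - f1)
  # mask: disc of 3 blob sigmas around blob 3's nominal center
  nr <- cfg$fundus_size[1]; nc <- cfg$fundus_size[2]
  ys <- seq(-1, 1, length.out = nr); xs <- seq(-1, 1, length.out = nc)
  theta <- 2 * pi * 2 / 8
  cy <- 0.55 * sin(theta); cx <- 0.55 * cos(theta)
  mask <- outer((ys - cy)^2, (xs - cx)^2, "+") <= (3 * 0.18)^2
  expect_gte(sum(d[mask]) / sum(d), 0.9)
})

test_that("zero latents and zero noise reproduce the fixed baseline template", {
  cfg <- tiny_config(noise_sd = 0)
  f1 <- render_fundus(rep(0, 8), cfg, noise_sd = 0)
  f2 <- render_fundus(rep(0, 8), cfg, noise_sd = 0)
  expect_identical(f1, f2)
  expect_true(all(dim(f1) == c(32, 32)))
  # blobs sit at their amplitude intercepts: brighter than the background
  expect_gt(max(f1), 1.3)
})

test_that("both noiseless modalities support a linear readout of the latents (R2 > 0.9)", {
  cfg <- synth_config(n_patients = 1, fundus_size = c(32, 32),
                      oct_slice_range = c(22, 22), oct_rows = 64, oct_cols = 48,
                      noise_sd = 0, seed = 1)
  n <- 480; ntr <- 350
  set.seed(100)
  Z <- matrix(rnorm(n * 8), n, 8)
  Xf <- matrix(0, n, 144)
  Xo <- matrix(0, n, 5 * 64)
  slice_sel <- round(seq(1, 22, length.out = 5))
  for (i in seq_len(n)) {
    f <- render_fundus(Z[i, ], cfg, noise_sd = 0)
    Xf[i, ] <- as.numeric(resize_image(f, c(12, 12)))
    v <- render_oct(Z[i, ], list(fluid = 0), cfg, n_slices = 22, noise_sd = 0)
    Xo[i, ] <- as.numeric(sapply(slice_sel, function(s) rowMeans(v[s, , ])))
  }
  oos_r2 <- function(X, y) {
    # rank-truncated least squares: the noiseless feature matrices are
    # rank-deficient, and the smallest numerical directions carry only
    # thickness-quantization rounding, so they are cut at a relative 1e-4
    A <- cbind(1, X[1:ntr, ])
    sv <- svd(A)
    keep <- sv$d > max(sv$d) * 1e-4
    coef <- sv$v[, keep] %*% ((t(sv$u[, keep]) %*% y[1:ntr]) / sv$d[keep])
    p <- cbind(1, X[(ntr + 1):n, ]) %*% coef
    1 - sum((y[(ntr + 1):n] - p)^2) / sum((y[(ntr + 1):n] - mean(y[(ntr + 1):n]))^2)
  }
  for (k in 1:8) {
    expect_gt(oos_r2(Xf, Z[, k]), 0.9, label = sprintf("fundus readout z%d", k))
    expect_gt(oos_r2(Xo, Z[, k]), 0.9, label = sprintf("oct readout z%d", k))
  }
})

test_that("cohorts round-trip through disk (PNG + NIfTI + manifest)", {
  dir <- tempfile("cohort")
  ch <- generate_cohort(tiny_config(n_patients = 3))
  path <- write_cohort(ch, dir)
  expect_true(file.exists(path))
  back <- read_cohort(dir)
  expect_length(back, 3)
  # NIfTI volumes are lossless
  expect_equal(back[[2]]$oct, ch[[2]]$oct, tolerance = 1e-6)
  # PNG fundus is 8-bit quantized on a fixed scale of 6
  expect_lt(max(abs(back[[1]]$fundus - pmin(ch[[1]]$fundus, 6))), 6 / 255 + 1e-6)
  expect_equal(cohort_manifest(back)$y_cst, cohort_manifest(ch)$y_cst)
})
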