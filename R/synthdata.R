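# Synthetic paired fundus/OCT cohort generator.
#
# Each (patient, eye, visit) gets an 8-dimensional latent factor vector z.
# The 2D fundus image and the 3D OCT volume are both rendered from the same
# z, so the two modalities share mutual information by construction and
# cross-modal retrieval is learnable. Clinical-style labels (visual acuity,
# central band thickness, fluid presence, disease class, injection counts,
# conversion) are simple documented functions of z. Rendering is a stand-in
# for real anatomy, not a retina simulation.

#' Synthetic cohort configuration
#'
#' @param n_patients number of patients (>= 1).
#' @param visits_per_patient visits per patient; a single count or a
#'   `c(lo, hi)` range sampled uniformly per patient.
#' @param fundus_size `c(rows, cols)` of the native fundus image.
#' @param oct_slice_range `c(lo, hi)` range of B-scan counts per volume,
#'   sampled uniformly per scan; default mirrors clinical protocol spread.
#' @param oct_rows,oct_cols in-plane size of each B-scan.
#' @param vendors named numeric vector of vendor intensity offsets, assigned
#'   round-robin over patients.
#' @param noise_sd standard deviation of additive intensity noise (images are
#'   clamped at zero afterwards). The default puts per-pixel lesion contrast
#'   well below the noise floor, as in speckle-dominated scans, so that only
#'   spatially integrating readouts recover the latent factors.
#' @param latent_dim length of the shared latent vector z.
#' @param drift_sd per-visit latent drift standard deviation.
#' @param seed mandatory integer seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_patients = 100,
                         visits_per_patient = 1,
                         fundus_size = c(64, 64),
                         oct_slice_range = c(21, 256),
                         oct_rows = 64, oct_cols = 64,
                         vendors = c(heidelberg = 0, topcon = 0.12, zeiss = -0.08),
                         noise_sd = 0.6,
                         latent_dim = 8,
                         drift_sd = 0.1,
                         seed = NULL) {
  if (is.null(seed)) stop("synth_config: a seed is mandatory")
  if (length(n_patients) != 1L || !is.finite(n_patients) || n_patients < 1) {
    stop("invalid config: n_patients must be a positive count")
  }
  if (length(visits_per_patient) == 1L) {
    visits_per_patient <- c(visits_per_patient, visits_per_patient)
  }
  stopifnot(all(fundus_size > 0), oct_rows > 0, oct_cols > 0,
            oct_slice_range[1] >= 1, oct_slice_range[1] <= oct_slice_range[2],
            noise_sd >= 0, latent_dim >= 1, length(vendors) >= 1)
  structure(list(
    n_patients = as.integer(n_patients),
    visits_per_patient = as.integer(visits_per_patient),
    fundus_size = as.integer(fundus_size),
    oct_slice_range = as.integer(oct_slice_range),
    oct_rows = as.integer(oct_rows), oct_cols = as.integer(oct_cols),
    vendors = vendors,
    noise_sd = noise_sd,
    latent_dim = as.integer(latent_dim),
    drift_sd = drift_sd,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# fixed, documented rendering and label constants
.render <- list(
  # fundus: K = latent_dim Gaussian blobs on a circle, amplitude and (mild)
  # radial position both linear in the blob's own latent component
  blob_radius = 0.55, blob_sigma = 0.18,
  amp_base = 0.7, amp_coef = 0.35, pos_coef = 0.03,
  bg_base = 1.0, bg_amp = 0.3, bg_sigma = 0.5,
  # oct: four horizontal bands. The central band has constant amplitude and
  # carries z[1] through its thickness alone; the three thin bands have fixed
  # positions and carry the remaining components through slice-wise cosine
  # amplitude modulations, so noiseless voxel intensities are linear in z
  # (up to thickness quantization).
  oct_bg = 0.25,
  top_pos = 0.10, top_thick = 0.06,
  inner_pos = 0.22, inner_thick = 0.06,
  band_amp = 0.8, band_coef = 0.2,
  mid_center = 0.55, mid_amp = 0.9,
  cst_base = 0.18, cst_coef = 0.045, cst_min = 3,
  bot_pos = 0.82, bot_thick = 0.08,
  band_col_span = c(0, 1),
  fluid_dim_factor = 0.15,
  cst_threshold = 0.45,
  cst_window = c(0.32, 0.76)
)

.labels <- list(
  bcva_intercept = 60,
  bcva_w = c(3, 0, 2.5, 2, 0, 1.5, 0, 0),
  bcva_noise_sd = 1.2,
  fluid_w = c(0, 1.8, 0, 0, 0, 0, 0, 0),
  conv_intercept = -1,
  conv_w = c(0, 0, 0, 0, 0.9, 0.6, 0, 0),
  ninj_a = 1.9, ninj_b = 0.45, ninj_max = 30,
  disease_classes = c("healthy", "DME", "iAMD", "RVO", "GA"),
  disease_W = matrix(c(
    -0.5, -0.5,  0.0,  0.0, 0, 0,  0.0,  0.0,
     0.0,  1.2,  0.0,  0.0, 0, 0,  0.4,  0.0,
     1.0,  0.0,  0.6,  0.0, 0, 0,  0.0,  0.0,
     0.0,  0.0,  0.0,  1.1, 0, 0,  0.0,  0.5,
     0.0,  0.0, -0.8,  0.0, 0, 0,  0.9,  0.0), nrow = 5, byrow = TRUE)
)

#' Categorize treatment need from a 2-year injection count
#'
#' `high` for `n_inj >= 16`, `low` for `n_inj <= 5`, `excluded` in between.
#'
#' @param n_inj non-negative integer vector of injection counts.
#' @return character vector in `{high, low, excluded}`.
#' @export
categorize_treatment_need <- function(n_inj) {
  if (any(n_inj < 0)) stop("n_inj must be non-negative")
  ifelse(n_inj >= 16, "high", ifelse(n_inj <= 5, "low", "excluded"))
}

# central-band thickness in voxels as a function of z[1]
cst_thickness <- function(z1, rows) {
  t_max <- floor(0.38 * rows + 0.5)
  pmin(pmax(floor(.render$cst_base * rows + .render$cst_coef * rows * z1 + 0.5),
            .render$cst_min), t_max)
}

# draw all stochastic labels for one latent vector (uses the current RNG)
draw_labels <- function(z, oct_rows) {
  lb <- .labels
  y_bcva <- lb$bcva_intercept + sum(lb$bcva_w * z) +
    stats::rnorm(1, 0, lb$bcva_noise_sd)
  fluid <- stats::rbinom(1, 1, stats::plogis(sum(lb$fluid_w * z)))
  logits <- as.numeric(lb$disease_W %*% z)
  disease <- lb$disease_classes[which.max(logits)]
  n_inj <- min(stats::rpois(1, exp(lb$ninj_a + lb$ninj_b * z[1])), lb$ninj_max)
  conversion <- stats::rbinom(1, 1, stats::plogis(lb$conv_intercept + sum(lb$conv_w * z)))
  list(y_bcva = y_bcva,
       y_cst = cst_thickness(z[1], oct_rows),
       fluid = fluid,
       disease = disease,
       n_inj = n_inj,
       treatment_need = categorize_treatment_need(n_inj),
       conversion = conversion)
}

#' Render a synthetic fundus image from latent factors
#'
#' A smooth radial background plus one Gaussian blob per latent component.
#' Blob k's amplitude is `0.7 + 0.35 z_k` (floored at 0) and its radial
#' position shifts by a factor `1 + 0.03 z_k`, so pixel intensities are
#' (near-)linear in z. Vendor offset and clamped Gaussian noise are added.
#' Noise uses the caller's RNG state.
#'
#' @param z latent vector.
#' @param config a [synth_config()].
#' @param vendor_offset additive vendor intensity offset.
#' @param noise_sd noise level; defaults to the config value.
#' @return rows x cols non-negative matrix.
#' @export
render_fundus <- function(z, config, vendor_offset = 0,
                          noise_sd = config$noise_sd) {
  stopifnot(all(is.finite(z)))
  p <- .render
  nr <- config$fundus_size[1]; nc <- config$fundus_size[2]
  ys <- seq(-1, 1, length.out = nr)
  xs <- seq(-1, 1, length.out = nc)
  r2 <- outer(ys^2, xs^2, "+")
  img <- p$bg_base + p$bg_amp * exp(-r2 / (2 * p$bg_sigma^2))
  K <- config$latent_dim
  for (k in seq_len(K)) {
    theta <- 2 * pi * (k - 1) / K
    rad <- p$blob_radius * (1 + p$pos_coef * z[k])
    cy <- rad * sin(theta); cx <- rad * cos(theta)
    amp <- max(0, p$amp_base + p$amp_coef * z[k])
    d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
    img <- img + amp * exp(-d2 / (2 * p$blob_sigma^2))
  }
  img <- img + vendor_offset
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
  pmax(img, 0)
}

# slice-wise cosine modulations encoding the remaining latent components
band_amplitudes <- function(z, n_slices) {
  u <- if (n_slices > 1) (seq_len(n_slices) - 1) / (n_slices - 1) else 0.5
  p <- .render
  list(
    top = p$band_amp + p$band_coef *
      (cos(pi * u) * z[3] + cos(2 * pi * u) * z[4] + cos(3 * pi * u) * z[7]),
    inner = p$band_amp + p$band_coef *
      (cos(pi * u) * z[2] + cos(2 * pi * u) * z[5]),
    mid = rep(p$mid_amp, length(u)),
    bot = p$band_amp + p$band_coef * (cos(pi * u) * z[6] + cos(2 * pi * u) * z[8])
  )
}

#' Render a synthetic OCT volume from latent factors
#'
#' Each B-scan holds four bright horizontal bands over a dark background.
#' The central band has constant amplitude and its thickness (in voxels) is
#' `clip(round(0.18 R + 0.045 R z_1))`, equal to the record's `y_cst`; the
#' three thin fixed-position bands are modulated across slices by
#' low-frequency cosines of the remaining latent components, so a linear
#' readout of the voxels recovers z. If `labels$fluid == 1`, a
#' dark ellipsoid is carved into the central slices (off the center column,
#' where thickness is measured). Vendor offset and clamped noise are added.
#'
#' @param z latent vector.
#' @param labels label list for the scan (uses `fluid`).
#' @param config a [synth_config()].
#' @param n_slices number of B-scans; default drawn by the caller.
#' @param vendor_offset additive vendor intensity offset.
#' @param noise_sd noise level; defaults to the config value.
#' @return slices x rows x cols non-negative array.
#' @export
render_oct <- function(z, labels, config, n_slices,
                       vendor_offset = 0, noise_sd = config$noise_sd) {
  stopifnot(all(is.finite(z)), n_slices >= 1)
  p <- .render
  R <- config$oct_rows; C <- config$oct_cols; S <- as.integer(n_slices)
  amps <- band_amplitudes(z, S)
  t_vox <- cst_thickness(z[1], R)
  band_rows <- function(pos, thick) {
    seq.int(max(1L, round(pos * R)),
            min(R, round(pos * R) + max(1L, round(thick * R)) - 1L))
  }
  top_rows <- band_rows(p$top_pos, p$top_thick)
  inner_rows <- band_rows(p$inner_pos, p$inner_thick)
  bot_rows <- band_rows(p$bot_pos, p$bot_thick)
  mid_start <- max(1L, round(p$mid_center * R - t_vox / 2))
  mid_rows <- seq.int(mid_start, min(R, mid_start + t_vox - 1L))
  # band column extent is configurable (full width by default); narrowing it
  # leaves background flanks that carry no latent information
  band_cols <- seq.int(max(1L, round(p$band_col_span[1] * C)),
                       min(C, round(p$band_col_span[2] * C)))
  vol <- array(p$oct_bg, dim = c(S, R, C))
  for (s in seq_len(S)) {
    vol[s, top_rows, band_cols] <- amps$top[s]
    vol[s, inner_rows, band_cols] <- amps$inner[s]
    vol[s, mid_rows, band_cols] <- amps$mid[s]
    vol[s, bot_rows, band_cols] <- amps$bot[s]
  }
  if (isTRUE(labels$fluid == 1)) {
    sc <- (seq_len(S) - 0.5 * S - 0.5) / (0.2 * S)
    rc <- (seq_len(R) - p$mid_center * R) / (0.1 * R)
    cc <- (seq_len(C) - 0.3 * C) / (0.12 * C)
    mask <- outer(outer(sc^2, rc^2, "+"), cc^2, "+") <= 1
    vol[mask] <- vol[mask] * p$fluid_dim_factor
  }
  vol <- vol + vendor_offset
  if (noise_sd > 0) vol <- vol + array(stats::rnorm(length(vol), 0, noise_sd), dim(vol))
  pmax(vol, 0)
}

#' Measure central-band thickness on a rendered volume
#'
#' Counts supra-threshold voxels in the center column of the middle B-scan,
#' restricted to the central depth window (rows 0.32R-0.76R) that contains
#' the central band at any admissible thickness but none of the thin bands.
#'
#' @param vol slices x rows x cols array.
#' @param threshold intensity threshold (default 0.45, between the background
#'   and the central-band amplitude).
#' @return integer voxel count.
#' @export
measure_cst <- function(vol, threshold = .render$cst_threshold) {
  d <- dim(vol)
  s <- ceiling(d[1] / 2); col <- ceiling(d[3] / 2)
  w <- .render$cst_window
  rows <- seq.int(max(1L, round(w[1] * d[2])), min(d[2], round(w[2] * d[2])))
  sum(vol[s, rows, col] > threshold)
}

#' Generate a synthetic paired cohort
#'
#' Deterministic under the config seed: one `paired_scan` per (patient,
#' visit), each holding a fundus image and an OCT volume rendered from the
#' same latent factors, plus all downstream labels. Vendors are assigned
#' round-robin over patients; eyes alternate OD/OS.
#'
#' @param config a [synth_config()].
#' @return a list of `paired_scan` records with attribute `config`, class
#'   `retina_cohort`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  vendor_names <- names(config$vendors)
  scans <- list()
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%04d", i)
    eye <- if (i %% 2 == 1) "OD" else "OS"
    vendor <- vendor_names[(i - 1) %% length(config$vendors) + 1]
    voff <- config$vendors[[vendor]]
    z <- stats::rnorm(config$latent_dim)
    nv <- if (config$visits_per_patient[1] == config$visits_per_patient[2]) {
      config$visits_per_patient[1]
    } else {
      sample(config$visits_per_patient[1]:config$visits_per_patient[2], 1)
    }
    for (v in seq_len(nv)) {
      if (v > 1) z <- z + stats::rnorm(config$latent_dim, 0, config$drift_sd)
      labels <- draw_labels(z, config$oct_rows)
      n_slices <- sample(config$oct_slice_range[1]:config$oct_slice_range[2], 1)
      fundus <- render_fundus(z, config, voff)
      oct <- render_oct(z, labels, config, n_slices, voff)
      scans[[length(scans) + 1L]] <- structure(list(
        patient_id = pid, eye = eye, visit_index = v, vendor = vendor,
        z = z, fundus = fundus, oct = oct, labels = labels
      ), class = "paired_scan")
    }
  }
  structure(scans, config = config, class = "retina_cohort")
}

#' Extract the manifest data frame of a cohort
#'
#' One row per scan with ids, vendor and all downstream labels (no pixel
#' data); the in-memory analog of the on-disk manifest CSV.
#'
#' @param cohort a `retina_cohort`.
#' @return data.frame.
#' @export
cohort_manifest <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) {
    data.frame(patient_id = s$patient_id, eye = s$eye,
               visit = s$visit_index, vendor = s$vendor,
               y_bcva = s$labels$y_bcva, y_cst = s$labels$y_cst,
               fluid = s$labels$fluid, disease = s$labels$disease,
               n_inj = s$labels$n_inj,
               treatment_need = s$labels$treatment_need,
               conversion = s$labels$conversion,
               stringsAsFactors = FALSE)
  }))
}

#' Write a cohort to disk (PNG fundus, NIfTI volumes, manifest CSV)
#'
#' Fundus intensities are stored as 8-bit PNG after division by a fixed
#' scale of 6 (clamped to `[0, 1]`); volumes are written losslessly as NIfTI.
#'
#' @param cohort a `retina_cohort`.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "fundus"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "oct"), recursive = TRUE, showWarnings = FALSE)
  man <- cohort_manifest(cohort)
  fundus_path <- character(length(cohort))
  oct_path <- character(length(cohort))
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    stem <- sprintf("%s_%s_v%02d", s$patient_id, s$eye, s$visit_index)
    fundus_path[i] <- file.path("fundus", paste0(stem, ".png"))
    oct_path[i] <- file.path("oct", paste0(stem, ".nii.gz"))
    png::writePNG(pmin(s$fundus / 6, 1), file.path(dir, fundus_path[i]))
    RNifti::writeNifti(aperm(s$oct, c(3, 2, 1)), file.path(dir, oct_path[i]))
  }
  man$fundus_path <- fundus_path
  man$oct_path <- oct_path
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.csv`.
#' @return a `retina_cohort` (without latent factors, which are not stored).
#' @export
read_cohort <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  scans <- lapply(seq_len(nrow(man)), function(i) {
    r <- man[i, ]
    fundus <- png::readPNG(file.path(dir, r$fundus_path)) * 6
    if (length(dim(fundus)) == 3L) fundus <- fundus[, , 1]
    oct <- aperm(as.array(RNifti::readNifti(file.path(dir, r$oct_path))), c(3, 2, 1))
    structure(list(
      patient_id = r$patient_id, eye = r$eye, visit_index = r$visit,
      vendor = r$vendor, z = NULL, fundus = fundus, oct = oct,
      labels = list(y_bcva = r$y_bcva, y_cst = r$y_cst, fluid = r$fluid,
                    disease = r$disease, n_inj = r$n_inj,
                    treatment_need = r$treatment_need,
                    conversion = r$conversion)
    ), class = "paired_scan")
  })
  structure(scans, class = "retina_cohort")
}
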