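# End-to-end workflows: the desk-scale demo (synthetic cohort -> CLIP and
# CLOOB pre-training -> retrieval evaluation -> linear probe -> modality
# interchange), manifest validation, and YAML experiment configs.

manifest_required_cols <- c("patient_id", "eye", "visit", "vendor",
                            "fundus_path", "oct_path", "y_bcva", "y_cst",
                            "fluid", "disease", "n_inj", "treatment_need",
                            "conversion")

#' Validate a cohort manifest CSV
#'
#' Checks required columns, referenced file existence, and label domains
#' (non-negative injection counts, 0/1 binary labels, known disease classes,
#' positive thickness, treatment-need consistency). All problems are
#' collected and raised together as an itemized error.
#'
#' @param path path to `manifest.csv` (file paths are resolved relative to
#'   its directory).
#' @return the manifest data frame, invisibly, when valid.
#' @export
validate_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  errors <- character(0)
  missing_cols <- setdiff(manifest_required_cols, names(man))
  if (length(missing_cols)) {
    errors <- c(errors, sprintf("missing column '%s'", missing_cols))
  }
  base <- dirname(path)
  for (col in intersect(c("fundus_path", "oct_path"), names(man))) {
    for (i in seq_len(nrow(man))) {
      f <- file.path(base, man[[col]][i])
      if (!file.exists(f)) {
        errors <- c(errors, sprintf("row %d: %s '%s' does not exist", i, col, man[[col]][i]))
      }
    }
  }
  check_domain <- function(col, ok, what) {
    if (!col %in% names(man)) return()
    bad <- which(!ok(man[[col]]))
    for (i in bad) {
      errors <<- c(errors, sprintf("row %d: column '%s' %s (got %s)",
                                   i, col, what, man[[col]][i]))
    }
  }
  check_domain("n_inj", function(x) x >= 0, "must be non-negative")
  check_domain("fluid", function(x) x %in% c(0, 1), "must be 0 or 1")
  check_domain("conversion", function(x) x %in% c(0, 1), "must be 0 or 1")
  check_domain("y_cst", function(x) x > 0, "must be positive")
  check_domain("disease", function(x) x %in% .labels$disease_classes,
               "must be a known disease class")
  if (all(c("n_inj", "treatment_need") %in% names(man)) &&
      all(man$n_inj >= 0)) {
    bad <- which(man$treatment_need != categorize_treatment_need(man$n_inj))
    for (i in bad) {
      errors <- c(errors, sprintf("row %d: treatment_need inconsistent with n_inj", i))
    }
  }
  if (length(errors)) {
    stop(paste0("manifest validation failed:\n  - ",
                paste(errors, collapse = "\n  - ")))
  }
  invisible(man)
}

#' Default desk-scale demo configuration
#'
#' The scales at which the full pipeline runs end-to-end on one CPU in a few
#' minutes: 250 patients (one visit each, so 200 training pairs at the
#' 80/15/5 pre-training split), 64 x 64 native images with 21-40 B-scans,
#' preprocessing to 48 x 48 with 8 retained slices, tiny encoders with d =
#' 32, and 30 pre-training epochs.
#'
#' @param seed master seed; all sub-seeds derive from it.
#' @return nested configuration list.
#' @export
demo_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = synth_config(n_patients = 250, visits_per_patient = c(2, 4),
                          fundus_size = c(64, 64),
                          oct_slice_range = c(21, 40),
                          oct_rows = 64, oct_cols = 64,
                          seed = seed),
    preprocess = preprocess_config(target_size = c(64, 64), n_keep_slices = 10),
    pretrain = list(epochs = 30, batch_size = 6, lr = 1e-3,
                    embed_dim = 32, hidden = 64),
    # the demo trades validation for test patients (80/5/15 rather than the
    # 80/15/5 shipping default) so the hold-out retrieval pool is large
    # enough (37 patients) for a statistically meaningful accuracy
    pretrain_ratios = c(0.80, 0.05, 0.15),
    probe = probe_config(seed = seed + 5L),
    ks = c(1, 5, 10)
  )
}

demo_pretrain_config <- function(objective, cfg) {
  pretrain_config(objective = objective,
                  epochs = cfg$pretrain$epochs,
                  batch_size = cfg$pretrain$batch_size,
                  lr = cfg$pretrain$lr,
                  embed_dim = cfg$pretrain$embed_dim,
                  hidden = cfg$pretrain$hidden,
                  seed = cfg$seed)
}

# embeddings for every cohort row from a multi-modal checkpoint
checkpoint_embeddings <- function(ckpt, pre, normalize = TRUE) {
  list(fundus = embed(pre$X, ckpt$encoder_x, normalize = normalize),
       oct = embed(pre$Y, ckpt$encoder_y, normalize = normalize))
}

#' Run the end-to-end desk-scale demonstration
#'
#' Generates a synthetic paired cohort, pre-trains tiny CLIP and CLOOB
#' models with one pair per patient per epoch, evaluates cross-modal
#' retrieval on the held-out test pool, linearly probes the visual-acuity
#' regression target on OCT embeddings (against a random-initialization
#' control), and runs the modality-interchange evaluation of the
#' fluid-detection head. All reports are written as JSON to `out_dir`
#' together with loss histories and a run log.
#'
#' @param config configuration from [demo_config()].
#' @param out_dir output directory (created if missing).
#' @return report bundle list (also serialized to `out_dir`).
#' @export
run_demo <- function(config = demo_config(), out_dir = tempfile("retinapair_demo")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), sprintf(...)),
        file = logf, append = TRUE)
  }
  log_line("demo start, seed %d", config$seed)
  cohort <- generate_cohort(config$cohort)
  man <- cohort_manifest(cohort)
  ratios <- if (!is.null(config$pretrain_ratios)) config$pretrain_ratios else c(0.80, 0.15, 0.05)
  split <- assign_splits(man, ratios, seed = config$seed + 2L)
  pre <- preprocess_cohort(cohort, config$preprocess)
  sp <- split_of(split, man)
  test_ix <- which(sp == "test")
  log_line("cohort %d scans; %d test", nrow(man), length(test_ix))

  bundle <- list(seed = config$seed, n_scans = nrow(man))
  ckpts <- list()
  for (obj in c("clip", "cloob")) {
    ck <- pretrain(cohort, split, demo_pretrain_config(obj, config),
                   config$preprocess)
    ckpts[[obj]] <- ck
    emb <- checkpoint_embeddings(ck, pre)
    # two evaluation pools, mirroring the one-sample- and all-samples-per-
    # patient retrieval setups; the one-sample pool is additionally averaged
    # over repeated visit draws to marginalize out visit-selection noise
    test1_ix <- test_ix[epoch_pairs(cohort[test_ix], config$seed + 4L)]
    draws <- vapply(1:20, function(r) {
      ix <- test_ix[epoch_pairs(cohort[test_ix], config$seed + 400L + r)]
      S <- unclass(emb$fundus[ix, , drop = FALSE]) %*%
        t(unclass(emb$oct[ix, , drop = FALSE]))
      c(topk_accuracy(S, 1, "fundus_to_oct"), topk_accuracy(S, 1, "oct_to_fundus"))
    }, numeric(2))
    rep <- list(
      one_per_patient = evaluate_retrieval(
        emb$fundus[test1_ix, , drop = FALSE], emb$oct[test1_ix, , drop = FALSE],
        ks = config$ks, patient_ids = man$patient_id[test1_ix]),
      one_per_patient_avg = list(top1_fundus_to_oct = mean(draws[1, ]),
                                 top1_oct_to_fundus = mean(draws[2, ]),
                                 n = length(test1_ix), n_draws = 20L),
      all_samples = evaluate_retrieval(
        emb$fundus[test_ix, , drop = FALSE], emb$oct[test_ix, , drop = FALSE],
        ks = config$ks, patient_ids = man$patient_id[test_ix]))
    bundle[[paste0("retrieval_", obj)]] <- rep
    bundle[[paste0("history_", obj)]] <- ck$history
    utils::write.csv(ck$history,
                     file.path(out_dir, sprintf("history_%s.csv", obj)),
                     row.names = FALSE)
    log_line("%s final train loss %.4f, test top-1 %.3f (pool %d)", obj,
             utils::tail(ck$history$train_loss, 1),
             rep$one_per_patient$fundus_to_oct$topk[["top1"]],
             rep$one_per_patient$fundus_to_oct$n)
  }

  # downstream: fresh patient-level 80/10/10 split, stratified on the fluid
  # label so the imbalanced binary task keeps both classes in every subset
  dsplit <- assign_splits(man, c(0.80, 0.10, 0.10), stratify_key = "fluid",
                          seed = config$seed + 3L)
  dsp <- split_of(dsplit, man)
  tr <- which(dsp == "train"); va <- which(dsp == "val"); te <- which(dsp == "test")
  # probing uses l2-normalized embeddings: under cosine-aligned training the
  # row norm is unconstrained nuisance and only hurts the linear readout
  emb <- checkpoint_embeddings(ckpts$clip, pre, normalize = TRUE)
  Eo <- unclass(emb$oct); Ef <- unclass(emb$fundus)

  probe <- linear_probe(Eo[tr, ], man$y_bcva[tr], Eo[va, ], man$y_bcva[va],
                        Eo[te, ], man$y_bcva[te], "regression", config$probe)
  # random-initialization control, averaged over three encoder draws so a
  # single unlucky random projection does not dominate the comparison
  rand_r2 <- vapply(1:3, function(k) {
    rand_enc <- make_encoder("oct3d", ncol(pre$Y), config$pretrain$embed_dim,
                             config$pretrain$hidden, seed = config$seed + 96L + k)
    Er <- unclass(embed(pre$Y, rand_enc, normalize = TRUE))
    pr <- linear_probe(Er[tr, ], man$y_bcva[tr], Er[va, ], man$y_bcva[va],
                       Er[te, ], man$y_bcva[te], "regression", config$probe)
    pr$report$metrics$r2
  }, numeric(1))
  bundle$probe_bcva <- list(pretrained = probe$report,
                            random_init = list(r2_mean = mean(rand_r2),
                                               r2 = rand_r2))
  log_line("probe R2 pretrained %.3f vs random-init mean %.3f",
           probe$report$metrics$r2, mean(rand_r2))

  fluid <- linear_probe(Eo[tr, ], man$fluid[tr], Eo[va, ], man$fluid[va],
                        Eo[te, ], man$fluid[te], "binary", config$probe)
  inter <- interchange_eval(fluid$head, Eo[te, ], Ef[te, ], man$fluid[te])
  bundle$interchange_fluid <- inter
  log_line("interchange fluid AUROC source %.3f swapped %.3f",
           inter$source, inter$swapped)

  for (nm in c("retrieval_clip", "retrieval_cloob", "probe_bcva",
               "interchange_fluid")) {
    jsonlite::write_json(strip_classes(bundle[[nm]]),
                         file.path(out_dir, paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  log_line("demo done")
  invisible(bundle)
}

# recursively drop S3 classes so jsonlite serializes plainly
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

experiment_allowed_keys <- list(
  top = c("seed", "out_dir", "cohort", "preprocess", "pretrain", "probe", "ks"),
  cohort = c("n_patients", "visits_per_patient", "fundus_size",
             "oct_slice_range", "oct_rows", "oct_cols", "noise_sd", "seed"),
  preprocess = c("target_size", "n_keep_slices"),
  pretrain = c("objective", "epochs", "batch_size", "lr", "embed_dim", "hidden")
)

#' Load and validate an experiment configuration from YAML
#'
#' Unknown keys are rejected with an error naming them; recognized keys
#' override the [demo_config()] defaults. All randomness derives from the
#' single `seed` key.
#'
#' @param path YAML file path.
#' @return nested configuration list as from [demo_config()].
#' @export
experiment_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  check_keys <- function(keys, allowed, where) {
    bad <- setdiff(keys, allowed)
    if (length(bad)) {
      stop(sprintf("unknown config key(s) in %s: %s", where,
                   paste(bad, collapse = ", ")))
    }
  }
  check_keys(names(raw), experiment_allowed_keys$top, "top level")
  for (sec in c("cohort", "preprocess", "pretrain")) {
    if (!is.null(raw[[sec]])) {
      check_keys(names(raw[[sec]]), experiment_allowed_keys[[sec]], sec)
    }
  }
  seed <- if (!is.null(raw$seed)) as.integer(raw$seed) else 1L
  cfg <- demo_config(seed)
  if (!is.null(raw$cohort)) {
    ca <- utils::modifyList(list(n_patients = cfg$cohort$n_patients,
                                 visits_per_patient = cfg$cohort$visits_per_patient,
                                 fundus_size = cfg$cohort$fundus_size,
                                 oct_slice_range = cfg$cohort$oct_slice_range,
                                 oct_rows = cfg$cohort$oct_rows,
                                 oct_cols = cfg$cohort$oct_cols,
                                 noise_sd = cfg$cohort$noise_sd,
                                 seed = seed), raw$cohort)
    cfg$cohort <- do.call(synth_config, ca)
  }
  if (!is.null(raw$preprocess)) {
    pa <- utils::modifyList(list(target_size = cfg$preprocess$target_size,
                                 n_keep_slices = cfg$preprocess$n_keep_slices),
                            raw$preprocess)
    cfg$preprocess <- do.call(preprocess_config, pa)
  }
  if (!is.null(raw$pretrain)) {
    cfg$pretrain <- utils::modifyList(cfg$pretrain, raw$pretrain)
  }
  if (!is.null(raw$ks)) cfg$ks <- raw$ks
  if (!is.null(raw$out_dir)) cfg$out_dir <- raw$out_dir
  cfg
}
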