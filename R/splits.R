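# Patient-level train/val/test partitioning with optional stratification,
# and the one-pair-per-patient epoch sampler used by multi-modal pre-training.

#' Assign patients to train/val/test splits
#'
#' Patient-disjoint partitioning at the given ratios (pre-training default
#' 80/15/5; downstream tasks use 80/10/10). With a `stratify_key`, patients
#' are shuffled and allocated within each label stratum using
#' largest-remainder rounding, so each split's label proportions match the
#' global ones to within one patient per stratum. Strata smaller than 3
#' patients are sent entirely to train with a warning.
#'
#' @param manifest data frame with a `patient_id` column (one or more rows
#'   per patient) and any label columns.
#' @param ratios length-3 non-negative vector summing to 1 (train, val, test).
#' @param stratify_key optional name of a manifest column to stratify on
#'   (the patient's first row defines their stratum).
#' @param seed integer seed controlling the shuffles.
#' @return a `split_assignment`: data.frame (patient_id, split) with the
#'   ratios, key and seed as attributes.
#' @export
assign_splits <- function(manifest, ratios = c(0.80, 0.15, 0.05),
                          stratify_key = NULL, seed = 1L) {
  stopifnot(nrow(manifest) > 0, "patient_id" %in% names(manifest))
  if (abs(sum(ratios) - 1) > 1e-9 || any(ratios < 0)) {
    stop("ratios must be non-negative and sum to 1")
  }
  pat <- manifest[!duplicated(manifest$patient_id), , drop = FALSE]
  if (!is.null(stratify_key)) {
    if (!stratify_key %in% names(manifest)) {
      stop(sprintf("unknown stratify_key '%s'", stratify_key))
    }
    strata <- split(pat$patient_id, as.character(pat[[stratify_key]]))
  } else {
    strata <- list(all = pat$patient_id)
  }
  set.seed(seed)
  out <- list()
  for (snm in names(strata)) {
    ids <- strata[[snm]]
    if (!is.null(stratify_key) && length(ids) < 3L) {
      warning(sprintf("stratum '%s' has fewer than 3 patients; assigning all to train", snm))
      out[[snm]] <- data.frame(patient_id = ids, split = "train",
                               stringsAsFactors = FALSE)
      next
    }
    ids <- sample(ids)
    n <- length(ids)
    raw <- n * ratios
    counts <- floor(raw)
    rem <- n - sum(counts)
    if (rem > 0) {
      extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    labels <- rep(c("train", "val", "test"), times = counts)
    out[[snm]] <- data.frame(patient_id = ids, split = labels,
                             stringsAsFactors = FALSE)
  }
  assignment <- do.call(rbind, out)
  rownames(assignment) <- NULL
  structure(assignment, ratios = ratios, stratify_key = stratify_key,
            seed = seed, class = c("split_assignment", "data.frame"))
}

#' Look up the split of each manifest row
#'
#' @param assignment a `split_assignment`.
#' @param manifest data frame with `patient_id`.
#' @return character vector of splits aligned to the manifest rows.
#' @export
split_of <- function(assignment, manifest) {
  assignment$split[match(manifest$patient_id, assignment$patient_id)]
}

#' Sample one scan per patient for a training epoch
#'
#' Uniformly selects a single (fundus, OCT) visit per patient, deterministic
#' under the epoch seed. The paper's time-seeded sampling is replaced by
#' explicit per-epoch seeds derived from a master seed, trading fidelity for
#' reproducibility.
#'
#' @param records list of `paired_scan` (or any records with `$patient_id`),
#'   typically the train split.
#' @param epoch_seed integer seed for this epoch.
#' @return integer vector of one record index per patient (in patient order).
#' @export
epoch_pairs <- function(records, epoch_seed) {
  stopifnot(length(records) > 0)
  pids <- vapply(records, function(r) r$patient_id, character(1))
  by_pat <- split(seq_along(records), pids)
  set.seed(epoch_seed)
  vapply(by_pat, function(ix) {
    if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
  }, integer(1))
}
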