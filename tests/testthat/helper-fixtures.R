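# Shared fixtures: a tiny cohort cheap enough for unit tests, and a cache so
# expensive artifacts (trained checkpoints) are built once per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

tiny_config <- function(n_patients = 8, visits = 1, noise_sd = 0.6, seed = 42) {
  synth_config(n_patients = n_patients, visits_per_patient = visits,
               fundus_size = c(32, 32), oct_slice_range = c(21, 24),
               oct_rows = 32, oct_cols = 32, noise_sd = noise_sd, seed = seed)
}

tiny_cohort <- function() {
  cached("tiny_cohort", function() generate_cohort(tiny_config()))
}

tiny_preprocess <- function() {
  preprocess_config(target_size = c(16, 16), n_keep_slices = 4)
}

# random unit-norm embedding matrix
rand_unit <- function(n, d, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(n * d), n, d)
  M / sqrt(rowSums(M^2))
}
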