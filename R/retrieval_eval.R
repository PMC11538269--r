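# Cross-modal retrieval evaluation: directional top-k accuracy with exact
# binomial confidence intervals, analytic chance levels, positive-pair
# cosine statistics, and the same-patient retrieval fraction.

#' Top-k retrieval accuracy from a similarity matrix
#'
#' Fraction of queries whose true cross-modal match (the diagonal entry)
#' ranks within the k largest similarities of their row
#' (`fundus_to_oct`) or column (`oct_to_fundus`). Ties are broken
#' deterministically in favor of the lowest index.
#'
#' @param S square n x n similarity matrix, queries in rows (fundus) and
#'   candidates in columns (OCT).
#' @param ks integer vector of k values, each <= n.
#' @param direction `"fundus_to_oct"` (rows) or `"oct_to_fundus"` (columns).
#' @return named numeric vector of accuracies, one per k.
#' @export
topk_accuracy <- function(S, ks = c(1, 5, 10),
                          direction = c("fundus_to_oct", "oct_to_fundus")) {
  direction <- match.arg(direction)
  stopifnot(nrow(S) == ncol(S))
  n <- nrow(S)
  if (any(ks > n) || any(ks < 1)) stop("k must lie in [1, pool size]")
  if (direction == "oct_to_fundus") S <- t(S)
  ranks <- vapply(seq_len(n), function(i) {
    better <- S[i, ] > S[i, i]
    tied_before <- which(S[i, ] == S[i, i])
    1L + sum(better) + sum(tied_before < i)
  }, integer(1))
  stats::setNames(vapply(ks, function(k) mean(ranks <= k), numeric(1)),
                  paste0("top", ks))
}

#' Index retrieved at rank 1 for each query
#'
#' @param S square similarity matrix.
#' @param direction as in [topk_accuracy()].
#' @return integer vector of retrieved candidate indices.
#' @export
top1_indices <- function(S, direction = c("fundus_to_oct", "oct_to_fundus")) {
  direction <- match.arg(direction)
  if (direction == "oct_to_fundus") S <- t(S)
  apply(S, 1L, which.max)
}

#' Expected top-k accuracy of an uninformative retrieval model
#'
#' Under exchangeable (chance-level) similarities the true match is
#' uniformly ranked, so the expected top-k accuracy is exactly `k / n`.
#'
#' @param n pool size.
#' @param k retrieval depth, `1 <= k <= n`.
#' @return expected accuracy.
#' @export
chance_topk <- function(n, k) {
  stopifnot(k >= 1, k <= n)
  k / n
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' @param successes number of successes (0..n).
#' @param n number of trials (> 0).
#' @param level confidence level (default 0.95).
#' @return numeric `c(lo, hi)`.
#' @export
binomial_ci <- function(successes, n, level = 0.95) {
  if (n <= 0) stop("n must be positive")
  stopifnot(successes >= 0, successes <= n)
  alpha <- 1 - level
  lo <- if (successes == 0) 0 else stats::qbeta(alpha / 2, successes, n - successes + 1)
  hi <- if (successes == n) 1 else stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lo = lo, hi = hi)
}

#' Mean and SD of the positive-pair cosine similarities
#'
#' @param U,V paired n x d embedding matrices with unit-norm rows.
#' @return list with `mean` and `sd` of `diag(U V^T)`.
#' @export
positive_pair_cosine_stats <- function(U, V) {
  if (nrow(U) == 0) stop("no pairs")
  check_same_shape(unclass(U), unclass(V))
  d <- rowSums(U * V)
  list(mean = mean(d), sd = stats::sd(d))
}

#' Fraction of top-1 retrievals that hit the query's own patient
#'
#' @param retrieved_ix integer vector of retrieved candidate indices (one per
#'   query, as from [top1_indices()]).
#' @param patient_ids patient id per pool position, aligned to both queries
#'   and candidates.
#' @return fraction in `[0, 1]`.
#' @export
same_patient_fraction <- function(retrieved_ix, patient_ids) {
  if (length(retrieved_ix) != length(patient_ids)) {
    stop("retrieved_ix and patient_ids must have equal length")
  }
  mean(patient_ids[retrieved_ix] == patient_ids)
}

#' Full retrieval report for a paired embedding pool
#'
#' Computes directional top-k accuracies with 95% Clopper-Pearson intervals,
#' positive-pair cosine statistics, and (when patient ids are given) the
#' same-patient top-1 fraction.
#'
#' @param U,V paired n x d unit-norm embedding matrices (fundus, OCT).
#' @param ks retrieval depths (default 1, 5, 10; capped at the pool size).
#' @param patient_ids optional patient id per pool position.
#' @param level confidence level.
#' @return a `retrieval_report` list, one entry per direction.
#' @export
evaluate_retrieval <- function(U, V, ks = c(1, 5, 10), patient_ids = NULL,
                               level = 0.95) {
  n <- nrow(U)
  ks <- unique(pmin(ks, n))
  S <- unclass(U) %*% t(unclass(V))
  cs <- positive_pair_cosine_stats(U, V)
  report_dir <- function(direction) {
    acc <- topk_accuracy(S, ks, direction)
    ci <- lapply(acc, function(a) binomial_ci(round(a * n), n, level))
    spf <- if (!is.null(patient_ids)) {
      same_patient_fraction(top1_indices(S, direction), patient_ids)
    } else NA_real_
    list(direction = direction, n = n, topk = acc, ci = ci,
         chance = stats::setNames(ks / n, paste0("top", ks)),
         same_patient_fraction = spf)
  }
  structure(list(fundus_to_oct = report_dir("fundus_to_oct"),
                 oct_to_fundus = report_dir("oct_to_fundus"),
                 cosine = cs, level = level),
            class = "retrieval_report")
}

#' Simulate chance-level top-1 retrieval with random unit embeddings
#'
#' Draws independent Gaussian embedding pairs, row-normalizes them, and
#' averages fundus-to-OCT top-1 accuracy over many repeats. Encoders never
#' exposed to paired data retrieve at this analytic chance level, the
#' reference against which trained retrieval accuracies are judged.
#'
#' @param n pool size (e.g. 189 for the one-sample-per-patient hold-out).
#' @param d embedding dimension (default 512).
#' @param reps number of seeded repeats.
#' @param seed integer seed.
#' @return list with `mean` top-1 accuracy, its `sd` across repeats, `n` and
#'   `reps`.
#' @export
simulate_chance_retrieval <- function(n = 189, d = 512, reps = 2000, seed = 1L) {
  set.seed(seed)
  accs <- vapply(seq_len(reps), function(r) {
    U <- matrix(stats::rnorm(n * d), n, d)
    V <- matrix(stats::rnorm(n * d), n, d)
    U <- U / sqrt(rowSums(U^2))
    V <- V / sqrt(rowSums(V^2))
    # top-1 via max.col (ties to the lowest index, matching topk_accuracy)
    mean(max.col(U %*% t(V), ties.method = "first") == seq_len(n))
  }, numeric(1))
  list(mean = mean(accs), sd = stats::sd(accs), n = n, reps = reps)
}
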