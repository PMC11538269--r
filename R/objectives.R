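# Contrastive pre-training objectives.
#
# All losses are written against the autodiff generics in autodiff.R: called
# with plain matrices they return plain numbers; called with advar nodes they
# build a gradient tape. Embeddings entering the multi-modal losses are
# expected row-l2-normalized (cosine similarity convention).

check_same_shape <- function(A, B) {
  if (!all(dim(A) == dim(B))) {
    stop(sprintf("shape mismatch: %dx%d vs %dx%d",
                 nrow(A), ncol(A), nrow(B), ncol(B)))
  }
}

#' Cosine similarity matrix between two embedding batches
#'
#' `S[i, j] = u_i . v_j` for row-normalized embeddings; entries lie in
#' `[-1, 1]` and `S(U, U)` has a unit diagonal.
#'
#' @param U,V n x d matrices (or `advar` nodes) with unit-norm rows.
#' @return n x n similarity matrix.
#' @export
similarity_matrix <- function(U, V) {
  check_same_shape(ad_value(U), ad_value(V))
  mm(U, transp(V))
}

#' InfoNCE (CLIP) loss
#'
#' Symmetric mean of the row-wise and column-wise cross-entropies of
#' `softmax(S / tau)` against the diagonal (the matched pairs). Always
#' non-negative; saturates toward 0 as positives dominate and approaches
#' `log n` for uninformative similarities.
#'
#' @param S square similarity matrix (matrix or `advar`).
#' @param tau softmax temperature, > 0 (numeric or 1x1 `advar`).
#' @return scalar loss.
#' @export
info_nce <- function(S, tau) {
  Sv <- ad_value(S)
  if (nrow(Sv) != ncol(Sv)) stop("info_nce requires a square similarity matrix")
  if (!is_advar(tau) && tau <= 0) stop("tau must be positive")
  P <- divide(S, tau)
  d <- diagpart(P)
  times(meann(plus(minus(logsumexp_rows(P), d),
                   minus(logsumexp_rows(transp(P)), d))), 0.5)
}

#' Modern Hopfield retrieval
#'
#' Each query row is replaced by the l2-normalized softmax-weighted
#' combination of the stored patterns: `normalize(t(stored) %*%
#' softmax(beta * stored %*% q))`. At `beta = 0` every output is the
#' normalized mean of the stored rows; as `beta` grows the nearest stored
#' pattern is returned.
#'
#' @param stored n x d matrix of stored patterns, unit-norm rows.
#' @param queries m x d matrix of query states, unit-norm rows.
#' @param beta non-negative inverse temperature of the retrieval softmax.
#' @return m x d matrix with unit-norm rows.
#' @export
hopfield_retrieve <- function(stored, queries, beta) {
  if (beta < 0) stop("beta must be non-negative")
  if (ncol(ad_value(stored)) != ncol(ad_value(queries))) {
    stop("stored and queries must share the embedding dimension")
  }
  P <- softmax_rows(times(mm(queries, transp(stored)), beta))
  rownorm2(mm(P, stored))
}

#' InfoLOOB (leave-one-out) contrastive loss
#'
#' Symmetric mean over both retrieval directions of
#' `-a_i . b_i / tau + log sum_{j != i} exp(a_i . b_j / tau)`.
#' The denominator excludes the positive pair, so the loss has no `log n`
#' floor and can go below zero.
#'
#' @param A,B n x d matrices with unit-norm rows, n >= 2.
#' @param tau temperature, > 0.
#' @return scalar loss.
#' @export
info_loob <- function(A, B, tau) {
  Av <- ad_value(A); Bv <- ad_value(B)
  check_same_shape(Av, Bv)
  if (nrow(Av) < 2L) stop("info_loob needs at least 2 pairs (no negatives otherwise)")
  if (!is_advar(tau) && tau <= 0) stop("tau must be positive")
  P <- divide(mm(A, transp(B)), tau)
  d <- diagpart(P)
  times(meann(plus(minus(logsumexp_offdiag_rows(P), d),
                   minus(logsumexp_offdiag_rows(transp(P)), d))), 0.5)
}

#' CLOOB loss: InfoLOOB on Hopfield-retrieved embeddings
#'
#' `info_loob(H_U(U), H_U(V)) + info_loob(H_V(U), H_V(V))` where `H_M(Q)`
#' retrieves the queries `Q` from the memory `M` with [hopfield_retrieve()].
#' Anchoring both terms in a single modality's memory is what propagates the
#' covariance structure of that modality into the objective.
#'
#' @inheritParams info_loob
#' @param beta Hopfield inverse temperature (default 8).
#' @return scalar loss.
#' @export
cloob_loss <- function(U, V, tau, beta = 8) {
  t1 <- info_loob(hopfield_retrieve(U, U, beta),
                  hopfield_retrieve(U, V, beta), tau)
  t2 <- info_loob(hopfield_retrieve(V, U, beta),
                  hopfield_retrieve(V, V, beta), tau)
  plus(t1, t2)
}

#' NT-Xent (SimCLR) loss
#'
#' Rows of both view batches are l2-normalized, stacked to 2n anchors, and
#' each anchor's positive (its other view) is contrasted against the 2n - 2
#' remaining samples with a softmax cross-entropy at temperature `tau`.
#'
#' @param Z1,Z2 n x p batches of projected views, n >= 2.
#' @param tau temperature, > 0.
#' @return scalar loss, always >= 0.
#' @export
nt_xent <- function(Z1, Z2, tau) {
  v1 <- ad_value(Z1); v2 <- ad_value(Z2)
  check_same_shape(v1, v2)
  if (nrow(v1) < 2L) stop("nt_xent needs at least 2 samples")
  if (!is_advar(tau) && tau <= 0) stop("tau must be positive")
  N1 <- rownorm2(Z1)
  N2 <- rownorm2(Z2)
  Z <- vconcat(N1, N2)
  S <- divide(mm(Z, transp(Z)), tau)
  pos <- diagpart(divide(mm(N1, transp(N2)), tau))
  meann(minus(logsumexp_offdiag_rows(S), vconcat(pos, pos)))
}

#' BYOL regression loss
#'
#' Mean over rows of `2 - 2 cos(pred_i, target_i)`. The target branch is
#' detached (receives no gradient); target weights are updated only by the
#' exponential moving average in the training loop.
#'
#' @param pred n x p online-network predictions.
#' @param target n x p target-network projections (treated as constant).
#' @return scalar loss in `[0, 4]`.
#' @export
byol_loss <- function(pred, target) {
  pv <- ad_value(pred); tv <- ad_value(target)
  check_same_shape(pv, tv)
  if (any(sqrt(rowSums(pv^2)) < 1e-12) || any(sqrt(rowSums(tv^2)) < 1e-12)) {
    stop("byol_loss: zero-norm rows are not allowed")
  }
  Tn <- tv / sqrt(rowSums(tv^2))  # detached
  meann(minus(2, times(2, rowsums(times(rownorm2(pred), Tn)))))
}

#' VICReg loss: invariance + variance hinge + covariance penalty
#'
#' `lambda * MSE(Z1, Z2)` plus, for each batch, `mu * mean_d max(0, 1 -
#' sqrt(var_d + eps))` over dimensions and `nu * (sum of squared off-diagonal
#' covariance entries) / p`. Variances and covariances use the unbiased
#' (n - 1) estimator; `var_eps = 1e-4` sits inside the square root.
#'
#' @param Z1,Z2 n x p view batches, n >= 2.
#' @param lambda_inv,mu_var,nu_cov term weights (defaults 25, 25, 1).
#' @param var_eps variance epsilon inside the square root.
#' @return scalar loss.
#' @export
vicreg_loss <- function(Z1, Z2, lambda_inv = 25, mu_var = 25, nu_cov = 1,
                        var_eps = 1e-4) {
  v1 <- ad_value(Z1); v2 <- ad_value(Z2)
  check_same_shape(v1, v2)
  n <- nrow(v1); p <- ncol(v1)
  if (n < 2L) stop("vicreg_loss needs at least 2 samples")
  D <- minus(Z1, Z2)
  inv <- meann(times(D, D))
  var_cov_terms <- function(Z) {
    C <- add_rowvec(Z, times(colmeans(Z), -1))
    varv <- times(colmeans(times(C, C)), n / (n - 1))
    stdv <- sqrtn(plus(varv, var_eps))
    vterm <- meann(relu(minus(1, stdv)))
    Cov <- divide(mm(transp(C), C), n - 1)
    dg <- diagpart(Cov)
    cterm <- divide(minus(sumn(times(Cov, Cov)), sumn(times(dg, dg))), p)
    list(v = vterm, c = cterm)
  }
  t1 <- var_cov_terms(Z1)
  t2 <- var_cov_terms(Z2)
  plus(plus(times(inv, lambda_inv),
            times(plus(t1$v, t2$v), mu_var)),
       times(plus(t1$c, t2$c), nu_cov))
}
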