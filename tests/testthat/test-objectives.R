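# Loss oracles: closed forms computed by hand and brute-force double-loop
# evaluations, independent of the vectorized implementations.

test_that("similarity matrix matches hand arithmetic and stays in [-1, 1]", {
  U <- rbind(c(1, 0), c(0, 1))
  V <- rbind(c(1, 0), c(sqrt(0.5), sqrt(0.5)))
  S <- similarity_matrix(U, V)
  expect_equal(S, rbind(c(1, sqrt(0.5)), c(0, sqrt(0.5))))
  R <- rand_unit(20, 8, seed = 2)
  expect_true(all(abs(similarity_matrix(R, rand_unit(20, 8, 3))) <= 1 + 1e-12))
  expect_equal(diag(similarity_matrix(R, R)), rep(1, 20))
  expect_error(similarity_matrix(R, rand_unit(10, 8, 4)), "mismatch")
})

test_that("InfoNCE hits its closed form, is non-negative, and saturates at log N", {
  expect_equal(info_nce(diag(2), 1), log(1 + exp(-1)), tolerance = 1e-12)
  expect_error(info_nce(diag(2), 0), "positive")
  expect_error(info_nce(matrix(0, 2, 3), 1), "square")
  set.seed(5)
  for (i in 1:5) {
    S <- matrix(rnorm(36), 6, 6)
    expect_gte(info_nce(S, 0.5), 0)
  }
  # near-uniform softmax limit at large d: loss ~ log N
  U <- rand_unit(64, 2048, seed = 7)
  V <- rand_unit(64, 2048, seed = 8)
  expect_equal(info_nce(similarity_matrix(U, V), 1), log(64), tolerance = 0.05)
})

test_that("Hopfield retrieval: uniform mean at beta 0, nearest pattern at large beta", {
  St <- rand_unit(5, 16, seed = 9)
  H0 <- hopfield_retrieve(St, rand_unit(3, 16, 10), 0)
  mu <- colMeans(St); mu <- mu / sqrt(sum(mu^2))
  expect_lt(max(abs(sweep(H0, 2, mu))), 1e-12)
  Hb <- hopfield_retrieve(St, St, 1e4)
  expect_lt(max(abs(Hb - St)), 1e-3)
  expect_equal(sqrt(rowSums(hopfield_retrieve(St, rand_unit(4, 16, 11), 3)^2)),
               rep(1, 4), tolerance = 1e-6)
  expect_error(hopfield_retrieve(St, St, -1), "non-negative")
})

test_that("InfoLOOB: closed form, permutation invariance, brute-force oracle", {
  expect_equal(info_loob(diag(2), diag(2), 1), -1, tolerance = 1e-12)
  expect_error(info_loob(matrix(1, 1, 2), matrix(1, 1, 2), 1), "at least 2")
  A <- rand_unit(4, 6, seed = 12); B <- rand_unit(4, 6, seed = 13)
  tau <- 0.4
  # independent double-loop evaluation
  brute <- 0
  for (i in 1:4) {
    num <- exp(sum(A[i, ] * B[i, ]) / tau)
    den_r <- sum(sapply(setdiff(1:4, i), function(j) exp(sum(A[i, ] * B[j, ]) / tau)))
    den_c <- sum(sapply(setdiff(1:4, i), function(j) exp(sum(A[j, ] * B[i, ]) / tau)))
    brute <- brute - log(num / den_r) / 8 - log(num / den_c) / 8
  }
  expect_equal(info_loob(A, B, tau), brute, tolerance = 1e-10)
  p <- c(3, 1, 4, 2)
  expect_equal(info_loob(A[p, ], B[p, ], tau), info_loob(A, B, tau),
               tolerance = 1e-12)
})

test_that("CLOOB equals its explicit Hopfield-then-InfoLOOB composition", {
  U <- rand_unit(5, 8, seed = 14); V <- rand_unit(5, 8, seed = 15)
  tau <- 0.3; beta <- 8
  explicit <- info_loob(hopfield_retrieve(U, U, beta),
                        hopfield_retrieve(U, V, beta), tau) +
              info_loob(hopfield_retrieve(V, U, beta),
                        hopfield_retrieve(V, V, beta), tau)
  expect_equal(cloob_loss(U, V, tau, beta), explicit, tolerance = 1e-10)
  expect_true(is.finite(cloob_loss(U, U, tau, beta)))
})

test_that("NT-Xent matches a brute-force 2n-way cross-entropy and its closed form", {
  Z1 <- matrix(rnorm(24), 4, 6); Z2 <- matrix(rnorm(24), 4, 6)
  tau <- 0.5
  N1 <- Z1 / sqrt(rowSums(Z1^2)); N2 <- Z2 / sqrt(rowSums(Z2^2))
  Z <- rbind(N1, N2)
  brute <- 0
  for (i in 1:8) {
    pos <- if (i <= 4) i + 4 else i - 4
    sims <- sapply(setdiff(1:8, i), function(j) exp(sum(Z[i, ] * Z[j, ]) / tau))
    brute <- brute - log(exp(sum(Z[i, ] * Z[pos, ]) / tau) / sum(sims)) / 8
  }
  expect_equal(nt_xent(Z1, Z2, tau), brute, tolerance = 1e-10)
  # perfectly aligned orthonormal views, n = 2, tau = 1
  expect_equal(nt_xent(diag(2), diag(2), 1), log(1 + 2 * exp(-1)),
               tolerance = 1e-12)
  expect_gte(nt_xent(Z1, Z2, 0.2), 0)
  expect_error(nt_xent(Z1[1, , drop = FALSE], Z2[1, , drop = FALSE], 1),
               "at least 2")
})

test_that("BYOL loss hits its closed-form cases and rejects zero rows", {
  set.seed(16)
  P <- matrix(rnorm(12), 3, 4)
  expect_equal(byol_loss(P, P), 0, tolerance = 1e-12)
  expect_equal(byol_loss(P, -P), 4, tolerance = 1e-12)
  expect_equal(byol_loss(rbind(c(1, 0)), rbind(c(0, 1))), 2, tolerance = 1e-12)
  expect_error(byol_loss(matrix(0, 2, 2), P[1:2, 1:2]), "zero-norm")
})

test_that("VICReg: zero at ideal views, hinge at the documented epsilon, oracle invariance", {
  set.seed(17)
  # whitened batch: unit per-dimension std and exactly diagonal covariance
  M <- matrix(rnorm(40), 10, 4)
  C <- scale(M, center = TRUE, scale = FALSE)
  Z <- C %*% solve(chol(stats::cov(C)))
  v <- vicreg_loss(Z, Z)
  expect_lt(abs(v), 1e-8)
  # constant batch: hinge = 1 - sqrt(var_eps) per batch
  const <- matrix(1, 4, 3)
  expect_equal(vicreg_loss(const, const, 25, 25, 1),
               2 * 25 * (1 - sqrt(1e-4)), tolerance = 1e-10)
  # invariance term equals the double-loop mean squared difference
  Z1 <- matrix(rnorm(30), 6, 5); Z2 <- matrix(rnorm(30), 6, 5)
  mse <- 0
  for (i in 1:6) for (j in 1:5) mse <- mse + (Z1[i, j] - Z2[i, j])^2 / 30
  expect_equal(vicreg_loss(Z1, Z2, 1, 0, 0), mse, tolerance = 1e-10)
})

test_that("losses are invariant to joint permutation and differ in their floors", {
  U <- rand_unit(6, 8, seed = 18); V <- rand_unit(6, 8, seed = 19)
  p <- c(4, 6, 1, 3, 5, 2)
  expect_equal(info_nce(similarity_matrix(U[p, ], V[p, ]), 0.5),
               info_nce(similarity_matrix(U, V), 0.5), tolerance = 1e-12)
  expect_equal(cloob_loss(U[p, ], V[p, ], 0.5, 8), cloob_loss(U, V, 0.5, 8),
               tolerance = 1e-10)
  expect_equal(nt_xent(U[p, ], V[p, ], 0.5), nt_xent(U, V, 0.5),
               tolerance = 1e-12)
  # InfoNCE floors at ~log N on uniform similarities; InfoLOOB goes below 0
  A <- diag(8)
  expect_gt(info_nce(matrix(0, 8, 8), 1), 0)
  expect_lt(info_loob(A, A, 0.1), 0)
})

test_that("loss gradients through the tape agree with finite differences", {
  set.seed(20)
  params <- list(A = matrix(rnorm(32), 4, 8), B = matrix(rnorm(32), 4, 8))
  cases <- list(
    clip = function(A, B) info_nce(similarity_matrix(rownorm2(A), rownorm2(B)), 0.5),
    cloob = function(A, B) cloob_loss(rownorm2(A), rownorm2(B), 0.3, 8),
    simclr = function(A, B) nt_xent(A, B, 0.5),
    byol = function(A, B) byol_loss(A, ad_value(B)),
    vicreg = function(A, B) vicreg_loss(A, B)
  )
  for (nm in names(cases)) {
    f <- cases[[nm]]
    nodes <- lapply(params, ad_param)
    ad_backward(f(nodes$A, nodes$B))
    ag <- ad_grad(nodes$A)
    ng <- numeric_gradient(function(p) as.numeric(ad_value(f(p$A, p$B))),
                           params)$A
    expect_lt(max(abs(ag - ng)) / max(abs(ng)), 1e-4, label = nm)
  }
})
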