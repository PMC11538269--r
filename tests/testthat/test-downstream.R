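# Downstream metrics, bootstrap, probe/fine-tune protocols, interchange.

test_that("regression metrics: perfect fit, mean predictor, negative R2", {
  y <- c(1, 2, 3, 4, 5)
  m <- compute_metrics(y, y, "regression")
  expect_equal(m$r2, 1)
  expect_equal(m$rmse, 0)
  m <- compute_metrics(rep(mean(y), 5), y, "regression")
  expect_equal(m$r2, 0)
  m <- compute_metrics(-y, y, "regression")
  expect_lt(m$r2, 0)
  expect_error(compute_metrics(1:4, 1:5, "regression"), "equal length")
})

test_that("AUROC matches the rank-based formula and keeps its orientation", {
  set.seed(31)
  y <- rbinom(60, 1, 0.4)
  s <- rnorm(60) + y
  # independent Wilcoxon/rank oracle
  rank_auc <- function(s, y) {
    r <- rank(s)
    (sum(r[y == 1]) - sum(y == 1) * (sum(y == 1) + 1) / 2) /
      (sum(y == 1) * sum(y == 0))
  }
  expect_equal(auroc(s, y), rank_auc(s, y), tolerance = 1e-12)
  # anti-informative scores must give AUROC < 0.5 (no auto-flip)
  expect_lt(auroc(-s, y), 0.5)
  expect_error(auroc(s, rep(1, 60)), "single class")
})

test_that("average precision matches a brute-force threshold sweep", {
  set.seed(32)
  y <- rbinom(40, 1, 0.3)
  s <- rnorm(40) + 0.8 * y
  brute_ap <- function(s, y) {
    th <- sort(unique(s), decreasing = TRUE)
    prec <- rec <- numeric(length(th))
    for (i in seq_along(th)) {
      sel <- s >= th[i]
      prec[i] <- sum(y[sel]) / sum(sel)
      rec[i] <- sum(y[sel]) / sum(y)
    }
    sum(diff(c(0, rec)) * prec)
  }
  expect_equal(average_precision(s, y), brute_ap(s, y), tolerance = 1e-12)
  # perfect ranking has AP 1
  expect_equal(average_precision(y + 0.1 * seq_along(y) / 100, y), 1)
})

test_that("weighted one-vs-rest AUROC reproduces the hand example (0.8125)", {
  # supports 8/4/4 with per-class AUROCs 1.0 / 0.5 / 0.75
  labels <- rep(c("A", "B", "C"), times = c(8, 4, 4))
  n <- 16
  scores <- matrix(0, n, 3, dimnames = list(NULL, c("A", "B", "C")))
  scores[, "A"] <- ifelse(labels == "A", 0.9, 0.1)
  scores[, "B"] <- 0.4                      # 6 negatives below the positives...
  scores[c(1:3, 13:15), "B"] <- 0.6         # ...and 6 above: AUC 0.5
  scores[labels == "B", "B"] <- 0.5
  scores[, "C"] <- 0.5                      # 9 negatives below...
  scores[1:3, "C"] <- 0.9                   # ...3 above: AUC 36/48 = 0.75
  scores[labels == "C", "C"] <- 0.7
  m <- compute_metrics(scores, labels, "multiclass")
  expect_equal(unname(m$per_class_auroc), c(1.0, 0.5, 0.75))
  expect_equal(m$auroc_weighted, 0.8125)
  expect_error(compute_metrics(scores[labels == "A", ], labels[labels == "A"],
                               "multiclass"), "single class")
})

test_that("bootstrap evaluation is seeded, consistent, and degenerate on perfection", {
  set.seed(33)
  y <- rbinom(80, 1, 0.5)
  s <- rnorm(80) + 1.5 * y
  metric <- function(p, l) auroc(p, l)
  b1 <- bootstrap_eval(s, y, metric, B = 200, seed = 9)
  b2 <- bootstrap_eval(s, y, metric, B = 200, seed = 9)
  expect_identical(b1, b2)
  point <- auroc(s, y)
  expect_lt(abs(b1$mean - point), 2 * b1$sd + 1e-3)
  perfect <- bootstrap_eval(y * 2 - 1, y, metric, B = 100, seed = 10)
  expect_equal(perfect$sd, 0)
  expect_error(bootstrap_eval(numeric(0), numeric(0), metric), "empty")
})

test_that("early stopping halts within patience epochs of the minimum", {
  stopper <- make_early_stopper(patience = 5)
  losses <- c(5, 4, 3, 2, 1, 1.1, 1.2, 1.3, 1.4, 1.5, 1.6)
  stopped_at <- NA
  for (i in seq_along(losses)) {
    if (stopper(losses[i])) { stopped_at <- i; break }
  }
  st <- attr(stopper, "state")
  expect_equal(st$best_epoch, 5)
  expect_equal(stopped_at, 10)  # exactly 5 non-improving epochs after the best
  # monotonically improving sequences never stop
  s2 <- make_early_stopper(5)
  expect_false(any(vapply(seq(10, 1), s2, logical(1))))
})

test_that("linear probe recovers a near-noiseless linear target (R2 >= 0.99)", {
  set.seed(34)
  E <- matrix(rnorm(300 * 8), 300, 8)
  w <- c(2, -1, 0.5, 1, 0, 0.3, -0.7, 0.2)
  y <- as.numeric(E %*% w) + rnorm(300, 0, 0.01) + 10
  tr <- 1:200; va <- 201:250; te <- 251:300
  fit <- linear_probe(E[tr, ], y[tr], E[va, ], y[va], E[te, ], y[te],
                      "regression", probe_config(seed = 35))
  expect_gte(fit$report$metrics$r2, 0.99)
  expect_equal(fit$report$mode, "linear_probe")
  expect_equal(fit$report$n_test, 50)
  expect_error(linear_probe(E[tr, ], y[va], E[va, ], y[va], E[te, ], y[te],
                            "regression"), "mismatch")
})

test_that("probing shuffled labels yields chance AUROC; separable tasks near 1", {
  set.seed(36)
  E <- matrix(rnorm(240 * 8), 240, 8)
  y_sep <- as.integer(E %*% c(1.5, -1, 0, 0, 0.5, 0, 0, 0) + rnorm(240, 0, 0.2) > 0)
  y_shuf <- sample(y_sep)
  tr <- 1:160; va <- 161:200; te <- 201:240
  cfg <- probe_config(seed = 37, bootstrap_B = 100)
  sep <- linear_probe(E[tr, ], y_sep[tr], E[va, ], y_sep[va], E[te, ], y_sep[te],
                      "binary", cfg)
  expect_gte(sep$report$metrics$auroc_weighted, 0.95)
  shuf <- linear_probe(E[tr, ], y_shuf[tr], E[va, ], y_shuf[va],
                       E[te, ], y_shuf[te], "binary", cfg)
  expect_lt(abs(shuf$report$metrics$auroc_weighted - 0.5), 0.12)
})

test_that("fine-tuning with a frozen encoder reproduces the linear probe exactly", {
  set.seed(38)
  enc <- make_encoder("fundus2d", 36, embed_dim = 8, hidden = 12, seed = 39)
  X <- matrix(rnorm(150 * 36), 150, 36)
  E <- unclass(embed(X, enc, normalize = FALSE))
  y <- as.numeric(E %*% rnorm(8)) + rnorm(150, 0, 0.1)
  tr <- 1:100; va <- 101:125; te <- 126:150
  cfg <- probe_config(seed = 40, max_epochs = 20, bootstrap_B = 50)
  probe <- linear_probe(E[tr, ], y[tr], E[va, ], y[va], E[te, ], y[te],
                        "regression", cfg)
  ft0 <- fine_tune(enc, X[tr, ], y[tr], X[va, ], y[va], X[te, ], y[te],
                   "regression", cfg, encoder_lr_scale = 0)
  expect_equal(ft0$report$metrics$r2, probe$report$metrics$r2, tolerance = 1e-10)
  expect_identical(ft0$encoder$params, enc$params)
  # unfrozen fine-tuning returns a well-formed report and can only match or
  # improve the validation loss of the frozen probe under equal budgets
  ft1 <- fine_tune(enc, X[tr, ], y[tr], X[va, ], y[va], X[te, ], y[te],
                   "regression", cfg, encoder_lr_scale = 1)
  expect_s3_class(ft1$report, "probe_report")
  expect_false(identical(ft1$encoder$params, enc$params))
})

test_that("interchange evaluation: zero decay on identical embeddings, hand arithmetic", {
  set.seed(41)
  y <- rep(c(1, 0), each = 5)
  # head reading dimension 1; OCT scores give AUC 0.8, fundus scores AUC 0.64
  oct_scores <- c(5, 4, 3, 2, 1.2, 4.5, 1.5, 1, 0.6, 0.2)    # 20/25 pairs won
  fun_scores <- c(5, 4, 1.2, 1.1, 0.5, 4.5, 1.5, 1, 0.6, 0.2) # 16/25 pairs won
  head <- list(Wh = matrix(c(1, 0), 2, 1), bh = matrix(0, 1, 1),
               classes = NULL, task_type = "binary",
               std = list(mu = c(0, 0), sd = c(1, 1)), y_scale = NULL)
  Eo <- cbind(oct_scores, rnorm(10))
  Ef <- cbind(fun_scores, rnorm(10))
  same <- interchange_eval(head, Eo, Eo, y)
  expect_equal(same$decay, 0)
  rep <- interchange_eval(head, Eo, Ef, y)
  expect_equal(rep$source, 0.8)
  expect_equal(rep$swapped, 0.64)
  expect_equal(rep$decay, 0.2)
  expect_error(interchange_eval(head, Eo[, 1, drop = FALSE], Ef, y), "dimension")
})
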