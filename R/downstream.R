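# Downstream adaptation: task metrics (R2, RMSE, support-weighted one-vs-rest
# AUROC and average precision), bootstrap variance estimation, linear probing
# and fine-tuning with AdamW + reduce-on-plateau + early stopping, and the
# modality-interchange evaluation.

#' Binary AUROC (fixed orientation)
#'
#' Wraps pROC with an explicit positive direction so that scores below 0.5
#' AUROC are reported as such (no auto-flipping).
#'
#' @param scores numeric scores, larger = more positive.
#' @param y 0/1 labels (both classes must be present).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, y) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("AUROC undefined: test labels contain a single class")
  }
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = as.numeric(scores),
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Average precision (threshold-stepped estimator)
#'
#' `sum_k (R_k - R_{k-1}) P_k` over descending score thresholds, with tied
#' scores grouped into one threshold.
#'
#' @param scores numeric scores.
#' @param y 0/1 labels with at least one positive.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores, y) {
  y <- as.integer(y)
  if (sum(y) == 0) stop("AP undefined: no positive labels")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- c(which(diff(ss) != 0), length(ss))  # end of each threshold group
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / sum(y)
  sum(diff(c(0, rec)) * prec)
}

#' Compute the task metric set for predictions against labels
#'
#' Regression: `R2 = 1 - SSres/SStot` (negative values indicate predictive
#' power worse than the mean predictor) and RMSE. Binary: support-weighted
#' AUROC and AP over the two classes (class 0 is scored with the negated
#' scores). Multiclass: support-weighted one-vs-rest AUROC and AP over the
#' score matrix columns.
#'
#' @param predictions numeric vector (regression/binary scores) or n x C
#'   score matrix with named columns (multiclass).
#' @param labels numeric vector (regression), 0/1 vector (binary), or
#'   class labels matching the score columns (multiclass).
#' @param task_type `"regression"`, `"binary"` or `"multiclass"`.
#' @return named list of metrics.
#' @export
compute_metrics <- function(predictions, labels,
                            task_type = c("regression", "binary", "multiclass")) {
  task_type <- match.arg(task_type)
  if (NROW(predictions) != length(labels)) {
    stop("predictions and labels must have equal length")
  }
  if (task_type == "regression") {
    res <- sum((labels - predictions)^2)
    tot <- sum((labels - mean(labels))^2)
    return(list(r2 = 1 - res / tot,
                rmse = sqrt(mean((labels - predictions)^2))))
  }
  if (task_type == "binary") {
    y <- as.integer(labels)
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    if (n1 == 0 || n0 == 0) stop("AUROC undefined: test labels contain a single class")
    auc1 <- auroc(predictions, y)
    auc0 <- auroc(-predictions, 1 - y)
    ap1 <- average_precision(predictions, y)
    ap0 <- average_precision(-predictions, 1 - y)
    n <- n0 + n1
    return(list(auroc_weighted = (n1 * auc1 + n0 * auc0) / n,
                ap_weighted = (n1 * ap1 + n0 * ap0) / n))
  }
  classes <- colnames(predictions)
  if (is.null(classes)) classes <- as.character(seq_len(ncol(predictions)))
  labels <- as.character(labels)
  present <- classes[classes %in% labels]
  if (length(present) < 2L) stop("AUROC undefined: test labels contain a single class")
  sup <- vapply(present, function(cl) sum(labels == cl), numeric(1))
  aucs <- vapply(present, function(cl) {
    auroc(predictions[, cl], as.integer(labels == cl))
  }, numeric(1))
  aps <- vapply(present, function(cl) {
    average_precision(predictions[, cl], as.integer(labels == cl))
  }, numeric(1))
  list(auroc_weighted = sum(sup * aucs) / sum(sup),
       ap_weighted = sum(sup * aps) / sum(sup),
       per_class_auroc = aucs, per_class_ap = aps, support = sup)
}

#' Bootstrap mean and SD of a metric on the hold-out set
#'
#' Seeded resampling of (prediction, label) pairs with replacement. Resamples
#' on which the metric is undefined (e.g. single-class AUROC draws) are
#' dropped; their count is reported.
#'
#' @param predictions vector or matrix of predictions.
#' @param labels label vector.
#' @param metric function(predictions, labels) -> scalar.
#' @param B number of resamples (default 1000).
#' @param seed integer seed.
#' @return list with `mean`, `sd`, `B_effective`.
#' @export
bootstrap_eval <- function(predictions, labels, metric, B = 1000, seed = 1L) {
  n <- length(labels)
  if (n == 0) stop("empty input")
  stopifnot(B >= 1)
  set.seed(seed)
  vals <- vapply(seq_len(B), function(b) {
    ix <- sample.int(n, n, replace = TRUE)
    p <- if (is.matrix(predictions)) predictions[ix, , drop = FALSE] else predictions[ix]
    tryCatch(metric(p, labels[ix]), error = function(e) NA_real_)
  }, numeric(1))
  list(mean = mean(vals, na.rm = TRUE), sd = stats::sd(vals, na.rm = TRUE),
       B_effective = sum(!is.na(vals)))
}

#' Early-stopping controller
#'
#' Returns a closure fed one validation loss per epoch; it reports `TRUE`
#' (stop) once the loss has not improved for `patience` consecutive epochs.
#' The best epoch seen is available via the `best_epoch` attribute function.
#'
#' @param patience non-improving epochs tolerated (default 5).
#' @return function(val_loss) -> logical, with environment fields
#'   `best_loss`, `best_epoch`, `epoch`.
#' @export
make_early_stopper <- function(patience = 5) {
  env <- new.env()
  env$best_loss <- Inf; env$best_epoch <- 0L; env$epoch <- 0L; env$bad <- 0L
  f <- function(val_loss) {
    env$epoch <- env$epoch + 1L
    if (val_loss < env$best_loss) {
      env$best_loss <- val_loss
      env$best_epoch <- env$epoch
      env$bad <- 0L
    } else {
      env$bad <- env$bad + 1L
    }
    env$bad >= patience
  }
  attr(f, "state") <- env
  f
}

#' Probe/fine-tune optimization configuration
#'
#' @param lr_grid candidate learning rates within the search interval
#'   `[1e-6, 1e-3]`, selected on validation loss.
#' @param max_epochs epoch cap (default 100).
#' @param batch_size minibatch size.
#' @param patience early-stopping patience (default 5).
#' @param plateau_patience,plateau_factor reduce-on-plateau scheduler: halve
#'   the rate after this many non-improving epochs.
#' @param weight_decay AdamW weight decay (default 0.1).
#' @param bootstrap_B bootstrap resamples for the report (default 1000).
#' @param seed integer seed (head init, batch order, bootstrap).
#' @return a `probe_config` list.
#' @export
probe_config <- function(lr_grid = c(1e-5, 1e-4, 1e-3), max_epochs = 100,
                         batch_size = 8, patience = 5,
                         plateau_patience = 2, plateau_factor = 0.5,
                         weight_decay = 0.1, bootstrap_B = 1000, seed = 1L) {
  structure(list(lr_grid = lr_grid, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor,
                 weight_decay = weight_decay,
                 bootstrap_B = as.integer(bootstrap_B),
                 seed = as.integer(seed)),
            class = "probe_config")
}

task_loss_node <- function(logits, y, task_type, classes = NULL) {
  if (task_type == "regression") {
    D <- minus(logits, matrix(y, ncol = 1))
    return(meann(times(D, D)))
  }
  if (task_type == "binary") {
    # margin form of BCE: mean log(1 + exp(-(2y - 1) * logit))
    s <- matrix(-(2 * y - 1), ncol = 1)
    return(meann(logn(plus(expn(times(logits, s)), 1))))
  }
  onehot <- outer(as.character(y), classes, "==") * 1
  meann(minus(logsumexp_rows(logits), rowsums(times(logits, onehot))))
}

task_out_dim <- function(task_type, classes) {
  if (task_type == "multiclass") length(classes) else 1L
}

# shared optimizer loop for probing (head only) and fine-tuning (encoder +
# head). `forward` maps (param nodes, row indices) to a prediction node.
train_supervised <- function(params, forward, n_train, val_loss_fn, config,
                             lr, lr_scale = NULL) {
  opt <- adamw_init(params)
  stopper <- make_early_stopper(config$patience)
  best <- list(params = params, val = Inf)
  cur_lr <- lr
  plateau_bad <- 0L; plateau_best <- Inf
  for (ep in seq_len(config$max_epochs)) {
    set.seed(config$seed + 1009L * ep)
    order_ix <- sample.int(n_train)
    chunks <- split(order_ix, ceiling(seq_along(order_ix) / config$batch_size))
    for (ch in chunks) {
      nodes <- lapply(params, ad_param)
      loss <- forward(nodes, ch)
      ad_backward(loss)
      grads <- lapply(nodes, ad_grad)
      lr_eff <- if (is.null(lr_scale)) cur_lr else {
        vapply(names(params), function(nm) cur_lr * lr_scale[[nm]], numeric(1))
      }
      step <- adamw_step(params, grads, opt, lr_eff,
                         weight_decay = config$weight_decay)
      params <- step$params
      opt <- step$state
    }
    vl <- val_loss_fn(params)
    if (vl < best$val) best <- list(params = params, val = vl)
    if (vl < plateau_best) {
      plateau_best <- vl; plateau_bad <- 0L
    } else {
      plateau_bad <- plateau_bad + 1L
      if (plateau_bad >= config$plateau_patience) {
        cur_lr <- cur_lr * config$plateau_factor
        plateau_bad <- 0L
      }
    }
    if (stopper(vl)) break
  }
  best
}

head_init <- function(d, out, seed, y_train, task_type, classes) {
  set.seed(seed)
  b <- if (task_type == "binary") {
    p <- mean(y_train == 1)
    stats::qlogis(min(max(p, 1e-3), 1 - 1e-3))
  } else if (task_type == "multiclass") {
    log(vapply(classes, function(cl) max(mean(y_train == cl), 1e-3), numeric(1)))
  } else 0  # regression heads are fit on standardized targets
  list(Wh = matrix(stats::rnorm(d * out, 0, 0.01), d, out),
       bh = matrix(b, 1, out))
}

# feature-wise standardization fitted once on the training embeddings of the
# initial (frozen) encoder; stored in the head and reapplied at prediction
fit_standardizer <- function(E) {
  mu <- colMeans(E)
  sd <- pmax(apply(E, 2, stats::sd), 1e-8)
  list(mu = mu, sd = sd)
}
apply_standardizer <- function(std, E) {
  sweep(sweep(E, 2, std$mu), 2, std$sd, "/")
}

head_logits <- function(params, E) add_rowvec(mm(E, params$Wh), params$bh)

predict_head <- function(head, E, task_type) {
  E <- apply_standardizer(head$std, unclass(E))
  L <- add_rowvec(E %*% head$Wh, as.numeric(head$bh))
  if (!is.null(head$y_scale)) L <- L * head$y_scale$sd + head$y_scale$mu
  if (task_type == "multiclass") {
    colnames(L) <- head$classes
    return(L)
  }
  as.numeric(L)
}

probe_report <- function(preds, y_test, task_type, mode, config) {
  metrics <- compute_metrics(preds, y_test, task_type)
  boot <- if (task_type == "regression") {
    list(r2 = bootstrap_eval(preds, y_test,
                             function(p, l) compute_metrics(p, l, "regression")$r2,
                             config$bootstrap_B, config$seed),
         rmse = bootstrap_eval(preds, y_test,
                               function(p, l) compute_metrics(p, l, "regression")$rmse,
                               config$bootstrap_B, config$seed))
  } else {
    list(auroc = bootstrap_eval(preds, y_test,
                                function(p, l) compute_metrics(p, l, task_type)$auroc_weighted,
                                config$bootstrap_B, config$seed),
         ap = bootstrap_eval(preds, y_test,
                             function(p, l) compute_metrics(p, l, task_type)$ap_weighted,
                             config$bootstrap_B, config$seed))
  }
  structure(list(mode = mode, task_type = task_type, metrics = metrics,
                 bootstrap = boot, n_test = length(y_test)),
            class = "probe_report")
}

#' Linear probe: train a single affine head on frozen embeddings
#'
#' The head is trained with the task loss (MSE / binary cross-entropy /
#' cross-entropy), AdamW, reduce-on-plateau, at most 100 epochs and early
#' stopping after `patience` non-improving validation epochs; the learning
#' rate is selected on validation loss over `config$lr_grid`. Test metrics
#' are bootstrapped.
#'
#' @param E_train,E_val,E_test n x d embedding matrices from a frozen encoder.
#' @param y_train,y_val,y_test aligned labels.
#' @param task_type `"regression"`, `"binary"` or `"multiclass"`.
#' @param config a [probe_config()].
#' @return list with `head` (affine weights and classes) and `report` (a
#'   `probe_report`).
#' @export
linear_probe <- function(E_train, y_train, E_val, y_val, E_test, y_test,
                         task_type = c("regression", "binary", "multiclass"),
                         config = probe_config()) {
  task_type <- match.arg(task_type)
  if (nrow(E_train) != length(y_train) || nrow(E_val) != length(y_val) ||
      nrow(E_test) != length(y_test)) {
    stop("embedding/label length mismatch")
  }
  E_train <- unclass(E_train); E_val <- unclass(E_val); E_test <- unclass(E_test)
  classes <- if (task_type == "multiclass") sort(unique(as.character(y_train))) else NULL
  out <- task_out_dim(task_type, classes)
  std <- fit_standardizer(E_train)
  Et <- apply_standardizer(std, E_train)
  Ev <- apply_standardizer(std, E_val)
  y_scale <- NULL
  yt <- y_train; yv <- y_val
  if (task_type == "regression") {
    y_scale <- list(mu = mean(y_train), sd = max(stats::sd(y_train), 1e-8))
    yt <- (y_train - y_scale$mu) / y_scale$sd
    yv <- (y_val - y_scale$mu) / y_scale$sd
  }
  best <- NULL; best_lr <- NA_real_
  for (lr in config$lr_grid) {
    params <- head_init(ncol(Et), out, config$seed + 101L, y_train,
                        task_type, classes)
    forward <- function(nodes, ix) {
      task_loss_node(head_logits(nodes, Et[ix, , drop = FALSE]),
                     yt[ix], task_type, classes)
    }
    val_fn <- function(p) {
      as.numeric(ad_value(task_loss_node(head_logits(p, Ev), yv,
                                         task_type, classes)))
    }
    fit <- train_supervised(params, forward, nrow(Et), val_fn, config, lr)
    if (is.null(best) || fit$val < best$val) {
      best <- fit; best_lr <- lr
    }
  }
  head <- list(Wh = best$params$Wh, bh = best$params$bh, classes = classes,
               task_type = task_type, lr = best_lr, std = std,
               y_scale = y_scale)
  preds <- predict_head(head, E_test, task_type)
  list(head = head,
       report = probe_report(preds, y_test, task_type, "linear_probe", config))
}

#' Fine-tune an encoder plus prediction head on a downstream task
#'
#' Same optimization protocol as [linear_probe()] with the encoder unfrozen;
#' `encoder_lr_scale` multiplies the selected learning rate for the encoder
#' parameters (0 freezes the encoder, reproducing the linear probe exactly).
#'
#' @param encoder a `retina_encoder`.
#' @param X_train,X_val,X_test flattened preprocessed inputs.
#' @param y_train,y_val,y_test aligned labels.
#' @param task_type task type.
#' @param config a [probe_config()].
#' @param encoder_lr_scale learning-rate multiplier for encoder weights.
#' @return list with `encoder` (updated), `head` and `report`.
#' @export
fine_tune <- function(encoder, X_train, y_train, X_val, y_val, X_test, y_test,
                      task_type = c("regression", "binary", "multiclass"),
                      config = probe_config(), encoder_lr_scale = 1) {
  task_type <- match.arg(task_type)
  if (nrow(X_train) != length(y_train)) stop("embedding/label length mismatch")
  classes <- if (task_type == "multiclass") sort(unique(as.character(y_train))) else NULL
  out <- task_out_dim(task_type, classes)
  enc_params <- prefix_params(encoder$params, "en")
  # standardization statistics are frozen from the initial encoder's train
  # embeddings (batch-norm-in-eval-mode convention), so an encoder learning
  # rate of 0 reproduces the linear probe exactly
  std <- fit_standardizer(encoder_forward(encoder$params, X_train))
  Dinv <- diag(1 / std$sd, length(std$sd))
  standardize_node <- function(E) mm(add_rowvec(E, matrix(-std$mu, nrow = 1)), Dinv)
  y_scale <- NULL
  yt <- y_train; yv <- y_val
  if (task_type == "regression") {
    y_scale <- list(mu = mean(y_train), sd = max(stats::sd(y_train), 1e-8))
    yt <- (y_train - y_scale$mu) / y_scale$sd
    yv <- (y_val - y_scale$mu) / y_scale$sd
  }
  best <- NULL; best_lr <- NA_real_
  for (lr in config$lr_grid) {
    hp <- head_init(encoder$embed_dim, out, config$seed + 101L, y_train,
                    task_type, classes)
    params <- c(enc_params, list(Wh = hp$Wh, bh = hp$bh))
    lr_scale <- stats::setNames(
      ifelse(startsWith(names(params), "en."), encoder_lr_scale, 1),
      names(params))
    forward <- function(nodes, ix) {
      E <- standardize_node(encoder_forward(unprefix_params(nodes, "en"),
                                            X_train[ix, , drop = FALSE]))
      task_loss_node(head_logits(nodes, E), yt[ix], task_type, classes)
    }
    val_fn <- function(p) {
      E <- standardize_node(encoder_forward(unprefix_params(p, "en"), X_val))
      as.numeric(ad_value(task_loss_node(head_logits(p, E), yv,
                                         task_type, classes)))
    }
    fit <- train_supervised(params, forward, nrow(X_train), val_fn, config,
                            lr, lr_scale)
    if (is.null(best) || fit$val < best$val) {
      best <- fit; best_lr <- lr
    }
  }
  encoder$params <- unprefix_params(best$params, "en")
  head <- list(Wh = best$params$Wh, bh = best$params$bh, classes = classes,
               task_type = task_type, lr = best_lr, std = std,
               y_scale = y_scale)
  E_test <- encoder_forward(encoder$params, X_test)
  preds <- predict_head(head, E_test, task_type)
  list(encoder = encoder, head = head,
       report = probe_report(preds, y_test, task_type, "fine_tune", config))
}

#' Modality interchange: feed fundus embeddings to an OCT-trained head
#'
#' Evaluates a linear head trained on OCT embeddings twice on the same test
#' labels: once with the OCT embeddings it was trained for (source) and once
#' with the paired fundus embeddings swapped in. Reports the relative decay
#' `(source - swapped) / source` of the primary metric.
#'
#' @param head head from [linear_probe()] trained on OCT embeddings.
#' @param E_oct_test,E_fundus_test paired test embeddings from the same
#'   multi-modal checkpoint.
#' @param y_test test labels.
#' @return an `interchange_report` list with `source`, `swapped`, `decay`.
#' @export
interchange_eval <- function(head, E_oct_test, E_fundus_test, y_test) {
  if (ncol(E_oct_test) != nrow(head$Wh) || ncol(E_fundus_test) != nrow(head$Wh)) {
    stop("embedding dimension does not match the head")
  }
  task_type <- head$task_type
  key <- if (task_type == "regression") "r2" else "auroc_weighted"
  src <- compute_metrics(predict_head(head, unclass(E_oct_test), task_type),
                         y_test, task_type)[[key]]
  swp <- compute_metrics(predict_head(head, unclass(E_fundus_test), task_type),
                         y_test, task_type)[[key]]
  structure(list(metric = key, source = src, swapped = swp,
                 decay = if (src > 0) (src - swp) / src else NA_real_),
            class = "interchange_report")
}
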