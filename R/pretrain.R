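# Pre-training loops: multi-modal CLIP (InfoNCE) and CLOOB (Hopfield +
# InfoLOOB) over paired fundus/OCT batches with one randomly selected pair
# per patient per epoch, and uni-modal SimCLR / BYOL / VICReg over augmented
# views. Single-process CPU, deterministic under the master seed.

#' Pre-training configuration
#'
#' @param objective one of `"clip"`, `"cloob"`, `"simclr"`, `"byol"`,
#'   `"vicreg"`.
#' @param epochs number of training epochs (shipping default 300; desk-scale
#'   runs use far fewer).
#' @param batch_size minibatch size; must be >= 2 for contrastive objectives.
#' @param lr AdamW learning rate (the paper searches `[1e-6, 1e-3]`; the
#'   default sits at the top of that interval, appropriate for small-batch
#'   desk-scale runs).
#' @param weight_decay AdamW decoupled weight decay (default 0.1).
#' @param embed_dim,hidden encoder sizes when encoders are built internally.
#' @param tau_init initial softmax temperature (0.07, the CLIP convention).
#' @param learnable_tau train the log-inverse-temperature (default TRUE).
#' @param max_inv_tau clamp on the inverse temperature (default 100).
#' @param hopfield_beta Hopfield inverse temperature for CLOOB training. The
#'   default (20) is sharper than the loss-level convention of 8: with
#'   desk-scale minibatches the retrieval softmax otherwise over-mixes the
#'   few stored patterns and the pair identity is lost.
#' @param proj_dim uni-modal projection head width (default 128).
#' @param ema_momentum BYOL target-network EMA momentum (default 0.996).
#' @param modality modality used by uni-modal objectives.
#' @param augment_policy [augmentation_policy()] for uni-modal view pairs
#'   (multi-modal pre-training uses no augmentation).
#' @param lr_schedule `"cosine"` (default; linear warmup then cosine decay,
#'   the OpenCLIP convention) or `"constant"`.
#' @param warmup_epochs warmup length for the cosine schedule.
#' @param seed master seed; every epoch's pair sampling and view draws derive
#'   from it.
#' @param checkpoint_path optional path; the final-epoch checkpoint is
#'   written there.
#' @return a `pretrain_config` list.
#' @export
pretrain_config <- function(objective = c("clip", "cloob", "simclr", "byol", "vicreg"),
                            epochs = 300, batch_size = 128, lr = 1e-3,
                            weight_decay = 0.1, embed_dim = 512, hidden = 64,
                            tau_init = 0.07, learnable_tau = TRUE,
                            max_inv_tau = 100, hopfield_beta = 20,
                            proj_dim = 128, ema_momentum = 0.996,
                            modality = c("oct3d", "fundus2d"),
                            augment_policy = augmentation_policy(),
                            lr_schedule = c("cosine", "constant"),
                            warmup_epochs = 3, seed = 1L,
                            checkpoint_path = NULL) {
  lr_schedule <- match.arg(lr_schedule)
  objective <- match.arg(objective)
  modality <- match.arg(modality)
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, tau_init > 0)
  contrastive <- objective %in% c("clip", "cloob", "simclr")
  if (contrastive && batch_size < 2) {
    stop("batch_size must be >= 2 for contrastive objectives")
  }
  structure(list(objective = objective, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay, embed_dim = as.integer(embed_dim),
                 hidden = as.integer(hidden), tau_init = tau_init,
                 learnable_tau = learnable_tau, max_inv_tau = max_inv_tau,
                 hopfield_beta = hopfield_beta, proj_dim = as.integer(proj_dim),
                 ema_momentum = ema_momentum, modality = modality,
                 augment_policy = augment_policy,
                 lr_schedule = lr_schedule,
                 warmup_epochs = as.integer(warmup_epochs),
                 seed = as.integer(seed),
                 checkpoint_path = checkpoint_path),
            class = "pretrain_config")
}

# split param list into prefixed named list and back (for joint optimization)
prefix_params <- function(params, prefix) {
  stats::setNames(params, paste0(prefix, ".", names(params)))
}
unprefix_params <- function(params, prefix) {
  sel <- startsWith(names(params), paste0(prefix, "."))
  stats::setNames(params[sel], sub(paste0("^", prefix, "\\."), "", names(params)[sel]))
}

tau_from_logit <- function(logit, max_inv) 1 / min(exp(logit), max_inv)

# per-epoch learning-rate factor: linear warmup then cosine decay to zero
schedule_factor <- function(config, epoch) {
  if (config$lr_schedule == "constant") return(1)
  w <- config$warmup_epochs
  if (epoch <= w) return(epoch / max(w, 1))
  prog <- (epoch - w) / max(config$epochs - w, 1)
  0.5 * (1 + cos(pi * prog))
}

# numeric multi-modal loss for validation tracking
mm_loss_value <- function(objective, Ex, Ey, tau, beta) {
  if (objective == "clip") {
    info_nce(similarity_matrix(Ex, Ey), tau)
  } else {
    cloob_loss(Ex, Ey, tau, beta)
  }
}

#' Contrastive pre-training
#'
#' Multi-modal objectives (`clip`, `cloob`) train the fundus and OCT encoders
#' jointly on one randomly selected pair per patient per epoch; uni-modal
#' objectives (`simclr`, `byol`, `vicreg`) train one encoder plus a
#' projection head on two augmented views per sample. Tracks per-epoch train
#' and validation losses (and validation top-1 retrieval for multi-modal
#' runs) and returns the final-epoch weights as the checkpoint.
#'
#' @param cohort a `retina_cohort` (or list of `paired_scan`).
#' @param split a `split_assignment` over the cohort's patients.
#' @param config a [pretrain_config()].
#' @param preprocess a [preprocess_config()]; applied once to every scan.
#' @param encoders optional list(x =, y =) of pre-built `retina_encoder`s
#'   (e.g. to continue training); built internally when NULL.
#' @return a `pretrain_checkpoint` list: trained encoder(s), temperature,
#'   config, and `history` (data.frame, one row per epoch). Written to
#'   `config$checkpoint_path` when set.
#' @export
pretrain <- function(cohort, split, config,
                     preprocess = preprocess_config(), encoders = NULL) {
  stopifnot(inherits(config, "pretrain_config"))
  man <- cohort_manifest(cohort)
  sp <- split_of(split, man)
  train_ix <- which(sp == "train")
  val_ix <- which(sp == "val")
  if (length(train_ix) == 0) stop("train split is empty")
  if (config$objective %in% c("clip", "cloob")) {
    pretrain_multimodal(cohort, train_ix, val_ix, config, preprocess, encoders)
  } else {
    pretrain_unimodal(cohort, train_ix, val_ix, config, preprocess, encoders)
  }
}

pretrain_multimodal <- function(cohort, train_ix, val_ix, config, preprocess,
                                encoders) {
  pre <- preprocess_cohort(cohort, preprocess)
  X <- pre$X; Y <- pre$Y
  if (is.null(encoders)) {
    encoders <- list(
      x = make_encoder("fundus2d", ncol(X), config$embed_dim, config$hidden,
                       seed = config$seed + 11L),
      y = make_encoder("oct3d", ncol(Y), config$embed_dim, config$hidden,
                       seed = config$seed + 13L))
  }
  params <- c(prefix_params(encoders$x$params, "ex"),
              prefix_params(encoders$y$params, "ey"))
  logit_tau <- log(1 / config$tau_init)
  if (config$learnable_tau) params$tlogit <- matrix(logit_tau, 1, 1)
  opt <- adamw_init(params)
  train_rec <- cohort[train_ix]
  val_rec <- if (length(val_ix)) cohort[val_ix] else NULL
  val_pairs <- if (length(val_ix)) val_ix[epoch_pairs(val_rec, config$seed)] else integer(0)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_top1 = numeric(0))
  for (ep in seq_len(config$epochs)) {
    epoch_seed <- config$seed + 7919L * ep
    pair_ix <- train_ix[epoch_pairs(train_rec, epoch_seed)]
    set.seed(epoch_seed + 1L)
    pair_ix <- sample(pair_ix)
    chunks <- split(pair_ix, ceiling(seq_along(pair_ix) / config$batch_size))
    ep_losses <- c()
    for (ch in chunks) {
      if (length(ch) < 2L) next
      nodes <- lapply(params, ad_param)
      Ex <- rownorm2(encoder_forward(unprefix_params(nodes, "ex"), X[ch, , drop = FALSE]))
      Ey <- rownorm2(encoder_forward(unprefix_params(nodes, "ey"), Y[ch, , drop = FALSE]))
      tau <- if (config$learnable_tau) {
        divide(1, expn(nodes$tlogit))
      } else {
        config$tau_init
      }
      loss <- if (config$objective == "clip") {
        info_nce(similarity_matrix(Ex, Ey), tau)
      } else {
        cloob_loss(Ex, Ey, tau, config$hopfield_beta)
      }
      ad_backward(loss)
      grads <- lapply(nodes, ad_grad)
      step <- adamw_step(params, grads, opt,
                         config$lr * schedule_factor(config, ep),
                         weight_decay = config$weight_decay)
      params <- step$params
      opt <- step$state
      if (config$learnable_tau) {
        params$tlogit[1, 1] <- min(params$tlogit[1, 1], log(config$max_inv_tau))
      }
      ep_losses <- c(ep_losses, as.numeric(ad_value(loss)))
    }
    tau_val <- if (config$learnable_tau) {
      tau_from_logit(params$tlogit[1, 1], config$max_inv_tau)
    } else {
      config$tau_init
    }
    px <- unprefix_params(params, "ex")
    py <- unprefix_params(params, "ey")
    if (length(val_pairs) >= 2) {
      Exv <- rownorm2(encoder_forward(px, X[val_pairs, , drop = FALSE]))
      Eyv <- rownorm2(encoder_forward(py, Y[val_pairs, , drop = FALSE]))
      vl <- as.numeric(mm_loss_value(config$objective, Exv, Eyv, tau_val,
                                     config$hopfield_beta))
      S <- Exv %*% t(Eyv)
      vt1 <- mean(c(topk_accuracy(S, 1, "fundus_to_oct"),
                    topk_accuracy(S, 1, "oct_to_fundus")))
    } else {
      vl <- NA_real_; vt1 <- NA_real_
    }
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = mean(ep_losses),
                                         val_loss = vl, val_top1 = vt1))
  }
  encoders$x$params <- unprefix_params(params, "ex")
  encoders$y$params <- unprefix_params(params, "ey")
  ckpt <- structure(list(objective = config$objective,
                         encoder_x = encoders$x, encoder_y = encoders$y,
                         tau = if (config$learnable_tau) {
                           tau_from_logit(params$tlogit[1, 1], config$max_inv_tau)
                         } else config$tau_init,
                         config = config, preprocess = preprocess,
                         history = history, seed = config$seed),
                    class = "pretrain_checkpoint")
  if (!is.null(config$checkpoint_path)) save_checkpoint(ckpt, config$checkpoint_path)
  ckpt
}

# preprocessed (un-flattened) arrays for one modality
preprocessed_arrays <- function(cohort, preprocess, modality) {
  lapply(cohort, function(s) {
    if (modality == "fundus2d") preprocess_fundus(s$fundus, preprocess)
    else preprocess_volume(s$oct, preprocess)
  })
}

pretrain_unimodal <- function(cohort, train_ix, val_ix, config, preprocess,
                              encoders) {
  arrays <- preprocessed_arrays(cohort, preprocess, config$modality)
  input_dim <- length(arrays[[train_ix[1]]])
  enc <- if (!is.null(encoders)) encoders else {
    make_encoder(config$modality, input_dim, config$embed_dim, config$hidden,
                 seed = config$seed + 17L)
  }
  head <- make_projection_head(config$embed_dim, config$proj_dim,
                               seed = config$seed + 19L)
  params <- c(prefix_params(enc$params, "en"), prefix_params(head$params, "ph"))
  is_byol <- config$objective == "byol"
  if (is_byol) {
    pred <- make_projection_head(config$proj_dim, config$proj_dim,
                                 seed = config$seed + 23L)
    params <- c(params, prefix_params(pred$params, "pr"))
    target <- params[startsWith(names(params), "en.") | startsWith(names(params), "ph.")]
  }
  opt <- adamw_init(params)
  train_rec <- cohort[train_ix]
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  views_of <- function(ix, seed0) {
    V1 <- matrix(0, length(ix), input_dim)
    V2 <- matrix(0, length(ix), input_dim)
    for (i in seq_along(ix)) {
      V1[i, ] <- as.numeric(augment(arrays[[ix[i]]], config$augment_policy,
                                    seed = seed0 + 2L * i))
      V2[i, ] <- as.numeric(augment(arrays[[ix[i]]], config$augment_policy,
                                    seed = seed0 + 2L * i + 1L))
    }
    list(V1 = V1, V2 = V2)
  }
  unimodal_loss <- function(p, V1, V2) {
    enc_p <- unprefix_params(p, "en")
    head_p <- list(params = unprefix_params(p, "ph"),
                   input_dim = config$embed_dim, out_dim = config$proj_dim)
    Z1 <- project(encoder_forward(enc_p, V1), head_p)
    Z2 <- project(encoder_forward(enc_p, V2), head_p)
    if (config$objective == "simclr") return(nt_xent(Z1, Z2, config$tau_init))
    if (config$objective == "vicreg") return(vicreg_loss(Z1, Z2))
    # byol: online predictions vs detached target projections, symmetrized
    pred_p <- list(params = unprefix_params(p, "pr"),
                   input_dim = config$proj_dim, out_dim = config$proj_dim)
    te <- unprefix_params(target, "en")
    th <- list(params = unprefix_params(target, "ph"),
               input_dim = config$embed_dim, out_dim = config$proj_dim)
    T1 <- project(encoder_forward(te, V1), th)
    T2 <- project(encoder_forward(te, V2), th)
    times(plus(byol_loss(project(Z1, pred_p), T2),
               byol_loss(project(Z2, pred_p), T1)), 0.5)
  }
  for (ep in seq_len(config$epochs)) {
    epoch_seed <- config$seed + 104729L * ep
    pair_ix <- train_ix[epoch_pairs(train_rec, epoch_seed)]
    set.seed(epoch_seed + 1L)
    pair_ix <- sample(pair_ix)
    chunks <- split(pair_ix, ceiling(seq_along(pair_ix) / config$batch_size))
    ep_losses <- c()
    off <- 0L
    for (ch in chunks) {
      if (config$objective != "byol" && length(ch) < 2L) next
      vw <- views_of(ch, epoch_seed + 100L + off)
      off <- off + 2L * length(ch) + 2L
      nodes <- lapply(params, ad_param)
      loss <- unimodal_loss(nodes, vw$V1, vw$V2)
      ad_backward(loss)
      grads <- lapply(nodes, ad_grad)
      step <- adamw_step(params, grads, opt,
                         config$lr * schedule_factor(config, ep),
                         weight_decay = config$weight_decay)
      params <- step$params
      opt <- step$state
      if (is_byol) {
        m <- config$ema_momentum
        for (nm in names(target)) {
          target[[nm]] <- m * target[[nm]] + (1 - m) * params[[nm]]
        }
      }
      ep_losses <- c(ep_losses, as.numeric(ad_value(loss)))
    }
    vl <- NA_real_
    if (length(val_ix) >= 2) {
      vw <- views_of(val_ix, config$seed + 31L)
      vl <- as.numeric(ad_value(unimodal_loss(params, vw$V1, vw$V2)))
    }
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = mean(ep_losses),
                                         val_loss = vl))
  }
  enc$params <- unprefix_params(params, "en")
  head$params <- unprefix_params(params, "ph")
  ckpt <- structure(list(objective = config$objective, encoder = enc,
                         projection_head = head,
                         target_params = if (is_byol) target else NULL,
                         config = config, preprocess = preprocess,
                         history = history, seed = config$seed),
                    class = "pretrain_checkpoint")
  if (!is.null(config$checkpoint_path)) save_checkpoint(ckpt, config$checkpoint_path)
  ckpt
}

#' Select a learning rate on validation loss over a small grid
#'
#' Runs short pre-training at each candidate within the search interval and
#' returns the rate with the lowest final validation loss.
#'
#' @param cohort,split,config,preprocess as in [pretrain()].
#' @param lrs candidate learning rates (default `1e-5, 1e-4, 1e-3`).
#' @param epochs short-run epoch budget per candidate.
#' @return list with `lr` (the selection) and `val_loss` per candidate.
#' @export
select_lr <- function(cohort, split, config, preprocess = preprocess_config(),
                      lrs = c(1e-5, 1e-4, 1e-3), epochs = 5) {
  vals <- vapply(lrs, function(lr) {
    cfg <- config
    cfg$lr <- lr
    cfg$epochs <- as.integer(epochs)
    cfg$checkpoint_path <- NULL
    ck <- pretrain(cohort, split, cfg, preprocess)
    utils::tail(ck$history$val_loss, 1)
  }, numeric(1))
  list(lr = lrs[which.min(vals)], val_loss = stats::setNames(vals, lrs))
}
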