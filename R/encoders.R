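# Encoder contracts: h^x maps preprocessed 2D fundus images and h^y maps
# preprocessed 3D OCT volumes into a shared d-dimensional embedding space.
# The shipped backbones are small dense stacks over the flattened
# preprocessed grids, trainable end-to-end on one CPU; the embedding
# interface (not the architecture) is the tested contract. The full-scale
# ResNet18/VideoResNet18 backbones with pretrained weights are not available
# in this implementation and are rejected with an informative error.

#' Encoder configuration and construction
#'
#' Builds a seeded, randomly initialized encoder for one modality. `tiny`
#' (the default) is a two-layer dense stack `input -> hidden -> relu ->
#' embed_dim`; weights use He-scaled Gaussian initialization.
#'
#' @param modality `"fundus2d"` or `"oct3d"` (tag only; both consume
#'   flattened feature rows).
#' @param input_dim number of flattened input features (e.g. 224*224 for the
#'   default fundus pipeline, 20*224*224 for volumes).
#' @param embed_dim embedding dimension d (shipping default 512; tests use
#'   smaller). Must be >= 2.
#' @param hidden hidden layer width.
#' @param backbone `"tiny"`; `"paper_default"` (ResNet18/VideoResNet18 with
#'   pretrained weights) is not available and errors.
#' @param seed integer seed for the initialization.
#' @return a `retina_encoder` list with `$params` (named matrices).
#' @export
make_encoder <- function(modality = c("fundus2d", "oct3d"), input_dim,
                         embed_dim = 512, hidden = 64,
                         backbone = c("tiny", "paper_default"), seed = 1L) {
  modality <- match.arg(modality)
  backbone <- match.arg(backbone)
  if (backbone == "paper_default") {
    stop("backbone 'paper_default' (pretrained ResNet18/VideoResNet18) is not ",
         "available; use backbone = 'tiny'")
  }
  stopifnot(input_dim >= 1, embed_dim >= 2, hidden >= 1)
  set.seed(seed)
  params <- list(
    W1 = matrix(stats::rnorm(input_dim * hidden, 0, sqrt(2 / input_dim)),
                input_dim, hidden),
    b1 = matrix(0, 1, hidden),
    W2 = matrix(stats::rnorm(hidden * embed_dim, 0, sqrt(2 / hidden)),
                hidden, embed_dim),
    b2 = matrix(0, 1, embed_dim)
  )
  structure(list(params = params, modality = modality,
                 input_dim = as.integer(input_dim),
                 embed_dim = as.integer(embed_dim),
                 hidden = as.integer(hidden),
                 backbone = backbone, seed = as.integer(seed)),
            class = "retina_encoder")
}

# forward pass; params may be plain matrices or advar nodes
encoder_forward <- function(params, X) {
  H <- relu(add_rowvec(mm(X, params$W1), params$b1))
  add_rowvec(mm(H, params$W2), params$b2)
}

#' Construct an embedding matrix object
#'
#' @param values n x d numeric matrix.
#' @param modality modality tag.
#' @param l2_normalized whether rows were l2-normalized.
#' @param ids optional row identifiers aligned to manifest rows.
#' @return `embedding_matrix` (a matrix with metadata attributes).
#' @export
embedding_matrix <- function(values, modality = "unknown",
                             l2_normalized = FALSE, ids = NULL) {
  stopifnot(is.matrix(values))
  structure(values, modality = modality, l2_normalized = l2_normalized,
            ids = ids, class = c("embedding_matrix", class(values)))
}

#' Embed a batch of preprocessed samples
#'
#' Deterministic (evaluation-mode) forward pass producing an n x d
#' [embedding_matrix()]; rows are l2-normalized when requested (the
#' convention before all contrastive losses and retrieval).
#'
#' @param batch n x input_dim matrix of flattened preprocessed samples, or a
#'   list of arrays that are flattened row-wise.
#' @param encoder a `retina_encoder`.
#' @param normalize l2-normalize rows (default TRUE).
#' @param ids optional row identifiers.
#' @return an [embedding_matrix()].
#' @export
embed <- function(batch, encoder, normalize = TRUE, ids = NULL) {
  if (is.list(batch)) {
    batch <- do.call(rbind, lapply(batch, as.numeric))
  }
  stopifnot(is.matrix(batch))
  if (ncol(batch) != encoder$input_dim) {
    stop(sprintf("embed: expected %d input features for modality '%s', got %d",
                 encoder$input_dim, encoder$modality, ncol(batch)))
  }
  E <- encoder_forward(encoder$params, batch)
  if (normalize) E <- rownorm2(E)
  embedding_matrix(E, modality = encoder$modality,
                   l2_normalized = normalize, ids = ids)
}

#' Seeded affine projection head (uni-modal pre-training only)
#'
#' The 128-dimensional linear layer placed on top of the encoder during
#' uni-modal self-supervised pre-training and discarded afterwards.
#'
#' @param input_dim encoder embedding dimension d.
#' @param out_dim projection dimension (default 128).
#' @param seed integer seed.
#' @return a `projection_head` list with `$params`.
#' @export
make_projection_head <- function(input_dim, out_dim = 128, seed = 1L) {
  set.seed(seed)
  structure(list(params = list(
    Wp = matrix(stats::rnorm(input_dim * out_dim, 0, sqrt(1 / input_dim)),
                input_dim, out_dim),
    bp = matrix(0, 1, out_dim)
  ), input_dim = as.integer(input_dim), out_dim = as.integer(out_dim)),
  class = "projection_head")
}

#' Apply a projection head to embeddings
#'
#' @param embeddings n x d matrix (or `advar`).
#' @param head a [make_projection_head()].
#' @return n x out_dim matrix (or `advar`).
#' @export
project <- function(embeddings, head) {
  E <- if (is_advar(embeddings)) ad_value(embeddings) else embeddings
  if (ncol(E) != head$input_dim) {
    stop(sprintf("project: head expects %d-dimensional embeddings, got %d",
                 head$input_dim, ncol(E)))
  }
  add_rowvec(mm(embeddings, head$params$Wp), head$params$bp)
}

#' Save / load a checkpoint (weights + config + seed)
#'
#' @param object any serializable checkpoint list.
#' @param path file path.
#' @return `load_checkpoint` returns the object; `save_checkpoint` the path,
#'   invisibly.
#' @export
save_checkpoint <- function(object, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Parameter count of an encoder or head
#' @param object `retina_encoder` or `projection_head`.
#' @return integer number of trainable scalars.
#' @export
n_parameters <- function(object) {
  sum(vapply(object$params, length, integer(1)))
}
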