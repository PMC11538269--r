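# Reverse-mode automatic differentiation over dense matrices.
#
# Every differentiable quantity is an `advar`: an environment holding a matrix
# value, its parent nodes and one vector-Jacobian-product closure per parent.
# The same operation generics have plain-matrix default methods, so loss
# functions written against these generics evaluate numerically when given
# matrices and build a gradient tape when given advars.

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0L

as_matrix1 <- function(x) if (is.matrix(x)) x else matrix(x, 1L, 1L)

# drop 1x1 matrices to scalars so R's recycling rules apply in elementwise ops
scal <- function(x) if (length(x) == 1L) as.numeric(x) else x

new_advar <- function(value, parents = list(), vjps = list(),
                      is_leaf = TRUE, requires = TRUE) {
  node <- new.env(parent = emptyenv())
  .ad$counter <- .ad$counter + 1L
  node$idx <- .ad$counter
  node$value <- as_matrix1(value)
  node$parents <- parents
  node$vjps <- vjps
  node$is_leaf <- is_leaf
  node$requires <- requires
  node$grad <- NULL
  class(node) <- "advar"
  node
}

#' Create a trainable autodiff parameter
#'
#' Wraps a numeric matrix as a leaf node of the gradient tape. After
#' [ad_backward()] the accumulated gradient is available via [ad_grad()].
#'
#' @param value numeric matrix (scalars are promoted to 1x1 matrices).
#' @return an `advar` node.
#' @export
ad_param <- function(value) new_advar(value, is_leaf = TRUE, requires = TRUE)

#' Wrap a constant (non-trainable) matrix for the gradient tape
#' @param value numeric matrix.
#' @return an `advar` node that receives no gradient.
#' @export
ad_const <- function(value) new_advar(value, is_leaf = TRUE, requires = FALSE)

is_advar <- function(x) inherits(x, "advar")

ad_wrap <- function(x) if (is_advar(x)) x else ad_const(x)

#' Numeric value of an autodiff node (or passthrough for matrices)
#' @param x `advar` or matrix.
#' @return numeric matrix.
#' @export
ad_value <- function(x) if (is_advar(x)) x$value else as_matrix1(x)

#' Gradient accumulated on a parameter by the last [ad_backward()] call
#' @param x `advar` created with [ad_param()].
#' @return numeric matrix of the same shape as the parameter.
#' @export
ad_grad <- function(x) {
  stopifnot(is_advar(x))
  if (is.null(x$grad)) matrix(0, nrow(x$value), ncol(x$value)) else x$grad
}

ad_op <- function(value, parents, vjps) {
  parents <- lapply(parents, ad_wrap)
  req <- any(vapply(parents, function(p) isTRUE(p$requires), logical(1)))
  new_advar(value, parents, vjps, is_leaf = FALSE, requires = req)
}

# collapse a broadcast gradient back onto a 1x1 operand
reduce_grad <- function(G, dims) {
  if (prod(dims) == 1L && length(G) > 1L) matrix(sum(G), 1L, 1L) else as_matrix1(G)
}

#' Backpropagate from a scalar loss node
#'
#' Walks the tape in reverse topological order and deposits gradients on every
#' reachable [ad_param()] leaf.
#'
#' @param root `advar` holding a 1x1 value.
#' @return invisibly, the root node.
#' @export
ad_backward <- function(root) {
  stopifnot(is_advar(root), length(root$value) == 1L)
  registry <- new.env(parent = emptyenv())
  stack <- list(root)
  while (length(stack) > 0L) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$idx)
    if (!is.null(registry[[key]])) next
    registry[[key]] <- nd
    for (p in nd$parents) if (is_advar(p) && isTRUE(p$requires)) {
      stack[[length(stack) + 1L]] <- p
    }
  }
  keys <- ls(registry)
  ord <- order(as.integer(keys), decreasing = TRUE)
  grads <- new.env(parent = emptyenv())
  grads[[as.character(root$idx)]] <- matrix(1, 1L, 1L)
  for (key in keys[ord]) {
    nd <- registry[[key]]
    G <- grads[[key]]
    if (is.null(G)) next
    if (nd$is_leaf) {
      if (isTRUE(nd$requires)) nd$grad <- G
      next
    }
    for (i in seq_along(nd$parents)) {
      p <- nd$parents[[i]]
      if (!isTRUE(p$requires)) next
      g <- nd$vjps[[i]](G)
      pk <- as.character(p$idx)
      grads[[pk]] <- if (is.null(grads[[pk]])) g else grads[[pk]] + g
    }
  }
  invisible(root)
}

## ---- operation generics ---------------------------------------------------

#' Autodiff-aware matrix operations
#'
#' Generics with plain-matrix default methods and tape-building `advar`
#' methods, so one implementation of a loss serves numeric evaluation and
#' gradient-based training alike. `mm` is matrix product, `transp` transpose,
#' `plus`/`minus`/`times`/`divide` elementwise arithmetic (1x1 operands
#' broadcast), `expn`/`logn`/`sqrtn`/`relu` elementwise maps, `sumn`/`meann`
#' full reductions, `rowsums`/`colmeans` partial reductions, `diagpart` the
#' main diagonal as a column, `rownorm2` row-wise l2 normalization,
#' `softmax_rows`/`logsumexp_rows` row-wise softmax and log-sum-exp,
#' `logsumexp_offdiag_rows` the same excluding the diagonal entry,
#' `add_rowvec` adds a 1xp row vector to every row, and `vconcat` stacks rows.
#'
#' @param a,b,v operands: numeric matrices or `advar` nodes.
#' @return a matrix (numeric inputs) or an `advar` node.
#' @name ad-ops
NULL

#' @rdname ad-ops
#' @export
mm <- function(a, b) UseMethod("mm")
#' @export
mm.default <- function(a, b) if (is_advar(b)) ad_mm(a, b) else a %*% b
#' @export
mm.advar <- function(a, b) ad_mm(a, b)
ad_mm <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ad_op(A %*% B, list(a, b),
        list(function(G) G %*% t(B), function(G) t(A) %*% G))
}

#' @rdname ad-ops
#' @export
transp <- function(a) UseMethod("transp")
#' @export
transp.default <- function(a) t(a)
#' @export
transp.advar <- function(a) {
  ad_op(t(ad_value(a)), list(a), list(function(G) t(G)))
}

binary_vals <- function(a, b) list(A = ad_value(a), B = ad_value(b))

#' @rdname ad-ops
#' @export
plus <- function(a, b) UseMethod("plus")
#' @export
plus.default <- function(a, b) if (is_advar(b)) ad_plus(a, b) else scal(a) + scal(b)
#' @export
plus.advar <- function(a, b) ad_plus(a, b)
ad_plus <- function(a, b) {
  v <- binary_vals(a, b)
  ad_op(scal(v$A) + scal(v$B), list(a, b),
        list(function(G) reduce_grad(G, dim(v$A)),
             function(G) reduce_grad(G, dim(v$B))))
}

#' @rdname ad-ops
#' @export
minus <- function(a, b) UseMethod("minus")
#' @export
minus.default <- function(a, b) if (is_advar(b)) ad_minus(a, b) else scal(a) - scal(b)
#' @export
minus.advar <- function(a, b) ad_minus(a, b)
ad_minus <- function(a, b) {
  v <- binary_vals(a, b)
  ad_op(scal(v$A) - scal(v$B), list(a, b),
        list(function(G) reduce_grad(G, dim(v$A)),
             function(G) reduce_grad(-G, dim(v$B))))
}

#' @rdname ad-ops
#' @export
times <- function(a, b) UseMethod("times")
#' @export
times.default <- function(a, b) if (is_advar(b)) ad_times(a, b) else scal(a) * scal(b)
#' @export
times.advar <- function(a, b) ad_times(a, b)
ad_times <- function(a, b) {
  v <- binary_vals(a, b)
  ad_op(scal(v$A) * scal(v$B), list(a, b),
        list(function(G) reduce_grad(G * scal(v$B), dim(v$A)),
             function(G) reduce_grad(G * scal(v$A), dim(v$B))))
}

#' @rdname ad-ops
#' @export
divide <- function(a, b) UseMethod("divide")
#' @export
divide.default <- function(a, b) if (is_advar(b)) ad_divide(a, b) else scal(a) / scal(b)
#' @export
divide.advar <- function(a, b) ad_divide(a, b)
ad_divide <- function(a, b) {
  v <- binary_vals(a, b)
  ad_op(scal(v$A) / scal(v$B), list(a, b),
        list(function(G) reduce_grad(G / scal(v$B), dim(v$A)),
             function(G) reduce_grad(-G * scal(v$A) / scal(v$B)^2, dim(v$B))))
}

unary_op <- function(a, fval, fgrad) {
  A <- ad_value(a)
  V <- fval(A)
  ad_op(V, list(a), list(function(G) fgrad(G, A, V)))
}

#' @rdname ad-ops
#' @export
expn <- function(a) UseMethod("expn")
#' @export
expn.default <- function(a) exp(a)
#' @export
expn.advar <- function(a) unary_op(a, exp, function(G, A, V) G * V)

#' @rdname ad-ops
#' @export
logn <- function(a) UseMethod("logn")
#' @export
logn.default <- function(a) log(a)
#' @export
logn.advar <- function(a) unary_op(a, log, function(G, A, V) G / A)

#' @rdname ad-ops
#' @export
sqrtn <- function(a) UseMethod("sqrtn")
#' @export
sqrtn.default <- function(a) sqrt(a)
#' @export
sqrtn.advar <- function(a) unary_op(a, sqrt, function(G, A, V) G / (2 * V))

#' @rdname ad-ops
#' @export
relu <- function(a) UseMethod("relu")
#' @export
relu.default <- function(a) pmax(a, 0)
#' @export
relu.advar <- function(a) unary_op(a, function(A) pmax(A, 0),
                                   function(G, A, V) G * (A > 0))

#' @rdname ad-ops
#' @export
sumn <- function(a) UseMethod("sumn")
#' @export
sumn.default <- function(a) sum(a)
#' @export
sumn.advar <- function(a) {
  A <- ad_value(a)
  ad_op(sum(A), list(a),
        list(function(G) matrix(as.numeric(G), nrow(A), ncol(A))))
}

#' @rdname ad-ops
#' @export
meann <- function(a) UseMethod("meann")
#' @export
meann.default <- function(a) mean(a)
#' @export
meann.advar <- function(a) {
  A <- ad_value(a)
  ad_op(mean(A), list(a),
        list(function(G) matrix(as.numeric(G) / length(A), nrow(A), ncol(A))))
}

#' @rdname ad-ops
#' @export
rowsums <- function(a) UseMethod("rowsums")
#' @export
rowsums.default <- function(a) matrix(rowSums(a), ncol = 1L)
#' @export
rowsums.advar <- function(a) {
  A <- ad_value(a)
  ad_op(matrix(rowSums(A), ncol = 1L), list(a),
        list(function(G) matrix(G, nrow(A), ncol(A))))
}

#' @rdname ad-ops
#' @export
colmeans <- function(a) UseMethod("colmeans")
#' @export
colmeans.default <- function(a) matrix(colMeans(a), nrow = 1L)
#' @export
colmeans.advar <- function(a) {
  A <- ad_value(a)
  n <- nrow(A)
  ad_op(matrix(colMeans(A), nrow = 1L), list(a),
        list(function(G) matrix(1, n, 1L) %*% G / n))
}

#' @rdname ad-ops
#' @export
diagpart <- function(a) UseMethod("diagpart")
#' @export
diagpart.default <- function(a) matrix(diag(a), ncol = 1L)
#' @export
diagpart.advar <- function(a) {
  A <- ad_value(a)
  stopifnot(nrow(A) == ncol(A))
  ad_op(matrix(diag(A), ncol = 1L), list(a),
        list(function(G) {
          D <- matrix(0, nrow(A), ncol(A))
          diag(D) <- G
          D
        }))
}

row_l2norms <- function(A) pmax(sqrt(rowSums(A^2)), 1e-12)

#' @rdname ad-ops
#' @export
rownorm2 <- function(a) UseMethod("rownorm2")
#' @export
rownorm2.default <- function(a) a / row_l2norms(a)
#' @export
rownorm2.advar <- function(a) {
  A <- ad_value(a)
  r <- row_l2norms(A)
  V <- A / r
  ad_op(V, list(a),
        list(function(G) (G - V * rowSums(G * V)) / r))
}

row_softmax <- function(A) {
  m <- apply(A, 1L, max)
  E <- exp(A - m)
  E / rowSums(E)
}

#' @rdname ad-ops
#' @export
softmax_rows <- function(a) UseMethod("softmax_rows")
#' @export
softmax_rows.default <- function(a) row_softmax(a)
#' @export
softmax_rows.advar <- function(a) {
  A <- ad_value(a)
  P <- row_softmax(A)
  ad_op(P, list(a),
        list(function(G) P * (G - rowSums(G * P))))
}

row_logsumexp <- function(A) {
  m <- apply(A, 1L, max)
  m + log(rowSums(exp(A - m)))
}

#' @rdname ad-ops
#' @export
logsumexp_rows <- function(a) UseMethod("logsumexp_rows")
#' @export
logsumexp_rows.default <- function(a) matrix(row_logsumexp(a), ncol = 1L)
#' @export
logsumexp_rows.advar <- function(a) {
  A <- ad_value(a)
  v <- row_logsumexp(A)
  P <- exp(A - v)
  ad_op(matrix(v, ncol = 1L), list(a),
        list(function(G) P * as.numeric(G)))
}

offdiag_lse_vals <- function(A) {
  stopifnot(nrow(A) == ncol(A))
  B <- A
  diag(B) <- -Inf
  row_logsumexp(B)
}

#' @rdname ad-ops
#' @export
logsumexp_offdiag_rows <- function(a) UseMethod("logsumexp_offdiag_rows")
#' @export
logsumexp_offdiag_rows.default <- function(a) matrix(offdiag_lse_vals(a), ncol = 1L)
#' @export
logsumexp_offdiag_rows.advar <- function(a) {
  A <- ad_value(a)
  v <- offdiag_lse_vals(A)
  B <- A
  diag(B) <- -Inf
  P <- exp(B - v)  # softmax over off-diagonal entries; exp(-Inf) zeroes the diagonal
  ad_op(matrix(v, ncol = 1L), list(a),
        list(function(G) P * as.numeric(G)))
}

#' @rdname ad-ops
#' @export
add_rowvec <- function(a, v) UseMethod("add_rowvec")
#' @export
add_rowvec.default <- function(a, v) {
  if (is_advar(v)) return(ad_add_rowvec(a, v))
  sweep(a, 2L, as.numeric(v), "+")
}
#' @export
add_rowvec.advar <- function(a, v) ad_add_rowvec(a, v)
ad_add_rowvec <- function(a, v) {
  A <- ad_value(a); B <- ad_value(v)
  stopifnot(nrow(B) == 1L, ncol(B) == ncol(A))
  ad_op(sweep(A, 2L, as.numeric(B), "+"), list(a, v),
        list(function(G) G,
             function(G) matrix(colSums(G), nrow = 1L)))
}

#' @rdname ad-ops
#' @export
vconcat <- function(a, b) UseMethod("vconcat")
#' @export
vconcat.default <- function(a, b) if (is_advar(b)) ad_vconcat(a, b) else rbind(a, b)
#' @export
vconcat.advar <- function(a, b) ad_vconcat(a, b)
ad_vconcat <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  na <- nrow(A)
  ad_op(rbind(A, B), list(a, b),
        list(function(G) G[seq_len(na), , drop = FALSE],
             function(G) G[-seq_len(na), , drop = FALSE]))
}

## ---- finite-difference gradient check -------------------------------------

#' Finite-difference gradient of a scalar function of named matrix parameters
#'
#' Central differences; used in tests to validate the tape against an
#' independent numerical derivative.
#'
#' @param fn function taking a named list of matrices, returning a scalar.
#' @param params named list of numeric matrices.
#' @param h step size.
#' @return named list of gradient matrices.
#' @export
numeric_gradient <- function(fn, params, h = 1e-5) {
  out <- params
  for (nm in names(params)) {
    P <- params[[nm]]
    G <- matrix(0, nrow(P), ncol(P))
    for (i in seq_along(P)) {
      pp <- params; pm <- params
      pp[[nm]][i] <- pp[[nm]][i] + h
      pm[[nm]][i] <- pm[[nm]][i] - h
      G[i] <- (fn(pp) - fn(pm)) / (2 * h)
    }
    out[[nm]] <- G
  }
  out
}

## ---- AdamW ----------------------------------------------------------------

#' Initialize AdamW optimizer state for a named list of parameter matrices
#' @param params named list of numeric matrices.
#' @return optimizer state list.
#' @export
adamw_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(P) matrix(0, nrow(P), ncol(P))),
       v = lapply(params, function(P) matrix(0, nrow(P), ncol(P))))
}

#' One AdamW step (decoupled weight decay)
#'
#' @param params named list of parameter matrices.
#' @param grads named list of gradients (same names/shapes).
#' @param state state from [adamw_init()].
#' @param lr learning rate: a scalar, or a named vector with one rate per
#'   parameter (e.g. to freeze a parameter group with rate 0).
#' @param beta1,beta2,eps Adam moment coefficients and stabilizer.
#' @param weight_decay decoupled weight-decay coefficient (applied to every
#'   parameter whose name does not start with `"b"`, i.e. biases and scalar
#'   temperatures are not decayed).
#' @return list with updated `params` and `state`.
#' @export
adamw_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    lr_nm <- if (length(lr) > 1L) lr[[nm]] else lr
    base <- sub("^.*\\.", "", nm)  # group prefixes like "en.W1" -> "W1"
    no_decay <- startsWith(base, "b") || base == "tlogit"
    decay <- if (weight_decay > 0 && !no_decay) weight_decay * params[[nm]] else 0
    params[[nm]] <- params[[nm]] - lr_nm * (mhat / (sqrt(vhat) + eps) + decay)
  }
  list(params = params, state = state)
}
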