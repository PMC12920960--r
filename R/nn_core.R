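#' @useDynLib airseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd
NULL

# ---- small numeric helpers --------------------------------------------------

sigmoid_ <- function(x) 1 / (1 + exp(-x))

relu_ <- function(x) relu_fwd_cpp(x)

#' Row-wise softmax of a matrix
#' @noRd
softmax_rows <- function(m) {
  rmax <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m - rmax)
  e / rowSums(e)
}

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

#' Validate a feature map array of shape B x C x H x W
#' @noRd
check_feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L)
    stop("feature map must be a 4-D array with dim c(B, C, H, W)", call. = FALSE)
  stopifnot_finite(x, "feature map")
  invisible(d)
}

# ---- parameter initialisation ----------------------------------------------
# Fan-in-scaled Gaussian (He) initialisation; biases zero. Callers are
# responsible for seeding the RNG so whole-model construction is reproducible.

init_weight <- function(n_out, n_in_eff, n_col) {
  matrix(rnorm(n_out * n_col, sd = sqrt(2 / n_in_eff)), nrow = n_out)
}

conv2d_init <- function(c_in, c_out, k) {
  list(W = init_weight(c_out, c_in * k * k, c_in * k * k),
       b = numeric(c_out))
}

linear_init <- function(n_in, n_out) {
  list(W = matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), nrow = n_in),
       b = numeric(n_out))
}

tconv2d_init <- function(c_in, c_out, k = 2L) {
  # weight rows follow the im2col row layout of the paired convolution
  list(W = matrix(rnorm(c_out * k * k * c_in, sd = sqrt(2 / (c_in * k * k))),
                  nrow = c_out * k * k),
       b = numeric(c_out))
}

# ---- convolution ------------------------------------------------------------
# Direct (no im2col materialisation) convolution kernels in C++; the cache
# keeps only a reference to the input.

# Training may switch the convolutions to single precision (sgemm), the
# field's standard arithmetic for network optimisation; everything else
# runs in double.
use_single_precision <- function()
  isTRUE(getOption("airseg.single_precision", FALSE))

conv2d_forward <- function(x, p, k, pad = (k - 1L) %/% 2L, stride = 1L) {
  d <- dim(x)
  y <- conv2d_gemm_fwd(x, p$W, p$b, d[1], d[2], d[3], d[4], k, pad, stride,
                       use_single_precision())
  list(y = y, cache = list(x = x, dim_in = d, k = k, pad = pad,
                           stride = stride))
}

conv2d_backward <- function(dy, p, cache) {
  di <- cache$dim_in
  r <- conv2d_gemm_bwd(dy, cache$x, p$W, di[1], di[2], di[3], di[4],
                       cache$k, cache$pad, cache$stride,
                       use_single_precision())
  list(dx = r$dx, grads = list(W = r$W, b = r$b))
}

# ---- transposed convolution (stride-2 upsampling) ---------------------------

tconv2d_forward <- function(x, p, k = 2L, stride = 2L) {
  d <- dim(x)
  c_out <- length(p$b)
  y <- tconv2d_gemm_fwd(x, p$W, p$b, d[1], d[2], d[3], d[4], c_out, k,
                        stride)
  list(y = y, cache = list(x = x, dim_in = d, k = k, stride = stride,
                           c_out = c_out))
}

tconv2d_backward <- function(dy, p, cache) {
  di <- cache$dim_in
  r <- tconv2d_gemm_bwd(dy, cache$x, p$W, di[1], di[2], di[3], di[4],
                        cache$c_out, cache$k, cache$stride)
  list(dx = r$dx, grads = list(W = r$W, b = r$b))
}

# ---- pooling ----------------------------------------------------------------

maxpool2_forward <- function(x) {
  d <- dim(x)
  out <- maxpool2_fwd(x, d[1], d[2], d[3], d[4])
  list(y = out$y, cache = list(argmax = out$argmax, dim_in = d))
}

maxpool2_backward <- function(dy, cache) {
  di <- cache$dim_in
  maxpool2_bwd(dy, cache$argmax, di[1], di[2], di[3], di[4])
}

# ---- linear -----------------------------------------------------------------

linear_forward <- function(x, p) {
  # x: n x in matrix
  sweep(x %*% p$W, 2L, p$b, "+")
}

linear_backward <- function(dy, x, p) {
  list(dx = tcrossprod(dy, p$W),
       grads = list(W = crossprod(x, dy), b = colSums(dy)))
}

# ---- token flatten / unflatten ---------------------------------------------
# Tokens are B x N x C with N = H*W in spatial column-major order (h fastest),
# so flatten -> unflatten is the identity.

tokens_from_feature <- function(x) {
  d <- dim(x)
  t4 <- aperm(x, c(1L, 3L, 4L, 2L))        # B, H, W, C
  dim(t4) <- c(d[1], d[3] * d[4], d[2])
  t4
}

feature_from_tokens <- function(tk, H, W) {
  d <- dim(tk)                             # B, N, C
  dim(tk) <- c(d[1], H, W, d[3])
  aperm(tk, c(1L, 4L, 2L, 3L))
}

# ---- parameter-tree utilities ----------------------------------------------
# Parameters live in arbitrarily nested named lists with numeric leaves.

ptree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    out <- lapply(seq_along(trees[[1]]), function(i) {
      do.call(ptree_map, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(trees[[1]])
    out
  } else {
    do.call(f, trees)
  }
}

ptree_zeros_like <- function(p) ptree_map(function(x) x * 0, p)

ptree_flatten <- function(p, prefix = "") {
  if (!is.list(p)) {
    out <- list(p)
    names(out) <- sub("\\.$", "", prefix)
    return(out)
  }
  nm <- names(p)
  if (is.null(nm)) nm <- as.character(seq_along(p))
  out <- list()
  for (i in seq_along(p))
    out <- c(out, ptree_flatten(p[[i]], paste0(prefix, nm[i], ".")))
  out
}

ptree_add <- function(a, b) ptree_map(`+`, a, b)

# Accumulate gradients: b may be NULL (stage skipped)
ptree_acc <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  ptree_map(`+`, a, b)
}

# ---- Adam optimiser ---------------------------------------------------------

adam_init <- function(params, lr = 1e-4, weight_decay = 1e-5,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = ptree_zeros_like(params), v = ptree_zeros_like(params),
       t = 0L, lr = lr, wd = weight_decay,
       beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(params, grads, state) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  lr <- state$lr; wd <- state$wd; eps <- state$eps
  state$m <- ptree_map(function(m, g, p) b1 * m + (1 - b1) * (g + wd * p),
                       state$m, grads, params)
  state$v <- ptree_map(function(v, g, p) {
    gg <- g + wd * p
    b2 * v + (1 - b2) * gg * gg
  }, state$v, grads, params)
  params <- ptree_map(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

# ---- broadcasting helpers for attention maps --------------------------------
# Expand an attention map (one of the five tagged shapes) to B x C x H x W.

broadcast_map <- function(map, d) {
  dm <- dim(map)
  if (all(dm == c(d[1], 1L, 1L, 1L))) {
    array(rep(as.numeric(map), times = prod(d[2:4])), dim = d)
  } else if (all(dm == c(d[1], 1L, d[3], d[4]))) {
    m <- array(map, dim = c(d[1], d[3], d[4]))
    aperm(array(m, dim = c(d[1], d[3], d[4], d[2])), c(1L, 4L, 2L, 3L))
  } else if (all(dm == c(d[1], d[2], 1L, 1L))) {
    array(rep(as.numeric(map), times = d[3] * d[4]), dim = d)
  } else {
    stop("unsupported attention-map shape: ", paste(dm, collapse = "x"),
         call. = FALSE)
  }
}

# Adjoint of broadcast_map: sum a full-size gradient back to the map shape.
reduce_to_map <- function(g, map_dim) {
  d <- dim(g)
  if (all(map_dim == c(d[1], 1L, 1L, 1L))) {
    array(rowSums(matrix(g, d[1])), dim = map_dim)
  } else if (all(map_dim == c(d[1], 1L, d[3], d[4]))) {
    s <- array(0, d[c(1, 3, 4)])
    for (cc in seq_len(d[2])) s <- s + array(g[, cc, , ], d[c(1, 3, 4)])
    array(s, dim = map_dim)
  } else if (all(map_dim == c(d[1], d[2], 1L, 1L))) {
    m <- g
    dim(m) <- c(d[1] * d[2], d[3] * d[4])
    array(rowSums(m), dim = map_dim)
  } else {
    stop("unsupported attention-map shape", call. = FALSE)
  }
}
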