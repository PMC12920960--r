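# The five attention operators of the AirSeg block. Each operator has an
# *_init() constructor drawing fan-in-scaled random weights from the current
# RNG stream, a forward function returning the attention map (values in [0,1])
# plus a cache, and an internal backward function used during training.
#
# Attention-map shapes follow the block's convention:
#   image     B x 1 x 1 x 1   one scalar gate per batch item
#   positional B x 1 x H x W  one weight per spatial location
#   semantic  B x C x 1 x 1   one weight per channel (global pools + MLP)
#   schannel  B x C x 1 x 1   one weight per channel (bottleneck 1x1 convs)
#   cspatial  B x 1 x H x W   one weight per spatial location

# ---- channel-wise pooling over C (used by PAM and conventional CSAM) --------

channel_max_pool <- function(f) {
  d <- dim(f)
  cmax <- array(f[, 1, , ], d[c(1, 3, 4)])
  argc <- array(1L, d[c(1, 3, 4)])
  if (d[2] > 1L) {
    for (cc in 2:d[2]) {
      fc <- array(f[, cc, , ], d[c(1, 3, 4)])
      sel <- fc > cmax
      cmax[sel] <- fc[sel]
      argc[sel] <- cc
    }
  }
  list(max = cmax, arg = argc)
}

channel_mean_pool <- function(f) {
  d <- dim(f)
  s <- array(0, d[c(1, 3, 4)])
  for (cc in seq_len(d[2])) s <- s + array(f[, cc, , ], d[c(1, 3, 4)])
  s / d[2]
}

# Scatter a (B,H,W) gradient into the argmax channel of a (B,C,H,W) array.
channel_max_scatter <- function(dmax, argc, d) {
  df <- array(0, d)
  j <- seq_len(prod(d[c(1, 3, 4)])) - 1L
  b <- j %% d[1]
  rest <- j %/% d[1]
  h <- rest %% d[3]
  w <- rest %/% d[3]
  flat <- 1 + b + d[1] * ((as.integer(argc) - 1L) + d[2] * (h + d[3] * w))
  df[flat] <- as.numeric(dmax)
  df
}

channel_mean_spread <- function(dmean, d) {
  df <- array(0, d)
  per <- as.numeric(dmean) / d[2]
  for (cc in seq_len(d[2])) df[, cc, , ] <- per
  df
}

# ---- replicate (edge) padding ----------------------------------------------
# Spatial-attention convolutions use replicate padding so that constant
# fields stay constant through the convolution.

pad_replicate <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  hi <- pmin(pmax(seq_len(d[3] + 2L * p) - p, 1L), d[3])
  wi <- pmin(pmax(seq_len(d[4] + 2L * p) - p, 1L), d[4])
  x[, , hi, wi, drop = FALSE]
}

unpad_replicate_grad <- function(dxp, p, H, W) {
  if (p == 0L) return(dxp)
  d <- dim(dxp)
  hi <- pmin(pmax(seq_len(H + 2L * p) - p, 1L), H)
  wi <- pmin(pmax(seq_len(W + 2L * p) - p, 1L), W)
  tmp <- array(0, c(d[1], d[2], H, d[4]))
  for (ph in seq_along(hi))
    tmp[, , hi[ph], ] <- tmp[, , hi[ph], ] + dxp[, , ph, ]
  dx <- array(0, c(d[1], d[2], H, W))
  for (pw in seq_along(wi))
    dx[, , , wi[pw]] <- dx[, , , wi[pw]] + tmp[, , , pw]
  dx
}

# ---- IAM: image attention (multi-head scaled dot-product) -------------------

#' Initialise image-attention (IAM) parameters
#'
#' Multi-head scaled dot-product attention over flattened spatial tokens,
#' with query/key/value and output projections.
#'
#' @param C feature dimension (channels); must be divisible by `heads`.
#' @param heads number of attention heads (default 3).
#' @return list of linear-projection parameters.
#' @export
iam_init <- function(C, heads = 3L) {
  if (C %% heads != 0L)
    stop("feature dimension C = ", C, " is not divisible by heads = ", heads,
         call. = FALSE)
  list(q = linear_init(C, C), k = linear_init(C, C),
       v = linear_init(C, C), o = linear_init(C, C))
}

#' Image attention forward pass
#'
#' Projects tokens to queries, keys and values, computes per-head scaled
#' dot-product attention `softmax(Q K' / sqrt(D))`, applies dropout to the
#' normalised scores during training, and projects the attended values back
#' to the token dimension.
#'
#' @param x token array of dim `c(B, N, C)` (N = flattened spatial positions).
#' @param params from [iam_init()].
#' @param heads number of heads; must divide C.
#' @param dropout dropout rate in `[0, 1)` applied to attention scores and to
#'   the output projection (training only).
#' @param training logical; enables dropout.
#' @param return_attn logical; also return the pre-dropout attention weights
#'   as a `B x heads x N x N` array.
#' @return list with `tokens` (same shape as `x`), `cache` (for the backward
#'   pass) and optionally `attn`.
#' @export
iam_forward <- function(x, params, heads = 3L, dropout = 0.1,
                        training = FALSE, return_attn = FALSE) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L)
    stop("tokens must have dim c(B, N, C)", call. = FALSE)
  B <- d[1]; N <- d[2]; C <- d[3]
  if (N < 1L) stop("empty token sequence (N = 0)", call. = FALSE)
  if (C %% heads != 0L)
    stop("C = ", C, " is not divisible by heads = ", heads, call. = FALSE)
  stopifnot_finite(x, "tokens")
  D <- C %/% heads
  out <- array(0, d)
  caches <- vector("list", B)
  attn <- if (return_attn) array(0, c(B, heads, N, N)) else NULL
  use_drop <- training && dropout > 0
  for (b in seq_len(B)) {
    X <- matrix(x[b, , ], N, C)
    Q <- linear_forward(X, params$q)
    K <- linear_forward(X, params$k)
    V <- linear_forward(X, params$v)
    O <- matrix(0, N, C)
    A_list <- vector("list", heads)
    M_list <- vector("list", heads)
    for (h in seq_len(heads)) {
      idx <- ((h - 1L) * D + 1L):(h * D)
      S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(D)
      A <- softmax_rows(S)
      if (return_attn) attn[b, h, , ] <- A
      if (use_drop) {
        M <- matrix((runif(N * N) >= dropout) / (1 - dropout), N, N)
        Ad <- A * M
        M_list[[h]] <- M
      } else Ad <- A
      O[, idx] <- Ad %*% V[, idx, drop = FALSE]
      A_list[[h]] <- A
    }
    Y <- linear_forward(O, params$o)
    M2 <- NULL
    if (use_drop) {
      M2 <- matrix((runif(N * C) >= dropout) / (1 - dropout), N, C)
      Y <- Y * M2
    }
    out[b, , ] <- Y
    caches[[b]] <- list(X = X, Q = Q, K = K, V = V, A = A_list,
                        M = M_list, M2 = M2, O = O)
  }
  res <- list(tokens = out,
              cache = list(per_item = caches, heads = heads, D = D,
                           dim = d, use_drop = use_drop))
  if (return_attn) res$attn <- attn
  res
}

iam_backward <- function(dout, params, cache) {
  d <- cache$dim
  B <- d[1]; N <- d[2]; C <- d[3]
  heads <- cache$heads; D <- cache$D
  g <- list(q = list(W = params$q$W * 0, b = params$q$b * 0),
            k = list(W = params$k$W * 0, b = params$k$b * 0),
            v = list(W = params$v$W * 0, b = params$v$b * 0),
            o = list(W = params$o$W * 0, b = params$o$b * 0))
  dx <- array(0, d)
  for (b in seq_len(B)) {
    cb <- cache$per_item[[b]]
    dY <- matrix(dout[b, , ], N, C)
    if (cache$use_drop) dY <- dY * cb$M2
    lo <- linear_backward(dY, cb$O, params$o)
    g$o$W <- g$o$W + lo$grads$W; g$o$b <- g$o$b + lo$grads$b
    dO <- lo$dx
    dQ <- matrix(0, N, C); dK <- matrix(0, N, C); dV <- matrix(0, N, C)
    for (h in seq_len(heads)) {
      idx <- ((h - 1L) * D + 1L):(h * D)
      A <- cb$A[[h]]
      Ad <- if (cache$use_drop) A * cb$M[[h]] else A
      dOh <- dO[, idx, drop = FALSE]
      dAd <- tcrossprod(dOh, cb$V[, idx, drop = FALSE])
      dV[, idx] <- crossprod(Ad, dOh)
      dA <- if (cache$use_drop) dAd * cb$M[[h]] else dAd
      dS <- A * (dA - rowSums(dA * A))
      dQ[, idx] <- dS %*% cb$K[, idx, drop = FALSE] / sqrt(D)
      dK[, idx] <- crossprod(dS, cb$Q[, idx, drop = FALSE]) / sqrt(D)
    }
    lq <- linear_backward(dQ, cb$X, params$q)
    lk <- linear_backward(dK, cb$X, params$k)
    lv <- linear_backward(dV, cb$X, params$v)
    g$q$W <- g$q$W + lq$grads$W; g$q$b <- g$q$b + lq$grads$b
    g$k$W <- g$k$W + lk$grads$W; g$k$b <- g$k$b + lk$grads$b
    g$v$W <- g$v$W + lv$grads$W; g$v$b <- g$v$b + lv$grads$b
    dx[b, , ] <- lq$dx + lk$dx + lv$dx
  }
  list(dx = dx, grads = g)
}

# ---- image gate: scalar per batch item --------------------------------------

#' @export
gate_init <- function(C) linear_init(C, 1L)

#' Reduce attended tokens to one scalar image gate per batch item
#'
#' A learned linear readout is applied to every token and averaged over the
#' sequence; a sigmoid squashes the average into `[0, 1]`, giving one
#' global gate per batch item (shape `B x 1 x 1 x 1`).
#'
#' @param x_attended tokens of dim `c(B, N, C)`, typically from
#'   [iam_forward()].
#' @param params from [gate_init()].
#' @return list with `map` (the `B x 1 x 1 x 1` gate) and `cache`.
#' @export
image_gate <- function(x_attended, params) {
  d <- dim(x_attended)
  B <- d[1]; N <- d[2]; C <- d[3]
  gates <- numeric(B)
  for (b in seq_len(B)) {
    X <- matrix(x_attended[b, , ], N, C)
    gates[b] <- sigmoid_(mean(linear_forward(X, params)))
  }
  list(map = array(gates, c(B, 1L, 1L, 1L)),
       cache = list(x = x_attended, gates = gates, dim = d))
}

image_gate_backward <- function(dmap, params, cache) {
  d <- cache$dim
  B <- d[1]; N <- d[2]; C <- d[3]
  dx <- array(0, d)
  gW <- params$W * 0; gb <- params$b * 0
  for (b in seq_len(B)) {
    g <- cache$gates[b]
    dz <- as.numeric(dmap[b, 1, 1, 1]) * g * (1 - g)
    X <- matrix(cache$x[b, , ], N, C)
    dr <- rep(dz / N, N)
    gW <- gW + crossprod(X, matrix(dr, ncol = 1L))
    gb <- gb + dz
    dx[b, , ] <- matrix(dr, ncol = 1L) %*% t(params$W)
  }
  list(dx = dx, grads = list(W = gW, b = gb))
}

# ---- PAM: positional attention ----------------------------------------------

#' @export
pam_init <- function(kernel = 7L) {
  if (kernel %% 2L == 0L)
    stop("positional-attention kernel must be odd, got ", kernel,
         call. = FALSE)
  list(conv = conv2d_init(2L, 1L, kernel))
}

#' Positional attention map
#'
#' Per-pixel channel max- and average-pooling produce two single-channel
#' maps that are concatenated (max first) and passed through a `k x k`
#' convolution (replicate padding) and a sigmoid, yielding a `B x 1 x H x W`
#' map of spatial weights.
#'
#' @param f feature map, dim `c(B, C, H, W)`.
#' @param params from [pam_init()].
#' @param kernel odd convolution kernel size (default 7).
#' @return list with `map` and `cache`.
#' @export
positional_attention <- function(f, params, kernel = 7L) {
  d <- check_feature_map(f)
  if (kernel %% 2L == 0L)
    stop("positional-attention kernel must be odd, got ", kernel,
         call. = FALSE)
  mx <- channel_max_pool(f)
  mn <- channel_mean_pool(f)
  xcat <- array(0, c(d[1], 2L, d[3], d[4]))
  xcat[, 1L, , ] <- mx$max
  xcat[, 2L, , ] <- mn
  p <- (kernel - 1L) %/% 2L
  xp <- pad_replicate(xcat, p)
  cf <- conv2d_forward(xp, params$conv, kernel, pad = 0L)
  m <- sigmoid_(cf$y)
  list(map = m,
       cache = list(argc = mx$arg, conv = cf$cache, m = m, dim = d,
                    pad = p))
}

pam_backward <- function(dmap, params, cache) {
  d <- cache$dim
  ds <- dmap * cache$m * (1 - cache$m)
  cb <- conv2d_backward(ds, params$conv, cache$conv)
  dxcat <- unpad_replicate_grad(cb$dx, cache$pad, d[3], d[4])
  dmx <- array(dxcat[, 1L, , ], d[c(1, 3, 4)])
  dmn <- array(dxcat[, 2L, , ], d[c(1, 3, 4)])
  df <- channel_max_scatter(dmx, cache$argc, d) + channel_mean_spread(dmn, d)
  list(dx = df, grads = list(conv = cb$grads))
}

# ---- shared channel-gate internals (SAM and SCAM) ---------------------------
# Global spatial max and average pools per channel feed a shared two-layer
# bottleneck (linear-ReLU-linear); the two branch outputs are summed and
# squashed by a sigmoid: one weight per channel.

channel_gate_init <- function(C, reduction) {
  Cr <- max(C %/% reduction, 1L)
  list(fc1 = linear_init(C, Cr), fc2 = linear_init(Cr, C))
}

channel_gate_forward <- function(f, params) {
  d <- check_feature_map(f)
  m <- f
  dim(m) <- c(d[1] * d[2], d[3] * d[4])
  imax <- max.col(m, ties.method = "first")
  mp <- matrix(m[cbind(seq_len(nrow(m)), imax)], d[1], d[2])
  ap <- matrix(rowMeans(m), d[1], d[2])
  pre_m <- linear_forward(mp, params$fc1)
  pre_a <- linear_forward(ap, params$fc1)
  h_m <- relu_(pre_m)
  h_a <- relu_(pre_a)
  z <- linear_forward(h_m, params$fc2) + linear_forward(h_a, params$fc2)
  s <- sigmoid_(z)
  list(map = array(s, c(d[1], d[2], 1L, 1L)),
       cache = list(mp = mp, ap = ap, imax = imax, pre_m = pre_m,
                    pre_a = pre_a, h_m = h_m, h_a = h_a, s = s, dim = d))
}

channel_gate_backward <- function(dmap, params, cache) {
  d <- cache$dim
  s <- cache$s
  ds <- matrix(dmap, d[1], d[2]) * s * (1 - s)
  g1W <- params$fc1$W * 0; g1b <- params$fc1$b * 0
  g2W <- params$fc2$W * 0; g2b <- params$fc2$b * 0
  branch <- function(ds, h, pre, x) {
    l2 <- linear_backward(ds, h, params$fc2)
    dpre <- l2$dx * (pre > 0)
    l1 <- linear_backward(dpre, x, params$fc1)
    list(dx = l1$dx, g1 = l1$grads, g2 = l2$grads)
  }
  bm <- branch(ds, cache$h_m, cache$pre_m, cache$mp)
  ba <- branch(ds, cache$h_a, cache$pre_a, cache$ap)
  g1W <- bm$g1$W + ba$g1$W; g1b <- bm$g1$b + ba$g1$b
  g2W <- bm$g2$W + ba$g2$W; g2b <- bm$g2$b + ba$g2$b
  # back through the global pools
  nrow_m <- d[1] * d[2]
  dm <- matrix(0, nrow_m, d[3] * d[4])
  dm[cbind(seq_len(nrow_m), cache$imax)] <- as.numeric(bm$dx)
  dm <- dm + as.numeric(ba$dx) / (d[3] * d[4])
  dim(dm) <- d
  list(dx = dm,
       grads = list(fc1 = list(W = g1W, b = g1b),
                    fc2 = list(W = g2W, b = g2b)))
}

# ---- SAM: semantic attention ------------------------------------------------

#' @export
sam_init <- function(C, mlp_reduction = 16L)
  channel_gate_init(C, mlp_reduction)

#' Semantic attention map
#'
#' Global spatial max- and average-pooling condense the feature map to one
#' value per channel; a shared two-layer MLP processes both summaries, the
#' results are summed and passed through a sigmoid. Every spatial position
#' of a channel receives the identical weight (`B x C x 1 x 1`).
#'
#' @param f feature map, dim `c(B, C, H, W)`.
#' @param params from [sam_init()].
#' @return list with `map` and `cache`.
#' @export
semantic_attention <- function(f, params) channel_gate_forward(f, params)

sam_backward <- channel_gate_backward

# ---- SCAM: self-channel attention -------------------------------------------

#' @export
scam_init <- function(C, ratio = 16L) channel_gate_init(C, ratio)

#' Self-channel attention map
#'
#' Global average- and max-pooled channel descriptors pass through a shared
#' two-layer 1x1-convolution bottleneck (width `max(C/ratio, 1)`, ReLU
#' between); the branch outputs are summed and squashed by a sigmoid,
#' giving one weight per channel (`B x C x 1 x 1`).
#'
#' @param f feature map, dim `c(B, C, H, W)`.
#' @param params from [scam_init()]; the two branches share weights.
#' @return list with `map` and `cache`.
#' @export
self_channel_attention <- function(f, params) channel_gate_forward(f, params)

scam_backward <- channel_gate_backward

# ---- CSAM: cross-spatial attention ------------------------------------------

#' @export
csam_init <- function(kernel = 7L) {
  if (!kernel %in% c(3L, 7L))
    stop("cross-spatial kernel must be 3 or 7, got ", kernel, call. = FALSE)
  list(conv = conv2d_init(2L, 1L, kernel))
}

#' Cross-spatial attention map
#'
#' In the default (conventional) mode, per-location channel mean and max of
#' the multi-channel input are concatenated (mean first) and convolved
#' (`k x k`, replicate padding) into a `B x 1 x H x W` sigmoid map with
#' spatial variation. In `literal` mode the input is first reduced to a
#' single channel by a channel mean and the *global* spatial mean and max
#' are broadcast to every pixel, which makes the resulting map spatially
#' uniform per batch item.
#'
#' @param f feature map, dim `c(B, C, H, W)`.
#' @param params from [csam_init()].
#' @param kernel 3 or 7.
#' @param literal logical; reproduce the spatially uniform closed form.
#' @return list with `map` and `cache`.
#' @export
cross_spatial_attention <- function(f, params, kernel = 7L, literal = FALSE) {
  d <- check_feature_map(f)
  if (!kernel %in% c(3L, 7L))
    stop("cross-spatial kernel must be 3 or 7, got ", kernel, call. = FALSE)
  if (!literal) {
    mn <- channel_mean_pool(f)
    mx <- channel_max_pool(f)
    xcat <- array(0, c(d[1], 2L, d[3], d[4]))
    xcat[, 1L, , ] <- mn
    xcat[, 2L, , ] <- mx$max
    p <- (kernel - 1L) %/% 2L
    xp <- pad_replicate(xcat, p)
    cf <- conv2d_forward(xp, params$conv, kernel, pad = 0L)
    m <- sigmoid_(cf$y)
    return(list(map = m,
                cache = list(literal = FALSE, argc = mx$arg, conv = cf$cache,
                             m = m, dim = d, pad = p)))
  }
  # literal closed form: channel-mean reduction, then global spatial mean and
  # max broadcast everywhere; the convolution of a constant field reduces to
  # a scalar affine map, so the attention value is one number per batch item.
  xs <- channel_mean_pool(f)                      # B x H x W
  xm <- xs
  dim(xm) <- c(d[1], d[3] * d[4])
  av <- rowMeans(xm)
  imax <- max.col(xm, ties.method = "first")
  mx <- xm[cbind(seq_len(d[1]), imax)]
  kk <- kernel * kernel
  S1 <- sum(params$conv$W[1, 1:kk])               # avg channel weights
  S2 <- sum(params$conv$W[1, (kk + 1L):(2L * kk)])  # max channel weights
  z <- av * S1 + mx * S2 + params$conv$b[1]
  g <- sigmoid_(z)
  m <- broadcast_map(array(g, c(d[1], 1L, 1L, 1L)),
                     c(d[1], 1L, d[3], d[4]))
  list(map = m,
       cache = list(literal = TRUE, g = g, av = av, mx = mx, imax = imax,
                    S1 = S1, S2 = S2, dim = d))
}

csam_backward <- function(dmap, params, cache) {
  d <- cache$dim
  if (!cache$literal) {
    ds <- dmap * cache$m * (1 - cache$m)
    cb <- conv2d_backward(ds, params$conv, cache$conv)
    dxcat <- unpad_replicate_grad(cb$dx, cache$pad, d[3], d[4])
    dmn <- array(dxcat[, 1L, , ], d[c(1, 3, 4)])
    dmx <- array(dxcat[, 2L, , ], d[c(1, 3, 4)])
    df <- channel_mean_spread(dmn, d) +
      channel_max_scatter(dmx, cache$argc, d)
    return(list(dx = df, grads = list(conv = cb$grads)))
  }
  kk <- ncol(params$conv$W) %/% 2L
  g <- cache$g
  dz <- apply(dmap, 1L, sum) * g * (1 - g)
  gW <- params$conv$W * 0
  gW[1, 1:kk] <- sum(dz * cache$av)
  gW[1, (kk + 1L):(2L * kk)] <- sum(dz * cache$mx)
  gb <- sum(dz)
  dav <- dz * cache$S1
  dmx <- dz * cache$S2
  # back to the single-channel map xs
  dxs <- matrix(as.numeric(dav) / (d[3] * d[4]), d[1], d[3] * d[4])
  dxs[cbind(seq_len(d[1]), cache$imax)] <-
    dxs[cbind(seq_len(d[1]), cache$imax)] + dmx
  dim(dxs) <- d[c(1, 3, 4)]
  # back through the channel-mean reduction
  df <- channel_mean_spread(dxs, d)
  list(dx = df, grads = list(conv = list(W = gW, b = gb)))
}
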