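# Composition of the five attention operators and the variance-based
# embedding into the AirSeg block.
#
# Stage order follows the dataflow IAM -> PAM -> SAM -> SCAM -> CSAM.
# In sequential fusion each stage computes its map from the previous stage's
# gated output; in sum fusion all maps are computed from the block input and
# combined additively (normalised mean) before being applied once; in
# parallel fusion the maps are computed from the block input and applied as
# one chained product, with one embedding factor per enabled stage as in the
# product form of the refinement equation.

STAGE_NAMES <- c("image", "positional", "semantic", "schannel", "cspatial")

#' AirSeg block configuration
#'
#' @param heads IAM attention heads (default 3); must divide the channel
#'   count of the gated feature map.
#' @param dropout IAM dropout rate (default 0.1).
#' @param pam_kernel odd kernel size of the positional-attention convolution
#'   (default 7).
#' @param sam_reduction hidden-width divisor of the semantic-attention MLP
#'   (default 16).
#' @param scam_ratio bottleneck ratio of the self-channel attention
#'   (default 16).
#' @param csam_kernel cross-spatial kernel, 3 or 7 (default 7).
#' @param csam_literal logical; use the spatially uniform closed form of the
#'   cross-spatial map (default `FALSE`).
#' @param lem a [lem_config()].
#' @param fusion_mode one of `"sequential"`, `"sum"`, `"parallel"`.
#' @param stage_mask named logical vector enabling the five stages
#'   (image, positional, semantic, schannel, cspatial); at least one must be
#'   enabled.
#' @param embedding per-stage embedding gate: `"lem"` (default), `"patch"`
#'   (non-overlapping patch linear map, ablation baseline), `"cnn"` (strided
#'   convolution stem, ablation baseline) or `"none"`.
#' @param patch_size patch edge for the patch-embedding baseline (default 4).
#' @return an object of class `airseg_config`.
#' @export
airseg_config <- function(heads = 3L, dropout = 0.1, pam_kernel = 7L,
                          sam_reduction = 16L, scam_ratio = 16L,
                          csam_kernel = 7L, csam_literal = FALSE,
                          lem = lem_config(),
                          fusion_mode = "sequential",
                          stage_mask = c(image = TRUE, positional = TRUE,
                                         semantic = TRUE, schannel = TRUE,
                                         cspatial = TRUE),
                          embedding = "lem", patch_size = 4L) {
  fusion_mode <- match.arg(fusion_mode, c("sequential", "sum", "parallel"))
  embedding <- match.arg(embedding, c("lem", "patch", "cnn", "none"))
  if (pam_kernel %% 2L == 0L) stop("pam_kernel must be odd", call. = FALSE)
  if (!csam_kernel %in% c(3L, 7L))
    stop("csam_kernel must be 3 or 7", call. = FALSE)
  if (is.null(names(stage_mask))) names(stage_mask) <- STAGE_NAMES
  stage_mask <- stage_mask[STAGE_NAMES]
  stage_mask[is.na(stage_mask)] <- FALSE
  names(stage_mask) <- STAGE_NAMES
  if (!any(stage_mask))
    stop("at least one attention stage must be enabled", call. = FALSE)
  structure(list(heads = as.integer(heads), dropout = dropout,
                 pam_kernel = as.integer(pam_kernel),
                 sam_reduction = as.integer(sam_reduction),
                 scam_ratio = as.integer(scam_ratio),
                 csam_kernel = as.integer(csam_kernel),
                 csam_literal = csam_literal, lem = lem,
                 fusion_mode = fusion_mode, stage_mask = stage_mask,
                 embedding = embedding, patch_size = as.integer(patch_size)),
            class = "airseg_config")
}

#' Initialise AirSeg block parameters for a given channel width
#'
#' @param C channel count of the gated feature map.
#' @param cfg an [airseg_config()].
#' @return nested parameter list (only enabled stages hold parameters).
#' @export
airseg_init <- function(C, cfg) {
  sm <- cfg$stage_mask
  p <- list()
  if (sm[["image"]]) {
    p$iam <- iam_init(C, cfg$heads)
    p$gate <- gate_init(C)
  }
  if (sm[["positional"]]) p$pam <- pam_init(cfg$pam_kernel)
  if (sm[["semantic"]]) p$sam <- sam_init(C, cfg$sam_reduction)
  if (sm[["schannel"]]) p$scam <- scam_init(C, cfg$scam_ratio)
  if (sm[["cspatial"]]) p$csam <- csam_init(cfg$csam_kernel)
  if (cfg$embedding == "lem") {
    p$lem <- lem_init(cfg$lem)
  } else if (cfg$embedding == "patch") {
    pp <- cfg$patch_size
    p$emb <- linear_init(pp * pp, pp * pp)
  } else if (cfg$embedding == "cnn") {
    p$emb <- list(stem = conv2d_init(C, C, 3L), up = tconv2d_init(C, C, 2L))
  }
  p
}

# ---- per-stage attention maps ----------------------------------------------

stage_map_fwd <- function(name, cur, params, cfg, training) {
  d <- dim(cur)
  switch(name,
    image = {
      tk <- tokens_from_feature(cur)
      ia <- iam_forward(tk, params$iam, cfg$heads, cfg$dropout, training)
      gt <- image_gate(ia$tokens, params$gate)
      list(map = gt$map,
           cache = list(ia = ia$cache, gate = gt$cache, H = d[3], W = d[4]))
    },
    positional = positional_attention(cur, params$pam, cfg$pam_kernel),
    semantic = semantic_attention(cur, params$sam),
    schannel = self_channel_attention(cur, params$scam),
    cspatial = cross_spatial_attention(cur, params$csam, cfg$csam_kernel,
                                       cfg$csam_literal))
}

stage_map_bwd <- function(name, dmap, params, cfg, cache) {
  switch(name,
    image = {
      gb <- image_gate_backward(dmap, params$gate, cache$gate)
      ib <- iam_backward(gb$dx, params$iam, cache$ia)
      list(dx = feature_from_tokens(ib$dx, cache$H, cache$W),
           grads = list(iam = ib$grads, gate = gb$grads))
    },
    positional = {
      r <- pam_backward(dmap, params$pam, cache)
      list(dx = r$dx, grads = list(pam = r$grads))
    },
    semantic = {
      r <- sam_backward(dmap, params$sam, cache)
      list(dx = r$dx, grads = list(sam = r$grads))
    },
    schannel = {
      r <- scam_backward(dmap, params$scam, cache)
      list(dx = r$dx, grads = list(scam = r$grads))
    },
    cspatial = {
      r <- csam_backward(dmap, params$csam, cache)
      list(dx = r$dx, grads = list(csam = r$grads))
    })
}

# ---- embedding gates ---------------------------------------------------------
# Returns the scaled features (scale_out), the gating field and a cache.
# For "lem" the scaling mode of the config applies; the ablation baselines
# (patch, cnn) always gate multiplicatively.

emb_fwd <- function(cur, params, cfg) {
  d <- dim(cur)
  switch(cfg$embedding,
    none = list(scale_out = cur, cache = NULL),
    lem = {
      lf <- lem_forward(cur, cfg$lem, params$lem, with_cache = TRUE)
      list(scale_out = lf$y, field = lf$yp, cache = lf$cache)
    },
    patch = {
      pp <- cfg$patch_size
      if (d[3] %% pp != 0L || d[4] %% pp != 0L)
        stop("patch embedding requires H and W divisible by patch_size",
             call. = FALSE)
      nh <- d[3] %/% pp; nw <- d[4] %/% pp
      xr <- cur
      dim(xr) <- c(d[1], d[2], pp, nh, pp, nw)
      xr <- aperm(xr, c(1L, 2L, 4L, 6L, 3L, 5L))
      dim(xr) <- c(d[1] * d[2] * nh * nw, pp * pp)
      z <- linear_forward(xr, params$emb)
      field_flat <- sigmoid_(z)
      fr <- field_flat
      dim(fr) <- c(d[1], d[2], nh, nw, pp, pp)
      fr <- aperm(fr, c(1L, 2L, 5L, 3L, 6L, 4L))
      dim(fr) <- d
      list(scale_out = cur * fr, field = fr,
           cache = list(xr = xr, field_flat = field_flat, nh = nh, nw = nw,
                        pp = pp, dim = d))
    },
    cnn = {
      if (d[3] %% 2L != 0L || d[4] %% 2L != 0L)
        stop("cnn embedding requires even H and W", call. = FALSE)
      st <- conv2d_forward(cur, params$emb$stem, 3L, pad = 1L, stride = 2L)
      r <- relu_(st$y)
      up <- tconv2d_forward(r, params$emb$up)
      fr <- sigmoid_(up$y)
      list(scale_out = cur * fr, field = fr,
           cache = list(stem = st$cache, pre = st$y, r = r, up = up$cache,
                        fr = fr))
    })
}

# dscale is the gradient wrt scale_out; cur is the stage input.
emb_bwd <- function(dscale, cur, ec, params, cfg) {
  switch(cfg$embedding,
    none = list(dx = dscale, grads = NULL),
    lem = {
      lb <- lem_backward(dscale, cfg$lem, ec$cache, params$lem)
      g <- if (is.null(lb$grads)) NULL else list(lem = lb$grads)
      list(dx = lb$dx, grads = g)
    },
    patch = {
      cc <- ec$cache
      d <- cc$dim
      dfield <- dscale * cur
      dx <- dscale * ec$field
      dfr <- dfield
      dim(dfr) <- c(d[1], d[2], cc$pp, cc$nh, cc$pp, cc$nw)
      dfr <- aperm(dfr, c(1L, 2L, 4L, 6L, 3L, 5L))
      dim(dfr) <- c(d[1] * d[2] * cc$nh * cc$nw, cc$pp * cc$pp)
      dz <- dfr * cc$field_flat * (1 - cc$field_flat)
      lb <- linear_backward(dz, cc$xr, params$emb)
      dxr <- lb$dx
      dim(dxr) <- c(d[1], d[2], cc$nh, cc$nw, cc$pp, cc$pp)
      dxr <- aperm(dxr, c(1L, 2L, 5L, 3L, 6L, 4L))
      dim(dxr) <- d
      list(dx = dx + dxr, grads = list(emb = lb$grads))
    },
    cnn = {
      cc <- ec$cache
      dfield <- dscale * cur
      dx <- dscale * ec$field
      dup <- dfield * cc$fr * (1 - cc$fr)
      tb <- tconv2d_backward(dup, params$emb$up, cc$up)
      dr <- relu_bwd_cpp(tb$dx, cc$pre)
      sb <- conv2d_backward(dr, params$emb$stem, cc$stem)
      list(dx = dx + sb$dx,
           grads = list(emb = list(stem = sb$grads, up = tb$grads)))
    })
}

acc_grads <- function(total, add) {
  if (is.null(add)) return(total)
  for (nm in names(add)) total[[nm]] <- ptree_acc(total[[nm]], add[[nm]])
  total
}

# ---- block forward / backward -----------------------------------------------

#' AirSeg block forward pass
#'
#' Applies the enabled attention stages and the per-stage embedding gate to
#' a feature map according to the configured fusion mode. Output shape
#' equals input shape.
#'
#' @param f feature map, dim `c(B, C, H, W)`.
#' @param params from [airseg_init()].
#' @param cfg an [airseg_config()].
#' @param training logical; enables IAM dropout.
#' @param with_cache logical; return the cache needed for
#'   [airseg_backward()].
#' @return the refined feature map, or a list `(y, cache)` when
#'   `with_cache = TRUE`.
#' @export
airseg_forward <- function(f, params, cfg, training = FALSE,
                           with_cache = FALSE) {
  d <- check_feature_map(f)
  stages <- STAGE_NAMES[cfg$stage_mask]
  if (length(stages) == 0L)
    stop("all attention stages are disabled", call. = FALSE)
  if (cfg$fusion_mode == "sequential") {
    cur <- f
    scache <- list()
    for (s in stages) {
      mp <- stage_map_fwd(s, cur, params, cfg, training)
      bmap <- broadcast_map(mp$map, d)
      ec <- emb_fwd(cur, params, cfg)
      new <- bmap * ec$scale_out
      scache[[s]] <- list(map = mp, bmap = bmap, ec = ec, cur_in = cur)
      cur <- new
    }
    out <- cur
    cache <- list(mode = "sequential", stages = stages, scache = scache,
                  d = d)
  } else if (cfg$fusion_mode == "sum") {
    scache <- list()
    bsum <- array(0, d)
    for (s in stages) {
      mp <- stage_map_fwd(s, f, params, cfg, training)
      bmap <- broadcast_map(mp$map, d)
      bsum <- bsum + bmap
      scache[[s]] <- list(map = mp)
    }
    M <- bsum / length(stages)
    ec <- emb_fwd(f, params, cfg)
    out <- M * ec$scale_out
    cache <- list(mode = "sum", stages = stages, scache = scache, M = M,
                  ec = ec, d = d, f = f)
  } else {                                   # parallel
    scache <- list()
    bmaps <- list()
    for (s in stages) {
      mp <- stage_map_fwd(s, f, params, cfg, training)
      bmaps[[s]] <- broadcast_map(mp$map, d)
      scache[[s]] <- list(map = mp)
    }
    G <- Reduce(`*`, bmaps)
    if (cfg$embedding == "none") {
      E <- 1
      field <- NULL
      ec <- NULL
    } else {
      ec <- emb_fwd(f, params, cfg)
      field <- ec$field
      E <- field^length(stages)
    }
    out <- f * G * E
    cache <- list(mode = "parallel", stages = stages, scache = scache,
                  bmaps = bmaps, G = G, E = E, ec = ec, d = d, f = f)
  }
  if (with_cache) list(y = out, cache = cache) else out
}

#' AirSeg block backward pass
#'
#' @param dout gradient wrt the block output (same shape as the input).
#' @param params,cfg as in [airseg_forward()].
#' @param cache from `airseg_forward(..., with_cache = TRUE)`.
#' @return list with `dx` and `grads` mirroring `params`.
#' @export
airseg_backward <- function(dout, params, cfg, cache) {
  grads <- ptree_zeros_like(params)
  d <- cache$d
  if (cache$mode == "sequential") {
    g <- dout
    for (s in rev(cache$stages)) {
      sc <- cache$scache[[s]]
      dbmap <- g * sc$ec$scale_out
      dscale <- g * sc$bmap
      dmap <- reduce_to_map(dbmap, dim(sc$map$map))
      mb <- stage_map_bwd(s, dmap, params, cfg, sc$map$cache)
      eb <- emb_bwd(dscale, sc$cur_in, sc$ec, params, cfg)
      grads <- acc_grads(grads, mb$grads)
      grads <- acc_grads(grads, eb$grads)
      g <- mb$dx + eb$dx
    }
    return(list(dx = g, grads = grads))
  }
  if (cache$mode == "sum") {
    n <- length(cache$stages)
    scale_out <- cache$ec$scale_out
    dM <- dout * scale_out
    dscale <- dout * cache$M
    dx <- array(0, d)
    for (s in cache$stages) {
      sc <- cache$scache[[s]]
      dmap <- reduce_to_map(dM / n, dim(sc$map$map))
      mb <- stage_map_bwd(s, dmap, params, cfg, sc$map$cache)
      grads <- acc_grads(grads, mb$grads)
      dx <- dx + mb$dx
    }
    eb <- emb_bwd(dscale, cache$f, cache$ec, params, cfg)
    grads <- acc_grads(grads, eb$grads)
    return(list(dx = dx + eb$dx, grads = grads))
  }
  # parallel
  n <- length(cache$stages)
  f <- cache$f
  G <- cache$G
  E <- cache$E
  dx <- dout * G * E
  dG <- dout * f * E
  for (s in cache$stages) {
    loo <- NULL
    for (t in cache$stages) {
      if (t == s) next
      loo <- if (is.null(loo)) cache$bmaps[[t]] else loo * cache$bmaps[[t]]
    }
    dbmap <- if (is.null(loo)) dG else dG * loo
    sc <- cache$scache[[s]]
    dmap <- reduce_to_map(dbmap, dim(sc$map$map))
    mb <- stage_map_bwd(s, dmap, params, cfg, sc$map$cache)
    grads <- acc_grads(grads, mb$grads)
    dx <- dx + mb$dx
  }
  if (!is.null(cache$ec)) {
    # E = field^n, so dE routes n * field^(n-1) into the field alone
    field <- cache$ec$field
    dfield_total <- dout * f * G * n * field^(n - 1)
    eb <- emb_field_bwd(dfield_total, f, cache$ec, params, cfg)
    grads <- acc_grads(grads, eb$grads)
    dx <- dx + eb$dx
  }
  list(dx = dx, grads = grads)
}

# Backward of the gating *field* alone (no multiplicative direct term),
# used by the parallel fusion where the field enters as a pure factor.
emb_field_bwd <- function(dfield, cur, ec, params, cfg) {
  switch(cfg$embedding,
    lem = {
      # reuse lem_backward with a purely additive view: out = yp, so
      # d_yp = dfield and no direct x term.
      cc <- ec$cache
      yp <- cc$yp
      dmat <- dfield
      dim(dmat) <- dim(cc$m)
      dY <- dmat * yp * (1 - yp)
      n <- cc$n; k <- cc$k; s2 <- cc$s2; dev <- cc$dev
      tsum <- rowSums(dY * dev)
      ddev <- dY / (k * s2) - tsum / (k * s2^2 * (n - 1))
      xm <- cc$m - cc$mu
      dx <- ddev * 2 * xm
      dx <- dx - rowSums(ddev * 2 * xm) / n
      g <- NULL
      if (isTRUE(cfg$lem$learnable) && !is.null(params$lem$rho_eps)) {
        d_eps <- -sum(rowSums(dY * dev) / (k * s2^2))
        d_k <- -sum(rowSums(dY * dev) / (k^2 * s2))
        g <- list(lem = list(rho_eps = d_eps * sigmoid_(params$lem$rho_eps),
                             rho_k = d_k * sigmoid_(params$lem$rho_k)))
      }
      dim(dx) <- cc$dim
      list(dx = dx, grads = g)
    },
    patch = {
      cc <- ec$cache
      d <- cc$dim
      dfr <- dfield
      dim(dfr) <- c(d[1], d[2], cc$pp, cc$nh, cc$pp, cc$nw)
      dfr <- aperm(dfr, c(1L, 2L, 4L, 6L, 3L, 5L))
      dim(dfr) <- c(d[1] * d[2] * cc$nh * cc$nw, cc$pp * cc$pp)
      dz <- dfr * cc$field_flat * (1 - cc$field_flat)
      lb <- linear_backward(dz, cc$xr, params$emb)
      dxr <- lb$dx
      dim(dxr) <- c(d[1], d[2], cc$nh, cc$nw, cc$pp, cc$pp)
      dxr <- aperm(dxr, c(1L, 2L, 5L, 3L, 6L, 4L))
      dim(dxr) <- d
      list(dx = dxr, grads = list(emb = lb$grads))
    },
    cnn = {
      cc <- ec$cache
      dup <- dfield * cc$fr * (1 - cc$fr)
      tb <- tconv2d_backward(dup, params$emb$up, cc$up)
      dr <- relu_bwd_cpp(tb$dx, cc$pre)
      sb <- conv2d_backward(dr, params$emb$stem, cc$stem)
      list(dx = sb$dx,
           grads = list(emb = list(stem = sb$grads, up = tb$grads)))
    })
}
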