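# UNet-like encoder-decoder segmentation networks with AirSeg blocks
# inserted after encoder feature extraction. Channel widths double per
# level; level `depth` is the bottleneck. Decoding uses stride-2 transposed
# convolutions and skip concatenation; an optional nested skip style adds
# one intermediate aggregation node per skip level.

#' Model specification
#'
#' @param backbone `"resunet"` (residual blocks) or `"unet"` (double
#'   convolution blocks).
#' @param base_width channels at the first level (>= 4); widths double per
#'   level.
#' @param depth number of encoder levels including the bottleneck (>= 2).
#' @param airseg an [airseg_config()] or `NULL` for the bare backbone.
#' @param airseg_placement encoder levels (1-based, `1..depth`) whose output
#'   is refined by an AirSeg block; default: the bottleneck level only.
#' @param embedding_ablation embedding used inside the AirSeg blocks:
#'   `"lem"` (default), `"patch"`, `"cnn"` or `"none"`.
#' @param skip_style `"plain"` or `"nested"` (one intermediate aggregation
#'   per skip level).
#' @param in_channels,out_channels image and mask channels (default 1).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(backbone = "resunet", base_width = 8L, depth = 3L,
                       airseg = airseg_config(), airseg_placement = NULL,
                       embedding_ablation = "lem", skip_style = "plain",
                       in_channels = 1L, out_channels = 1L) {
  backbone <- match.arg(backbone, c("resunet", "unet"))
  skip_style <- match.arg(skip_style, c("plain", "nested"))
  embedding_ablation <- match.arg(embedding_ablation,
                                  c("lem", "patch", "cnn", "none"))
  if (depth < 2L) stop("depth must be >= 2", call. = FALSE)
  if (base_width < 4L) stop("base_width must be >= 4", call. = FALSE)
  if (is.null(airseg_placement)) airseg_placement <- depth
  airseg_placement <- sort(unique(as.integer(airseg_placement)))
  if (length(airseg_placement) &&
      (min(airseg_placement) < 1L || max(airseg_placement) > depth))
    stop("airseg_placement levels must lie in 1..depth", call. = FALSE)
  if (!is.null(airseg)) airseg$embedding <- embedding_ablation
  structure(list(backbone = backbone, base_width = as.integer(base_width),
                 depth = as.integer(depth), airseg = airseg,
                 airseg_placement = airseg_placement,
                 embedding_ablation = embedding_ablation,
                 skip_style = skip_style,
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels)),
            class = "model_spec")
}

level_width <- function(spec, i) spec$base_width * 2L^(i - 1L)

# ---- backbone blocks --------------------------------------------------------

block_init <- function(c_in, c_out, backbone) {
  p <- list(c1 = conv2d_init(c_in, c_out, 3L),
            c2 = conv2d_init(c_out, c_out, 3L))
  if (backbone == "resunet" && c_in != c_out)
    p$sc <- conv2d_init(c_in, c_out, 1L)
  p
}

block_fwd <- function(x, p, backbone) {
  f1 <- conv2d_forward(x, p$c1, 3L, pad = 1L)
  a1 <- relu_(f1$y)
  f2 <- conv2d_forward(a1, p$c2, 3L, pad = 1L)
  if (backbone == "resunet") {
    if (!is.null(p$sc)) {
      s <- conv2d_forward(x, p$sc, 1L, pad = 0L)
      pre <- f2$y + s$y
      sc_cache <- s$cache
    } else {
      pre <- f2$y + x
      sc_cache <- NULL
    }
    y <- relu_(pre)
    cache <- list(c1 = f1$cache, c2 = f2$cache, pre1 = f1$y, pre = pre,
                  sc = sc_cache, res = TRUE)
  } else {
    y <- relu_(f2$y)
    cache <- list(c1 = f1$cache, c2 = f2$cache, pre1 = f1$y,
                  pre = f2$y, res = FALSE)
  }
  list(y = y, cache = cache)
}

block_bwd <- function(dy, p, cache) {
  dpre <- relu_bwd_cpp(dy, cache$pre)
  b2 <- conv2d_backward(dpre, p$c2, cache$c2)
  da1 <- relu_bwd_cpp(b2$dx, cache$pre1)
  b1 <- conv2d_backward(da1, p$c1, cache$c1)
  dx <- b1$dx
  g <- list(c1 = b1$grads, c2 = b2$grads)
  if (cache$res) {
    if (!is.null(cache$sc)) {
      bs <- conv2d_backward(dpre, p$sc, cache$sc)
      dx <- dx + bs$dx
      g$sc <- bs$grads
    } else {
      dx <- dx + dpre
    }
  }
  list(dx = dx, grads = g)
}

# ---- model construction -----------------------------------------------------

#' Build a segmentation network
#'
#' Constructs all parameters deterministically from the spec and seed.
#' Backbone parameters are drawn first, so the "without AirSeg" arm of a
#' comparison is bit-identical to the bare backbone built with the same
#' seed.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for weight initialisation.
#' @return an object of class `airseg_model`.
#' @export
build_model <- function(spec, seed) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(seed)
  d <- spec$depth
  params <- list(enc = vector("list", d))
  c_prev <- spec$in_channels
  for (i in seq_len(d)) {
    ci <- level_width(spec, i)
    params$enc[[i]] <- block_init(c_prev, ci, spec$backbone)
    c_prev <- ci
  }
  params$dec <- vector("list", d - 1L)
  for (i in seq_len(d - 1L)) {
    ci <- level_width(spec, i)
    params$dec[[i]] <- list(up = tconv2d_init(level_width(spec, i + 1L), ci),
                            blk = block_init(2L * ci, ci, spec$backbone))
  }
  if (spec$skip_style == "nested") {
    params$nested <- vector("list", d - 1L)
    for (i in seq_len(d - 1L)) {
      ci <- level_width(spec, i)
      params$nested[[i]] <-
        list(up = tconv2d_init(level_width(spec, i + 1L), ci),
             conv = conv2d_init(2L * ci, ci, 3L))
    }
  }
  params$final <- conv2d_init(level_width(spec, 1L), spec$out_channels, 1L)
  # start output probabilities near the sparse foreground prevalence so the
  # overlap losses see a sensible operating point from the first step
  params$final$b[] <- stats::qlogis(0.075)
  if (!is.null(spec$airseg) && length(spec$airseg_placement)) {
    params$airseg <- list()
    for (i in spec$airseg_placement) {
      ci <- level_width(spec, i)
      if (ci %% spec$airseg$heads != 0L)
        stop("encoder level ", i, " has ", ci,
             " channels, not divisible by heads = ", spec$airseg$heads,
             call. = FALSE)
      params$airseg[[as.character(i)]] <- airseg_init(ci, spec$airseg)
    }
  }
  structure(list(spec = spec, params = params, seed = seed),
            class = "airseg_model")
}

#' @export
print.airseg_model <- function(x, ...) {
  np <- sum(vapply(ptree_flatten(x$params), length, numeric(1)))
  s <- x$spec
  cat(sprintf("airseg_model: %s, width %d, depth %d, %s skips\n",
              s$backbone, s$base_width, s$depth, s$skip_style))
  if (!is.null(s$airseg) && length(s$airseg_placement))
    cat(sprintf("  AirSeg (%s fusion, %s embedding) at level(s) %s\n",
                s$airseg$fusion_mode, s$airseg$embedding,
                paste(s$airseg_placement, collapse = ", ")))
  else cat("  bare backbone (no AirSeg)\n")
  cat(sprintf("  parameters: %d\n", np))
  invisible(x)
}

has_airseg_at <- function(spec, i)
  !is.null(spec$airseg) && i %in% spec$airseg_placement

# ---- forward ----------------------------------------------------------------

model_forward <- function(model, x, training = FALSE, with_cache = FALSE) {
  spec <- model$spec
  p <- model$params
  d <- dim(x)
  if (length(d) != 4L || d[2] != spec$in_channels)
    stop("input must have dim c(B, ", spec$in_channels, ", H, W)",
         call. = FALSE)
  if (d[3] %% 2L^(spec$depth - 1L) != 0L || d[4] %% 2L^(spec$depth - 1L) != 0L)
    stop("H and W must be divisible by 2^(depth-1)", call. = FALSE)
  enc <- vector("list", spec$depth)
  skips <- vector("list", spec$depth)
  f <- x
  for (i in seq_len(spec$depth)) {
    bf <- block_fwd(f, p$enc[[i]], spec$backbone)
    f <- bf$y
    ac <- NULL
    if (has_airseg_at(spec, i)) {
      af <- airseg_forward(f, p$airseg[[as.character(i)]], spec$airseg,
                           training = training, with_cache = TRUE)
      f <- af$y
      ac <- af$cache
    }
    skips[[i]] <- f
    pc <- NULL
    if (i < spec$depth) {
      mp <- maxpool2_forward(f)
      f <- mp$y
      pc <- mp$cache
    }
    enc[[i]] <- list(block = bf$cache, airseg = ac, pool = pc)
  }
  used <- skips
  nested <- NULL
  if (spec$skip_style == "nested") {
    nested <- vector("list", spec$depth - 1L)
    for (i in seq_len(spec$depth - 1L)) {
      up <- tconv2d_forward(skips[[i + 1L]], p$nested[[i]]$up)
      ci <- level_width(spec, i)
      cat2 <- concat_channels(skips[[i]], up$y)
      cv <- conv2d_forward(cat2, p$nested[[i]]$conv, 3L, pad = 1L)
      used[[i]] <- relu_(cv$y)
      nested[[i]] <- list(up = up$cache, conv = cv$cache, pre = cv$y,
                          ci = ci)
    }
  }
  dec <- vector("list", spec$depth - 1L)
  g <- skips[[spec$depth]]
  for (i in rev(seq_len(spec$depth - 1L))) {
    up <- tconv2d_forward(g, p$dec[[i]]$up)
    cat2 <- concat_channels(used[[i]], up$y)
    bf <- block_fwd(cat2, p$dec[[i]]$blk, spec$backbone)
    g <- bf$y
    dec[[i]] <- list(up = up$cache, blk = bf$cache,
                     ci = level_width(spec, i))
  }
  fin <- conv2d_forward(g, p$final, 1L, pad = 0L)
  prob <- sigmoid_(fin$y)
  if (!with_cache) return(list(prob = prob))
  list(prob = prob,
       cache = list(enc = enc, nested = nested, dec = dec, fin = fin$cache,
                    prob = prob, dims = d))
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2] + db[2], da[3], da[4]))
  out[, seq_len(da[2]), , ] <- a
  out[, da[2] + seq_len(db[2]), , ] <- b
  out
}

# ---- backward ---------------------------------------------------------------
# dprob: gradient wrt the output probabilities.

model_backward <- function(model, dprob, cache) {
  spec <- model$spec
  p <- model$params
  grads <- ptree_zeros_like(p)
  prob <- cache$prob
  dlog <- dprob * prob * (1 - prob)
  fb <- conv2d_backward(dlog, p$final, cache$fin)
  grads$final <- fb$grads
  dg <- fb$dx
  dused <- vector("list", spec$depth)
  for (i in seq_len(spec$depth - 1L)) {
    dc <- cache$dec[[i]]
    bb <- block_bwd(dg, p$dec[[i]]$blk, dc$blk)
    grads$dec[[i]]$blk <- bb$grads
    ci <- dc$ci
    dskip_part <- bb$dx[, seq_len(ci), , , drop = FALSE]
    dup <- bb$dx[, ci + seq_len(dim(bb$dx)[2] - ci), , , drop = FALSE]
    tb <- tconv2d_backward(dup, p$dec[[i]]$up, dc$up)
    grads$dec[[i]]$up <- tb$grads
    dused[[i]] <- dskip_part
    dg <- tb$dx
  }
  draw <- vector("list", spec$depth)
  draw[[spec$depth]] <- dg
  if (spec$skip_style == "nested") {
    for (i in seq_len(spec$depth - 1L)) {
      nc <- cache$nested[[i]]
      dpre <- relu_bwd_cpp(dused[[i]], nc$pre)
      cb <- conv2d_backward(dpre, p$nested[[i]]$conv, nc$conv)
      grads$nested[[i]]$conv <- cb$grads
      ci <- nc$ci
      draw[[i]] <- ptree_acc(draw[[i]],
                             cb$dx[, seq_len(ci), , , drop = FALSE])
      dup <- cb$dx[, ci + seq_len(dim(cb$dx)[2] - ci), , , drop = FALSE]
      tb <- tconv2d_backward(dup, p$nested[[i]]$up, nc$up)
      grads$nested[[i]]$up <- tb$grads
      draw[[i + 1L]] <- ptree_acc(draw[[i + 1L]], tb$dx)
    }
  } else {
    for (i in seq_len(spec$depth - 1L))
      draw[[i]] <- ptree_acc(draw[[i]], dused[[i]])
  }
  carry <- NULL
  for (i in rev(seq_len(spec$depth))) {
    dcur <- ptree_acc(draw[[i]], carry)
    ec <- cache$enc[[i]]
    if (has_airseg_at(spec, i)) {
      ab <- airseg_backward(dcur, p$airseg[[as.character(i)]], spec$airseg,
                            ec$airseg)
      grads$airseg[[as.character(i)]] <- ab$grads
      dcur <- ab$dx
    }
    bb <- block_bwd(dcur, p$enc[[i]], ec$block)
    grads$enc[[i]] <- bb$grads
    if (i > 1L)
      carry <- maxpool2_backward(bb$dx, cache$enc[[i - 1L]]$pool)
  }
  grads
}

# ---- inference --------------------------------------------------------------

#' Threshold model probabilities into binary masks
#'
#' @param model an `airseg_model`.
#' @param batch input images, dim `c(B, in_channels, H, W)`, values in
#'   `[0, 1]`.
#' @param threshold binarisation threshold in `(0, 1)`; probabilities
#'   `>= threshold` map to 1 (default 0.5).
#' @return binary array of dim `c(B, out_channels, H, W)`.
#' @export
forward_infer <- function(model, batch, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  prob <- model_forward(model, batch, training = FALSE)$prob
  (prob >= threshold) * 1
}

# Convert a list of slice samples into model input/target batches. Images
# are standardised per slice (zero mean, unit variance) at the network
# boundary; the stored 0-255 range is a storage convention only.
samples_to_batch <- function(samples) {
  B <- length(samples)
  d <- dim(samples[[1]]$image)
  images <- array(0, c(B, 1L, d[1], d[2]))
  masks <- array(0, c(B, 1L, d[1], d[2]))
  for (j in seq_len(B)) {
    img <- samples[[j]]$image
    s <- stats::sd(img)
    if (s == 0) s <- 1
    images[j, 1, , ] <- (img - mean(img)) / s
    masks[j, 1, , ] <- samples[[j]]$mask
  }
  list(images = images, masks = masks)
}

# ---- checkpoints ------------------------------------------------------------
# Flat named-array container with a spec header (format "airseg-checkpoint",
# version 1): the parameter tree is flattened to named numeric leaves and
# restored into a skeleton rebuilt from the stored spec.

ptree_unflatten <- function(skeleton, flat) {
  i <- 0L
  fill <- function(node) {
    if (is.list(node)) return(lapply(node, fill))
    i <<- i + 1L
    leaf <- flat[[i]]
    dim(leaf) <- dim(node)
    leaf
  }
  out <- fill(skeleton)
  rapply(out, function(x) x, how = "replace")
}

#' Save a model checkpoint
#'
#' @param model an `airseg_model`.
#' @param path output file.
#' @export
checkpoint_save <- function(model, path) {
  obj <- list(format = "airseg-checkpoint", version = 1L,
              spec = model$spec, seed = model$seed,
              arrays = ptree_flatten(model$params))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [checkpoint_save()].
#' @return an `airseg_model`.
#' @export
checkpoint_load <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "airseg-checkpoint"))
    stop("not an airseg checkpoint: ", path, call. = FALSE)
  model <- build_model(obj$spec, seed = obj$seed)
  model$params <- ptree_unflatten(model$params, obj$arrays)
  model
}
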