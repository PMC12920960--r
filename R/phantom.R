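# Synthetic branching-airway phantom generator.
#
# Masks are recursive binary trees of thick line segments (anti-aliased
# tubes, then thresholded), with radius and length decaying per generation
# so the corpus reproduces the foreground/background and large/small-branch
# imbalance of airway slices. Images overlay branch intensities on a
# textured noisy background whose realised intensities overlap the
# foreground range, so a global threshold cannot solve the task.

#' Phantom specification
#'
#' @param image_size square image edge in pixels (default 256).
#' @param n_generations branching depth of the airway tree (default 4).
#' @param root_radius_px radius of the root tube in pixels (default
#'   `max(2, round(image_size / 32))`).
#' @param radius_decay per-generation radius multiplier in (0, 1)
#'   (default 0.65), so terminal branches are thinnest.
#' @param branch_angle_deg range (degrees) from which each child's
#'   deviation from the parent direction is drawn (default 20-50).
#' @param intensity_fg foreground intensity range on the 0-255 scale
#'   (default 150-220).
#' @param intensity_bg background base-intensity range (default 60-140).
#' @param noise_sd additive Gaussian noise SD (default 12); with the
#'   default ranges the realised background and foreground intensities
#'   overlap.
#' @param n_distractors number of bright elliptical background structures
#'   (mucus- or vessel-like) drawn at foreground-range intensity but
#'   excluded from the mask (default 8). They force segmentation by shape
#'   and context: a global intensity threshold cannot separate airways
#'   from them.
#' @param seed integer seed making the phantom fully reproducible.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 256L, n_generations = 4L,
                         root_radius_px = NULL, radius_decay = 0.65,
                         branch_angle_deg = c(20, 50),
                         intensity_fg = c(150, 220),
                         intensity_bg = c(60, 140),
                         noise_sd = 12, n_distractors = 8L, seed = 1L) {
  if (is.null(root_radius_px))
    root_radius_px <- max(2, round(image_size / 32))
  stopifnot(root_radius_px >= 2, radius_decay > 0, radius_decay < 1,
            image_size >= 16, n_generations >= 1)
  structure(list(image_size = as.integer(image_size),
                 n_generations = as.integer(n_generations),
                 root_radius_px = root_radius_px,
                 radius_decay = radius_decay,
                 branch_angle_deg = branch_angle_deg,
                 intensity_fg = intensity_fg, intensity_bg = intensity_bg,
                 noise_sd = noise_sd,
                 n_distractors = as.integer(n_distractors),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Anti-aliased coverage of a thick segment (stadium shape) on the pixel
# grid: coverage = clamp(radius + 0.5 - distance_to_segment, 0, 1).
segment_coverage <- function(H, W, x0, y0, x1, y1, radius) {
  lo_x <- max(1L, floor(min(x0, x1) - radius - 1))
  hi_x <- min(W, ceiling(max(x0, x1) + radius + 1))
  lo_y <- max(1L, floor(min(y0, y1) - radius - 1))
  hi_y <- min(H, ceiling(max(y0, y1) + radius + 1))
  if (lo_x > hi_x || lo_y > hi_y) return(NULL)
  xs <- lo_x:hi_x
  ys <- lo_y:hi_y
  px <- matrix(rep(xs, each = length(ys)), length(ys))
  py <- matrix(rep(ys, times = length(xs)), length(ys))
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx * vx + vy * vy
  if (len2 < 1e-12) {
    dist <- sqrt((px - x0)^2 + (py - y0)^2)
  } else {
    t <- pmin(pmax(((px - x0) * vx + (py - y0) * vy) / len2, 0), 1)
    dist <- sqrt((px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2)
  }
  cov <- pmin(pmax(radius + 0.5 - dist, 0), 1)
  list(rows = ys, cols = xs, cov = cov)
}

clamp_point <- function(x, y, H, W, margin = 2) {
  c(min(max(x, 1 + margin), W - margin), min(max(y, 1 + margin), H - margin))
}

#' Generate one branching-airway phantom slice
#'
#' Draws a recursive binary tree of tubes (radius shrinking by
#' `radius_decay` per generation, endpoints clamped inside the image so the
#' mask is one connected component), overlays per-branch foreground
#' intensities on a textured background, adds Gaussian noise and clips to
#' `[0, 255]`. Fully deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param id sample identifier string.
#' @return a `slice_sample`: list with `image` (H x W in `[0, 255]`),
#'   `mask` (H x W in `{0, 1}`) and `id`; the per-generation newly claimed
#'   mask pixel counts are attached as attribute `gen_pixels`.
#' @export
generate_phantom <- function(spec, id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  H <- spec$image_size; W <- spec$image_size
  radii <- spec$root_radius_px * spec$radius_decay^(seq_len(spec$n_generations) - 1L)
  n_gen <- sum(radii >= 1)
  if (n_gen < spec$n_generations)
    warning("terminal radii fall below 1 px; depth truncated to ", n_gen,
            " generations")
  n_gen <- max(n_gen, 1L)
  cov_total <- matrix(0, H, W)
  gen_pixels <- integer(n_gen)
  gen_of <- matrix(0L, H, W)
  fg_int <- matrix(0, H, W)
  len0 <- spec$image_size * 0.32
  start <- clamp_point(W / 2 + runif(1, -W / 8, W / 8), H * 0.92, H, W)
  branches <- list(list(x = start[1], y = start[2],
                        angle = -90 + runif(1, -10, 10), gen = 1L))
  while (length(branches) > 0L) {
    nxt <- list()
    for (br in branches) {
      g <- br$gen
      if (g > n_gen) next
      len <- len0 * 0.72^(g - 1L) * runif(1, 0.85, 1.15)
      rad <- spec$root_radius_px * spec$radius_decay^(g - 1L)
      th <- br$angle * pi / 180
      endp <- clamp_point(br$x + len * cos(th), br$y + len * sin(th), H, W)
      seg <- segment_coverage(H, W, br$x, br$y, endp[1], endp[2], rad)
      if (!is.null(seg)) {
        sub <- cov_total[seg$rows, seg$cols]
        new_mask <- seg$cov >= 0.5 & sub < 0.5
        gen_pixels[g] <- gen_pixels[g] + sum(new_mask)
        gsub <- gen_of[seg$rows, seg$cols]
        gsub[new_mask] <- g
        gen_of[seg$rows, seg$cols] <- gsub
        cov_total[seg$rows, seg$cols] <- pmax(sub, seg$cov)
        isub <- fg_int[seg$rows, seg$cols]
        bri <- runif(1, spec$intensity_fg[1], spec$intensity_fg[2])
        isub[seg$cov > 0 & isub == 0] <- bri
        fg_int[seg$rows, seg$cols] <- isub
      }
      if (g < n_gen) {
        spread <- runif(2, spec$branch_angle_deg[1], spec$branch_angle_deg[2])
        nxt[[length(nxt) + 1L]] <- list(x = endp[1], y = endp[2],
                                        angle = br$angle - spread[1],
                                        gen = g + 1L)
        nxt[[length(nxt) + 1L]] <- list(x = endp[1], y = endp[2],
                                        angle = br$angle + spread[2],
                                        gen = g + 1L)
      }
    }
    branches <- nxt
  }
  mask <- (cov_total >= 0.5) * 1
  # textured background: low-frequency field inside the background range
  bg_mid <- mean(spec$intensity_bg)
  bg_amp <- diff(spec$intensity_bg) / 2
  coarse <- matrix(runif(64, -1, 1), 8, 8)
  texture <- resize_bilinear(coarse, H, W)
  bg <- bg_mid + bg_amp * 0.8 * texture
  # bright elliptical distractors at foreground-like intensity, not part of
  # the mask: airway-lookalike tissue that defeats intensity thresholding
  n_dis <- spec$n_distractors %||% 0L
  if (n_dis > 0L) {
    rad_rng <- c(0.02, 0.055) * spec$image_size
    px <- matrix(rep(seq_len(W), each = H), H)
    py <- matrix(rep(seq_len(H), times = W), H)
    for (k in seq_len(n_dis)) {
      cx <- runif(1, 1, W); cy <- runif(1, 1, H)
      ra <- runif(1, rad_rng[1], rad_rng[2])
      rb <- runif(1, rad_rng[1], rad_rng[2])
      th <- runif(1, 0, pi)
      bri <- runif(1, spec$intensity_fg[1], spec$intensity_fg[2])
      u <- (px - cx) * cos(th) + (py - cy) * sin(th)
      v <- -(px - cx) * sin(th) + (py - cy) * cos(th)
      dcov <- pmin(pmax(1.5 - sqrt((u / ra)^2 + (v / rb)^2), 0), 1)
      bg <- bg * (1 - dcov) + bri * dcov
    }
  }
  img <- bg * (1 - cov_total) + fg_int * cov_total
  img <- img + rnorm(H * W, sd = spec$noise_sd)
  img <- pmin(pmax(img, 0), 255)
  structure(list(image = img, mask = mask, id = id,
                 gen_pixels = gen_pixels),
            class = "slice_sample")
}

#' Generate a train/test phantom corpus
#'
#' Each sample gets its own sub-seed drawn from the master seed, so splits
#' are disjoint and the whole corpus is reproducible.
#'
#' @param spec a [phantom_spec()] used as template (its `seed` is replaced
#'   per sample).
#' @param n_train,n_test split sizes (>= 1).
#' @param seed master seed.
#' @return list with `train` and `test` sample lists.
#' @export
generate_corpus <- function(spec, n_train, n_test, seed = 1L) {
  stopifnot(n_train >= 1L, n_test >= 1L)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_train + n_test)
  make <- function(i, split) {
    s <- spec
    s$seed <- sub_seeds[i]
    generate_phantom(s, id = sprintf("%s_%03d", split,
                                     if (split == "train") i else i - n_train))
  }
  list(train = lapply(seq_len(n_train), make, split = "train"),
       test = lapply(n_train + seq_len(n_test), make, split = "test"))
}

#' Geometric augmentation of a slice sample
#'
#' Applies one transform from `ops` (chosen uniformly when several are
#' given, using `seed`) to image and mask alike. All transforms are pixel
#' permutations, so the mask stays binary and its pixel count is unchanged.
#'
#' @param sample a `slice_sample`.
#' @param ops nonempty subset of `c("hflip", "vflip", "rot90", "rot180",
#'   "rot270")`.
#' @param seed optional seed for the transform choice.
#' @return the transformed `slice_sample`.
#' @export
augment <- function(sample, ops, seed = NULL) {
  ops <- match.arg(ops, c("hflip", "vflip", "rot90", "rot180", "rot270"),
                   several.ok = TRUE)
  if (length(ops) > 1L) {
    if (!is.null(seed)) set.seed(seed)
    op <- sample(ops, 1L)
  } else op <- ops
  tf <- switch(op,
               hflip = function(m) m[, rev(seq_len(ncol(m))), drop = FALSE],
               vflip = function(m) m[rev(seq_len(nrow(m))), , drop = FALSE],
               rot90 = function(m) t(m)[rev(seq_len(ncol(m))), ,
                                        drop = FALSE],
               rot180 = function(m) m[rev(seq_len(nrow(m))),
                                      rev(seq_len(ncol(m))), drop = FALSE],
               rot270 = function(m) t(m)[, rev(seq_len(nrow(m))),
                                         drop = FALSE])
  out <- sample
  out$image <- tf(sample$image)
  out$mask <- tf(sample$mask)
  out
}

#' Free-angle rotation of a slice sample (nearest-neighbour resampling)
#'
#' Exact multiples of 90 degrees should use [augment()]; this variant
#' exists for augmentation studies needing arbitrary angles.
#'
#' @param sample a `slice_sample`.
#' @param angle_deg rotation angle in degrees (counter-clockwise).
#' @param fill background fill value for pixels rotated in from outside.
#' @return the rotated `slice_sample` (mask stays binary).
#' @export
augment_rotate <- function(sample, angle_deg, fill = 0) {
  th <- angle_deg * pi / 180
  H <- nrow(sample$image); W <- ncol(sample$image)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  py <- matrix(rep(seq_len(H), W), H) - cy
  px <- matrix(rep(seq_len(W), each = H), H) - cx
  sx <- round(cos(th) * px + sin(th) * py + cx)
  sy <- round(-sin(th) * px + cos(th) * py + cy)
  ok <- as.vector(sx >= 1 & sx <= W & sy >= 1 & sy <= H)
  idx <- cbind(as.vector(pmin(pmax(sy, 1), H)),
               as.vector(pmin(pmax(sx, 1), W)))
  rot <- function(m, fill) {
    out <- matrix(fill, H, W)
    out[ok] <- m[idx[ok, , drop = FALSE]]
    out
  }
  out <- sample
  out$image <- rot(sample$image, fill)
  out$mask <- rot(sample$mask, 0)
  out
}

# Matrix resizing (background texture and slice preprocessing) is delegated
# to EBImage; rows map to the first image dimension.
resize_bilinear <- function(m, H, W) {
  if (nrow(m) == H && ncol(m) == W) return(m)
  as.matrix(EBImage::resize(m, w = H, h = W, filter = "bilinear"))
}

resize_nearest <- function(m, H, W) {
  if (nrow(m) == H && ncol(m) == W) return(m)
  as.matrix(EBImage::resize(m, w = H, h = W, filter = "none"))
}
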