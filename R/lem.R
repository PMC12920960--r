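# Learnable variance-based embedding module (LEM).
#
# For each (batch item, channel), the spatial mean mu and the unbiased
# spatial variance of the squared deviations drive a scaling field
#     y  = deviation / (k * sigma^2) + 0.5,   sigma^2 = var + epsilon,
#     y' = sigmoid(y),
# which reweights the features. Because deviation >= 0, y >= 0.5 everywhere
# and y' lies in (sigmoid(0.5), 1). The field is (nearly) invariant to affine
# maps of the input: deviation and variance both scale by a^2, so their ratio
# cancels up to O(epsilon / sigma^2).

#' LEM configuration
#'
#' @param epsilon variance stabiliser added to the unbiased spatial variance
#'   (default `1e-4`).
#' @param k sensitivity divisor of the deviation-to-variance ratio
#'   (default 4; smaller k reacts more strongly to local variance).
#' @param scaling_mode how the sigmoid field `y'` is applied:
#'   `"multiplicative"` (`x * y'`), `"additive"` (`x + y'`) or `"hybrid"`
#'   (`x * y' + y'`).
#' @param learnable logical; when `TRUE`, `epsilon` and `k` are treated as
#'   trainable positive scalars (softplus-parameterised, initialised at the
#'   given values). The default frozen mode reproduces the closed-form
#'   behaviour exactly.
#' @return an object of class `lem_config`.
#' @export
lem_config <- function(epsilon = 1e-4, k = 4, scaling_mode = "multiplicative",
                       learnable = FALSE) {
  stopifnot(epsilon > 0, k > 0)
  scaling_mode <- match.arg(scaling_mode,
                            c("multiplicative", "additive", "hybrid"))
  structure(list(epsilon = epsilon, k = k, scaling_mode = scaling_mode,
                 learnable = learnable),
            class = "lem_config")
}

softplus_ <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_inv_ <- function(y) ifelse(y > 30, y, log(expm1(y)))

#' @export
lem_init <- function(cfg) {
  if (!isTRUE(cfg$learnable)) return(list())
  list(rho_eps = softplus_inv_(cfg$epsilon), rho_k = softplus_inv_(cfg$k))
}

lem_resolve <- function(cfg, params = NULL) {
  if (isTRUE(cfg$learnable) && !is.null(params$rho_eps))
    list(eps = softplus_(params$rho_eps), k = softplus_(params$rho_k))
  else
    list(eps = cfg$epsilon, k = cfg$k)
}

#' Variance-based feature reweighting (LEM forward pass)
#'
#' @param x feature map, dim `c(B, C, H, W)` with `H * W >= 2`.
#' @param cfg a [lem_config()].
#' @param params optional trainable parameters from [lem_init()] (learnable
#'   mode only).
#' @param with_cache logical; also return intermediate fields for the
#'   backward pass and for diagnostics.
#' @return the reweighted array, or (with `with_cache = TRUE`) a list with
#'   `y` (the scaled output), `yp` (the sigmoid field), `yfield` (the raw
#'   scaling field) and `cache`.
#' @export
lem_forward <- function(x, cfg, params = NULL, with_cache = FALSE) {
  d <- check_feature_map(x)
  n <- d[3] * d[4]
  if (n < 2L)
    stop("LEM requires H * W >= 2 (unbiased variance undefined)",
         call. = FALSE)
  hp <- lem_resolve(cfg, params)
  m <- x
  dim(m) <- c(d[1] * d[2], n)
  mu <- rowMeans(m)
  dev <- (m - mu)^2
  s2 <- rowSums(dev) / (n - 1) + hp$eps
  yf <- dev / (hp$k * s2) + 0.5
  yp <- sigmoid_(yf)
  out <- switch(cfg$scaling_mode,
                multiplicative = m * yp,
                additive = m + yp,
                hybrid = m * yp + yp)
  dim(out) <- d
  if (!with_cache) return(out)
  yfield <- yf; dim(yfield) <- d
  ypfield <- yp; dim(ypfield) <- d
  list(y = out, yp = ypfield, yfield = yfield,
       cache = list(m = m, mu = mu, dev = dev, s2 = s2, yf = yf, yp = yp,
                    dim = d, n = n, eps = hp$eps, k = hp$k))
}

# Backward pass; dout has the shape of x. Returns dx and, in learnable mode,
# gradients for rho_eps / rho_k.
lem_backward <- function(dout, cfg, cache, params = NULL) {
  d <- cache$dim
  n <- cache$n
  k <- cache$k
  m <- cache$m; mu <- cache$mu; dev <- cache$dev
  s2 <- cache$s2; yp <- cache$yp
  dmat <- dout
  dim(dmat) <- dim(m)
  d_yp <- switch(cfg$scaling_mode,
                 multiplicative = dmat * m,
                 additive = dmat,
                 hybrid = dmat * (m + 1))
  dx_direct <- switch(cfg$scaling_mode,
                      multiplicative = dmat * yp,
                      additive = dmat,
                      hybrid = dmat * yp)
  dY <- d_yp * yp * (1 - yp)
  ks2 <- k * s2
  tsum <- rowSums(dY * dev)                       # per (b, c)
  ddev <- dY / ks2 - tsum / (k * s2^2 * (n - 1))
  xm <- m - mu
  dx <- dx_direct + ddev * 2 * xm
  dx <- dx - rowSums(ddev * 2 * xm) / n
  grads <- NULL
  if (isTRUE(cfg$learnable) && !is.null(params$rho_eps)) {
    d_eps <- -sum(rowSums(dY * dev) / (k * s2^2))
    d_k <- -sum(rowSums(dY * dev) / (k^2 * s2))
    grads <- list(rho_eps = d_eps * sigmoid_(params$rho_eps),
                  rho_k = d_k * sigmoid_(params$rho_k))
  }
  dim(dx) <- d
  list(dx = dx, grads = grads)
}

#' Sensitivity sweep of the LEM scaling field over epsilon and k
#'
#' Recomputes the raw scaling field `y` for a fixed input across grids of
#' `epsilon` and `k` and summarises its spread around the neutral value 0.5.
#' `(y - 0.5)` is exactly inversely proportional to `k` at fixed epsilon,
#' and its maximum is nonincreasing in epsilon.
#'
#' @param x feature map, dim `c(B, C, H, W)`.
#' @param epsilons nonempty numeric vector of stabiliser values.
#' @param ks nonempty numeric vector of sensitivity divisors.
#' @return a data frame with one row per (epsilon, k) combination and
#'   summaries of the y field.
#' @export
lem_sensitivity_sweep <- function(x, epsilons = c(1e-3, 1e-4, 1e-5),
                                  ks = c(2, 4, 8)) {
  stopifnot(length(epsilons) >= 1L, length(ks) >= 1L)
  rows <- list()
  for (eps in epsilons) {
    for (k in ks) {
      cfg <- lem_config(epsilon = eps, k = k)
      fw <- lem_forward(x, cfg, with_cache = TRUE)
      yc <- fw$yfield - 0.5
      rows[[length(rows) + 1L]] <- data.frame(
        epsilon = eps, k = k,
        max_y_excess = max(yc),
        mean_y_excess = mean(yc),
        min_yp = min(fw$yp), max_yp = max(fw$yp))
    }
  }
  do.call(rbind, rows)
}
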