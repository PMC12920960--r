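# Independent naive-loop reference implementations used to validate the
# vectorised operators. These deliberately share no code with the package
# internals: everything is scalar arithmetic in plain loops.

oracle_conv2d <- function(x, W, b, k, pad, stride = 1L,
                          replicate_pad = FALSE) {
  d <- dim(x)
  B <- d[1]; C <- d[2]; H <- d[3]; Wd <- d[4]
  Co <- nrow(W)
  Ho <- (H + 2 * pad - k) %/% stride + 1L
  Wo <- (Wd + 2 * pad - k) %/% stride + 1L
  y <- array(0, c(B, Co, Ho, Wo))
  for (bb in 1:B) for (co in 1:Co) for (ho in 1:Ho) for (wo in 1:Wo) {
    s <- b[co]
    for (ci in 1:C) for (dh in 1:k) for (dw in 1:k) {
      hh <- (ho - 1) * stride - pad + dh
      ww <- (wo - 1) * stride - pad + dw
      if (replicate_pad) {
        hh <- min(max(hh, 1), H)
        ww <- min(max(ww, 1), Wd)
      }
      if (hh >= 1 && hh <= H && ww >= 1 && ww <= Wd)
        s <- s + W[co, (ci - 1) * k * k + (dh - 1) * k + dw] *
          x[bb, ci, hh, ww]
    }
    y[bb, co, ho, wo] <- s
  }
  y
}

oracle_sigmoid <- function(z) 1 / (1 + exp(-z))

# Multi-head scaled dot-product attention over B x N x C tokens.
oracle_iam <- function(x, params, heads) {
  d <- dim(x)
  B <- d[1]; N <- d[2]; C <- d[3]
  D <- C %/% heads
  out <- array(0, d)
  lin <- function(v, p) as.numeric(v %*% p$W) + p$b
  for (bb in 1:B) {
    X <- matrix(x[bb, , ], N, C)
    Q <- t(apply(X, 1, lin, p = params$q))
    K <- t(apply(X, 1, lin, p = params$k))
    V <- t(apply(X, 1, lin, p = params$v))
    if (C == 1) { Q <- t(Q); K <- t(K); V <- t(V) }
    O <- matrix(0, N, C)
    for (h in 1:heads) {
      idx <- ((h - 1) * D + 1):(h * D)
      for (i in 1:N) {
        sc <- numeric(N)
        for (j in 1:N)
          sc[j] <- sum(Q[i, idx] * K[j, idx]) / sqrt(D)
        w <- exp(sc - max(sc))
        w <- w / sum(w)
        for (dd in idx)
          O[i, dd] <- sum(w * V[, dd])
      }
    }
    Y <- t(apply(O, 1, lin, p = params$o))
    if (C == 1) Y <- t(Y)
    out[bb, , ] <- Y
  }
  out
}

oracle_pam <- function(f, params, k) {
  d <- dim(f)
  B <- d[1]; C <- d[2]; H <- d[3]; Wd <- d[4]
  xcat <- array(0, c(B, 2, H, Wd))
  for (bb in 1:B) for (h in 1:H) for (w in 1:Wd) {
    v <- f[bb, , h, w]
    xcat[bb, 1, h, w] <- max(v)
    xcat[bb, 2, h, w] <- mean(v)
  }
  oracle_sigmoid(oracle_conv2d(xcat, params$conv$W, params$conv$b, k,
                               (k - 1) %/% 2, replicate_pad = TRUE))
}

oracle_channel_gate <- function(f, params) {
  d <- dim(f)
  B <- d[1]; C <- d[2]
  out <- array(0, c(B, C, 1, 1))
  mlp <- function(v) {
    h <- pmax(as.numeric(v %*% params$fc1$W) + params$fc1$b, 0)
    as.numeric(h %*% params$fc2$W) + params$fc2$b
  }
  for (bb in 1:B) {
    mp <- numeric(C); ap <- numeric(C)
    for (cc in 1:C) {
      mp[cc] <- max(f[bb, cc, , ])
      ap[cc] <- mean(f[bb, cc, , ])
    }
    out[bb, , 1, 1] <- oracle_sigmoid(mlp(mp) + mlp(ap))
  }
  out
}

oracle_csam <- function(f, params, k) {
  d <- dim(f)
  B <- d[1]; H <- d[3]; Wd <- d[4]
  xcat <- array(0, c(B, 2, H, Wd))
  for (bb in 1:B) for (h in 1:H) for (w in 1:Wd) {
    v <- f[bb, , h, w]
    xcat[bb, 1, h, w] <- mean(v)
    xcat[bb, 2, h, w] <- max(v)
  }
  oracle_sigmoid(oracle_conv2d(xcat, params$conv$W, params$conv$b, k,
                               (k - 1) %/% 2, replicate_pad = TRUE))
}

oracle_lem <- function(x, epsilon, k, mode = "multiplicative") {
  d <- dim(x)
  out <- array(0, d)
  for (bb in 1:d[1]) for (cc in 1:d[2]) {
    n <- d[3] * d[4]
    mu <- 0
    for (h in 1:d[3]) for (w in 1:d[4]) mu <- mu + x[bb, cc, h, w]
    mu <- mu / n
    s2 <- 0
    for (h in 1:d[3]) for (w in 1:d[4])
      s2 <- s2 + (x[bb, cc, h, w] - mu)^2
    s2 <- s2 / (n - 1) + epsilon
    for (h in 1:d[3]) for (w in 1:d[4]) {
      dev <- (x[bb, cc, h, w] - mu)^2
      yp <- oracle_sigmoid(dev / (k * s2) + 0.5)
      out[bb, cc, h, w] <- switch(mode,
                                  multiplicative = x[bb, cc, h, w] * yp,
                                  additive = x[bb, cc, h, w] + yp,
                                  hybrid = x[bb, cc, h, w] * yp + yp)
    }
  }
  out
}

oracle_dice <- function(pred, gt, smooth = 0) {
  i <- 0; p <- 0; g <- 0
  for (j in seq_along(pred)) {
    i <- i + pred[j] * gt[j]
    p <- p + pred[j]
    g <- g + gt[j]
  }
  if (p + g + smooth == 0) return(1)
  (2 * i + smooth) / (p + g + smooth)
}

oracle_iou <- function(pred, gt, smooth = 0) {
  i <- sum(pred * gt)
  u <- sum(pred) + sum(gt) - i
  if (u + smooth == 0) return(1)
  (i + smooth) / (u + smooth)
}

# random feature map helper
rand_fmap <- function(B, C, H, W) array(rnorm(B * C * H * W), c(B, C, H, W))
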