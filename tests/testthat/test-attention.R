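# Unit tests of the five attention operators: shape and codomain
# contracts, spec-level closed-form examples, naive-loop oracle agreement
# and error handling.

test_that("IAM softmax rows normalise and single-key attention is identity", {
  set.seed(1)
  # N = 1: softmax over one key is 1, so the attended value is V and the
  # output is the output projection of V
  p <- iam_init(4L, heads = 2L)
  x1 <- array(rnorm(4), c(1, 1, 4))
  out <- iam_forward(x1, p, heads = 2L)
  V <- airseg:::linear_forward(matrix(x1[1, , ], 1, 4), p$v)
  expect_equal(as.numeric(out$tokens[1, , ]),
               as.numeric(airseg:::linear_forward(V, p$o)), tolerance = 1e-12)
  # attention rows sum to 1
  x <- array(rnorm(1 * 4 * 6), c(1, 4, 6))
  p6 <- iam_init(6L, heads = 3L)
  out <- iam_forward(x, p6, heads = 3L, return_attn = TRUE)
  for (h in 1:3)
    expect_equal(rowSums(out$attn[1, h, , ]), rep(1, 4), tolerance = 1e-6)
})

test_that("IAM matches a hand-evaluated scaled dot-product oracle", {
  # B=1, N=2, C=2, one head, identity projections, zero bias:
  # scores = x x' / sqrt(2), output = softmax(scores) %*% x
  p <- iam_init(2L, heads = 1L)
  for (nm in c("q", "k", "v", "o")) {
    p[[nm]]$W <- diag(2)
    p[[nm]]$b <- c(0, 0)
  }
  x <- array(0, c(1, 2, 2))
  x[1, , ] <- diag(2)                      # tokens [1,0], [0,1]
  out <- iam_forward(x, p, heads = 1L)
  S <- diag(2) %*% t(diag(2)) / sqrt(2)
  A <- t(apply(S, 1, function(r) exp(r) / sum(exp(r))))
  expect_equal(out$tokens[1, , ], A %*% diag(2), tolerance = 1e-6)
  # and against the generic naive oracle with random weights
  set.seed(7)
  pr <- iam_init(4L, heads = 2L)
  xr <- array(rnorm(2 * 5 * 4), c(2, 5, 4))
  expect_equal(iam_forward(xr, pr, heads = 2L)$tokens,
               oracle_iam(xr, pr, 2L), tolerance = 1e-6)
})

test_that("IAM rejects invalid configurations", {
  expect_error(iam_init(7L, heads = 3L), "divisible")
  p <- iam_init(4L, heads = 2L)
  expect_error(iam_forward(array(rnorm(4), c(1, 1, 4)), p, heads = 3L),
               "divisible")
  expect_error(iam_forward(array(0, c(1, 0, 4)), p, heads = 2L), "empty")
})

test_that("image gate reduces tokens to sigmoid-squashed per-item scalars", {
  set.seed(2)
  x <- array(rnorm(3 * 6 * 5), c(3, 6, 5))
  p <- gate_init(5L)
  p$W[] <- 0; p$b[] <- 0
  expect_equal(as.numeric(image_gate(x, p)$map), rep(0.5, 3))
  p$b[] <- 20
  expect_equal(as.numeric(image_gate(x, p)$map), rep(1, 3),
               tolerance = 1e-6)
  p2 <- gate_init(5L)
  g <- image_gate(x, p2)$map
  expect_identical(dim(g), c(3L, 1L, 1L, 1L))
  expect_true(all(g >= 0 & g <= 1))
})

test_that("positional attention pools channels and matches the loop oracle", {
  set.seed(3)
  p <- pam_init(3L)
  # C = 1: channel max and mean both equal the slice itself
  f1 <- rand_fmap(2, 1, 5, 5)
  m <- positional_attention(f1, p, 3L)$map
  expect_identical(dim(m), c(2L, 1L, 5L, 5L))
  expect_true(all(m >= 0 & m <= 1))
  # constant input -> constant map sigmoid(c * sum(W) + b) everywhere
  cc <- 1.7
  fc <- array(cc, c(1, 3, 6, 6))
  mc <- positional_attention(fc, p, 3L)$map
  expect_equal(as.numeric(mc),
               rep(1 / (1 + exp(-(cc * sum(p$conv$W) + p$conv$b))), 36),
               tolerance = 1e-9)
  # random input vs naive oracle
  f <- rand_fmap(2, 4, 6, 7)
  expect_equal(positional_attention(f, p, 3L)$map, oracle_pam(f, p, 3L),
               tolerance = 1e-6)
  expect_error(pam_init(4L), "odd")
  expect_error(positional_attention(f, p, 4L), "odd")
})

test_that("semantic attention weights channels globally", {
  set.seed(4)
  C <- 4L
  p <- sam_init(C, mlp_reduction = 2L)
  f <- rand_fmap(2, C, 5, 5)
  r <- semantic_attention(f, p)
  expect_identical(dim(r$map), c(2L, C, 1L, 1L))
  expect_true(all(r$map >= 0 & r$map <= 1))
  expect_equal(r$map, oracle_channel_gate(f, p), tolerance = 1e-6)
  # identity MLP on an input whose spatial max equals its mean per channel
  # gives sigmoid(2 v_c)
  pid <- list(fc1 = list(W = diag(C), b = numeric(C)),
              fc2 = list(W = diag(C), b = numeric(C)))
  v <- c(0.2, 0.5, 0.9, 1.4)
  fconst <- array(rep(v, each = 2), c(2, C, 3, 3))
  expect_equal(as.numeric(semantic_attention(fconst, pid)$map[1, , 1, 1]),
               1 / (1 + exp(-2 * v)), tolerance = 1e-9)
  # gating ratio is constant across all pixels of a channel
  g <- airseg:::broadcast_map(r$map, dim(f))
  fp <- f * g
  ratio <- fp / f
  for (cc in 1:C)
    expect_lt(diff(range(ratio[1, cc, , ])), 1e-12)
})

test_that("self-channel attention matches its oracle and default ratio", {
  set.seed(5)
  expect_identical(airseg_config()$scam_ratio, 16L)
  p <- scam_init(8L, ratio = 4L)
  f <- rand_fmap(2, 8, 4, 4)
  r <- self_channel_attention(f, p)
  expect_identical(dim(r$map), c(2L, 8L, 1L, 1L))
  expect_true(all(r$map >= 0 & r$map <= 1))
  expect_equal(r$map, oracle_channel_gate(f, p), tolerance = 1e-6)
  # bottleneck width clamps to >= 1
  p1 <- scam_init(2L, ratio = 16L)
  expect_identical(ncol(p1$fc1$W), 1L)
})

test_that("SAM and SCAM maps are invariant to spatial pixel permutation", {
  set.seed(6)
  f <- rand_fmap(2, 4, 4, 5)
  perm <- sample(20)
  fp <- f
  for (bb in 1:2) for (cc in 1:4) {
    v <- as.numeric(f[bb, cc, , ])
    fp[bb, cc, , ] <- array(v[perm], c(4, 5))
  }
  ps <- sam_init(4L, 2L)
  pc <- scam_init(4L, 2L)
  expect_equal(semantic_attention(f, ps)$map,
               semantic_attention(fp, ps)$map, tolerance = 1e-12)
  expect_equal(self_channel_attention(f, pc)$map,
               self_channel_attention(fp, pc)$map, tolerance = 1e-12)
})

test_that("cross-spatial attention: conventional vs literal closed form", {
  set.seed(7)
  p <- csam_init(3L)
  f <- rand_fmap(2, 4, 6, 6)
  r <- cross_spatial_attention(f, p, 3L)
  expect_identical(dim(r$map), c(2L, 1L, 6L, 6L))
  expect_true(all(r$map >= 0 & r$map <= 1))
  expect_equal(r$map, oracle_csam(f, p, 3L), tolerance = 1e-6)
  # constant input through the conventional path is spatially constant
  fc <- array(0.4, c(1, 3, 6, 6))
  mc <- cross_spatial_attention(fc, p, 3L)$map
  expect_lt(diff(range(mc)), 1e-12)
  expect_true(mc[1] > 0 && mc[1] < 1)
  # literal mode: global pools make the map spatially uniform per item
  ml <- cross_spatial_attention(f, p, 3L, literal = TRUE)$map
  for (bb in 1:2) expect_equal(diff(range(ml[bb, 1, , ])), 0)
  expect_error(csam_init(5L), "3 or 7")
  expect_error(cross_spatial_attention(f, p, 5L), "3 or 7")
})

test_that("attention operator backward passes match finite differences", {
  set.seed(8)
  fd_input <- function(fun, x, g_analytic, n = 8, tol = 1e-6) {
    idx <- sample(length(x), n)
    for (i in idx) {
      eps <- 1e-6
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      fd <- (fun(xp) - fun(xm)) / (2 * eps)
      expect_lt(abs(g_analytic[i] - fd), tol)
    }
  }
  f <- rand_fmap(2, 4, 4, 4)
  # PAM
  p <- pam_init(3L)
  r <- positional_attention(f, p, 3L)
  w <- array(rnorm(length(r$map)), dim(r$map))
  bk <- airseg:::pam_backward(w, p, r$cache)
  fd_input(function(z) sum(positional_attention(z, p, 3L)$map * w), f, bk$dx)
  # SCAM
  p2 <- scam_init(4L, 2L)
  r2 <- self_channel_attention(f, p2)
  w2 <- array(rnorm(length(r2$map)), dim(r2$map))
  bk2 <- airseg:::scam_backward(w2, p2, r2$cache)
  fd_input(function(z) sum(self_channel_attention(z, p2)$map * w2), f,
           bk2$dx)
  # CSAM literal
  p3 <- csam_init(3L)
  r3 <- cross_spatial_attention(f, p3, 3L, literal = TRUE)
  w3 <- array(rnorm(length(r3$map)), dim(r3$map))
  bk3 <- airseg:::csam_backward(w3, p3, r3$cache)
  fd_input(function(z)
    sum(cross_spatial_attention(z, p3, 3L, literal = TRUE)$map * w3), f,
    bk3$dx)
})
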