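# Block composition: identity gating, broadcasting contracts, stage
# disabling, fusion-mode relationships and gradient flow.

# Configure every stage so its attention map is exactly 1 (sigmoid
# saturated by a large bias with zero weights).
saturate_block <- function(p) {
  if (!is.null(p$gate)) { p$gate$W[] <- 0; p$gate$b[] <- 50 }
  if (!is.null(p$pam)) { p$pam$conv$W[] <- 0; p$pam$conv$b[] <- 50 }
  if (!is.null(p$sam)) {
    p$sam$fc1$W[] <- 0; p$sam$fc1$b[] <- 0
    p$sam$fc2$W[] <- 0; p$sam$fc2$b[] <- 50
  }
  if (!is.null(p$scam)) {
    p$scam$fc1$W[] <- 0; p$scam$fc1$b[] <- 0
    p$scam$fc2$W[] <- 0; p$scam$fc2$b[] <- 50
  }
  if (!is.null(p$csam)) { p$csam$conv$W[] <- 0; p$csam$conv$b[] <- 50 }
  p
}

small_cfg <- function(...) {
  airseg_config(heads = 2L, pam_kernel = 3L, sam_reduction = 2L,
                scam_ratio = 2L, csam_kernel = 3L, patch_size = 2L, ...)
}

test_that("identity gating returns the input exactly", {
  set.seed(21)
  f <- rand_fmap(2, 4, 4, 4)
  cfg <- small_cfg(embedding = "none")
  p <- saturate_block(airseg_init(4L, cfg))
  expect_identical(airseg_forward(f, p, cfg), f)
})

test_that("fully multiplicative gating never amplifies features", {
  set.seed(22)
  f <- rand_fmap(2, 4, 8, 8)
  cfg <- small_cfg()                      # sequential + multiplicative LEM
  p <- airseg_init(4L, cfg)
  y <- airseg_forward(f, p, cfg)
  expect_identical(dim(y), dim(f))
  expect_true(all(abs(y) <= abs(f) + 1e-12))
})

test_that("broadcasting applies channel maps per channel and spatial maps per pixel", {
  set.seed(23)
  f <- rand_fmap(2, 3, 4, 4)
  d <- dim(f)
  # channel-shaped map: one scalar per channel across all pixels
  ps <- sam_init(3L, 1L)
  ms <- semantic_attention(f, ps)$map
  g <- f * airseg:::broadcast_map(ms, d)
  for (cc in 1:3)
    expect_lt(diff(range((g / f)[1, cc, , ])), 1e-12)
  # spatially shaped map: one scalar per pixel across all channels
  pp <- pam_init(3L)
  mp <- positional_attention(f, pp, 3L)$map
  g2 <- f * airseg:::broadcast_map(mp, d)
  r2 <- g2 / f
  for (h in 1:4) for (w in 1:4)
    expect_lt(diff(range(r2[1, , h, w])), 1e-12)
})

test_that("disabling a stage equals substituting a unit map", {
  set.seed(24)
  f <- rand_fmap(1, 4, 4, 4)
  masks <- c(image = TRUE, positional = TRUE, semantic = FALSE,
             schannel = TRUE, cspatial = TRUE)
  cfg_off <- small_cfg(embedding = "none", stage_mask = masks)
  cfg_on <- small_cfg(embedding = "none")
  set.seed(99); p_off <- airseg_init(4L, cfg_off)
  set.seed(99); p_on <- airseg_init(4L, cfg_on)
  # force the extra (semantic) stage of the full block to the unit map and
  # copy the shared stages
  p_on$sam$fc1$W[] <- 0; p_on$sam$fc1$b[] <- 0
  p_on$sam$fc2$W[] <- 0; p_on$sam$fc2$b[] <- 50
  for (nm in names(p_off)) p_on[[nm]] <- p_off[[nm]]
  expect_identical(airseg_forward(f, p_off, cfg_off),
                   airseg_forward(f, p_on, cfg_on))
  expect_error(small_cfg(stage_mask = rep(FALSE, 5)), "at least one")
})

test_that("sequential fusion equals composing the public operators", {
  set.seed(25)
  f <- rand_fmap(2, 4, 4, 6)
  cfg <- small_cfg()
  p <- airseg_init(4L, cfg)
  got <- airseg_forward(f, p, cfg)
  # reference composition through the exported operator surface
  d <- dim(f)
  cur <- f
  lemf <- function(z) lem_forward(z, cfg$lem, with_cache = TRUE)
  stage <- function(cur, map) {
    bm <- airseg:::broadcast_map(map, d)
    bm * lemf(cur)$y
  }
  tk <- tokens_from_feature <- airseg:::tokens_from_feature
  cur <- stage(cur, image_gate(iam_forward(tk(cur), p$iam, cfg$heads,
                                           cfg$dropout)$tokens,
                               p$gate)$map)
  cur <- stage(cur, positional_attention(cur, p$pam, cfg$pam_kernel)$map)
  cur <- stage(cur, semantic_attention(cur, p$sam)$map)
  cur <- stage(cur, self_channel_attention(cur, p$scam)$map)
  cur <- stage(cur, cross_spatial_attention(cur, p$csam,
                                            cfg$csam_kernel)$map)
  expect_equal(got, cur, tolerance = 1e-6)
})

test_that("sequential and parallel fusion coincide for input-independent maps", {
  set.seed(26)
  f <- array(0.8, c(2, 4, 4, 4))           # constant input
  base <- airseg_init(4L, small_cfg(embedding = "lem", csam_literal = TRUE))
  # zero weights + finite biases make every map input-independent
  base$gate$W[] <- 0; base$gate$b[] <- 0.3
  base$pam$conv$W[] <- 0; base$pam$conv$b[] <- 0.1
  base$sam$fc1$W[] <- 0; base$sam$fc2$W[] <- 0; base$sam$fc2$b[] <- 0.2
  base$scam$fc1$W[] <- 0; base$scam$fc2$W[] <- 0; base$scam$fc2$b[] <- -0.1
  base$csam$conv$W[] <- 0; base$csam$conv$b[] <- 0.4
  cfg_seq <- small_cfg(fusion_mode = "sequential", csam_literal = TRUE)
  cfg_par <- small_cfg(fusion_mode = "parallel", csam_literal = TRUE)
  y_seq <- airseg_forward(f, base, cfg_seq)
  y_par <- airseg_forward(f, base, cfg_par)
  expect_equal(y_seq, y_par, tolerance = 1e-9)
  # but they differ in general
  set.seed(27)
  fr <- rand_fmap(1, 4, 4, 4)
  pr <- airseg_init(4L, cfg_seq)
  expect_gt(max(abs(airseg_forward(fr, pr, cfg_seq) -
                      airseg_forward(fr, pr, cfg_par))), 1e-6)
})

test_that("sum fusion applies the averaged map once", {
  set.seed(28)
  f <- rand_fmap(1, 4, 4, 4)
  cfg <- small_cfg(fusion_mode = "sum", embedding = "none")
  p <- airseg_init(4L, cfg)
  y <- airseg_forward(f, p, cfg)
  d <- dim(f)
  maps <- list(
    image_gate(iam_forward(airseg:::tokens_from_feature(f), p$iam,
                           cfg$heads, cfg$dropout)$tokens, p$gate)$map,
    positional_attention(f, p$pam, cfg$pam_kernel)$map,
    semantic_attention(f, p$sam)$map,
    self_channel_attention(f, p$scam)$map,
    cross_spatial_attention(f, p$csam, cfg$csam_kernel)$map)
  M <- Reduce(`+`, lapply(maps, airseg:::broadcast_map, d = d)) / 5
  expect_equal(y, f * M, tolerance = 1e-9)
})

test_that("gradients reach every enabled stage and the embedding", {
  set.seed(29)
  f <- rand_fmap(2, 4, 4, 4)
  for (emb in c("lem", "patch", "cnn")) {
    cfg <- small_cfg(embedding = emb,
                     lem = lem_config(learnable = (emb == "lem")))
    p <- airseg_init(4L, cfg)
    fw <- airseg_forward(f, p, cfg, with_cache = TRUE)
    g <- airseg_backward(array(rnorm(length(fw$y)), dim(fw$y)), p, cfg,
                         fw$cache)
    expect_identical(dim(g$dx), dim(f))
    for (stage in names(p)) {
      leaves <- airseg:::ptree_flatten(g$grads[[stage]])
      vals <- unlist(leaves)
      expect_true(all(is.finite(vals)), label = paste("finite", stage))
      expect_gt(max(abs(vals)), 0)
    }
  }
})
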