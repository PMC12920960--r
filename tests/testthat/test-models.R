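# Model construction, forward contracts, determinism, the bare-backbone
# identity and checkpoint round-trips.

tiny_airseg <- function(...) {
  airseg_config(heads = 2L, pam_kernel = 3L, sam_reduction = 2L,
                scam_ratio = 2L, csam_kernel = 3L, ...)
}

test_that("forward pass maps images to probabilities of the same size", {
  spec <- model_spec(backbone = "unet", base_width = 8L, depth = 3L,
                     airseg = NULL)
  m <- build_model(spec, seed = 1)
  x <- array(0, c(2, 1, 16, 16))
  pr <- airseg:::model_forward(m, x)$prob
  expect_identical(dim(pr), c(2L, 1L, 16L, 16L))
  expect_true(all(is.finite(pr) & pr >= 0 & pr <= 1))
  expect_error(airseg:::model_forward(m, array(0, c(2, 1, 10, 10))),
               "divisible")
  expect_error(airseg:::model_forward(m, array(0, c(2, 2, 16, 16))), "dim")
})

test_that("adding AirSeg strictly increases the parameter count", {
  sp0 <- model_spec(backbone = "resunet", base_width = 8L, depth = 3L,
                    airseg = NULL)
  sp1 <- model_spec(backbone = "resunet", base_width = 8L, depth = 3L,
                    airseg = tiny_airseg(), airseg_placement = c(1, 2, 3))
  n0 <- sum(lengths(airseg:::ptree_flatten(build_model(sp0, 1)$params)))
  n1 <- sum(lengths(airseg:::ptree_flatten(build_model(sp1, 1)$params)))
  expect_gt(n1, n0)
})

test_that("construction is deterministic given spec and seed", {
  spec <- model_spec(base_width = 8L, depth = 3L, airseg = tiny_airseg(),
                     skip_style = "nested")
  m1 <- build_model(spec, seed = 42)
  m2 <- build_model(spec, seed = 42)
  expect_identical(m1$params, m2$params)
  x <- array(runif(1 * 1 * 16 * 16), c(1, 1, 16, 16))
  expect_identical(airseg:::model_forward(m1, x)$prob,
                   airseg:::model_forward(m2, x)$prob)
})

test_that("the without-AirSeg arm is bit-identical to the bare backbone", {
  with_spec <- model_spec(backbone = "resunet", base_width = 8L, depth = 3L,
                          airseg = tiny_airseg())
  bare_spec <- model_spec(backbone = "resunet", base_width = 8L, depth = 3L,
                          airseg = NULL)
  mw <- build_model(with_spec, seed = 5)
  mb <- build_model(bare_spec, seed = 5)
  fw <- airseg:::ptree_flatten(mw$params)
  fb <- airseg:::ptree_flatten(mb$params)
  expect_identical(fw[names(fb)], fb)
})

test_that("heads must divide the gated channel width", {
  spec <- model_spec(base_width = 8L, depth = 2L,
                     airseg = airseg_config(heads = 3L),
                     airseg_placement = 1L)
  expect_error(build_model(spec, 1), "divisible")
  expect_error(model_spec(depth = 1L), "depth")
  expect_error(model_spec(base_width = 2L), "base_width")
  expect_error(model_spec(airseg_placement = 5L, depth = 3L), "1..depth")
})

test_that("forward_infer thresholds with a >= rule", {
  spec <- model_spec(base_width = 4L, depth = 2L, airseg = NULL)
  m <- build_model(spec, 1)
  # direct comparison contract on synthetic probabilities
  pr <- array(runif(32), c(2, 1, 4, 4))
  expect_identical((pr >= 0.5) * 1, (pr >= 0.5) * 1)
  expect_equal(unique(as.numeric((array(0.7, c(1, 1, 2, 2)) >= 0.5) * 1)), 1)
  expect_equal(unique(as.numeric((array(0.5 - 1e-6, c(1, 1, 2, 2)) >= 0.5)
                                 * 1)), 0)
  # model path: output mask is binary with matching shape
  x <- array(runif(16), c(1, 1, 4, 4))
  mk <- forward_infer(m, x, threshold = 0.5)
  expect_true(all(mk %in% c(0, 1)))
  expect_identical(dim(mk), c(1L, 1L, 4L, 4L))
  pr2 <- airseg:::model_forward(m, x)$prob
  expect_identical(mk, (pr2 >= 0.5) * 1)
  expect_error(forward_infer(m, x, threshold = 1.2), "threshold")
})

test_that("checkpoints round-trip through the flat named-array container", {
  spec <- model_spec(base_width = 8L, depth = 2L, airseg = tiny_airseg(),
                     airseg_placement = 2L)
  m <- build_model(spec, seed = 9)
  path <- tempfile(fileext = ".ckpt")
  checkpoint_save(m, path)
  m2 <- checkpoint_load(path)
  expect_identical(m$params, m2$params)
  x <- array(runif(32), c(2, 1, 4, 4))
  expect_identical(airseg:::model_forward(m, x)$prob,
                   airseg:::model_forward(m2, x)$prob)
  saveRDS(list(a = 1), path)
  expect_error(checkpoint_load(path), "checkpoint")
})

test_that("a small AirSegRes trains one step within the time contract", {
  spec <- model_spec(backbone = "resunet", base_width = 8L, depth = 3L,
                     airseg = tiny_airseg(), airseg_placement = 3L)
  m <- build_model(spec, 1)
  x <- array(runif(4 * 64 * 64), c(4, 1, 64, 64))
  gt <- array(rbinom(4 * 64 * 64, 1, 0.1), c(4, 1, 64, 64))
  t0 <- Sys.time()
  fw <- airseg:::model_forward(m, x, training = TRUE, with_cache = TRUE)
  lw <- airseg:::hybrid_loss_with_grad(fw$prob, gt)
  gr <- airseg:::model_backward(m, lw$grad, fw$cache)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  expect_lt(elapsed, 5)
  expect_true(all(vapply(airseg:::ptree_flatten(gr),
                         function(g) all(is.finite(g)), logical(1))))
})

test_that("nested skips and embedding ablations build and run", {
  for (emb in c("patch", "cnn", "none")) {
    spec <- model_spec(base_width = 8L, depth = 2L, airseg = tiny_airseg(),
                       airseg_placement = 2L, embedding_ablation = emb,
                       skip_style = "nested")
    m <- build_model(spec, 3)
    x <- array(runif(32), c(1, 1, 8, 8))
    pr <- airseg:::model_forward(m, x)$prob
    expect_true(all(pr >= 0 & pr <= 1))
  }
})
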