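# Overlap metrics, hybrid loss and report aggregation.

test_that("dice coefficient matches hand counts and conventions", {
  gt <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_equal(dice_coefficient(gt, gt, smooth = 1), 1)
  expect_equal(dice_coefficient(gt, gt), 1)
  expect_equal(dice_coefficient(1 - gt, gt), 0)
  pred <- c(1, 1, 0, 0, 1, 1, 0, 0)        # 4 px, overlap 2
  expect_equal(dice_coefficient(pred, gt), 0.5)
  expect_equal(dice_coefficient(numeric(8), numeric(8), smooth = 1), 1)
  expect_equal(dice_coefficient(numeric(8), numeric(8)), 1)
  expect_error(dice_coefficient(1:3, 1:4), "differ")
})

test_that("iou matches hand counts and links to dice", {
  gt <- c(1, 1, 1, 1, 0, 0, 0, 0)
  pred <- c(1, 1, 0, 0, 1, 1, 0, 0)        # overlap 2, union 6
  expect_equal(iou_score(pred, gt), 1 / 3, tolerance = 1e-9)
  expect_equal(iou_score(gt, gt), 1)
  expect_equal(iou_score(numeric(4), numeric(4), smooth = 1), 1)
  # dsc = 2 iou / (1 + iou) for arbitrary binary masks
  set.seed(31)
  for (i in 1:20) {
    a <- rbinom(50, 1, 0.3)
    b <- rbinom(50, 1, 0.3)
    d <- dice_coefficient(a, b)
    j <- iou_score(a, b)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-9)
    expect_lte(j, d)
  }
})

test_that("metrics are invariant to simultaneous flips and rotations", {
  set.seed(32)
  a <- matrix(rbinom(64, 1, 0.3), 8)
  b <- matrix(rbinom(64, 1, 0.3), 8)
  d0 <- dice_coefficient(a, b)
  for (tf in list(function(m) m[8:1, ], function(m) m[, 8:1],
                  function(m) t(m)[8:1, ])) {
    expect_equal(dice_coefficient(tf(a), tf(b)), d0, tolerance = 1e-12)
    expect_equal(iou_score(tf(a), tf(b)), iou_score(a, b),
                 tolerance = 1e-12)
  }
})

test_that("hybrid loss attains its bounds and rejects bad weights", {
  gt <- array(c(1, 1, 0, 0), c(1, 1, 2, 2))
  expect_equal(hybrid_loss(gt, gt, smooth = 0), 0)
  expect_equal(hybrid_loss(1 - gt, gt, smooth = 0), 2)
  expect_gt(hybrid_loss(array(0.5, dim(gt)), gt), 0)
  expect_error(hybrid_loss(gt, gt, w_dice = 0, w_iou = 0), "weights")
  expect_error(hybrid_loss(gt, gt, w_dice = -1), "weights")
  expect_error(hybrid_loss(array(0, c(1, 1, 2, 2)),
                           array(0, c(1, 1, 4, 1))), "differ")
})

test_that("soft dice approaches hard dice for saturated probabilities", {
  set.seed(33)
  gt <- array(rbinom(64, 1, 0.2), c(1, 1, 8, 8))
  pred_hard <- array(rbinom(64, 1, 0.3), c(1, 1, 8, 8))
  pred_soft <- pred_hard * 0.999999 + (1 - pred_hard) * 1e-6
  expect_equal(dice_coefficient(pred_soft, gt),
               dice_coefficient(pred_hard, gt), tolerance = 1e-4)
})

test_that("analytic loss gradient matches finite differences", {
  set.seed(34)
  pred <- array(runif(64, 0.05, 0.95), c(1, 1, 8, 8))
  gt <- array(rbinom(64, 1, 0.3), c(1, 1, 8, 8))
  lw <- airseg:::hybrid_loss_with_grad(pred, gt)
  idx <- sample(64, 10)
  for (i in idx) {
    eps <- 1e-6
    pp <- pred; pp[i] <- pp[i] + eps
    pm <- pred; pm[i] <- pm[i] - eps
    fd <- (hybrid_loss(pp, gt) - hybrid_loss(pm, gt)) / (2 * eps)
    expect_lt(abs(lw$grad[i] - fd), 1e-4)
  }
})

test_that("report aggregates use mean and sample SD and check the identity", {
  iou <- c(1, 1 / 3, 0)
  dsc <- 2 * iou / (1 + iou)
  rep <- metrics_report(data.frame(id = c("a", "b", "c"), dsc = dsc,
                                   iou = iou))
  expect_equal(rep$aggregates$mean, c(mean(dsc), mean(iou)))
  expect_equal(rep$aggregates$sd, c(sd(dsc), sd(iou)))
  # two-image arithmetic example
  iou2 <- c(1 / 3, 1)
  rep2 <- metrics_report(data.frame(id = c("a", "b"),
                                    dsc = 2 * iou2 / (1 + iou2),
                                    iou = iou2))
  expect_equal(rep2$aggregates$mean[1], 0.75)
  # violating the identity warns
  expect_warning(metrics_report(data.frame(id = "x", dsc = 0.9, iou = 0.5)),
                 "violate")
})

test_that("evaluate_dataset reports per-image metrics with the identity", {
  set.seed(35)
  spec <- model_spec(base_width = 4L, depth = 2L, airseg = NULL)
  m <- build_model(spec, 1)
  corpus <- generate_corpus(phantom_spec(image_size = 32,
                                         n_generations = 2,
                                         root_radius_px = 3),
                            n_train = 1, n_test = 3, seed = 4)
  rep <- evaluate_dataset(m, corpus$test)
  expect_identical(nrow(rep$per_image), 3L)
  expect_true(all(c("id", "dsc", "iou") %in% names(rep$per_image)))
  with(rep$per_image, expect_lt(max(abs(dsc - 2 * iou / (1 + iou))), 1e-9))
  expect_error(evaluate_dataset(m, list()), "empty")
  out <- capture.output(print(rep))
  expect_match(out[1], "3 images")
  # CSV / JSON round trip
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_metrics(rep, csv, js)
  expect_equal(utils::read.csv(csv)$dsc, rep$per_image$dsc)
  agg <- jsonlite::read_json(js)
  expect_equal(agg$mean_dsc, rep$aggregates$mean[1], tolerance = 1e-9)
})
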