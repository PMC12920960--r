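# Phantom generator: determinism, imbalance regime, tree connectivity,
# corpus discipline and augmentation.

test_that("phantom generation is bit-identical under a fixed seed", {
  sp <- phantom_spec(image_size = 64, root_radius_px = 4, seed = 7)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_true(all(a$mask %in% c(0, 1)))
  expect_true(all(a$image >= 0 & a$image <= 255))
})

test_that("default phantoms live in the sparse-foreground regime", {
  fracs <- vapply(1:25, function(i)
    mean(generate_phantom(phantom_spec(seed = i))$mask), numeric(1))
  expect_true(all(fracs > 0.005 & fracs < 0.10))
})

test_that("masks form a single connected airway tree", {
  for (i in c(3, 11, 19)) {
    m <- generate_phantom(phantom_spec(seed = i))$mask
    expect_equal(max(EBImage::bwlabel(m)), 1)
  }
  m1 <- generate_phantom(phantom_spec(n_generations = 1, seed = 3))$mask
  expect_equal(max(EBImage::bwlabel(m1)), 1)
})

test_that("per-generation pixel mass decreases with branch generation", {
  counts <- rowMeans(vapply(1:15, function(i) {
    generate_phantom(phantom_spec(seed = i))$gen_pixels
  }, numeric(4)))
  expect_true(all(diff(counts) < 0))
})

test_that("realised foreground and background intensities overlap", {
  s <- generate_phantom(phantom_spec(seed = 5))
  fg <- s$image[s$mask == 1]
  bg <- s$image[s$mask == 0]
  expect_gt(max(bg), min(fg))            # histograms overlap
  expect_gt(mean(fg), mean(bg))          # but foreground is brighter
})

test_that("requesting more generations than radii allow truncates", {
  sp <- phantom_spec(image_size = 64, root_radius_px = 2,
                     radius_decay = 0.5, n_generations = 5, seed = 1)
  expect_warning(s <- generate_phantom(sp), "truncated")
  expect_lt(length(s$gen_pixels), 5L)
})

test_that("corpus generation is disjoint, labelled and reproducible", {
  sp <- phantom_spec(image_size = 32, n_generations = 2, root_radius_px = 3)
  c1 <- generate_corpus(sp, n_train = 34, n_test = 10, seed = 3)
  expect_length(c1$train, 34)
  expect_length(c1$test, 10)
  ids <- vapply(c(c1$train, c1$test), `[[`, character(1), "id")
  expect_identical(anyDuplicated(ids), 0L)
  c2 <- generate_corpus(sp, n_train = 34, n_test = 10, seed = 3)
  expect_identical(c1$train[[17]]$image, c2$train[[17]]$image)
  expect_identical(c1$test[[10]]$mask, c2$test[[10]]$mask)
})

test_that("augmentation transforms image and mask together", {
  s <- generate_phantom(phantom_spec(image_size = 32, n_generations = 2,
                                     root_radius_px = 3, seed = 2))
  # involution
  expect_identical(augment(augment(s, "hflip"), "hflip"), s)
  expect_identical(augment(augment(s, "vflip"), "vflip"), s)
  expect_identical(augment(augment(s, "rot180"), "rot180"), s)
  expect_identical(augment(augment(s, "rot90"), "rot270")$mask, s$mask)
  for (op in c("hflip", "vflip", "rot90", "rot180", "rot270")) {
    a <- augment(s, op)
    expect_identical(sum(a$mask), sum(s$mask))
    expect_true(all(a$mask %in% c(0, 1)))
    # the pixel permutation commutes with intensity thresholding
    thr <- 150
    s_thr <- s
    s_thr$image <- (s$image >= thr) * 1
    expect_identical((a$image >= thr) * 1, augment(s_thr, op)$image)
  }
  # random choice among several ops is seeded
  a1 <- augment(s, c("hflip", "rot90"), seed = 5)
  a2 <- augment(s, c("hflip", "rot90"), seed = 5)
  expect_identical(a1, a2)
  # free-angle rotation keeps the mask binary
  r <- augment_rotate(s, 30)
  expect_true(all(r$mask %in% c(0, 1)))
  expect_identical(dim(r$image), dim(s$image))
})
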