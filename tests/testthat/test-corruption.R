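test_that("random anchors are in bounds and uniform", {
  set.seed(1)
  a <- sample_anchors_random(c(40, 60), 8, 5000)
  expect_true(all(a[, 1] >= 0 & a[, 1] <= 32))
  expect_true(all(a[, 2] >= 0 & a[, 2] <= 52))
  # K = H = W leaves only anchor (0, 0)
  expect_equal(sample_anchors_random(c(16, 16), 16, 5),
               matrix(0L, 5, 2), ignore_attr = TRUE)
  expect_error(sample_anchors_random(c(16, 16), 17, 1), "K")
  # chi-square uniformity over the anchor grid at alpha = 0.01
  set.seed(2)
  n <- 1e5
  a <- sample_anchors_random(c(24, 24), 16, n)   # 9 x 9 = 81 cells
  counts <- table(factor(a[, 1], levels = 0:8),
                  factor(a[, 2], levels = 0:8))
  p <- stats::chisq.test(as.vector(counts),
                         p = rep(1 / 81, 81))$p.value
  expect_gt(p, 0.01)
})

test_that("poisson-disc anchors satisfy the K*sqrt(2) distance rule", {
  set.seed(3)
  for (K in c(16, 32)) {
    a <- sample_anchors_poisson(c(256, 256), K, ceiling(256^2 / 4 / K^2))
    expect_gte(min_center_distance(a, K), K * sqrt(2) - 1e-9)
    expect_true(patches_pairwise_disjoint(a, K))
  }
  # 512x512, K = 64: exactly 16 disjoint patches give exactly 1/4 area
  a <- sample_anchors_poisson(c(512, 512), 64, 16)
  expect_equal(nrow(a), 16)
  expect_gte(min_center_distance(a, 64), 90.50)
  expect_true(patches_pairwise_disjoint(a, 64))
  expect_error(sample_anchors_poisson(c(64, 64), 32, 4), "K <=")
})

test_that("prediction masks cover a quarter of the area with bounded overshoot", {
  set.seed(4)
  for (sampler in c("random", "poisson")) for (K in c(8, 16, 32)) {
    m <- build_prediction_mask(c(128, 128), K, sampler)
    frac <- mask_coverage(m)
    expect_gte(frac, 0.25)
    expect_lt(frac, 0.25 + K^2 / (128 * 128))
    expect_equal(sum(mask_covered(m)), m$covered_count)
    expect_true(all(m$anchors >= 0) && all(m$anchors <= 128 - K))
  }
  # poisson at 512, K = 64 gives exactly 16 patches and fraction 1/4
  m <- build_prediction_mask(c(512, 512), 64, "poisson")
  expect_equal(nrow(m$anchors), 16)
  expect_equal(mask_coverage(m), 0.25)
})

test_that("restoration masks keep pairs disjoint and respect coverage bounds", {
  set.seed(5)
  for (sampler in c("random", "poisson")) for (K in c(8, 16, 32)) {
    m <- build_restoration_mask(c(128, 128), K, sampler)
    frac <- mask_coverage(m)
    expect_gte(frac, 0.25)
    expect_lt(frac, 0.25 + 2 * K^2 / (128 * 128))
    for (i in seq_len(nrow(m$pairs)))
      expect_true(abs(m$pairs[i, 1] - m$pairs[i, 3]) >= K ||
                    abs(m$pairs[i, 2] - m$pairs[i, 4]) >= K)
    if (sampler == "poisson") {
      a <- rbind(m$pairs[, 1:2], m$pairs[, 3:4])
      expect_true(patches_pairwise_disjoint(a, K))
    }
  }
  m <- build_restoration_mask(c(512, 512), 64, "poisson")
  expect_equal(nrow(m$pairs), 8)
  expect_equal(mask_coverage(m), 0.25)
})

test_that("apply_prediction zeroes exactly the masked pixels in all channels", {
  set.seed(6)
  m <- build_prediction_mask(c(64, 64), 16, "random")
  cov <- mask_covered(m)
  x <- matrix(rnorm(64 * 64) + 5, 64, 64)
  y <- apply_prediction(x, m)
  expect_true(all(y[cov] == 0))
  expect_identical(y[!cov], x[!cov])
  # channel consistency on 3-channel input
  a <- array(rnorm(64 * 64 * 3) + 5, c(64, 64, 3))
  ya <- apply_prediction(a, m)
  for (k in 1:3) {
    expect_true(all(ya[, , k][cov] == 0))
    expect_identical(ya[, , k][!cov], a[, , k][!cov])
  }
  # all-zero image is a fixed point
  z <- matrix(0, 64, 64)
  expect_identical(apply_prediction(z, m), z)
  expect_error(apply_prediction(matrix(0, 32, 32), m), "shape")
})

test_that("apply_restoration preserves the pixel multiset and involutes", {
  set.seed(7)
  for (sampler in c("random", "poisson")) {
    m <- build_restoration_mask(c(96, 96), 16, sampler)
    x <- matrix(rnorm(96 * 96), 96, 96)
    y <- apply_restoration(x, m)
    expect_identical(sort(as.vector(y)), sort(as.vector(x)))
    if (sampler == "poisson")  # disjoint pairs: swap twice restores
      expect_identical(apply_restoration(y, m), x)
  }
  # constant image is a fixed point; channels move together
  m <- build_restoration_mask(c(96, 96), 16, "poisson")
  cst <- matrix(4, 96, 96)
  expect_identical(apply_restoration(cst, m), cst)
  a <- array(rnorm(96 * 96 * 3), c(96, 96, 3))
  ya <- apply_restoration(a, m)
  for (k in 1:3)
    expect_identical(ya[, , k], apply_restoration(a[, , k], m))
})

test_that("mask rotation follows the grid algebra and preserves coverage", {
  set.seed(8)
  m <- build_prediction_mask(c(128, 128), 32, "random")
  # 4 quarter turns = identity
  r <- m
  for (i in 1:4) r <- rotate_mask(r, 1)
  expect_equal(r$anchors, m$anchors)
  # 180 degrees maps (r, c) -> (H - r - K, W - c - K)
  r2 <- rotate_mask(m, 2)
  expect_equal(r2$anchors[, 1], 128 - m$anchors[, 1] - 32)
  expect_equal(r2$anchors[, 2], 128 - m$anchors[, 2] - 32)
  # covered count invariant, and the covered grid matches matrix rotation
  for (q in 0:3) {
    rq <- rotate_mask(m, q)
    expect_equal(sum(mask_covered(rq)), m$covered_count)
  }
  ccw <- function(mat) t(mat)[ncol(mat):1, ]   # 90 deg counter-clockwise
  expect_equal(mask_covered(rotate_mask(m, 1)), ccw(mask_covered(m)))
  mr <- build_restoration_mask(c(64, 64), 8, "poisson")
  expect_equal(sum(mask_covered(rotate_mask(mr, 3))), mr$covered_count)
  # non-square shapes reject odd quarter turns
  mq <- build_prediction_mask(c(64, 128), 16, "random")
  expect_error(rotate_mask(mq, 1), "square")
  expect_silent(rotate_mask(mq, 2))
})

test_that("mask banks have 4x effective size and draw uniformly", {
  set.seed(9)
  bank <- build_mask_bank("prediction", "random", 16, c(64, 64), n_base = 5)
  expect_equal(effective_size(bank), 20)
  expect_equal(effective_size(build_mask_bank("prediction", "random", 16,
                                              c(64, 64), n_base = 1)), 4)
  # determinism under seed
  set.seed(9)
  bank2 <- build_mask_bank("prediction", "random", 16, c(64, 64), n_base = 5)
  expect_identical(bank, bank2)
  # draw frequencies uniform over (mask, rotation) variants of a 2-mask bank
  set.seed(10)
  b2 <- build_mask_bank("prediction", "random", 32, c(64, 64), n_base = 2)
  n <- 2e4
  keys <- replicate(n, {
    m <- draw_mask(b2)
    paste(m$anchors, collapse = ",")
  })
  freq <- table(keys)
  expect_equal(length(freq), 8)   # 2 masks x 4 rotations, all distinct
  # each frequency within 3 sigma of n/8
  sigma <- sqrt(n * (1 / 8) * (7 / 8))
  expect_true(all(abs(freq - n / 8) < 3.5 * sigma))
  drawn <- draw_mask(b2)
  expect_gte(mask_coverage(drawn), 0.25)
})

test_that("mask banks serialize to JSON and reload bit-exactly", {
  set.seed(11)
  for (task in c("prediction", "restoration")) {
    bank <- build_mask_bank(task, "poisson", 16, c(96, 96), n_base = 3)
    path <- withr::local_tempfile(fileext = ".json")
    save_mask_bank(bank, path)
    back <- load_mask_bank(path)
    expect_identical(back, bank)
  }
})
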