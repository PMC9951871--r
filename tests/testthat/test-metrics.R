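test_that("dice_score matches its closed form and is symmetric", {
  a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L
  expect_equal(dice_score(a, a, 1), 1)
  b <- matrix(0L, 4, 4); b[3:4, 3:4] <- 1L
  expect_equal(dice_score(a, b, 1), 0)
  # |P| = |G| = 4 with overlap 2 -> 2*2/8 = 0.5
  c_ <- matrix(0L, 4, 4); c_[1:2, 2:3] <- 1L
  expect_equal(dice_score(a, c_, 1), 0.5)
  expect_equal(dice_score(c_, a, 1), dice_score(a, c_, 1))
  # both empty -> 1 by convention
  expect_equal(dice_score(a, a, 3), 1)
  # invariant under a common permutation of pixels
  set.seed(1)
  p <- sample(16)
  ap <- matrix(a[p], 4, 4); cp <- matrix(c_[p], 4, 4)
  expect_equal(dice_score(ap, cp, 1), 0.5)
  expect_error(dice_score(a, matrix(0L, 2, 2), 1), "shapes differ")
})

test_that("inpainting_l2 is the per-channel Euclidean norm, channel-averaged", {
  x <- matrix(0, 512, 512)
  y <- x + 0.2
  expect_equal(inpainting_l2(y, x), 102.4)   # 0.2 * 512
  expect_equal(inpainting_l2(x, x), 0)
  # multi-channel: mean of per-channel norms (60, 90, 120 -> 90)
  a <- array(0, c(100, 100, 3)); b <- a
  b[, , 1] <- 60 / 100; b[, , 2] <- 90 / 100; b[, , 3] <- 120 / 100
  expect_equal(inpainting_l2(b, a), 90)
  # agrees with a brute-force flat-vector norm on random single-channel input
  set.seed(2)
  r1 <- matrix(rnorm(400), 20, 20); r2 <- matrix(rnorm(400), 20, 20)
  expect_equal(inpainting_l2(r1, r2), sqrt(sum((as.vector(r1) - as.vector(r2))^2)))
})

test_that("clinical geometry metrics follow their definitions", {
  m <- matrix(0L, 20, 20); m[1:10, 1:10] <- 2L
  expect_equal(tissue_volume(m, 0.5, 2, 2), 50)     # 100 px * 0.25 * 2
  expect_equal(tissue_volume(m, 0.5, 2, 1), 0)      # empty mask
  expect_equal(tissue_volume(m, 1.0, 2, 2), 4 * tissue_volume(m, 0.5, 2, 2))
  expect_equal(cross_sectional_area(m, 1, 2), 100)
  expect_equal(cross_sectional_area(m, 2, 2), 400)
  expect_equal(cross_sectional_area(m, 1, 4), 0)
  expect_error(tissue_volume(m, NULL, 2, 2), "spacing")
  # multi-slice volume sums over slices
  expect_equal(tissue_volume(list(m, m), 0.5, 2, 2), 100)
})

test_that("mean_t2 and mean_hu average over the mask, NA when empty", {
  lab <- matrix(0L, 4, 4); lab[1, 1:2] <- 1L
  t2 <- matrix(35, 4, 4)
  expect_equal(mean_t2(t2, lab, 1), 35)
  t2[1, 1] <- 30; t2[1, 2] <- 50
  expect_equal(mean_t2(t2, lab, 1), 40)
  expect_true(is.na(mean_t2(t2, lab, 2)))
  hu <- matrix(40, 4, 4)
  expect_equal(mean_hu(hu, lab, 1), 40)
  hu[1, 1] <- -100; hu[1, 2] <- 100
  expect_equal(mean_hu(hu, lab, 1), 0)
  expect_true(is.na(mean_hu(hu, lab, 3)))
})

test_that("percent_error returns magnitudes with NA for zero ground truth", {
  expect_equal(percent_error(10, 10), 0)
  expect_equal(percent_error(11, 10), 10)
  expect_equal(percent_error(5, 10), 50)
  expect_equal(percent_error(5, 10, signed = TRUE), -50)
  expect_true(is.na(percent_error(1, 0)))
})

test_that("ground truth against itself yields zero percent error end-to-end", {
  for (modality in c("mri", "ct")) {
    s <- generate_sample(phantom_spec(96, 96, modality = modality, seed = 3), 0)
    tm <- tissue_metrics(s$label_map, s)
    pe <- tm$percent_error[tm$metric != "dice"]
    expect_true(all(pe == 0))
    expect_true(all(tm$predicted[tm$metric == "dice"] == 1))
  }
  # noiseless phantoms recover the generating tables exactly
  sp <- phantom_spec(96, 96, noise_sigma = 0, seed = 5)
  s <- generate_sample(sp, 1)
  for (cls in 1:4)
    expect_equal(mean_t2(s$t2_map, s$label_map, cls),
                 unname(sp$t2_table[[cls]]))
  spc <- phantom_spec(96, 96, modality = "ct", noise_sigma = 0, seed = 5)
  sc <- generate_sample(spc, 1)
  for (cls in 1:4)
    expect_equal(mean_hu(sc$image, sc$label_map, cls),
                 unname(spc$intensity_table[[cls]]))
})

test_that("per_image_comparison averages over classes and regimes", {
  tbl <- function(err) data.frame(
    id = rep(c("a", "b"), each = 4),
    class = rep(1:2, 4),
    regime = rep(rep(c(0.1, 0.05), each = 2), 2),
    percent_error = err)
  sup <- tbl(c(10, 20, 30, 40, 1, 2, 3, 4))
  ssl <- tbl(c(5, 10, 15, 20, 1, 2, 3, 4))
  cmp <- per_image_comparison(sup, ssl)
  expect_equal(cmp$supervised[cmp$id == "a"], 25)
  expect_equal(cmp$ssl[cmp$id == "a"], 12.5)
  expect_equal(cmp$difference[cmp$id == "a"], 12.5)
  expect_equal(cmp$difference[cmp$id == "b"], 0)
  # identical inputs -> zero differences
  cmp0 <- per_image_comparison(sup, sup)
  expect_true(all(cmp0$difference == 0))
  # class exclusion removes the named class from the average
  cmp1 <- per_image_comparison(sup, ssl, exclude_classes = 2)
  expect_equal(cmp1$supervised[cmp1$id == "a"], mean(c(10, 30)))
  # single image, classes at 10% and 20%, one regime -> mean 15%
  one <- data.frame(id = "x", class = 1:2, regime = 0.5,
                    percent_error = c(10, 20))
  expect_equal(per_image_comparison(one, one)$supervised, 15)
  bad <- sup; bad$id[1] <- "c"
  expect_error(per_image_comparison(bad, ssl), "index")
})

test_that("probability discretization applies argmax with background threshold", {
  p <- array(0, c(2, 2, 4))
  p[1, 1, ] <- c(0.7, 0.1, 0.1, 0.1)   # clear class 1
  p[1, 2, ] <- c(0.1, 0.6, 0.2, 0.1)   # class 2
  p[2, 1, ] <- c(0.3, 0.3, 0.2, 0.2)   # no class above 0.5 -> background
  p[2, 2, ] <- c(0.05, 0.05, 0.05, 0.85)
  lab <- discretize_probs(p)
  expect_equal(lab, matrix(c(1L, 0L, 2L, 4L), 2, 2))
  expect_equal(discretize_probs(p, background_threshold = 0.25),
               matrix(c(1L, 1L, 2L, 4L), 2, 2))
})

test_that("headline dice aggregates per class then over classes", {
  scores <- data.frame(id = rep(c("a", "b"), each = 2),
                       class = rep(1:2, 2),
                       dice = c(0.8, 0.6, 0.9, 0.7))
  agg <- aggregate_dice(scores)
  expect_equal(unname(agg$per_class), c(0.85, 0.65))
  expect_equal(agg$overall, 0.75)
})
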