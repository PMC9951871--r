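test_that("label subsets are nested with round-half-up sizes", {
  ids <- sprintf("v%03d", 1:86)
  ls <- make_label_subsets(ids, c(1, 0.5, 0.25, 0.10, 0.05), seed = 2)
  expect_equal(lengths(ls$subsets), c(`1` = 86, `0.5` = 43, `0.25` = 22,
                                      `0.1` = 9, `0.05` = 4))
  # nestedness: every smaller subset is contained in all larger ones
  subs <- ls$subsets
  for (i in seq_len(length(subs) - 1))
    expect_true(all(subs[[i + 1]] %in% subs[[i]]))
  # n = 709 at 10% gives 71
  l7 <- make_label_subsets(seq_len(709), c(1, 0.10), seed = 1)
  expect_equal(length(l7$subsets[["0.1"]]), 71)
  # printed cohort sizes that round differently can be imposed
  lo <- make_label_subsets(ids, c(1, 0.05), seed = 2, sizes = c(`0.05` = 5))
  expect_equal(length(lo$subsets[["0.05"]]), 5)
  # determinism
  expect_identical(make_label_subsets(ids, c(1, 0.5), seed = 9)$subsets,
                   make_label_subsets(ids, c(1, 0.5), seed = 9)$subsets)
  expect_error(make_label_subsets(character(0)), "empty")
})

test_that("dice loss follows the pooled mini-batch definition", {
  # perfect one-hot prediction: loss ~ 0
  lab <- matrix(c(rep(1, 8), rep(2, 8), rep(3, 8), rep(4, 8)), 4, 8)
  oh <- onehot_labels(lab)
  expect_lt(dice_loss(oh, oh), 1e-6)
  # prediction and label disjoint for every class: loss -> 1
  lab2 <- matrix(((lab) %% 4) + 1, 4, 8)
  expect_gt(dice_loss(onehot_labels(lab2), oh), 1 - 1e-6)
  # batch aggregation pools sums over the whole batch: two images with
  # per-image Dice 1 and 0 on equal-size masks give pooled Dice 0.5,
  # verified against hand-computed pooled intersections/denominators
  g1 <- matrix(0L, 4, 4); g1[1:2, 1:2] <- 1L
  p1 <- g1                                   # perfect on image 1
  g2 <- g1
  p2 <- matrix(0L, 4, 4); p2[3:4, 3:4] <- 1L # disjoint on image 2
  probs <- list(onehot_labels(p1), onehot_labels(p2))
  labs <- list(onehot_labels(g1), onehot_labels(g2))
  # hand computation: class 1 pooled: 2*4 / (8 + 8) = 0.5; classes 2-4 empty
  # in both pred and truth so their smoothed Dice is 1
  expect_equal(dice_loss(probs, labs), 1 - mean(c(0.5, 1, 1, 1)),
               tolerance = 1e-6)
  expect_error(dice_loss(onehot_labels(g1), onehot_labels(matrix(0L, 2, 2))),
               "shapes differ")
})

test_that("pretraining reduces the reconstruction objective deterministically", {
  set.seed(20)
  imgs <- tiny_images(n = 6, size = 64, seed = 4)
  bank <- build_mask_bank("restoration", "random", 8, c(64, 64), n_base = 4)
  cfg <- tiny_config(depth = 2, base_filters = 4, groups = 2, seed = 8)
  oc <- optim_config(batch_size = 3, max_epochs = 5, early_stop_patience = 5,
                     seed = 17)
  pt <- pretrain(build_model(cfg, "inpainting"), imgs, bank, oc)
  expect_lt(pt$history$train_loss[5], pt$history$train_loss[1])
  expect_equal(pt$bundle$provenance, "pretrained")
  # identical seeds give identical loss histories
  pt2 <- pretrain(build_model(cfg, "inpainting"), imgs, bank, oc)
  expect_equal(pt$history, pt2$history, tolerance = 1e-12)
  expect_error(pretrain(build_model(cfg, "inpainting"), list(), bank, oc),
               "empty")
})

test_that("early stopping returns the best-validation weights, not the last", {
  set.seed(21)
  imgs <- tiny_images(n = 4, size = 64, seed = 6)
  bank <- build_mask_bank("prediction", "random", 8, c(64, 64), n_base = 3)
  cfg <- tiny_config(depth = 2, base_filters = 4, groups = 2, seed = 3)
  # large lr destabilizes the loss, so the best epoch is rarely the last
  oc <- optim_config(initial_lr = 1e-2, batch_size = 4, max_epochs = 8,
                     early_stop_patience = 3, seed = 5)
  pt <- pretrain(build_model(cfg, "inpainting"), imgs, bank, oc)
  expect_equal(pt$best_epoch, which.min(pt$history$val_loss))
  expect_lte(nrow(pt$history),
             which.min(pt$history$val_loss) + oc$early_stop_patience)
})

test_that("fine-tuning schedules honor freezing and improve over no training", {
  set.seed(22)
  labeled <- tiny_labeled(n = 4, size = 64, seed = 8)
  imgs <- lapply(labeled, `[[`, "x")
  bank <- build_mask_bank("restoration", "random", 8, c(64, 64), n_base = 3)
  cfg <- tiny_config(depth = 2, base_filters = 4, groups = 2, seed = 12)
  oc <- optim_config(batch_size = 4, max_epochs = 4, early_stop_patience = 4,
                     seed = 31)
  pt <- pretrain(build_model(cfg, "inpainting"), imgs, bank, oc)

  strat <- ssl_strategy("restoration", 8L, "random", "encoder_only",
                        "immediate", 1e-3)
  seg0 <- transfer_weights(pt$bundle,
                           build_model(tiny_config(depth = 2, base_filters = 4,
                                                   groups = 2, seed = 77),
                                       "segmentation"),
                           "encoder_only")
  untrained_loss <- mean(vapply(labeled, function(s)
    dice_loss(predict(seg0, s$x), onehot_labels(s$y)), numeric(1)))
  ft <- finetune(seg0, labeled, strat, oc)
  expect_lt(ft$best_val, untrained_loss)
  expect_true(all(ft$history$phase == 1L))

  # freeze_then_unfreeze: transferred scopes unchanged during phase 1
  strat2 <- ssl_strategy("restoration", 8L, "random", "encoder_only",
                         "freeze_then_unfreeze", 1e-3, phase2_lr = 1e-4)
  ft2 <- finetune(seg0, labeled, strat2, oc)
  enc <- names(seg0$params)[seg0$scopes == "encoder"]
  expect_identical(ft2$phase1_model$params[enc], seg0$params[enc])
  expect_setequal(unique(ft2$history$phase), c(1L, 2L))
})

test_that("the supervised baseline trains a 4-class model from scratch", {
  set.seed(23)
  labeled <- tiny_labeled(n = 4, size = 64, seed = 10)
  cfg <- tiny_config(depth = 2, base_filters = 4, groups = 2, seed = 2)
  oc <- optim_config(batch_size = 4, max_epochs = 5, early_stop_patience = 5,
                     seed = 41)
  bl <- train_supervised_baseline(labeled, cfg, oc)
  expect_equal(dim(predict(bl$model, labeled[[1]]$x))[3], 4)
  expect_lt(bl$history$train_loss[5], bl$history$train_loss[1])
  expect_error(train_supervised_baseline(list(), cfg, oc), "empty")
})
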