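test_that("heads differ only in output channels and shapes are preserved", {
  cfg <- tiny_config(in_channels = 3, depth = 3, base_filters = 4,
                     groups = 2, seed = 3)
  mi <- build_model(cfg, "inpainting")
  ms <- build_model(cfg, "segmentation")
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  oi <- unet_forward(mi, x)$out
  os <- unet_forward(ms, x)$out
  expect_equal(dim(oi), c(32, 32, 3))   # inpainting: channels in = out
  expect_equal(dim(os), c(32, 32, 4))   # segmentation: 4 classes
  # identical topology except the post-processing layer
  shared <- setdiff(names(mi$params), c("post.w", "post.b"))
  expect_identical(mi$params[shared], ms$params[shared])
  expect_false(identical(dim(mi$params$post.w), dim(ms$params$post.w)))
  # spatial size preserved at another resolution
  x64 <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
  expect_equal(dim(unet_forward(mi, x64)$out)[1:2], c(64, 64))
  # seeded determinism
  expect_identical(build_model(cfg, "inpainting")$params, mi$params)
  expect_error(unet_config(groupnorm_groups = 3, base_filters = 16), "divide")
})

test_that("scope partition is total, disjoint and correctly assigned", {
  m <- build_model(tiny_config(depth = 3), "segmentation")
  expect_setequal(unique(m$scopes), c("encoder", "decoder", "post_processing"))
  expect_equal(length(m$scopes), length(m$params))
  expect_true(all(m$scopes[grep("^enc", names(m$params))] == "encoder"))
  expect_true(all(m$scopes[grep("^(up|dec)", names(m$params))] == "decoder"))
  expect_equal(unname(m$scopes[c("post.w", "post.b")]),
               rep("post_processing", 2))
})

test_that("weight standardization gives zero-mean unit-variance filters", {
  set.seed(4)
  w <- array(rnorm(3 * 3 * 8 * 16, 2, 3), c(3, 3, 8, 16))
  ws <- standardize_kernel(w)
  wm <- matrix(ws, 3 * 3 * 8, 16)
  popvar <- function(v) mean(v^2) - mean(v)^2
  expect_true(all(abs(colMeans(wm)) <= 1e-6))
  expect_true(all(abs(apply(wm, 2, popvar) - 1) <= 1e-4))
  # idempotent up to eps effects
  expect_equal(standardize_kernel(ws), ws, tolerance = 1e-5)
  # constant filters collapse to zero
  wc <- array(5, c(3, 3, 2, 4))
  expect_true(all(standardize_kernel(wc) == 0))
  # forward output is invariant to per-filter affine rescaling of raw kernels
  cfg <- tiny_config(seed = 9)
  m <- build_model(cfg, "inpainting")
  x <- array(rnorm(16 * 16), c(16, 16, 1))
  base <- unet_forward(m, x)$out
  m2 <- m
  w1 <- m2$params[["enc1.conv1.w"]]
  for (f in seq_len(dim(w1)[4]))
    w1[, , , f] <- w1[, , , f] * (1 + f / 3) + 0.7 * f
  m2$params[["enc1.conv1.w"]] <- w1
  expect_equal(unet_forward(m2, x)$out, base, tolerance = 1e-6)
})

test_that("backpropagation matches finite differences on a tiny net", {
  set.seed(5)
  cfg <- tiny_config(depth = 2, base_filters = 2, groups = 1, seed = 5)
  m <- build_model(cfg, "inpainting")
  x <- array(rnorm(8 * 8), c(8, 8, 1))
  tgt <- array(rnorm(8 * 8), c(8, 8, 1))
  lossf <- function(mm) mean((unet_forward(mm, x)$out - tgt)^2)
  fw <- unet_forward(m, x, keep_cache = TRUE)
  g <- unet_backward(m, fw$cache, 2 * (fw$out - tgt) / length(tgt))
  eps <- 1e-6
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(2, length(p)))) {
      mp <- m; mp$params[[nm]][i] <- p[i] + eps
      mm_ <- m; mm_$params[[nm]][i] <- p[i] - eps
      fd <- (lossf(mp) - lossf(mm_)) / (2 * eps)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-4,
                   label = sprintf("gradient of %s", nm))
    }
  }
})

test_that("transfer copies exactly the requested scopes, never the head", {
  cfg <- tiny_config(depth = 3, seed = 21)
  src_model <- build_model(cfg, "inpainting")
  bundle <- weight_bundle(src_model, "pretrained")
  cfg2 <- cfg; cfg2$seed <- 99L
  enc_names <- names(src_model$params)[src_model$scopes == "encoder"]
  dec_names <- names(src_model$params)[src_model$scopes == "decoder"]

  t1 <- transfer_weights(bundle, build_model(cfg2, "segmentation"),
                         "encoder_only")
  expect_identical(t1$params[enc_names], bundle$params[enc_names])
  fresh <- build_model(cfg2, "segmentation")
  expect_identical(t1$params[dec_names], fresh$params[dec_names])
  expect_false(identical(t1$params[dec_names], bundle$params[dec_names]))

  t2 <- transfer_weights(bundle, build_model(cfg2, "segmentation"),
                         "encoder_and_decoder")
  expect_identical(t2$params[c(enc_names, dec_names)],
                   bundle$params[c(enc_names, dec_names)])
  # post-processing layer never transferred (shapes differ anyway)
  expect_identical(t2$params$post.w, fresh$params$post.w)
  expect_false(identical(dim(t2$params$post.w), dim(bundle$params$post.w)))

  # topology mismatch errors name the offending tensor
  cfg3 <- tiny_config(depth = 3, base_filters = 8, seed = 1)
  expect_error(transfer_weights(bundle, build_model(cfg3, "segmentation"),
                                "encoder_only"),
               "enc1.conv1.w")
})

test_that("frozen scopes are untouched by training steps", {
  set.seed(6)
  imgs <- tiny_images(n = 3, size = 64)
  bank <- build_mask_bank("prediction", "random", 8, c(64, 64), n_base = 2)
  cfg <- tiny_config(depth = 2, base_filters = 4, groups = 2, seed = 7)
  m <- build_model(cfg, "inpainting")
  m <- set_trainable(m, "encoder", frozen = TRUE)
  pt <- pretrain(m, imgs, bank,
                 optim_config(batch_size = 3, max_epochs = 2,
                              early_stop_patience = 2, seed = 3))
  enc <- names(m$params)[m$scopes == "encoder"]
  expect_identical(pt$model$params[enc], m$params[enc])
  # non-frozen scopes do move
  dec <- names(m$params)[m$scopes == "decoder"]
  expect_false(identical(pt$model$params[dec], m$params[dec]))
  # freezing everything leaves the loss constant across epochs
  mf <- set_trainable(build_model(cfg, "inpainting"), "all", frozen = TRUE)
  ptf <- pretrain(mf, imgs, bank,
                  optim_config(batch_size = 3, max_epochs = 3,
                               early_stop_patience = 5, seed = 3))
  expect_identical(ptf$model$params, mf$params)
  expect_lt(diff(range(ptf$history$val_loss)), 0.2)  # only mask-draw noise
  expect_error(set_trainable(m, "bogus_scope", TRUE), "unknown scope")
})

test_that("weight bundles serialize with scope manifest and validate shapes", {
  m <- build_model(tiny_config(seed = 13), "inpainting")
  b <- weight_bundle(m, "pretrained")
  path <- withr::local_tempfile(fileext = ".json")
  save_weights(b, path)
  back <- load_weights(path)
  expect_equal(back$params, b$params)
  expect_equal(back$scopes, b$scopes, ignore_attr = TRUE)
  expect_equal(back$provenance, "pretrained")
})
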