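#' Optimizer and training-loop configuration
#'
#' ADAM with beta1 = 0.99, beta2 = 0.995 and a batch size of 9 by default.
#' Training uses early stopping on the validation objective: when the
#' validation loss has not improved for `early_stop_patience` epochs the
#' loop stops and the best-validation weights (not the last) are returned.
#'
#' @param initial_lr Initial learning rate; the study grid is
#'   `1e-2, 1e-3, 1e-4, 1e-5`.
#' @param beta1,beta2 ADAM moment decay rates.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param adam_eps ADAM denominator floor.
#' @param seed Seed for data ordering and mask draws.
#' @return Object of class `optim_config`.
#' @export
optim_config <- function(initial_lr = 1e-3, beta1 = 0.99, beta2 = 0.995,
                         batch_size = 9L, max_epochs = 200L,
                         early_stop_patience = 10L, adam_eps = 1e-8,
                         seed = 1L) {
  if (initial_lr <= 0) stop("initial_lr must be positive")
  if (batch_size < 1L) stop("batch_size must be at least 1")
  structure(list(initial_lr = initial_lr, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 adam_eps = adam_eps, seed = as.integer(seed)),
            class = "optim_config")
}

#' A pretraining + transfer strategy
#'
#' One point of the design-choice grid: pretext task, patch size, patch
#' sampler, which scopes to transfer, fine-tuning schedule and initial
#' learning rate. The default is the combination found to provide the most
#' benefit over supervised learning on both MRI and CT: context
#' restoration, 32 x 32 patches, Poisson-disc sampling, encoder-only
#' transfer, immediate fine-tuning at 1e-3.
#'
#' @param task `"prediction"` or `"restoration"`.
#' @param patch_size K in `{8, 16, 32, 64}`.
#' @param sampler `"random"` or `"poisson"`.
#' @param transfer_scope `"encoder_only"` or `"encoder_and_decoder"`.
#' @param schedule `"immediate"` (one phase) or `"freeze_then_unfreeze"`
#'   (transferred scopes frozen until early stop, then all weights
#'   trained).
#' @param initial_lr Fine-tuning learning rate.
#' @param phase2_lr Learning rate for the unfreeze phase (defaults to
#'   `initial_lr`; the study's best two-phase variant used 1e-3 then 1e-4).
#' @return Object of class `ssl_strategy`.
#' @export
ssl_strategy <- function(task = c("restoration", "prediction"),
                         patch_size = 32L,
                         sampler = c("poisson", "random"),
                         transfer_scope = c("encoder_only", "encoder_and_decoder"),
                         schedule = c("immediate", "freeze_then_unfreeze"),
                         initial_lr = 1e-3, phase2_lr = NULL) {
  task <- match.arg(task); sampler <- match.arg(sampler)
  transfer_scope <- match.arg(transfer_scope); schedule <- match.arg(schedule)
  if (!patch_size %in% c(8L, 16L, 32L, 64L))
    stop("patch_size must be one of 8, 16, 32, 64")
  if (!initial_lr %in% c(1e-2, 1e-3, 1e-4, 1e-5))
    warning("initial_lr outside the study grid {1e-2, 1e-3, 1e-4, 1e-5}")
  structure(list(task = task, patch_size = as.integer(patch_size),
                 sampler = sampler, transfer_scope = transfer_scope,
                 schedule = schedule, initial_lr = initial_lr,
                 phase2_lr = phase2_lr %||% initial_lr),
            class = "ssl_strategy")
}

#' @export
print.ssl_strategy <- function(x, ...) {
  cat(sprintf("ssl_strategy: %s K=%d %s | transfer %s, %s, lr %g\n",
              x$task, x$patch_size, x$sampler, x$transfer_scope, x$schedule,
              x$initial_lr))
  invisible(x)
}

#' Strategy label (for tables)
#' @param s An `ssl_strategy`.
#' @export
strategy_id <- function(s) {
  sprintf("%s_K%d_%s", s$task, s$patch_size, s$sampler)
}

#' Nested label-limited training subsets
#'
#' Splits training ids into nested subsets: every member of a smaller
#' subset belongs to all larger subsets. Sizes default to
#' `max(1, round-half-up(fraction * n))`; printed cohort sizes that follow
#' a different rounding can be imposed via `sizes`.
#'
#' @param ids Character or integer vector of training ids.
#' @param fractions Decreasing label fractions (default
#'   `1, 0.5, 0.25, 0.10, 0.05`).
#' @param seed Seed for the single shuffle that defines the nesting.
#' @param sizes Optional named vector overriding the size per fraction.
#' @return Object of class `label_subsets`: a named list of id vectors.
#' @export
make_label_subsets <- function(ids, fractions = c(1, 0.5, 0.25, 0.10, 0.05),
                               seed = 1L, sizes = NULL) {
  n <- length(ids)
  if (n < 1L) stop("empty training set")
  fractions <- sort(fractions, decreasing = TRUE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ord <- sample(ids)
  subsets <- lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    m <- if (!is.null(sizes) && !is.na(sizes[as.character(f)]))
      sizes[[as.character(f)]]
    else max(1L, floor(f * n + 0.5))
    if (m > n) stop("subset size exceeds number of ids")
    ord[seq_len(m)]
  })
  names(subsets) <- as.character(fractions)
  structure(list(subsets = subsets, fractions = fractions, n = n),
            class = "label_subsets")
}

#' @export
print.label_subsets <- function(x, ...) {
  cat("label_subsets:",
      paste(sprintf("%s%%=%d", as.numeric(names(x$subsets)) * 100,
                    lengths(x$subsets)), collapse = ", "), "\n")
  invisible(x)
}

# ---- ADAM ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(model, grads, state, lr, optim) {
  state$t <- state$t + 1L
  b1 <- optim$beta1; b2 <- optim$beta2
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (nm in names(model$params)) {
    if (!model$trainable[[nm]]) next
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    model$params[[nm]] <- model$params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + optim$adam_eps)
  }
  list(model = model, state = state)
}

# ---- losses ----

#' Soft Dice loss aggregated over a mini-batch per class
#'
#' For each of the 4 foreground classes the soft Dice coefficient is
#' computed from sums pooled over *all* pixels of the whole mini-batch:
#' `D_c = (2 * sum(p*g) + eps) / (sum(p) + sum(g) + eps)`. The loss is
#' `1 - mean(D_c)` over the 4 classes. Background is not a Dice term; it is
#' represented implicitly as "none of the foreground classes".
#'
#' @param probs Class probabilities: H x W x 4 array or list of such
#'   arrays (one per batch member); must sum to 1 across classes.
#' @param onehot Ground-truth one-hot labels, same shape(s).
#' @param eps Smoothing constant.
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(probs, onehot, eps = 1e-7) {
  if (!is.list(probs)) { probs <- list(probs); onehot <- list(onehot) }
  sums <- dice_pooled_sums(probs, onehot)
  d <- (2 * sums$pg + eps) / (sums$p + sums$g + eps)
  1 - mean(d)
}

dice_pooled_sums <- function(probs, onehot) {
  nc <- dim(probs[[1]])[3]
  p <- g <- pg <- numeric(nc)
  for (i in seq_along(probs)) {
    if (!identical(dim(probs[[i]]), dim(onehot[[i]])))
      stop("probability and label shapes differ")
    for (c in seq_len(nc)) {
      p[c] <- p[c] + sum(probs[[i]][, , c])
      g[c] <- g[c] + sum(onehot[[i]][, , c])
      pg[c] <- pg[c] + sum(probs[[i]][, , c] * onehot[[i]][, , c])
    }
  }
  list(p = p, g = g, pg = pg)
}

# gradient of the pooled dice loss wrt one image's probabilities
dice_loss_grad_one <- function(probs_i, onehot_i, sums, eps = 1e-7) {
  nc <- dim(probs_i)[3]
  den <- sums$p + sums$g + eps
  num <- 2 * sums$pg + eps
  dp <- probs_i * 0
  for (c in seq_len(nc))
    dp[, , c] <- -(2 * onehot_i[, , c] * den[c] - num[c]) / den[c]^2 / nc
  dp
}

#' One-hot encode a label map for the 4 foreground classes
#'
#' @param label_map H x W integer matrix with values 0 (background) to 4.
#' @return H x W x 4 array.
#' @export
onehot_labels <- function(label_map) {
  out <- array(0, c(dim(label_map), 4L))
  for (c in 1:4) out[, , c] <- (label_map == c) * 1
  out
}

# ---- generic epoch loop with early stopping ----

run_training <- function(model, step_fn, val_fn, optim, lr,
                         max_epochs = optim$max_epochs,
                         history_extra = NULL, verbose = FALSE) {
  state <- adam_init(model$params)
  best <- list(params = model$params, val = Inf, epoch = 0L)
  hist <- data.frame()
  wait <- 0L
  for (epoch in seq_len(max_epochs)) {
    res <- step_fn(model, state, lr)
    model <- res$model; state <- res$state
    val <- val_fn(model)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = res$train_loss,
                                   val_loss = val, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.6f  val %.6f", epoch,
                      res$train_loss, val))
    if (val < best$val - 1e-12) {
      best <- list(params = model$params, val = val, epoch = epoch)
      wait <- 0L
    } else if ((wait <- wait + 1L) >= optim$early_stop_patience) break
  }
  model$params <- best$params
  list(model = model, history = hist, best_epoch = best$epoch,
       best_val = best$val)
}

batches_of <- function(n, batch_size) {
  ord <- sample.int(n)
  split(ord, ceiling(seq_along(ord) / batch_size))
}

# ---- pretraining (inpainting) ----

#' Pretrain a U-Net on an inpainting pretext task
#'
#' Every step draws a fresh mask from the bank for every image, corrupts
#' the (already normalized) image, and minimizes the pixelwise mean squared
#' reconstruction error against the uncorrupted image (computed over the
#' full image). Early stopping monitors the same objective on the
#' validation images; the best-validation weights are returned.
#'
#' @param model A `unet` with an inpainting head.
#' @param images List of normalized H x W (x C) arrays.
#' @param bank A [build_mask_bank()] matching the image shape.
#' @param optim An [optim_config()].
#' @param val_images Validation images (defaults to `images` when too few
#'   are supplied to hold out).
#' @param verbose Print per-epoch losses.
#' @return List with `bundle` (a pretrained [weight_bundle()]), `model`,
#'   `history` (per-epoch train/validation loss) and `best_epoch`.
#' @export
pretrain <- function(model, images, bank, optim = optim_config(),
                     val_images = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "unet"), model$head == "inpainting")
  if (length(images) == 0L) stop("empty pretraining dataset")
  images <- lapply(images, ensure_3d)
  if (!all(dim(images[[1]])[1:2] == bank$image_shape))
    stop("image shape does not match mask bank")
  val_images <- if (is.null(val_images)) images else lapply(val_images, ensure_3d)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(optim$seed)

  step_fn <- function(model, state, lr) {
    total <- 0; nb <- 0L
    for (batch in batches_of(length(images), optim$batch_size)) {
      grads_acc <- NULL
      bl <- 0
      for (i in batch) {
        x <- images[[i]]
        xc <- apply_corruption(x, draw_mask(bank))
        fw <- unet_forward(model, xc, keep_cache = TRUE)
        diff <- fw$out - x
        bl <- bl + mean(diff^2)
        g <- unet_backward(model, fw$cache, 2 * diff / length(diff))
        grads_acc <- acc_grads(grads_acc, g)
      }
      grads_acc <- scale_grads(grads_acc, 1 / length(batch))
      upd <- adam_step(model, grads_acc, state, lr, optim)
      model <- upd$model; state <- upd$state
      total <- total + bl / length(batch); nb <- nb + 1L
    }
    list(model = model, state = state, train_loss = total / nb)
  }
  val_fn <- function(model) {
    mean(vapply(val_images, function(x) {
      xc <- apply_corruption(x, draw_mask(bank))
      mean((unet_forward(model, xc)$out - x)^2)
    }, numeric(1)))
  }
  res <- run_training(model, step_fn, val_fn, optim, optim$initial_lr,
                      verbose = verbose)
  list(bundle = weight_bundle(res$model, "pretrained"), model = res$model,
       history = res$history, best_epoch = res$best_epoch)
}

ensure_3d <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

acc_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}
scale_grads <- function(g, s) {
  for (nm in names(g)) g[[nm]] <- g[[nm]] * s
  g
}

# ---- segmentation training (shared by fine-tuning and the baseline) ----

train_segmentation_phase <- function(model, xs, ys, optim, lr, val_xs, val_ys,
                                     max_epochs, verbose = FALSE) {
  step_fn <- function(model, state, lr) {
    total <- 0; nb <- 0L
    for (batch in batches_of(length(xs), optim$batch_size)) {
      fws <- lapply(batch, function(i)
        unet_forward(model, xs[[i]], keep_cache = TRUE))
      probs <- lapply(fws, function(f) softmax_channels(f$out))
      labs <- ys[batch]
      sums <- dice_pooled_sums(probs, labs)
      loss <- dice_loss(probs, labs)
      grads_acc <- NULL
      for (j in seq_along(batch)) {
        dp <- dice_loss_grad_one(probs[[j]], labs[[j]], sums)
        # softmax backward per pixel
        dot <- channel_dot_sum(dp, probs[[j]])
        dlogit <- probs[[j]] * sweep(dp, c(1, 2), dot)
        g <- unet_backward(model, fws[[j]]$cache, dlogit)
        grads_acc <- acc_grads(grads_acc, g)
      }
      upd <- adam_step(model, grads_acc, state, lr, optim)
      model <- upd$model; state <- upd$state
      total <- total + loss; nb <- nb + 1L
    }
    list(model = model, state = state, train_loss = total / nb)
  }
  val_fn <- function(model) {
    mean(vapply(seq_along(val_xs), function(i)
      dice_loss(predict(model, val_xs[[i]]), val_ys[[i]]), numeric(1)))
  }
  run_training(model, step_fn, val_fn, optim, lr, max_epochs = max_epochs,
               verbose = verbose)
}

prepare_labeled <- function(samples) {
  xs <- lapply(samples, function(s) ensure_3d(s$x))
  ys <- lapply(samples, function(s)
    if (is.matrix(s$y)) onehot_labels(s$y) else s$y)
  list(xs = xs, ys = ys)
}

#' Fine-tune a model for segmentation after weight transfer
#'
#' The transfer itself (per `strategy$transfer_scope`) must already have
#' been applied with [transfer_weights()]. With the `immediate` schedule a
#' single phase trains all weights at `strategy$initial_lr`; with
#' `freeze_then_unfreeze` the transferred scopes are frozen for phase 1
#' (trained until early stop), then everything is unfrozen and trained
#' until early stop at `strategy$phase2_lr` with a restarted optimizer.
#'
#' @param model A `unet` with a segmentation head and transferred weights.
#' @param labeled List of `list(x = image, y = label map or one-hot)`.
#' @param strategy An [ssl_strategy()].
#' @param optim An [optim_config()].
#' @param val Validation samples, same structure as `labeled` (defaults to
#'   `labeled`).
#' @param verbose Print per-epoch losses.
#' @return List with `model` (best-validation), `history` (with a `phase`
#'   column) and `best_val`.
#' @export
finetune <- function(model, labeled, strategy, optim = optim_config(),
                     val = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "unet"), model$head == "segmentation",
            inherits(strategy, "ssl_strategy"))
  if (length(labeled) == 0L) stop("empty labeled dataset")
  tr <- prepare_labeled(labeled)
  va <- if (is.null(val)) tr else prepare_labeled(val)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(optim$seed)
  frozen_scopes <- if (strategy$transfer_scope == "encoder_only") "encoder"
  else c("encoder", "decoder")
  if (strategy$schedule == "immediate") {
    model <- set_trainable(model, "all", frozen = FALSE)
    res <- train_segmentation_phase(model, tr$xs, tr$ys, optim,
                                    strategy$initial_lr, va$xs, va$ys,
                                    optim$max_epochs, verbose)
    res$history$phase <- 1L
    return(list(model = res$model, history = res$history,
                best_val = res$best_val))
  }
  model <- set_trainable(model, "all", frozen = FALSE)
  model <- set_trainable(model, frozen_scopes, frozen = TRUE)
  p1 <- train_segmentation_phase(model, tr$xs, tr$ys, optim,
                                 strategy$initial_lr, va$xs, va$ys,
                                 optim$max_epochs, verbose)
  m <- set_trainable(p1$model, "all", frozen = FALSE)
  p2 <- train_segmentation_phase(m, tr$xs, tr$ys, optim, strategy$phase2_lr,
                                 va$xs, va$ys, optim$max_epochs, verbose)
  p1$history$phase <- 1L; p2$history$phase <- 2L
  p2$history$epoch <- p2$history$epoch + nrow(p1$history)
  list(model = p2$model, history = rbind(p1$history, p2$history),
       best_val = p2$best_val, phase1_model = p1$model)
}

#' Train a fully-supervised segmentation baseline
#'
#' Identical to [finetune()] with no transfer: He initialization
#' throughout, single phase, all weights trainable. Under the same
#' `optim$seed` the data order matches an SSL fine-tune run.
#'
#' @param labeled,optim,val,verbose As in [finetune()].
#' @param config A [unet_config()] for the fresh model.
#' @param initial_lr Learning rate.
#' @return As [finetune()], plus the trained `model`.
#' @export
train_supervised_baseline <- function(labeled, config, optim = optim_config(),
                                      initial_lr = 1e-3, val = NULL,
                                      verbose = FALSE) {
  if (length(labeled) == 0L) stop("empty labeled dataset")
  model <- build_model(config, head = "segmentation")
  tr <- prepare_labeled(labeled)
  va <- if (is.null(val)) tr else prepare_labeled(val)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(optim$seed)
  res <- train_segmentation_phase(model, tr$xs, tr$ys, optim, initial_lr,
                                  va$xs, va$ys, optim$max_epochs, verbose)
  res$history$phase <- 1L
  list(model = res$model, history = res$history, best_val = res$best_val)
}
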