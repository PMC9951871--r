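#' Phantom-scale experiment plan
#'
#' Bundles everything needed to run the design-choice grid, the
#' data-scaling sweep and the SSL-versus-supervised comparison on
#' phantoms: dataset sizes, model size, optimizer settings, the strategy
#' grid, label fractions and pretraining-amount levels. Defaults are
#' deliberately small (96 x 96 phantoms, depth-3 U-Net with 8 base
#' filters, short schedules) so a full plan runs on one CPU in minutes;
#' the vignette discusses this scaling.
#'
#' @param modality `"mri"` or `"ct"`.
#' @param image_size Phantom side length (square; at least 96 for 32 x 32
#'   Poisson-disc corruption).
#' @param n_unlabeled,n_labeled,n_val,n_test Dataset sizes.
#' @param strategies List of [ssl_strategy()] objects.
#' @param fractions Label-limited fine-tuning fractions.
#' @param pretrain_levels Pretraining-data amounts in percent of the
#'   unlabeled set, including 0 (the supervised baseline).
#' @param model A [unet_config()].
#' @param optim An [optim_config()].
#' @param seed Master seed; all stage seeds derive from it.
#' @return Object of class `experiment_plan`.
#' @export
experiment_plan <- function(modality = "mri",
                            image_size = 96L,
                            n_unlabeled = 12L, n_labeled = 8L,
                            n_val = 3L, n_test = 4L,
                            strategies = list(
                              ssl_strategy("restoration", 16L, "poisson"),
                              ssl_strategy("prediction", 16L, "random")),
                            fractions = c(1, 0.5),
                            pretrain_levels = c(0, 25, 50, 100),
                            model = unet_config(in_channels = if (modality == "ct") 3L else 1L,
                                                depth = 3L, base_filters = 8L,
                                                groupnorm_groups = 4L),
                            optim = optim_config(batch_size = 4L,
                                                 max_epochs = 6L,
                                                 early_stop_patience = 3L),
                            seed = 1L) {
  pretrain_levels <- sort(pretrain_levels)
  structure(list(modality = modality, image_size = as.integer(image_size),
                 n_unlabeled = as.integer(n_unlabeled),
                 n_labeled = as.integer(n_labeled),
                 n_val = as.integer(n_val), n_test = as.integer(n_test),
                 strategies = strategies, fractions = fractions,
                 pretrain_levels = pretrain_levels,
                 model = model, optim = optim, seed = as.integer(seed)),
            class = "experiment_plan")
}

derive_seed <- function(seed, salt) {
  (as.double(seed) * 69621 + salt * 104729) %% 2147483113
}

#' Materialize a plan's phantom data in memory
#'
#' Generates unlabeled pretraining images and labeled
#' train/validation/test samples, normalized the way the pipeline expects
#' (per volume for MRI; three windowed channels each standardized for
#' CT). Test samples keep their raw image, label and quantitative maps
#' for clinical metrics.
#'
#' @param plan An [experiment_plan()].
#' @return List with `unlabeled` (normalized arrays), `train`, `val`
#'   (lists of `list(x, y)`), `test` (raw `phantom_sample`s plus `x`),
#'   and `spec`.
#' @export
plan_data <- function(plan) {
  spec <- phantom_spec(height = plan$image_size, width = plan$image_size,
                       modality = plan$modality,
                       seed = as.integer(derive_seed(plan$seed, 11)))
  prep <- function(s) {
    if (plan$modality == "ct")
      normalize_image(stack_ct_channels(s$image), "per_channel")$data
    else normalize_image(s$image, "per_volume")$data
  }
  idx <- 0L
  take <- function(n, labeled) {
    out <- lapply(seq_len(n), function(i) {
      s <- generate_sample(spec, idx + i - 1L)
      if (labeled) list(x = prep(s), y = s$label_map, sample = s)
      else prep(s)
    })
    idx <<- idx + n
    out
  }
  unlabeled <- take(plan$n_unlabeled, FALSE)
  train <- take(plan$n_labeled, TRUE)
  val <- take(plan$n_val, TRUE)
  test <- take(plan$n_test, TRUE)
  list(unlabeled = unlabeled, train = train, val = val, test = test,
       spec = spec)
}

pretrain_for_strategy <- function(plan, data, strategy, images = NULL,
                                  salt = 0) {
  images <- images %||% data$unlabeled
  set.seed(derive_seed(plan$seed, 23 + salt))
  bank <- build_mask_bank(strategy$task, strategy$sampler,
                          strategy$patch_size,
                          c(plan$image_size, plan$image_size),
                          n_base = 20L)
  model <- build_model(plan$model, head = "inpainting")
  optim <- plan$optim
  optim$seed <- as.integer(derive_seed(plan$seed, 31 + salt))
  pretrain(model, images, bank, optim,
           val_images = lapply(data$val, `[[`, "x"))
}

finetune_for_strategy <- function(plan, data, strategy, bundle, labeled) {
  seg_cfg <- plan$model
  model <- build_model(seg_cfg, head = "segmentation")
  model <- transfer_weights(bundle, model, strategy$transfer_scope)
  optim <- plan$optim
  # identical fine-tuning seed across strategies, per protocol
  optim$seed <- as.integer(derive_seed(plan$seed, 47))
  finetune(model, labeled, strategy, optim, val = data$val)
}

baseline_for_plan <- function(plan, labeled, data, lr = 1e-3) {
  optim <- plan$optim
  optim$seed <- as.integer(derive_seed(plan$seed, 47))
  train_supervised_baseline(labeled, plan$model, optim, initial_lr = lr,
                            val = data$val)
}

eval_test_dice <- function(model, data) {
  vapply(data$test, function(s) {
    pred <- discretize_probs(predict(model, s$x))
    class_averaged_dice(pred, s$y)
  }, numeric(1))
}

label_subset_for <- function(plan, data, fraction) {
  subs <- make_label_subsets(seq_along(data$train),
                             fractions = unique(c(1, plan$fractions)),
                             seed = derive_seed(plan$seed, 7))
  data$train[subs$subsets[[as.character(fraction)]]]
}

#' Run the design-choice grid
#'
#' For every (strategy, label fraction) cell: pretrain with the
#' strategy's corruption settings, transfer per its transfer scope,
#' fine-tune on the label subset and evaluate mean class-averaged test
#' Dice. A fully-supervised baseline is trained for every fraction.
#' All strategies share identical fine-tuning seeds. Failures in a cell
#' are recorded and the run continues.
#'
#' @param plan An [experiment_plan()].
#' @param verbose Print progress.
#' @return Data frame: `strategy`, `fraction`, `mean_dice`, `l2_norm`
#'   (test-set inpainting error; `NA` for the baseline rows), `status`.
#' @export
run_design_grid <- function(plan, verbose = FALSE) {
  data <- plan_data(plan)
  rows <- list()
  note <- function(...) if (verbose) message(sprintf(...))
  for (strategy in plan$strategies) {
    sid <- strategy_id(strategy)
    cell <- tryCatch({
      note("pretraining %s", sid)
      pt <- pretrain_for_strategy(plan, data, strategy)
      eval_bank <- build_mask_bank(strategy$task, strategy$sampler,
                                   strategy$patch_size,
                                   c(plan$image_size, plan$image_size),
                                   n_base = 5L)
      l2 <- mean(vapply(data$test, function(s) {
        xc <- apply_corruption(ensure_3d(s$x), draw_mask(eval_bank))
        inpainting_l2(unet_forward(pt$model, xc)$out, ensure_3d(s$x))
      }, numeric(1)))
      list(pt = pt, l2 = l2)
    }, error = function(e) e)
    if (inherits(cell, "error")) {
      for (f in plan$fractions)
        rows[[length(rows) + 1L]] <- data.frame(
          strategy = sid, fraction = f, mean_dice = NA_real_,
          l2_norm = NA_real_, status = conditionMessage(cell))
      next
    }
    for (f in plan$fractions) {
      row <- tryCatch({
        note("fine-tuning %s at fraction %g", sid, f)
        ft <- finetune_for_strategy(plan, data, strategy, cell$pt$bundle,
                                    label_subset_for(plan, data, f))
        data.frame(strategy = sid, fraction = f,
                   mean_dice = mean(eval_test_dice(ft$model, data)),
                   l2_norm = cell$l2, status = "ok")
      }, error = function(e)
        data.frame(strategy = sid, fraction = f, mean_dice = NA_real_,
                   l2_norm = cell$l2, status = conditionMessage(e)))
      rows[[length(rows) + 1L]] <- row
    }
  }
  for (f in plan$fractions) {
    row <- tryCatch({
      note("supervised baseline at fraction %g", f)
      bl <- baseline_for_plan(plan, label_subset_for(plan, data, f), data)
      data.frame(strategy = "supervised", fraction = f,
                 mean_dice = mean(eval_test_dice(bl$model, data)),
                 l2_norm = NA_real_, status = "ok")
    }, error = function(e)
      data.frame(strategy = "supervised", fraction = f,
                 mean_dice = NA_real_, l2_norm = NA_real_,
                 status = conditionMessage(e)))
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- plan$seed
  out
}

#' Run the pretraining-data scaling sweep
#'
#' Pretrains the plan's first strategy on nested subsets of the unlabeled
#' pool at each level (percent of the full pool; level 0 is the
#' fully-supervised baseline), fine-tunes at every label fraction, and
#' fits the Dice-versus-amount power law per fraction when at least four
#' levels are available.
#'
#' @param plan An [experiment_plan()]; `pretrain_levels` must include 0.
#' @param verbose Print progress.
#' @return List with `points` (data frame: `level`, `fraction`,
#'   `mean_dice`) and `fits` (per-fraction [fit_power_law()] results or
#'   `NULL`).
#' @export
run_scaling_sweep <- function(plan, verbose = FALSE) {
  if (length(plan$pretrain_levels) < 3L || plan$pretrain_levels[1] != 0)
    stop("pretrain_levels must include 0 and at least three levels")
  data <- plan_data(plan)
  strategy <- plan$strategies[[1]]
  rows <- list()
  for (lv in plan$pretrain_levels) {
    bundle <- NULL
    if (lv > 0) {
      n_img <- max(1L, round(lv / 100 * plan$n_unlabeled))
      if (verbose) message(sprintf("pretraining at level %g%% (%d images)", lv, n_img))
      pt <- pretrain_for_strategy(plan, data, strategy,
                                  images = data$unlabeled[seq_len(n_img)],
                                  salt = lv)
      bundle <- pt$bundle
    }
    for (f in plan$fractions) {
      labeled <- label_subset_for(plan, data, f)
      md <- if (lv == 0) baseline_for_plan(plan, labeled, data)
      else finetune_for_strategy(plan, data, strategy, bundle, labeled)
      rows[[length(rows) + 1L]] <- data.frame(
        level = lv, fraction = f,
        mean_dice = mean(eval_test_dice(md$model, data)))
    }
  }
  points <- do.call(rbind, rows)
  fits <- lapply(setNames(plan$fractions, plan$fractions), function(f) {
    sub <- points[points$fraction == f, ]
    if (length(unique(sub$level)) >= 4L)
      fit_power_law(sub$level, sub$mean_dice)
    else NULL
  })
  list(points = points, fits = fits)
}

#' Compare SSL and supervised models on clinical metrics
#'
#' Trains, for every label fraction, a fully-supervised baseline and an
#' SSL model (the plan's first strategy), computes the clinically
#' relevant per-tissue metrics on every test image for both arms,
#' tabulates percent errors, pairs them per image (averaged over classes
#' and fractions), and summarizes SSL benefit with a one-sided Wilcoxon
#' signed-rank test on the pooled class-averaged Dice scores.
#'
#' @param plan An [experiment_plan()].
#' @param exclude_classes Classes excluded from the per-image comparison
#'   average.
#' @param verbose Print progress.
#' @return List with `errors` (long table of percent errors per arm),
#'   `comparison` (per-image paired table), `dice` (per-image
#'   class-averaged Dice per arm and fraction), `wilcoxon` (htest or
#'   `NULL`), and `seed`.
#' @export
compare_ssl_supervised <- function(plan, exclude_classes = integer(0),
                                   verbose = FALSE) {
  data <- plan_data(plan)
  strategy <- plan$strategies[[1]]
  pt <- pretrain_for_strategy(plan, data, strategy)
  err_rows <- list(); dice_rows <- list()
  for (f in plan$fractions) {
    labeled <- label_subset_for(plan, data, f)
    if (verbose) message(sprintf("fraction %g", f))
    bl <- baseline_for_plan(plan, labeled, data)
    ft <- finetune_for_strategy(plan, data, strategy, pt$bundle, labeled)
    for (arm in c("supervised", "ssl")) {
      model <- if (arm == "supervised") bl$model else ft$model
      for (s in data$test) {
        pred <- discretize_probs(predict(model, s$x))
        tm <- tissue_metrics(pred, s$sample)
        tm$regime <- f; tm$arm <- arm
        err_rows[[length(err_rows) + 1L]] <- tm
        dice_rows[[length(dice_rows) + 1L]] <- data.frame(
          id = s$sample$metadata$id, regime = f, arm = arm,
          dice = class_averaged_dice(pred, s$y))
      }
    }
  }
  errors <- do.call(rbind, err_rows)
  dice <- do.call(rbind, dice_rows)
  emetrics <- errors[errors$metric != "dice", ]
  sup <- emetrics[emetrics$arm == "supervised", ]
  ssl <- emetrics[emetrics$arm == "ssl", ]
  comparison <- per_image_comparison(sup, ssl, exclude_classes)
  wide <- merge(dice[dice$arm == "ssl", c("id", "regime", "dice")],
                dice[dice$arm == "supervised", c("id", "regime", "dice")],
                by = c("id", "regime"), suffixes = c("_ssl", "_sup"))
  wc <- tryCatch(wilcoxon_one_sided(wide$dice_ssl, wide$dice_sup),
                 error = function(e) NULL)
  list(errors = errors, comparison = comparison, dice = dice,
       wilcoxon = wc, seed = plan$seed)
}
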