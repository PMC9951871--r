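#' Patch corruption masks for inpainting pretext tasks
#'
#' Two pretext tasks corrupt a quarter of the image area with K x K patches:
#'
#' * *context prediction*: patches are set to zero (the image mean, since
#'   corruption happens after normalization);
#' * *context restoration*: pairs of non-overlapping patches are swapped,
#'   preserving the image's pixel-value distribution exactly.
#'
#' Patches are selected iteratively until the number of corrupted pixels
#' equals or exceeds 1/4 of the image area; the patch (or pair) that first
#' reaches the target is kept whole, so the corrupted fraction always lies
#' in `[1/4, 1/4 + step/(H*W))` where `step` is the pixel count added per
#' iteration (K^2 for prediction, 2*K^2 for a swapped pair).
#'
#' Anchors are 0-based top-left corners with half-open extents
#' `[r, r+K) x [c, c+K)`, constrained to lie fully inside the image. Two
#' samplers are available: fully `random` anchors (patches may overlap;
#' coverage is counted as the union) and `poisson` (Poisson-disc) anchors
#' whose patch centers are at least `K*sqrt(2)` apart, which guarantees all
#' patches are pairwise disjoint.
#'
#' @name corruption
NULL

check_patch_args <- function(image_shape, K) {
  if (length(image_shape) != 2L || any(image_shape < 1))
    stop("image_shape must be (H, W)")
  if (K < 1 || K > min(image_shape))
    stop("patch size K must satisfy 1 <= K <= min(H, W)")
}

#' Draw uniformly random in-bounds patch anchors
#'
#' @param image_shape Integer `(H, W)`.
#' @param K Patch side in pixels.
#' @param n Number of anchors to draw.
#' @return n x 2 integer matrix of 0-based (row, col) anchors, uniform over
#'   `[0, H-K] x [0, W-K]`.
#' @export
sample_anchors_random <- function(image_shape, K, n = 1L) {
  check_patch_args(image_shape, K)
  H <- image_shape[1]; W <- image_shape[2]
  cbind(sample.int(H - K + 1L, n, replace = TRUE) - 1L,
        sample.int(W - K + 1L, n, replace = TRUE) - 1L)
}

#' Draw Poisson-disc patch anchors
#'
#' Dart throwing with rejection: candidate anchors are uniform, and a
#' candidate is accepted only if its patch center is at least `K*sqrt(2)`
#' (Euclidean) from every accepted center. This is the smallest distance
#' bound that guarantees two axis-aligned K x K patches cannot overlap.
#' Sampling restarts from scratch if it stalls and errors after bounded
#' retries.
#'
#' @inheritParams sample_anchors_random
#' @param n Number of anchors required.
#' @return n x 2 integer matrix of 0-based anchors.
#' @export
sample_anchors_poisson <- function(image_shape, K, n) {
  check_patch_args(image_shape, K)
  if (K > min(image_shape) / 3)
    stop("Poisson-disc sampling requires K <= min(H, W) / 3 so that a quarter of the area can be covered")
  .poisson_anchors_cpp(as.integer(image_shape[1]), as.integer(image_shape[2]),
                       as.integer(K), as.integer(n))
}

#' Build a context-prediction mask
#'
#' @inheritParams sample_anchors_random
#' @param sampler `"random"` or `"poisson"`.
#' @param target_fraction Fraction of the area to corrupt (default 1/4).
#' @return Object of class `prediction_mask` with fields `patch_size`,
#'   `anchors`, `image_shape`, `covered_count`.
#' @export
build_prediction_mask <- function(image_shape, K,
                                  sampler = c("random", "poisson"),
                                  target_fraction = 0.25) {
  sampler <- match.arg(sampler)
  check_patch_args(image_shape, K)
  H <- image_shape[1]; W <- image_shape[2]
  target <- target_fraction * H * W
  if (sampler == "poisson") {
    n <- ceiling(target / K^2)
    anchors <- sample_anchors_poisson(image_shape, K, n)
    covered_count <- n * K^2
  } else {
    covered <- matrix(FALSE, H, W)
    anchors <- matrix(0L, 0L, 2L)
    covered_count <- 0L
    while (covered_count < target) {
      a <- sample_anchors_random(image_shape, K, 1L)
      ri <- (a[1] + 1L):(a[1] + K); ci <- (a[2] + 1L):(a[2] + K)
      block <- covered[ri, ci]
      covered_count <- covered_count + sum(!block)
      covered[ri, ci] <- TRUE
      anchors <- rbind(anchors, a)
    }
  }
  structure(list(patch_size = as.integer(K), anchors = unname(anchors),
                 image_shape = as.integer(image_shape),
                 covered_count = as.integer(covered_count),
                 sampler = sampler),
            class = c("prediction_mask", "corruption_mask"))
}

#' Build a context-restoration mask
#'
#' Anchors are drawn in pairs; the two patches of a pair are always
#' disjoint (re-drawn until disjoint in random mode; automatic in
#' Poisson-disc mode, where *all* patches are pairwise disjoint and the
#' sampled anchors are paired at random).
#'
#' @inheritParams build_prediction_mask
#' @return Object of class `restoration_mask` with fields `patch_size`,
#'   `pairs` (n x 4 matrix: r1, c1, r2, c2), `image_shape`,
#'   `covered_count`.
#' @export
build_restoration_mask <- function(image_shape, K,
                                   sampler = c("random", "poisson"),
                                   target_fraction = 0.25) {
  sampler <- match.arg(sampler)
  check_patch_args(image_shape, K)
  H <- image_shape[1]; W <- image_shape[2]
  target <- target_fraction * H * W
  if (sampler == "poisson") {
    n_pairs <- ceiling(target / (2 * K^2))
    anchors <- sample_anchors_poisson(image_shape, K, 2L * n_pairs)
    ord <- sample.int(2L * n_pairs)
    pairs <- cbind(anchors[ord[seq_len(n_pairs) * 2L - 1L], , drop = FALSE],
                   anchors[ord[seq_len(n_pairs) * 2L], , drop = FALSE])
    covered_count <- 2L * n_pairs * K^2
  } else {
    covered <- matrix(FALSE, H, W)
    pairs <- matrix(0L, 0L, 4L)
    covered_count <- 0L
    while (covered_count < target) {
      a1 <- sample_anchors_random(image_shape, K, 1L)
      repeat {
        a2 <- sample_anchors_random(image_shape, K, 1L)
        if (abs(a1[1] - a2[1]) >= K || abs(a1[2] - a2[2]) >= K) break
      }
      for (a in list(a1, a2)) {
        ri <- (a[1] + 1L):(a[1] + K); ci <- (a[2] + 1L):(a[2] + K)
        covered_count <- covered_count + sum(!covered[ri, ci])
        covered[ri, ci] <- TRUE
      }
      pairs <- rbind(pairs, cbind(a1, a2))
    }
  }
  structure(list(patch_size = as.integer(K), pairs = unname(pairs),
                 image_shape = as.integer(image_shape),
                 covered_count = as.integer(covered_count),
                 sampler = sampler),
            class = c("restoration_mask", "corruption_mask"))
}

mask_anchors <- function(mask) {
  if (inherits(mask, "prediction_mask")) mask$anchors
  else rbind(mask$pairs[, 1:2, drop = FALSE], mask$pairs[, 3:4, drop = FALSE])
}

#' Boolean grid of corrupted pixels
#'
#' @param mask A `prediction_mask` or `restoration_mask`.
#' @return H x W logical matrix, `TRUE` where the mask corrupts.
#' @export
mask_covered <- function(mask) {
  stopifnot(inherits(mask, "corruption_mask"))
  H <- mask$image_shape[1]; W <- mask$image_shape[2]; K <- mask$patch_size
  covered <- matrix(FALSE, H, W)
  a <- mask_anchors(mask)
  for (i in seq_len(nrow(a)))
    covered[(a[i, 1] + 1L):(a[i, 1] + K), (a[i, 2] + 1L):(a[i, 2] + K)] <- TRUE
  covered
}

#' Fraction of image pixels a mask corrupts
#' @param mask A corruption mask.
#' @export
mask_coverage <- function(mask) {
  mask$covered_count / prod(mask$image_shape)
}

#' @export
print.prediction_mask <- function(x, ...) {
  cat(sprintf("prediction_mask: %d patches of %dx%d on %dx%d (%s), coverage %.4f\n",
              nrow(x$anchors), x$patch_size, x$patch_size,
              x$image_shape[1], x$image_shape[2], x$sampler, mask_coverage(x)))
  invisible(x)
}

#' @export
print.restoration_mask <- function(x, ...) {
  cat(sprintf("restoration_mask: %d pairs of %dx%d on %dx%d (%s), coverage %.4f\n",
              nrow(x$pairs), x$patch_size, x$patch_size,
              x$image_shape[1], x$image_shape[2], x$sampler, mask_coverage(x)))
  invisible(x)
}

#' Rotate a corruption mask by quarter turns (counter-clockwise)
#'
#' Rotation by 90 or 270 degrees requires a square image shape. The
#' corrupted-pixel count is invariant.
#'
#' @param mask A corruption mask.
#' @param quarter_turns 0, 1, 2 or 3 counter-clockwise quarter turns.
#' @return Rotated mask of the same class.
#' @export
rotate_mask <- function(mask, quarter_turns) {
  stopifnot(inherits(mask, "corruption_mask"))
  q <- as.integer(quarter_turns) %% 4L
  H <- mask$image_shape[1]; W <- mask$image_shape[2]
  if (q %in% c(1L, 3L) && H != W)
    stop("90/270 degree rotation requires a square image shape")
  K <- mask$patch_size
  rot1 <- function(a, H, W)  # one CCW turn; new shape (W, H)
    cbind(W - a[, 2] - K, a[, 1])
  rot <- function(a) {
    h <- H; w <- W
    for (i in seq_len(q)) {
      a <- rot1(a, h, w)
      tmp <- h; h <- w; w <- tmp
    }
    a
  }
  out <- mask
  if (inherits(mask, "prediction_mask")) {
    out$anchors <- rot(mask$anchors)
  } else {
    out$pairs <- cbind(rot(mask$pairs[, 1:2, drop = FALSE]),
                       rot(mask$pairs[, 3:4, drop = FALSE]))
  }
  out$image_shape <- if (q %% 2L == 1L) c(W, H) else c(H, W)
  out
}

#' Corrupt an image for context prediction
#'
#' Sets corrupted pixels to zero; all other pixels are untouched. Since
#' images are corrupted after normalization, zero equals the unit's mean
#' intensity. For multi-channel input the same spatial mask is applied to
#' every channel (identical corruption locations across channels).
#'
#' @param image H x W matrix or H x W x C array on the normalized scale.
#' @param mask A `prediction_mask` matching the image shape.
#' @return Corrupted image, same shape.
#' @export
apply_prediction <- function(image, mask) {
  stopifnot(inherits(mask, "prediction_mask"))
  d <- dim(image)
  if (!all(d[1:2] == mask$image_shape)) stop("image and mask shapes differ")
  cov <- mask_covered(mask)
  if (length(d) == 2L) {
    image[cov] <- 0
  } else {
    for (k in seq_len(d[3])) {
      ch <- image[, , k]; ch[cov] <- 0; image[, , k] <- ch
    }
  }
  image
}

#' Corrupt an image for context restoration
#'
#' Swaps the two patches of every pair (channel-consistently for
#' multi-channel input). The multiset of pixel values is exactly preserved.
#' Swapping with the same mask twice restores the original image when the
#' mask's pairs are mutually disjoint (always true for Poisson-disc masks).
#'
#' @param image H x W matrix or H x W x C array.
#' @param mask A `restoration_mask` matching the image shape.
#' @return Corrupted image, same shape.
#' @export
apply_restoration <- function(image, mask) {
  stopifnot(inherits(mask, "restoration_mask"))
  d <- dim(image)
  if (!all(d[1:2] == mask$image_shape)) stop("image and mask shapes differ")
  K <- mask$patch_size
  two_d <- length(d) == 2L
  for (i in seq_len(nrow(mask$pairs))) {
    r1 <- (mask$pairs[i, 1] + 1L):(mask$pairs[i, 1] + K)
    c1 <- (mask$pairs[i, 2] + 1L):(mask$pairs[i, 2] + K)
    r2 <- (mask$pairs[i, 3] + 1L):(mask$pairs[i, 3] + K)
    c2 <- (mask$pairs[i, 4] + 1L):(mask$pairs[i, 4] + K)
    if (two_d) {
      tmp <- image[r1, c1]
      image[r1, c1] <- image[r2, c2]
      image[r2, c2] <- tmp
    } else {
      tmp <- image[r1, c1, , drop = FALSE]
      image[r1, c1, ] <- image[r2, c2, , drop = FALSE]
      image[r2, c2, ] <- tmp
    }
  }
  image
}

#' Apply any corruption mask
#'
#' Dispatches to [apply_prediction()] or [apply_restoration()].
#' @inheritParams apply_prediction
#' @export
apply_corruption <- function(image, mask) {
  if (inherits(mask, "prediction_mask")) apply_prediction(image, mask)
  else apply_restoration(image, mask)
}

#' Precompute a bank of corruption masks
#'
#' A bank holds `n_base` independently sampled masks of one task type;
#' during training a mask is drawn uniformly and rotated by a uniformly
#' random quarter turn, so the effective number of masks is `4 * n_base`
#' (400 for the default bank of 100).
#'
#' @param task `"prediction"` or `"restoration"`.
#' @inheritParams build_prediction_mask
#' @param n_base Number of base masks (default 100).
#' @return Object of class `mask_bank`.
#' @export
build_mask_bank <- function(task = c("prediction", "restoration"),
                            sampler = c("random", "poisson"),
                            K, image_shape, n_base = 100L,
                            target_fraction = 0.25) {
  task <- match.arg(task); sampler <- match.arg(sampler)
  build <- if (task == "prediction") build_prediction_mask else build_restoration_mask
  base_masks <- lapply(seq_len(n_base), function(i)
    build(image_shape, K, sampler, target_fraction))
  structure(list(task = task, sampler = sampler, patch_size = as.integer(K),
                 image_shape = as.integer(image_shape),
                 base_masks = base_masks, n_base = as.integer(n_base)),
            class = "mask_bank")
}

#' @export
print.mask_bank <- function(x, ...) {
  cat(sprintf("mask_bank: %d base %s masks (%s, K=%d) on %dx%d; effective size %d\n",
              x$n_base, x$task, x$sampler, x$patch_size,
              x$image_shape[1], x$image_shape[2], effective_size(x)))
  invisible(x)
}

#' Effective number of masks in a bank (base masks times 4 rotations)
#' @param bank A `mask_bank`.
#' @export
effective_size <- function(bank) {
  stopifnot(inherits(bank, "mask_bank"))
  4L * bank$n_base
}

#' Draw a random rotated mask from a bank
#'
#' Uniform over base masks and over the four quarter-turn rotations.
#'
#' @param bank A `mask_bank`.
#' @return A corruption mask.
#' @export
draw_mask <- function(bank) {
  stopifnot(inherits(bank, "mask_bank"))
  if (bank$n_base < 1L) stop("empty mask bank")
  i <- sample.int(bank$n_base, 1L)
  q <- sample.int(4L, 1L) - 1L
  rotate_mask(bank$base_masks[[i]], q)
}

#' Serialize / restore a mask bank
#'
#' Banks are stored as JSON (task, sampler, patch size, image shape and the
#' anchor lists of every base mask); reloading is bit-exact.
#'
#' @param bank A `mask_bank`.
#' @param path File path.
#' @export
save_mask_bank <- function(bank, path) {
  stopifnot(inherits(bank, "mask_bank"))
  payload <- list(
    task = bank$task, sampler = bank$sampler,
    patch_size = bank$patch_size, image_shape = bank$image_shape,
    n_base = bank$n_base,
    # anchor matrices stored as flat column-major vectors for a stable layout
    masks = lapply(bank$base_masks, function(m)
      if (bank$task == "prediction")
        list(anchors = as.vector(m$anchors), covered_count = m$covered_count)
      else list(pairs = as.vector(m$pairs), covered_count = m$covered_count))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_mask_bank
#' @export
load_mask_bank <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  shape <- as.integer(unlist(p$image_shape))
  cls <- if (p$task == "prediction") c("prediction_mask", "corruption_mask")
  else c("restoration_mask", "corruption_mask")
  masks <- lapply(seq_len(p$n_base), function(i) {
    m <- p$masks[[i]]
    fields <- if (p$task == "prediction")
      list(patch_size = as.integer(p$patch_size),
           anchors = matrix(as.integer(unlist(m$anchors)), ncol = 2L))
    else
      list(patch_size = as.integer(p$patch_size),
           pairs = matrix(as.integer(unlist(m$pairs)), ncol = 4L))
    structure(c(fields, list(image_shape = shape,
                             covered_count = as.integer(m$covered_count),
                             sampler = p$sampler)), class = cls)
  })
  structure(list(task = p$task, sampler = p$sampler,
                 patch_size = as.integer(p$patch_size), image_shape = shape,
                 base_masks = masks, n_base = as.integer(p$n_base)),
            class = "mask_bank")
}
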