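#' Dice coefficient between two hard label maps for one class
#'
#' `2|P intersect G| / (|P| + |G|)`; defined as 1 when both masks are
#' empty. Symmetric in its arguments.
#'
#' @param pred,truth Integer label maps of identical shape.
#' @param class_id Class to score.
#' @return Dice in `[0, 1]`.
#' @export
dice_score <- function(pred, truth, class_id) {
  if (!identical(dim(pred), dim(truth))) stop("label map shapes differ")
  p <- pred == class_id
  g <- truth == class_id
  np <- sum(p); ng <- sum(g)
  if (np + ng == 0L) return(1)
  2 * sum(p & g) / (np + ng)
}

#' Class-averaged Dice for one image/volume
#'
#' Mean of the 4 per-class Dice scores (used for strategy ranking).
#' @inheritParams dice_score
#' @export
class_averaged_dice <- function(pred, truth) {
  mean(vapply(1:4, function(c) dice_score(pred, truth, c), numeric(1)))
}

#' Inpainting reconstruction error (L2 norm)
#'
#' Euclidean norm of the difference image on the normalized scale. For
#' multi-channel images the norm is computed per channel and averaged
#' across channels.
#'
#' @param reconstruction,original Same-shape arrays on the normalized
#'   scale.
#' @return Non-negative scalar.
#' @export
inpainting_l2 <- function(reconstruction, original) {
  if (!identical(dim(reconstruction), dim(original)))
    stop("image shapes differ")
  d <- dim(reconstruction)
  diff <- reconstruction - original
  if (length(d) == 2L) return(sqrt(sum(diff^2)))
  mean(vapply(seq_len(d[3]), function(k) sqrt(sum(diff[, , k]^2)), numeric(1)))
}

#' Tissue volume from label maps
#'
#' Pixel count times squared in-plane spacing times slice thickness,
#' summed over slices.
#'
#' @param label_map Label map matrix or list of per-slice matrices.
#' @param pixel_spacing In-plane pixel size in mm.
#' @param slice_thickness Slice thickness in mm.
#' @param class_id Tissue class.
#' @return Volume in mm^3.
#' @export
tissue_volume <- function(label_map, pixel_spacing, slice_thickness, class_id) {
  if (missing(pixel_spacing) || missing(slice_thickness) ||
      is.null(pixel_spacing) || is.null(slice_thickness) ||
      !is.finite(pixel_spacing) || !is.finite(slice_thickness) ||
      pixel_spacing <= 0 || slice_thickness <= 0)
    stop("valid pixel spacing and slice thickness are required")
  if (!is.list(label_map)) label_map <- list(label_map)
  n <- sum(vapply(label_map, function(m) sum(m == class_id), numeric(1)))
  n * pixel_spacing^2 * slice_thickness
}

#' Mean T2 relaxation time over a tissue mask
#'
#' @param t2_map T2 map in milliseconds.
#' @param label_map Matching label map.
#' @param class_id Tissue class.
#' @return Mean T2 in ms, or `NA` when the mask is empty.
#' @export
mean_t2 <- function(t2_map, label_map, class_id) {
  if (!identical(dim(t2_map), dim(label_map))) stop("map shapes differ")
  m <- label_map == class_id
  if (!any(m)) return(NA_real_)
  mean(t2_map[m])
}

#' Tissue cross-sectional area
#'
#' Pixel count times squared pixel spacing.
#' @inheritParams tissue_volume
#' @return Area in mm^2.
#' @export
cross_sectional_area <- function(label_map, pixel_spacing, class_id) {
  if (missing(pixel_spacing) || is.null(pixel_spacing) ||
      !is.finite(pixel_spacing) || pixel_spacing <= 0)
    stop("valid pixel spacing is required")
  sum(label_map == class_id) * pixel_spacing^2
}

#' Mean Hounsfield-unit value over a tissue mask
#'
#' Computed on the raw, un-windowed, un-normalized HU image so the value
#' stays physically meaningful (even when the model consumed windowed,
#' normalized channels).
#'
#' @param hu_image Raw HU matrix.
#' @param label_map Matching label map.
#' @param class_id Tissue class.
#' @return Mean HU, or `NA` when the mask is empty.
#' @export
mean_hu <- function(hu_image, label_map, class_id) {
  if (!identical(dim(hu_image), dim(label_map))) stop("map shapes differ")
  m <- label_map == class_id
  if (!any(m)) return(NA_real_)
  mean(hu_image[m])
}

#' Percent error of a predicted metric against ground truth
#'
#' `100 * |pred - gt| / |gt|` (magnitudes; the signed error is available
#' via `signed = TRUE` for diagnostics).
#'
#' @param pred,gt Metric values; `gt` must be non-zero.
#' @param signed Return the signed error instead of the magnitude.
#' @return Percent error, or `NA` when `gt` is 0 or either value is `NA`.
#' @export
percent_error <- function(pred, gt, signed = FALSE) {
  out <- ifelse(is.na(gt) | is.na(pred) | gt == 0, NA_real_,
                100 * (pred - gt) / abs(gt))
  if (signed) out else abs(out)
}

#' Discretize class probabilities to a hard label map
#'
#' Argmax over the 4 foreground classes, with a pixel assigned to
#' background when no class probability exceeds `background_threshold`.
#'
#' @param probs H x W x 4 probability array.
#' @param background_threshold Minimum winning probability (default 0.5).
#' @return H x W integer label map with values 0-4.
#' @export
discretize_probs <- function(probs, background_threshold = 0.5) {
  d <- dim(probs)
  flat <- matrix(probs, d[1] * d[2], d[3])
  win <- max.col(flat, ties.method = "first")
  best <- flat[cbind(seq_len(nrow(flat)), win)]
  win[best <= background_threshold] <- 0L
  matrix(as.integer(win), d[1], d[2])
}

#' Clinically relevant per-tissue metrics for one sample
#'
#' For MRI: per-class Dice, tissue volume (mm^3) and mean T2 (ms); for CT:
#' per-class Dice, cross-sectional area (mm^2) and mean HU. Percent errors
#' compare prediction-derived values to ground-truth-derived values.
#'
#' @param pred_label Predicted label map.
#' @param sample A `phantom_sample` (or equivalent list with `image`,
#'   `label_map`, optional `t2_map` and `metadata`).
#' @return Data frame: one row per (class, metric) with predicted,
#'   ground-truth, percent error and signed percent error.
#' @export
tissue_metrics <- function(pred_label, sample) {
  md <- sample$metadata
  mri <- identical(md$modality, "mri")
  rows <- list()
  for (cls in 1:4) {
    d <- dice_score(pred_label, sample$label_map, cls)
    rows[[length(rows) + 1L]] <- data.frame(
      id = md$id, class = cls, metric = "dice",
      predicted = d, ground_truth = 1, percent_error = NA_real_,
      signed_percent_error = NA_real_, stringsAsFactors = FALSE)
    vals <- if (mri) list(
      volume = c(tissue_volume(pred_label, md$pixel_spacing,
                               md$slice_thickness, cls),
                 tissue_volume(sample$label_map, md$pixel_spacing,
                               md$slice_thickness, cls)),
      mean_t2 = c(mean_t2(sample$t2_map, pred_label, cls),
                  mean_t2(sample$t2_map, sample$label_map, cls)))
    else list(
      csa = c(cross_sectional_area(pred_label, md$pixel_spacing, cls),
              cross_sectional_area(sample$label_map, md$pixel_spacing, cls)),
      mean_hu = c(mean_hu(sample$image, pred_label, cls),
                  mean_hu(sample$image, sample$label_map, cls)))
    for (mname in names(vals)) {
      v <- vals[[mname]]
      rows[[length(rows) + 1L]] <- data.frame(
        id = md$id, class = cls, metric = mname,
        predicted = v[1], ground_truth = v[2],
        percent_error = percent_error(v[1], v[2]),
        signed_percent_error = percent_error(v[1], v[2], signed = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Pair per-image percent errors of supervised and SSL models
#'
#' Averages each arm's percent error over classes and label-limited
#' regimes, yielding one row per test image with the supervised mean, the
#' SSL mean and their difference. Classes can be excluded from the average
#' (e.g. intramuscular fat for CT, whose tiny area inflates errors).
#'
#' @param supervised,ssl Data frames with columns `id`, `class`, `regime`,
#'   `percent_error` over identical index sets.
#' @param exclude_classes Classes dropped before averaging.
#' @return Data frame: `id`, `supervised`, `ssl`, `difference`.
#' @export
per_image_comparison <- function(supervised, ssl, exclude_classes = integer(0)) {
  key <- function(d) paste(d$id, d$class, d$regime)
  if (!setequal(key(supervised), key(ssl)))
    stop("supervised and ssl tables index different (image, class, regime) sets")
  keep <- !(supervised$class %in% exclude_classes)
  sup <- supervised[keep, ]
  ssl2 <- ssl[!(ssl$class %in% exclude_classes), ]
  ms <- tapply(sup$percent_error, sup$id, mean, na.rm = TRUE)
  ml <- tapply(ssl2$percent_error, ssl2$id, mean, na.rm = TRUE)
  ids <- sort(names(ms))
  data.frame(id = ids, supervised = as.numeric(ms[ids]),
             ssl = as.numeric(ml[ids]),
             difference = as.numeric(ms[ids] - ml[ids]),
             stringsAsFactors = FALSE)
}

#' Headline Dice aggregation
#'
#' Per class: mean over volumes/slices of the per-volume class Dice; the
#' headline value is the mean of the per-class means.
#'
#' @param scores Data frame with columns `id`, `class`, `dice`.
#' @return List with `per_class` (named numeric) and `overall`.
#' @export
aggregate_dice <- function(scores) {
  per_class <- tapply(scores$dice, scores$class, mean)
  per_class <- setNames(as.numeric(per_class), names(per_class))
  list(per_class = per_class, overall = mean(per_class))
}
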