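#' Phantom specification
#'
#' Describes a family of synthetic 2D MRI-like or CT-like images with four
#' non-overlapping tissue structures (axis-aligned ellipses, one rendered as
#' an annulus) on a constant background. Each structure carries a constant
#' class intensity (Hounsfield units for CT, arbitrary units for MRI), and
#' MRI phantoms additionally carry a piecewise-constant T2 relaxation map.
#' Additive Gaussian noise is applied on top. The phantoms exist so that
#' every downstream stage (corruption, training, metrics) is testable with
#' analytically known ground truth; they make no attempt at realistic
#' anatomy.
#'
#' @param height,width Image dimensions in pixels (at least 64).
#' @param modality `"mri"` or `"ct"`.
#' @param intensity_table Named numeric vector mapping class ids `1:4` to
#'   mean intensity. CT values must lie in `[-1024, 3071]` HU.
#' @param t2_table Named numeric vector mapping class ids `1:4` to T2 in
#'   milliseconds (MRI only).
#' @param background Background intensity (same units as `intensity_table`).
#' @param noise_sigma Standard deviation of additive Gaussian noise.
#' @param pixel_spacing In-plane pixel size in mm (isotropic).
#' @param slice_thickness Slice thickness in mm.
#' @param seed Integer seed; together with a sample index it fully
#'   determines each generated sample.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 128, width = 128,
                         modality = c("mri", "ct"),
                         intensity_table = NULL,
                         t2_table = c(`1` = 35, `2` = 40, `3` = 45, `4` = 20),
                         background = NULL,
                         noise_sigma = 5,
                         pixel_spacing = 0.5,
                         slice_thickness = 2,
                         seed = 1L) {
  modality <- match.arg(modality)
  if (height < 64 || width < 64)
    stop("phantom dimensions must be at least 64x64")
  if (is.null(intensity_table)) {
    intensity_table <- if (modality == "ct")
      c(`1` = 40, `2` = -105, `3` = -90, `4` = 300)   # muscle / fat / fat / bone-ish
    else
      c(`1` = 400, `2` = 300, `3` = 200, `4` = 500)
  }
  if (length(intensity_table) != 4L)
    stop("intensity_table must map exactly 4 classes")
  if (is.null(background)) background <- if (modality == "ct") -50 else 100
  if (modality == "ct" &&
      (any(intensity_table < -1024) || any(intensity_table > 3071)))
    stop("CT intensities must lie in [-1024, 3071] HU")
  if (modality == "mri" && length(t2_table) != 4L)
    stop("t2_table must map exactly 4 classes")
  structure(list(
    height = as.integer(height), width = as.integer(width),
    modality = modality,
    intensity_table = intensity_table,
    t2_table = if (modality == "mri") t2_table else NULL,
    background = background,
    noise_sigma = noise_sigma,
    pixel_spacing = pixel_spacing,
    slice_thickness = slice_thickness,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %dx%d %s, noise sigma %.3g, spacing %.3g mm, seed %d\n",
              x$height, x$width, toupper(x$modality), x$noise_sigma,
              x$pixel_spacing, x$seed))
  invisible(x)
}

# deterministic per-sample seed below 2^31
sample_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483629
}

# boolean mask of an axis-aligned ellipse (optionally annulus) on an HxW grid
ellipse_mask <- function(H, W, cy, cx, ry, rx, inner = 0) {
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  d <- ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2
  m <- d <= 1
  if (inner > 0) m <- m & (((yy - cy) / (ry * inner))^2 +
                             ((xx - cx) / (rx * inner))^2 > 1)
  m
}

#' Generate one phantom sample
#'
#' Deterministic in `(spec$seed, index)`. The four structures are placed one
#' per image quadrant with jittered centers and radii bounded so they stay
#' disjoint and fully inside the image; class 4 is rendered as an annulus.
#' Each class is guaranteed to occupy at least 0.5% of the pixels.
#'
#' @param spec A [phantom_spec()].
#' @param index Sample index (non-negative integer).
#' @return A list of class `phantom_sample` with elements `image` (H x W
#'   matrix; raw HU for CT), `label_map` (H x W integer matrix, values 0-4),
#'   `t2_map` (H x W matrix in ms, MRI only, else `NULL`) and `metadata`.
#' @export
generate_sample <- function(spec, index = 0L) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$height; W <- spec$width
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sample_seed(spec$seed, index))

  label <- matrix(0L, H, W)
  qc <- list(c(0.25, 0.25), c(0.25, 0.75), c(0.75, 0.25), c(0.75, 0.75))
  min_px <- ceiling(0.005 * H * W)
  for (cls in 1:4) {
    placed <- FALSE
    for (attempt in 1:50) {
      jy <- runif(1, -H / 16, H / 16); jx <- runif(1, -W / 16, W / 16)
      cy <- qc[[cls]][1] * H + jy; cx <- qc[[cls]][2] * W + jx
      # radius bounded by quadrant half-size minus jitter and a 2px margin
      rmax_y <- H / 4 - abs(jy) - 2; rmax_x <- W / 4 - abs(jx) - 2
      ry <- runif(1, H / 12, max(H / 12 + 1, min(H / 5.5, rmax_y)))
      rx <- runif(1, W / 12, max(W / 12 + 1, min(W / 5.5, rmax_x)))
      ry <- min(ry, rmax_y); rx <- min(rx, rmax_x)
      m <- ellipse_mask(H, W, cy, cx, ry, rx,
                        inner = if (cls == 4L) 0.5 else 0)
      if (sum(m) >= min_px && !any(label[m] != 0L)) {
        label[m] <- cls
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("failed to place structure for class %d after bounded retries", cls))
  }

  img <- matrix(spec$background, H, W)
  for (cls in 1:4) img[label == cls] <- spec$intensity_table[[cls]]
  if (spec$noise_sigma > 0)
    img <- img + matrix(rnorm(H * W, 0, spec$noise_sigma), H, W)
  if (spec$modality == "ct") img <- pmin(pmax(img, -1024), 3071)

  t2 <- NULL
  if (spec$modality == "mri") {
    t2 <- matrix(0, H, W)
    for (cls in 1:4) t2[label == cls] <- spec$t2_table[[cls]]
  }

  structure(list(
    image = img, label_map = label, t2_map = t2,
    metadata = list(
      id = sprintf("%s_%04d", spec$modality, as.integer(index)),
      modality = spec$modality,
      pixel_spacing = spec$pixel_spacing,
      slice_thickness = spec$slice_thickness
    )
  ), class = "phantom_sample")
}

# save/restore the global RNG state so generators are pure wrt the session
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a phantom dataset on disk
#'
#' Writes each sample's image (plus label map and, for MRI, T2 map) as
#' NIfTI (`.nii.gz`) and a CSV manifest. Unlabeled rows (used for
#' pretraining only) have empty `label_path` and `t2_path`.
#'
#' @param spec A [phantom_spec()].
#' @param n_labeled,n_unlabeled Numbers of labeled / unlabeled samples.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame (also written to
#'   `manifest.csv` in `out_dir`).
#' @export
generate_dataset <- function(spec, n_labeled, n_unlabeled, out_dir) {
  stopifnot(n_labeled >= 0, n_unlabeled >= 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_labeled + n_unlabeled
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_sample(spec, index = i - 1L)
    labeled <- i <= n_labeled
    id <- s$metadata$id
    ipath <- file.path(out_dir, paste0(id, "_image.nii.gz"))
    RNifti::writeNifti(nifti_with_spacing(s$image, spec), ipath)
    lpath <- tpath <- ""
    if (labeled) {
      lpath <- file.path(out_dir, paste0(id, "_label.nii.gz"))
      RNifti::writeNifti(nifti_with_spacing(s$label_map, spec), lpath)
      if (spec$modality == "mri") {
        tpath <- file.path(out_dir, paste0(id, "_t2.nii.gz"))
        RNifti::writeNifti(nifti_with_spacing(s$t2_map, spec), tpath)
      }
    }
    rows[[i]] <- data.frame(
      id = id,
      split = if (labeled) "labeled" else "unlabeled",
      image_path = ipath, label_path = lpath, t2_path = tpath,
      pixel_spacing_mm = spec$pixel_spacing,
      slice_thickness_mm = spec$slice_thickness,
      modality = spec$modality,
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

nifti_with_spacing <- function(arr, spec) {
  RNifti::asNifti(arr, pixdim = c(spec$pixel_spacing, spec$pixel_spacing))
}

#' Read a manifest row's grids back into memory
#'
#' @param row One row of a manifest data frame written by
#'   [generate_dataset()].
#' @return A `phantom_sample`-shaped list (absent grids are `NULL`).
#' @export
read_sample <- function(row) {
  img <- drop(as.array(RNifti::readNifti(row$image_path)))
  lab <- if (nzchar(row$label_path))
    matrix(as.integer(round(as.array(RNifti::readNifti(row$label_path)))),
           nrow(img), ncol(img))
  else NULL
  t2 <- if (nzchar(row$t2_path)) drop(as.array(RNifti::readNifti(row$t2_path)))
  else NULL
  structure(list(
    image = img, label_map = lab, t2_map = t2,
    metadata = list(id = row$id, modality = row$modality,
                    pixel_spacing = row$pixel_spacing_mm,
                    slice_thickness = row$slice_thickness_mm)
  ), class = "phantom_sample")
}
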