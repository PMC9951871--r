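#' CT window/level settings
#'
#' The three Hounsfield-unit windows used to build multi-channel CT input:
#' soft tissue (W/L = 400/50), bone (W/L = 1800/40) and a custom setting
#' (W/L = 500/50). A window of width W centered at level L clips intensities
#' to `[L - W/2, L + W/2]`.
#'
#' @return Named list of `window_level` objects in channel order.
#' @export
ct_window_levels <- function() {
  list(soft_tissue = window_level(400, 50),
       bone        = window_level(1800, 40),
       custom      = window_level(500, 50))
}

#' @rdname ct_window_levels
#' @param window Window width in HU (positive).
#' @param level Window center in HU.
#' @export
window_level <- function(window, level) {
  if (!is.numeric(window) || window <= 0) stop("window width must be positive")
  structure(list(window = window, level = level), class = "window_level")
}

#' Apply a HU window to a CT image
#'
#' Clips intensities to `[L - W/2, L + W/2]`; values inside the window are
#' unchanged and the output stays in HU (rescaling is left to
#' [normalize_image()]).
#'
#' @param hu_image Numeric matrix/array of raw HU values.
#' @param wl A [window_level()].
#' @return Clipped image, same shape.
#' @export
window_ct <- function(hu_image, wl) {
  stopifnot(inherits(wl, "window_level"))
  if (any(!is.finite(hu_image))) stop("hu_image must be finite")
  lo <- wl$level - wl$window / 2
  hi <- wl$level + wl$window / 2
  pmin(pmax(hu_image, lo), hi)
}

#' Stack a CT slice into three windowed channels
#'
#' Channel order: soft tissue (400/50), bone (1800/40), custom (500/50).
#'
#' @param hu_image Single-channel raw-HU matrix.
#' @return H x W x 3 array of windowed HU values.
#' @export
stack_ct_channels <- function(hu_image) {
  if (length(dim(hu_image)) != 2L)
    stop("stack_ct_channels expects a single-channel image")
  wls <- ct_window_levels()
  out <- array(0, c(dim(hu_image), 3L))
  for (k in seq_along(wls)) out[, , k] <- window_ct(hu_image, wls[[k]])
  dimnames(out) <- list(NULL, NULL, names(wls))
  out
}

#' Standardize an image to zero mean and unit variance
#'
#' MRI images are normalized over the whole volume (`per_volume`; a single
#' 2D image is its own unit), CT images per windowed channel
#' (`per_channel`). The means and standard deviations used are returned so
#' the transform can be inverted.
#'
#' @param image Matrix (H x W) or array (H x W x C).
#' @param mode `"per_volume"` or `"per_channel"`.
#' @return List of class `normalized_image` with `data`, `center`, `scale`,
#'   `mode`.
#' @export
normalize_image <- function(image, mode = c("per_volume", "per_channel")) {
  mode <- match.arg(mode)
  d <- dim(image)
  if (mode == "per_channel" && length(d) != 3L)
    stop("per_channel normalization requires an H x W x C array")
  if (mode == "per_volume") {
    mu <- mean(image)
    sigma <- stats::sd(as.vector(image))
    if (!is.finite(sigma) || sigma == 0)
      stop("cannot normalize a constant unit (zero standard deviation)")
    out <- (image - mu) / sigma
  } else {
    C <- d[3]
    mu <- sigma <- numeric(C)
    out <- image
    for (k in seq_len(C)) {
      v <- image[, , k]
      mu[k] <- mean(v)
      sigma[k] <- stats::sd(as.vector(v))
      if (!is.finite(sigma[k]) || sigma[k] == 0)
        stop(sprintf("cannot normalize constant channel %d (zero standard deviation)", k))
      out[, , k] <- (v - mu[k]) / sigma[k]
    }
  }
  structure(list(data = out, center = mu, scale = sigma, mode = mode),
            class = "normalized_image")
}

#' Invert [normalize_image()]
#'
#' @param norm A `normalized_image`, or a plain array together with the
#'   `center`/`scale` record.
#' @param data Optional replacement data on the normalized scale (e.g. a
#'   network reconstruction) to map back to original units.
#' @return Array in original units.
#' @export
denormalize_image <- function(norm, data = NULL) {
  stopifnot(inherits(norm, "normalized_image"))
  x <- if (is.null(data)) norm$data else data
  if (norm$mode == "per_volume") return(x * norm$scale + norm$center)
  out <- x
  for (k in seq_along(norm$scale))
    out[, , k] <- x[, , k] * norm$scale[k] + norm$center[k]
  out
}
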