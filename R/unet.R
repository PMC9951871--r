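#' U-Net model configuration
#'
#' A 2D U-Net whose weights are partitioned into three scopes: the
#' *encoder* (contracting path including the bottleneck), the *decoder*
#' (expanding path: transposed convolutions and the convolutions after skip
#' concatenation) and the *post-processing* layer (the final 1x1
#' convolution that defines the head). Inpainting and segmentation heads
#' share an identical topology apart from the post-processing layer's
#' output channels (`in_channels` for inpainting, 4 for segmentation).
#'
#' Every level applies two 3x3 convolution blocks (weight-standardized
#' convolution, Group Normalization, ReLU); downsampling is 2x2 max
#' pooling, upsampling a 2x2 stride-2 transposed convolution, and skip
#' connections concatenate encoder features to the decoder.
#'
#' @param in_channels Input channels (1 for MRI, 3 for windowed CT).
#' @param depth Number of resolution levels (at least 2).
#' @param base_filters Channels at the top level; doubled per level.
#' @param groupnorm_groups Groups for Group Normalization; must divide
#'   every layer's channel count.
#' @param gn_eps,ws_eps Numerical floors for Group Normalization and
#'   weight standardization.
#' @param seed Seed for He weight initialization.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(in_channels = 1L, depth = 4L, base_filters = 16L,
                        groupnorm_groups = 8L, gn_eps = 1e-5, ws_eps = 1e-7,
                        seed = 1L) {
  if (depth < 2L) stop("depth must be at least 2")
  ch <- base_filters * 2^(seq_len(depth) - 1L)
  if (any(ch %% groupnorm_groups != 0L))
    stop("groupnorm_groups must divide every layer's channel count")
  structure(list(in_channels = as.integer(in_channels),
                 depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 groupnorm_groups = as.integer(groupnorm_groups),
                 gn_eps = gn_eps, ws_eps = ws_eps, seed = as.integer(seed)),
            class = "unet_config")
}

he_init <- function(dims) {
  fan_in <- prod(dims[-length(dims)])
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

scope_of <- function(name) {
  if (startsWith(name, "enc")) "encoder"
  else if (startsWith(name, "post")) "post_processing"
  else "decoder"
}

#' Build a U-Net
#'
#' @param config A [unet_config()].
#' @param head `"inpainting"` (output channels = input channels) or
#'   `"segmentation"` (4 output channels).
#' @return Object of class `unet` with named parameter arrays, a scope map
#'   and per-parameter trainability flags. Weights are He-initialized
#'   (fan-in, normal) deterministically under `config$seed`.
#' @export
build_model <- function(config, head = c("inpainting", "segmentation")) {
  head <- match.arg(head)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  D <- config$depth
  ch <- config$base_filters * 2^(seq_len(D) - 1L)
  out_ch <- if (head == "segmentation") 4L else config$in_channels
  params <- list()
  add_block <- function(prefix, cin, cout) {
    params[[paste0(prefix, ".w")]] <<- he_init(c(3L, 3L, cin, cout))
    params[[paste0(prefix, ".gn.gamma")]] <<- rep(1, cout)
    params[[paste0(prefix, ".gn.beta")]] <<- rep(0, cout)
  }
  for (d in seq_len(D)) {
    cin <- if (d == 1L) config$in_channels else ch[d - 1L]
    add_block(sprintf("enc%d.conv1", d), cin, ch[d])
    add_block(sprintf("enc%d.conv2", d), ch[d], ch[d])
  }
  for (d in rev(seq_len(D - 1L))) {
    params[[sprintf("up%d.w", d)]] <- he_init(c(2L, 2L, ch[d + 1L], ch[d]))
    add_block(sprintf("dec%d.conv1", d), 2L * ch[d], ch[d])
    add_block(sprintf("dec%d.conv2", d), ch[d], ch[d])
  }
  params[["post.w"]] <- he_init(c(1L, 1L, ch[1L], out_ch))
  params[["post.b"]] <- rep(0, out_ch)
  scopes <- vapply(names(params), scope_of, character(1))
  structure(list(config = config, head = head, params = params,
                 scopes = scopes,
                 trainable = setNames(rep(TRUE, length(params)), names(params))),
            class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("unet: %s head, depth %d, base %d filters, %d parameters\n",
              x$head, x$config$depth, x$config$base_filters, n_par))
  for (s in c("encoder", "decoder", "post_processing"))
    cat(sprintf("  %-16s %d tensors (%s)\n", s, sum(x$scopes == s),
                if (all(x$trainable[x$scopes == s])) "trainable"
                else if (any(x$trainable[x$scopes == s])) "mixed" else "frozen"))
  invisible(x)
}

# one conv block: weight-standardized 3x3 conv -> GroupNorm -> ReLU
block_fwd <- function(model, prefix, x) {
  p <- model$params
  g <- model$config$groupnorm_groups
  w <- p[[paste0(prefix, ".w")]]
  ws <- standardize_kernel(w, model$config$ws_eps)
  z <- conv_fwd(x, ws)
  gn <- group_norm_fwd(z, p[[paste0(prefix, ".gn.gamma")]],
                       p[[paste0(prefix, ".gn.beta")]], g, model$config$gn_eps)
  r <- relu_fwd(gn$y)
  list(y = r$y, cache = list(x = x, ws = ws, gn = gn, relu_mask = r$mask))
}

block_bwd <- function(model, prefix, cache, dy, grads) {
  p <- model$params
  dy <- dy * cache$relu_mask
  gnb <- group_norm_bwd(cache$gn, p[[paste0(prefix, ".gn.gamma")]], dy)
  grads[[paste0(prefix, ".gn.gamma")]] <- gnb$dgamma
  grads[[paste0(prefix, ".gn.beta")]] <- gnb$dbeta
  cb <- conv_bwd(cache$x, cache$ws, gnb$dx)
  grads[[paste0(prefix, ".w")]] <-
    standardize_kernel_bwd(p[[paste0(prefix, ".w")]], cb$dw,
                           model$config$ws_eps)
  list(dx = cb$dx, grads = grads)
}

#' Forward pass through a U-Net
#'
#' @param model A `unet`.
#' @param x Input image: H x W matrix or H x W x C array (C must equal
#'   `in_channels`); H and W must be divisible by `2^(depth-1)`.
#' @param keep_cache Keep intermediate activations for [unet_backward()].
#' @return List with `out` (H x W x out_channels logits/reconstruction) and
#'   (if requested) `cache`.
#' @export
unet_forward <- function(model, x, keep_cache = FALSE) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[3] != model$config$in_channels)
    stop("input channel count does not match model config")
  D <- model$config$depth
  if (any(dim(x)[1:2] %% 2^(D - 1L) != 0))
    stop("spatial dimensions must be divisible by 2^(depth-1)")
  cache <- list(enc = vector("list", D), pool = vector("list", D - 1L),
                dec = vector("list", D - 1L), input = x)
  h <- x
  skips <- vector("list", D - 1L)
  for (d in seq_len(D)) {
    b1 <- block_fwd(model, sprintf("enc%d.conv1", d), h)
    b2 <- block_fwd(model, sprintf("enc%d.conv2", d), b1$y)
    cache$enc[[d]] <- list(b1 = b1$cache, b2 = b2$cache)
    h <- b2$y
    if (d < D) {
      skips[[d]] <- h
      mp <- .maxpool2_fwd_cpp(h)
      cache$pool[[d]] <- list(idx = mp$idx, H = dim(h)[1], W = dim(h)[2])
      h <- mp$y
    }
  }
  for (d in rev(seq_len(D - 1L))) {
    wu <- model$params[[sprintf("up%d.w", d)]]
    wus <- standardize_kernel(wu, model$config$ws_eps)
    up <- .upconv2_fwd_cpp(h, as_wmat(wus))
    cat_in <- array(0, c(dim(up)[1], dim(up)[2],
                         dim(skips[[d]])[3] + dim(up)[3]))
    cat_in[, , seq_len(dim(skips[[d]])[3])] <- skips[[d]]
    cat_in[, , dim(skips[[d]])[3] + seq_len(dim(up)[3])] <- up
    b1 <- block_fwd(model, sprintf("dec%d.conv1", d), cat_in)
    b2 <- block_fwd(model, sprintf("dec%d.conv2", d), b1$y)
    cache$dec[[d]] <- list(x_below = h, wus = wus, n_skip = dim(skips[[d]])[3],
                           b1 = b1$cache, b2 = b2$cache)
    h <- b2$y
  }
  wp <- model$params[["post.w"]]
  out <- conv_fwd(h, wp, pad = 0L)
  out <- sweep(out, 3L, model$params[["post.b"]], "+")
  cache$head_in <- h
  list(out = out, cache = if (keep_cache) cache else NULL)
}

#' Backward pass through a U-Net
#'
#' @param model A `unet`.
#' @param cache Cache from [unet_forward()] with `keep_cache = TRUE`.
#' @param dout Gradient of the loss with respect to the output.
#' @return Named list of parameter gradients.
#' @export
unet_backward <- function(model, cache, dout) {
  D <- model$config$depth
  grads <- list()
  grads[["post.b"]] <- apply(dout, 3L, sum)
  cbh <- conv_bwd(cache$head_in, model$params[["post.w"]], dout, pad = 0L)
  grads[["post.w"]] <- cbh$dw
  dh <- cbh$dx
  dskips <- vector("list", D - 1L)
  for (d in seq_len(D - 1L)) {
    dc <- cache$dec[[d]]
    b2 <- block_bwd(model, sprintf("dec%d.conv2", d), dc$b2, dh, grads)
    grads <- b2$grads
    b1 <- block_bwd(model, sprintf("dec%d.conv1", d), dc$b1, b2$dx, grads)
    grads <- b1$grads
    n_skip <- dc$n_skip
    dcat <- b1$dx
    dskips[[d]] <- dcat[, , seq_len(n_skip), drop = FALSE]
    dup <- dcat[, , n_skip + seq_len(dim(dcat)[3] - n_skip), drop = FALSE]
    ub <- .upconv2_bwd_cpp(dc$x_below, as_wmat(dc$wus), dup)
    wu <- model$params[[sprintf("up%d.w", d)]]
    dim(ub$dw) <- dim(wu)
    grads[[sprintf("up%d.w", d)]] <-
      standardize_kernel_bwd(wu, ub$dw, model$config$ws_eps)
    dh <- ub$dx
  }
  # dh currently holds the gradient flowing into the bottleneck (enc D);
  # walk the encoder from the bottom up
  for (d in rev(seq_len(D))) {
    if (d < D) {
      pool <- cache$pool[[d]]
      dh <- .maxpool2_bwd_cpp(dh, pool$idx, pool$H, pool$W)
      dh <- dh + dskips[[d]]
    }
    b2 <- block_bwd(model, sprintf("enc%d.conv2", d), cache$enc[[d]]$b2, dh, grads)
    grads <- b2$grads
    b1 <- block_bwd(model, sprintf("enc%d.conv1", d), cache$enc[[d]]$b1, b2$dx, grads)
    grads <- b1$grads
    dh <- b1$dx
  }
  grads
}

#' Predict with a U-Net
#'
#' For a segmentation model returns per-pixel class probabilities
#' (softmax over the 4 classes); for an inpainting model the
#' reconstruction.
#'
#' @param object A `unet`.
#' @param x Input image.
#' @param ... Unused.
#' @return H x W x out_channels array.
#' @export
predict.unet <- function(object, x, ...) {
  out <- unet_forward(object, x)$out
  if (object$head == "segmentation") softmax_channels(out) else out
}

#' Extract the weights of a model as a scoped bundle
#'
#' @param model A `unet`.
#' @param provenance `"random"` or `"pretrained"`.
#' @return Object of class `weight_bundle`: named tensors plus a total,
#'   disjoint scope partition (`encoder`, `decoder`, `post_processing`).
#' @export
weight_bundle <- function(model, provenance = c("random", "pretrained")) {
  provenance <- match.arg(provenance)
  structure(list(params = model$params, scopes = model$scopes,
                 provenance = provenance),
            class = "weight_bundle")
}

#' Transfer pretrained weights into a model
#'
#' Copies the source bundle's tensors into the target for the selected
#' scope(s). The post-processing layer is never transferred;
#' non-transferred scopes keep the target's own (fresh) initialization.
#'
#' @param source A [weight_bundle()].
#' @param target A `unet`.
#' @param scope `"encoder_only"` or `"encoder_and_decoder"`.
#' @return The target model with transferred weights.
#' @export
transfer_weights <- function(source, target,
                             scope = c("encoder_only", "encoder_and_decoder")) {
  scope <- match.arg(scope)
  stopifnot(inherits(source, "weight_bundle"), inherits(target, "unet"))
  wanted <- if (scope == "encoder_only") "encoder" else c("encoder", "decoder")
  for (nm in names(target$params)) {
    if (!(target$scopes[[nm]] %in% wanted)) next
    if (is.null(source$params[[nm]]))
      stop(sprintf("topology mismatch: source bundle lacks tensor '%s'", nm))
    sdim <- dim(source$params[[nm]]) %||% length(source$params[[nm]])
    tdim <- dim(target$params[[nm]]) %||% length(target$params[[nm]])
    if (!identical(sdim, tdim))
      stop(sprintf("topology mismatch at tensor '%s': source %s vs target %s",
                   nm, paste(sdim, collapse = "x"),
                   paste(tdim, collapse = "x")))
    target$params[[nm]] <- source$params[[nm]]
  }
  target
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Freeze or unfreeze parameter scopes
#'
#' Frozen tensors receive no gradient updates; a training step leaves them
#' bit-identical.
#'
#' @param model A `unet`.
#' @param scopes Character vector of scope names (`"encoder"`, `"decoder"`,
#'   `"post_processing"`) or `"all"`.
#' @param frozen `TRUE` to freeze, `FALSE` to unfreeze.
#' @return The updated model.
#' @export
set_trainable <- function(model, scopes, frozen) {
  stopifnot(inherits(model, "unet"))
  if (identical(scopes, "all")) scopes <- unique(model$scopes)
  unknown <- setdiff(scopes, unique(model$scopes))
  if (length(unknown))
    stop(sprintf("unknown scope(s): %s", paste(unknown, collapse = ", ")))
  sel <- model$scopes %in% scopes
  model$trainable[sel] <- !frozen
  model
}

#' Serialize / restore a weight bundle
#'
#' A single JSON archive: a manifest (tensor name, scope, shape,
#' provenance) plus flattened values; loading validates shapes.
#'
#' @param bundle A [weight_bundle()].
#' @param path File path.
#' @export
save_weights <- function(bundle, path) {
  stopifnot(inherits(bundle, "weight_bundle"))
  payload <- list(
    provenance = bundle$provenance,
    tensors = lapply(names(bundle$params), function(nm) {
      v <- bundle$params[[nm]]
      list(name = nm, scope = bundle$scopes[[nm]],
           shape = dim(v) %||% length(v), values = as.vector(v))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  params <- list(); scopes <- character(0)
  for (t in p$tensors) {
    shape <- as.integer(unlist(t$shape))
    v <- as.numeric(unlist(t$values))
    if (length(v) != prod(shape))
      stop(sprintf("corrupt weight archive: tensor '%s' has %d values for shape %s",
                   t$name, length(v), paste(shape, collapse = "x")))
    params[[t$name]] <- if (length(shape) > 1L) array(v, shape) else v
    scopes[[t$name]] <- t$scope
  }
  structure(list(params = params, scopes = scopes,
                 provenance = p$provenance), class = "weight_bundle")
}
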