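#' Network configuration
#'
#' Complete hyper-parameter record from which a segmentation model (and
#' its exact trainable-parameter count) is a pure function.  The shipped
#' defaults are the calibrated CMM-Net configuration: four encoder
#' levels of widths 32/96/256/512 (two 3x3 convolutions each, batch
#' normalization + ReLU), a pyramid pooling module after each of the
#' first three levels, dilation rates 6/5/4/3 down the encoder and 4/5/6
#' up the decoder, and a softmax head over two classes.
#'
#' @param input_height,input_width Spatial input size; both must be
#'   divisible by `2^(levels - 1)`.
#' @param input_channels Input channel count (3 for RGB / stacked MR).
#' @param num_classes Number of output classes (`>= 2`; class 2 is the
#'   foreground throughout this package).
#' @param levels Number of encoder levels (4).
#' @param encoder_channels Per-level channel widths, length `levels`.
#' @param ppm_bottleneck_channels Channels per pyramid branch (64 for the
#'   dermoscopy/MR configurations, 128 for the retinal-patch one).
#' @param ppm_max_scale Largest pyramid pooling output side (64
#'   dermoscopy, 48 MR, 32 fundus).  Ignored when `ppm_pooled_sizes` is
#'   given.
#' @param ppm_pooled_sizes Optional explicit strictly-decreasing pyramid
#'   sizes; default `c(max, max %/% 3, 4, 1)` (requires
#'   `ppm_max_scale >= 16`).  At build time each level's pyramid is
#'   clipped to that level's spatial side.
#' @param encoder_dilation_rates Length-`levels` dilation rates, shallow
#'   to deep.
#' @param decoder_dilation_rates Length-`levels - 1` rates, deep to
#'   shallow.
#' @param use_ppm_per_level `TRUE` for CMM-Net, `FALSE` for the plain
#'   U-Net baseline.
#' @return An object of class `network_config`.
#' @examples
#' cfg <- network_config()          # dermoscopy-sized CMM-Net
#' @export
network_config <- function(input_height = 192L, input_width = 256L,
                           input_channels = 3L, num_classes = 2L,
                           levels = 4L,
                           encoder_channels = c(32L, 96L, 256L, 512L),
                           ppm_bottleneck_channels = 64L,
                           ppm_max_scale = 64L,
                           ppm_pooled_sizes = NULL,
                           encoder_dilation_rates = c(6L, 5L, 4L, 3L),
                           decoder_dilation_rates = c(4L, 5L, 6L),
                           use_ppm_per_level = TRUE) {
  f <- 2^(levels - 1)
  if (input_height %% f != 0 || input_width %% f != 0)
    stop("input dims must be divisible by 2^(levels - 1) = ", f)
  if (num_classes < 2) stop("num_classes must be >= 2")
  if (length(encoder_channels) != levels)
    stop("encoder_channels must have one width per level")
  if (length(encoder_dilation_rates) != levels)
    stop("encoder_dilation_rates must have length ", levels)
  if (length(decoder_dilation_rates) != levels - 1)
    stop("decoder_dilation_rates must have length ", levels - 1)
  if (is.null(ppm_pooled_sizes)) {
    if (ppm_max_scale < 16)
      stop("default pyramid rule needs ppm_max_scale >= 16; ",
           "give ppm_pooled_sizes explicitly for smaller scales")
    ppm_pooled_sizes <- c(ppm_max_scale, ppm_max_scale %/% 3, 4L, 1L)
  }
  if (any(ppm_pooled_sizes < 1) || any(diff(ppm_pooled_sizes) >= 0))
    stop("ppm_pooled_sizes must be strictly decreasing positive integers")
  structure(list(input_height = as.integer(input_height),
                 input_width = as.integer(input_width),
                 input_channels = as.integer(input_channels),
                 num_classes = as.integer(num_classes),
                 levels = as.integer(levels),
                 encoder_channels = as.integer(encoder_channels),
                 ppm_bottleneck_channels = as.integer(ppm_bottleneck_channels),
                 ppm_max_scale = as.integer(ppm_max_scale),
                 ppm_pooled_sizes = as.integer(ppm_pooled_sizes),
                 encoder_dilation_rates = as.integer(encoder_dilation_rates),
                 decoder_dilation_rates = as.integer(decoder_dilation_rates),
                 use_ppm_per_level = isTRUE(use_ppm_per_level)),
            class = "network_config")
}

# Pyramid sizes actually used at encoder level l (1-based): clipped to the
# level's spatial side so adaptive pooling never upsamples.
level_ppm_sizes <- function(config, level) {
  side <- min(config$input_height, config$input_width) %/% 2^(level - 1)
  pmax(pmin(config$ppm_pooled_sizes, side), 1L)
}

#' Build a CMM-Net segmentation model
#'
#' Assembles the full network: a four-level contracting path (eight 3x3
#' convolutions, three 2x2 max poolings) with a pyramid pooling module
#' concatenated after each of the first three levels, and an expanding
#' path (three 2x bilinear upsamplings, six 3x3 convolutions plus a
#' final 3x3 convolution feeding a per-pixel softmax).  Every interior
#' convolution is followed by batch normalization and ReLU; the skip
#' connection at each level carries the PPM-augmented features.
#'
#' @param config A [network_config()].
#' @param seed Integer seed for the He-normal weight initialization.
#' @return An object of class `cmm_model`.
#' @examples
#' m <- build_cmm_net(network_config(input_height = 64, input_width = 64,
#'                                   encoder_channels = c(8, 16, 32, 64),
#'                                   ppm_bottleneck_channels = 8,
#'                                   ppm_pooled_sizes = c(8, 4, 2, 1)))
#' count_parameters(m)
#' @export
build_cmm_net <- function(config = network_config(), seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  with_seed(seed, build_net_impl(config))
}

#' Build the plain U-Net baseline
#'
#' Same contracting/expanding skeleton as [build_cmm_net()] but without
#' pyramid pooling modules and with all dilation rates equal to 1; used
#' for ablation-style comparisons.
#'
#' @inheritParams build_cmm_net
#' @return An object of class `cmm_model` with `type = "unet"`.
#' @export
build_unet_baseline <- function(config = network_config(), seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  config$use_ppm_per_level <- FALSE
  config$encoder_dilation_rates <- rep(1L, config$levels)
  config$decoder_dilation_rates <- rep(1L, config$levels - 1)
  with_seed(seed, build_net_impl(config))
}

build_net_impl <- function(config) {
  K <- config$levels
  ch <- config$encoder_channels
  b <- config$ppm_bottleneck_channels
  nb <- length(config$ppm_pooled_sizes)
  use_ppm <- config$use_ppm_per_level
  er <- config$encoder_dilation_rates
  dr <- config$decoder_dilation_rates

  layers <- list()
  ppm_sizes <- list()
  inn <- config$input_channels
  for (l in seq_len(K)) {
    layers[[paste0("enc", l, "a")]] <-
      init_conv_layer(3L, 3L, inn, ch[l], rate = er[l])
    layers[[paste0("enc", l, "b")]] <-
      init_conv_layer(3L, 3L, ch[l], ch[l], rate = er[l])
    if (use_ppm && l < K) {
      for (i in seq_len(nb))
        layers[[paste0("ppm", l, "_", i)]] <-
          init_conv_layer(1L, 1L, ch[l], b, bias = FALSE)
      ppm_sizes[[l]] <- level_ppm_sizes(config, l)
      inn <- ch[l] + nb * b
    } else {
      inn <- ch[l]
    }
  }
  skip_ch <- if (use_ppm) ch[seq_len(K - 1)] + nb * b else ch[seq_len(K - 1)]
  for (l in rev(seq_len(K - 1))) {
    r <- dr[K - l]                    # deep -> shallow ordering
    layers[[paste0("dec", l, "up")]] <-
      init_conv_layer(3L, 3L, if (l == K - 1) ch[K] else ch[l + 1], ch[l],
                      rate = r)
    layers[[paste0("dec", l, "mix")]] <-
      init_conv_layer(3L, 3L, ch[l] + skip_ch[l], ch[l], rate = r)
  }
  layers[["final"]] <- init_conv_layer(3L, 3L, ch[1], config$num_classes,
                                       bias = TRUE, bn = FALSE, act = "none")
  structure(list(config = config,
                 type = if (use_ppm) "cmm" else "unet",
                 layers = layers, ppm_sizes = ppm_sizes),
            class = "cmm_model")
}

#' Count trainable parameters
#'
#' Total number of trainable scalars in a model: convolution weights and
#' biases plus batch-norm scale/shift pairs (running statistics are not
#' trainable and are excluded).  The count is a pure function of the
#' configuration and is independent of input size, dilation rates and
#' pyramid pooled sizes.
#'
#' @param model A `cmm_model`.
#' @return A non-negative integer (returned as double to avoid overflow).
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "cmm_model"))
  sum(vapply(model$layers, layer_n_params, numeric(1)))
}

#' @export
print.cmm_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<%s segmentation model>\n",
              if (x$type == "cmm") "CMM-Net" else "U-Net baseline"))
  cat(sprintf("  input: %d x %d x %d, %d classes\n", cfg$input_height,
              cfg$input_width, cfg$input_channels, cfg$num_classes))
  cat(sprintf("  encoder widths: %s\n",
              paste(cfg$encoder_channels, collapse = "/")))
  if (x$type == "cmm")
    cat(sprintf("  PPM: bottleneck %d, pyramid %s\n",
                cfg$ppm_bottleneck_channels,
                paste(cfg$ppm_pooled_sizes, collapse = "/")))
  cat(sprintf("  dilation rates: encoder %s, decoder %s\n",
              paste(cfg$encoder_dilation_rates, collapse = "/"),
              paste(cfg$decoder_dilation_rates, collapse = "/")))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# Full forward pass.  Returns per-pixel class probabilities plus (when
# keep_caches) everything backward needs, and the model with refreshed
# batch-norm running statistics.
net_forward <- function(model, x, training = FALSE, keep_caches = training) {
  K <- model$config$levels
  use_ppm <- model$config$use_ppm_per_level
  nb <- length(model$config$ppm_pooled_sizes)
  L <- model$layers
  caches <- list()
  skips <- list()
  h <- x
  for (l in seq_len(K)) {
    if (l > 1) {
      mp <- cpp_maxpool2_fwd(h)
      caches[[paste0("pool", l)]] <- list(idx = mp$idx, xdim = dim(h))
      h <- mp$y
    }
    for (s in c("a", "b")) {
      key <- paste0("enc", l, s)
      bf <- block_fwd(L[[key]], h, training)
      L[[key]] <- bf$layer
      if (keep_caches) caches[[key]] <- bf$cache
      h <- bf$y
    }
    if (use_ppm && l < K) {
      bkeys <- paste0("ppm", l, "_", seq_len(nb))
      pf <- ppm_layer_fwd(list(branches = L[bkeys],
                               sizes = model$ppm_sizes[[l]]), h, training)
      L[bkeys] <- pf$branches
      if (keep_caches) caches[[paste0("ppm", l)]] <- pf$cache
      h <- pf$y
    }
    if (l < K) skips[[l]] <- h
  }
  for (l in rev(seq_len(K - 1))) {
    sd <- dim(skips[[l]])
    caches[[paste0("up", l)]] <- dim(h)
    h <- cpp_bilinear_fwd(h, sd[1], sd[2])
    key <- paste0("dec", l, "up")
    bf <- block_fwd(L[[key]], h, training)
    L[[key]] <- bf$layer
    if (keep_caches) caches[[key]] <- bf$cache
    caches[[paste0("cat", l)]] <- c(dim(bf$y)[3], sd[3])
    h <- chan_cat(bf$y, skips[[l]])
    key <- paste0("dec", l, "mix")
    bf <- block_fwd(L[[key]], h, training)
    L[[key]] <- bf$layer
    if (keep_caches) caches[[key]] <- bf$cache
    h <- bf$y
  }
  bf <- block_fwd(L[["final"]], h, training)
  L[["final"]] <- bf$layer
  if (keep_caches) caches[["final"]] <- bf$cache
  probs <- softmax_fwd(bf$y)
  model$layers <- L
  list(probs = probs, logits = bf$y, caches = if (keep_caches) caches,
       model = model)
}

# Backward pass from d(loss)/d(logits).  Returns gradients keyed like
# model$layers (each a list with W/b/gamma/beta entries).
net_backward <- function(model, caches, dlogits) {
  K <- model$config$levels
  use_ppm <- model$config$use_ppm_per_level
  nb <- length(model$config$ppm_pooled_sizes)
  L <- model$layers
  grads <- list()

  bb <- block_bwd(L[["final"]], caches[["final"]], dlogits)
  grads[["final"]] <- bb$grads
  dh <- bb$dx
  dskips <- vector("list", K - 1)
  for (l in seq_len(K - 1)) {
    key <- paste0("dec", l, "mix")
    bb <- block_bwd(L[[key]], caches[[key]], dh)
    grads[[key]] <- bb$grads
    split <- caches[[paste0("cat", l)]]
    ddec <- bb$dx[, , seq_len(split[1]), , drop = FALSE]
    dskips[[l]] <- bb$dx[, , split[1] + seq_len(split[2]), , drop = FALSE]
    key <- paste0("dec", l, "up")
    bb <- block_bwd(L[[key]], caches[[key]], ddec)
    grads[[key]] <- bb$grads
    hd <- caches[[paste0("up", l)]]
    dh <- cpp_bilinear_bwd(bb$dx, hd[1], hd[2])
  }
  for (l in rev(seq_len(K))) {
    if (l < K) dh <- dh + dskips[[l]]
    if (use_ppm && l < K) {
      bkeys <- paste0("ppm", l, "_", seq_len(nb))
      pb <- ppm_layer_bwd(list(branches = L[bkeys],
                               sizes = model$ppm_sizes[[l]]),
                          caches[[paste0("ppm", l)]], dh)
      for (i in seq_len(nb)) grads[[bkeys[i]]] <- pb$grads[[i]]
      dh <- pb$dx
    }
    for (s in c("b", "a")) {
      key <- paste0("enc", l, s)
      bb <- block_bwd(L[[key]], caches[[key]], dh)
      grads[[key]] <- bb$grads
      dh <- bb$dx
    }
    if (l > 1) {
      pc <- caches[[paste0("pool", l)]]
      dh <- cpp_maxpool2_bwd(pc$idx, dh, pc$xdim)
    }
  }
  grads
}

#' Predict a segmentation from a fitted model
#'
#' @param object A `cmm_model`.
#' @param image `(H, W, C)` array (or `(H, W)` for single-channel
#'   models) with values in `[0, 1]`; spatial dims must be divisible by
#'   `2^(levels - 1)`.
#' @param type `"prob"` for the per-pixel class-probability map
#'   (`H x W x num_classes`, summing to 1 per pixel) or `"mask"` for the
#'   binary foreground map.
#' @param threshold Foreground-probability threshold for `type = "mask"`.
#' @param ... Unused.
#' @return Probability array or 0/1 matrix.
#' @export
predict.cmm_model <- function(object, image, type = c("prob", "mask"),
                              threshold = 0.5, ...) {
  type <- match.arg(type)
  xt <- as_tensor(image)
  d <- dim(xt)
  f <- 2^(object$config$levels - 1)
  if (d[1] %% f != 0 || d[2] %% f != 0)
    stop("image dims must be divisible by ", f)
  if (d[3] != object$config$input_channels)
    stop("image has ", d[3], " channels; model expects ",
         object$config$input_channels)
  probs <- net_forward(object, xt, training = FALSE, keep_caches = FALSE)$probs
  probs <- drop_tensor(probs, 3L)
  if (type == "prob") return(probs)
  (probs[, , 2L] >= threshold) * 1
}

#' Save / load model checkpoints
#'
#' Checkpoints are written with R's native serialization ([saveRDS()]),
#' carrying the configuration, all weights and batch-norm statistics.
#'
#' @param model A `cmm_model`.
#' @param path File path (conventionally `.rds`).
#' @return `load_checkpoint` returns the restored `cmm_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "cmm_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cmm_model")) stop("not a cmm_model checkpoint: ", path)
  model
}
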