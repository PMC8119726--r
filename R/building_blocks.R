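#' Receptive-field side length of stacked dilated 3x3 convolutions
#'
#' Dilated (atrous) convolutions enlarge the receptive field without
#' adding parameters.  Stacking 3x3 convolutions with doubling dilation
#' rates ending at rate `r` yields a square receptive field whose side
#' grows exponentially as \eqn{2^{r+1} - 1}; at `r = 1` this reduces to
#' the ordinary 3x3 case.
#'
#' @param r Integer dilation rate(s), `r >= 1`.
#' @return The side length \eqn{2^{r+1} - 1} (an odd positive integer);
#'   the receptive field covers that many pixels squared.
#' @examples
#' receptive_field_side(1)  # 3, the plain 3x3 convolution
#' receptive_field_side(2)  # 7
#' @export
receptive_field_side <- function(r) {
  if (!is.numeric(r) || any(r < 1) || any(r != round(r)))
    stop("dilation rate 'r' must be an integer >= 1")
  as.integer(2^(r + 1) - 1)
}

#' Specification of a dilated convolution layer
#'
#' @param in_channels,out_channels Positive integer channel counts.
#' @param kernel_size Positive odd kernel side (3 throughout the
#'   networks shipped here).
#' @param dilation_rate Integer dilation rate `r >= 1`; `r = 1` is a
#'   standard convolution.
#' @param with_batchnorm Append batch normalization?
#' @param activation `"relu"` or `"none"`.
#' @return An object of class `dilated_conv_spec`.
#' @export
dilated_conv_spec <- function(in_channels, out_channels, kernel_size = 3L,
                              dilation_rate = 1L, with_batchnorm = TRUE,
                              activation = c("relu", "none")) {
  activation <- match.arg(activation)
  if (in_channels < 1 || out_channels < 1)
    stop("channel counts must be positive")
  if (kernel_size < 1 || kernel_size %% 2 == 0)
    stop("kernel_size must be a positive odd integer")
  if (dilation_rate < 1 || dilation_rate != round(dilation_rate))
    stop("dilation_rate must be an integer >= 1")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel_size = as.integer(kernel_size),
                 dilation_rate = as.integer(dilation_rate),
                 with_batchnorm = isTRUE(with_batchnorm),
                 activation = activation),
            class = "dilated_conv_spec")
}

#' Dilated discrete convolution
#'
#' Computes the discrete convolution of `x` with `kernel` where the
#' kernel taps are spaced `rate - 1` zeros apart,
#' \deqn{(f *_r w)[x] = \sum_k f[k]\, w[r(x - k)],}
#' with zero padding sized so the output keeps the input's spatial
#' dimensions.  At `rate = 1` this is the ordinary discrete convolution.
#' Note the kernel is flipped, as in the mathematical definition; deep
#' learning "convolutions" (cross-correlations) are obtained by
#' pre-flipping the kernel.
#'
#' @param x Input signal: a numeric vector (1-D), a matrix `(H, W)`, or
#'   an `(H, W, C)` array.
#' @param kernel Numeric vector (1-D), odd-sided matrix, or
#'   `(kh, kw, Cin, Cout)` array matching the input channel count.
#' @param rate Dilation rate, integer `>= 1`.
#' @param bias Optional numeric vector of length `Cout` added per output
#'   channel.
#' @return Output of the same spatial size as `x`, with `Cout` channels
#'   for multi-channel kernels.
#' @export
dilated_convolve <- function(x, kernel, rate = 1L, bias = NULL) {
  if (rate < 1 || rate != round(rate))
    stop("dilation rate must be an integer >= 1")
  vec_in <- is.null(dim(x))
  if (vec_in) {
    if (!is.null(dim(kernel))) stop("1-D input requires a 1-D kernel")
    if (length(kernel) %% 2 == 0) stop("kernel length must be odd")
    x <- matrix(x, nrow = 1)
    kernel <- array(kernel, c(1, length(kernel), 1, 1))
  } else if (is.matrix(kernel)) {
    kernel <- array(kernel, c(dim(kernel), 1, 1))
  }
  if (length(dim(kernel)) != 4L)
    stop("kernel must be a vector, matrix, or (kh, kw, Cin, Cout) array")
  kd <- dim(kernel)
  if (kd[1] %% 2 == 0 || kd[2] %% 2 == 0) stop("kernel dims must be odd")
  xt <- as_tensor(x)
  if (dim(xt)[3] != kd[3])
    stop("input has ", dim(xt)[3], " channels but kernel expects ", kd[3])
  flipped <- kernel[rev(seq_len(kd[1])), rev(seq_len(kd[2])), , , drop = FALSE]
  dim(flipped) <- kd
  y <- cpp_conv2d_fwd(xt, flipped, bias, as.integer(rate))
  if (vec_in) return(as.numeric(y))
  if (kd[4] == 1L && length(dim(x)) == 2L) return(drop_tensor(y, 2L))
  drop_tensor(y, 3L)
}

#' Specification of a pyramid pooling module (PPM)
#'
#' A PPM pools its input feature map to several pyramid scales in
#' parallel, bottlenecks each pooled map with a 1x1 convolution (batch
#' normalization, no bias, ReLU), bilinearly upsamples each back to the
#' input size, and concatenates everything with the original features.
#' With `N` pyramid levels the default bottleneck width is `C / N`, so
#' the concatenated output has `C + N * (C / N) = 2C` channels.
#'
#' @param in_channels Input channel count `C`.
#' @param pooled_sizes Strictly decreasing positive integers, one per
#'   pyramid level (largest scale first; the canonical configuration
#'   ends at 1, i.e. global average pooling).
#' @param bottleneck_channels Channels per pyramid level after the 1x1
#'   bottleneck; defaults to `C / N`.
#' @param pooling Pooling operator; only `"average"` is supported.
#' @return An object of class `ppm_spec`.
#' @examples
#' ppm_spec(256, c(64, 21, 4, 1))  # bottleneck 64, output 512 channels
#' @export
ppm_spec <- function(in_channels, pooled_sizes = c(64L, 21L, 4L, 1L),
                     bottleneck_channels = NULL, pooling = "average") {
  pooling <- match.arg(pooling, "average")
  if (in_channels < 1) stop("in_channels must be positive")
  if (any(pooled_sizes < 1) || any(diff(pooled_sizes) >= 0))
    stop("pooled_sizes must be strictly decreasing positive integers")
  n <- length(pooled_sizes)
  if (is.null(bottleneck_channels)) bottleneck_channels <- in_channels %/% n
  if (bottleneck_channels < 1) stop("bottleneck_channels must be positive")
  structure(list(in_channels = as.integer(in_channels),
                 pooled_sizes = as.integer(pooled_sizes),
                 bottleneck_channels = as.integer(bottleneck_channels),
                 pooling = pooling),
            class = "ppm_spec")
}

#' Initialize weights for a pyramid pooling module
#'
#' @param spec A [ppm_spec()].
#' @param seed Integer seed for the He-normal 1x1 kernel draws.
#' @return A list with one `(1, 1, C, bottleneck)` kernel and batch-norm
#'   parameters per pyramid level.
#' @export
ppm_init <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "ppm_spec"))
  with_seed(seed, lapply(spec$pooled_sizes, function(s) {
    init_conv_layer(1L, 1L, spec$in_channels, spec$bottleneck_channels,
                    bias = FALSE, bn = TRUE, rate = 1L, act = "relu")
  }))
}

#' Forward pass of a pyramid pooling module
#'
#' @param x Feature map `(H, W, C)` or `(H, W, C, N)` with
#'   `C = spec$in_channels` and `min(H, W) >= max(pooled_sizes)`.
#' @param spec A [ppm_spec()].
#' @param weights Branch weights from [ppm_init()]; freshly initialized
#'   (seed 1) when omitted.
#' @param training Use batch statistics (`TRUE`) or running statistics
#'   (`FALSE`) in the branch batch normalization.
#' @return The concatenation of `x` with all upsampled pyramid branches:
#'   `C + N * bottleneck_channels` output channels, same spatial size.
#' @export
ppm_forward <- function(x, spec, weights = NULL, training = FALSE) {
  stopifnot(inherits(spec, "ppm_spec"))
  xt <- as_tensor(x)
  d <- dim(xt)
  if (d[3] != spec$in_channels)
    stop("input has ", d[3], " channels but spec expects ", spec$in_channels)
  if (min(d[1], d[2]) < max(spec$pooled_sizes))
    stop("pooled size ", max(spec$pooled_sizes),
         " exceeds input spatial side ", min(d[1], d[2]))
  if (is.null(weights)) weights <- ppm_init(spec)
  out <- ppm_layer_fwd(list(branches = weights, sizes = spec$pooled_sizes),
                       xt, training = training)$y
  if (length(dim(x)) < 4L) out <- drop_tensor(out, max(3L, length(dim(x))))
  out
}
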