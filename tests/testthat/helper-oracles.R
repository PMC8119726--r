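# Independent brute-force oracles used across the suite.  These are
# deliberately naive (explicit loops) so they cannot share bugs with
# the vectorized implementations they check.

# Direct double-loop evaluation of the dilated-convolution sum
# y[x] = sum_k f[k] w[r(x - k)] with zero padding, 2-D single channel.
oracle_dilated_conv <- function(x, k, r) {
  H <- nrow(x); W <- ncol(x)
  kh <- nrow(k); kw <- ncol(k)
  ch <- (kh - 1) / 2; cw <- (kw - 1) / 2
  y <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    s <- 0
    for (u in 1:kh) for (v in 1:kw) {
      ii <- i - r * (u - 1 - ch)
      jj <- j - r * (v - 1 - cw)
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        s <- s + x[ii, jj] * k[u, v]
    }
    y[i, j] <- s
  }
  y
}

# Per-pixel max / min over a list of masks.
oracle_pixel_max <- function(masks) {
  out <- masks[[1]]
  for (i in seq_along(out))
    out[i] <- max(vapply(masks, function(m) m[i], numeric(1)))
  out
}

oracle_pixel_min <- function(masks) {
  out <- masks[[1]]
  for (i in seq_along(out))
    out[i] <- min(vapply(masks, function(m) m[i], numeric(1)))
  out
}

# AUC as the pairwise ranking (Mann-Whitney) statistic.
oracle_auc_pairwise <- function(prob, gt) {
  pos <- prob[gt == 1]
  neg <- prob[gt == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Number of 8-connected foreground components (flood fill).
oracle_n_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  H <- nrow(mask); W <- ncol(mask)
  comp <- 0L
  for (i0 in 1:H) for (j0 in 1:W) {
    if (mask[i0, j0] == 0 || lab[i0, j0] != 0) next
    comp <- comp + 1L
    stack <- list(c(i0, j0))
    lab[i0, j0] <- comp
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        i <- p[1] + di; j <- p[2] + dj
        if (i >= 1 && i <= H && j >= 1 && j <= W &&
            mask[i, j] == 1 && lab[i, j] == 0) {
          lab[i, j] <- comp
          stack[[length(stack) + 1L]] <- c(i, j)
        }
      }
    }
  }
  comp
}

# A small asymmetric array (no nontrivial symmetry), for group tests.
asym_array <- function(h = 5, w = 7) {
  matrix(seq_len(h * w) + sin(seq_len(h * w)), h, w)
}

# Tiny network configuration used by gradient / shape tests.
tiny_config <- function(...) {
  defaults <- list(input_height = 16L, input_width = 16L,
                   input_channels = 2L,
                   encoder_channels = c(3L, 4L, 5L, 6L),
                   ppm_bottleneck_channels = 2L, ppm_max_scale = 16L,
                   ppm_pooled_sizes = c(3L, 1L))
  do.call(network_config, utils::modifyList(defaults, list(...)))
}

mask_dsc <- function(pred, gt) {
  unname(scalar_metrics(contingency(pred, gt))["DSC"])
}
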