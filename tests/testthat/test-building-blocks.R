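test_that("receptive-field law matches direct evaluation and is odd/increasing", {
  expect_identical(receptive_field_side(1), 3L)
  expect_identical(receptive_field_side(2), 7L)
  expect_identical(receptive_field_side(3), 15L)
  sides <- receptive_field_side(1:6)
  expect_identical(sides, as.integer(2^(2:7) - 1))
  expect_true(all(sides %% 2 == 1))
  expect_true(all(diff(sides) > 0))
  expect_error(receptive_field_side(0), "rate")
})

test_that("dilated convolution matches the explicit-loop evaluation", {
  set.seed(11)
  for (r in 1:3) {
    for (side in c(5, 9)) {
      x <- matrix(rnorm(side^2), side, side)
      k <- matrix(rnorm(9), 3, 3)
      expect_lt(max(abs(dilated_convolve(x, k, rate = r) -
                          oracle_dilated_conv(x, k, r))), 1e-6)
    }
  }
})

test_that("rate 1 reduces to standard convolution and respects linearity", {
  set.seed(12)
  x <- matrix(rnorm(49), 7, 7)
  k <- matrix(rnorm(25), 5, 5)
  expect_equal(dilated_convolve(x, k, rate = 1), oracle_dilated_conv(x, k, 1))
  # 1-D reduction
  expect_equal(dilated_convolve(c(0, 0, 1, 0, 0), c(1, 2, 3), rate = 1),
               c(0, 1, 2, 3, 0))
  # zero input -> zero output
  expect_equal(dilated_convolve(matrix(0, 6, 6), k, rate = 2),
               matrix(0, 6, 6))
})

test_that("impulse response spreads the kernel with rate-spaced taps", {
  k <- matrix(1:9, 3, 3)
  for (r in 1:3) {
    x <- matrix(0, 11, 11)
    x[6, 6] <- 1
    y <- dilated_convolve(x, k, rate = r)
    nz <- which(y != 0, arr.ind = TRUE)
    expect_true(all((nz[, 1] - 6) %% r == 0))
    expect_true(all(abs(nz - 6) <= r))
    # taps carry the (unflipped) kernel values under true convolution
    expect_equal(y[6 + r, 6 + r], k[3, 3])
    expect_equal(y[6 - r, 6 - r], k[1, 1])
  }
})

test_that("dilated convolution validates its inputs", {
  x <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  k <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
  expect_error(dilated_convolve(x, k), "channels")
  expect_error(dilated_convolve(matrix(0, 4, 4), matrix(0, 2, 2)), "odd")
  expect_error(dilated_convolve(matrix(0, 4, 4), matrix(0, 3, 3), rate = 0),
               "rate")
})

test_that("PPM channel arithmetic: bottleneck C/N and output C + N*b", {
  grid <- list(c(C = 256, b = NA), c(C = 64, b = NA), c(C = 32, b = 8))
  for (g in grid) {
    spec <- if (is.na(g["b"])) ppm_spec(g[["C"]], c(8, 4, 2, 1))
            else ppm_spec(g[["C"]], c(8, 4, 2, 1),
                          bottleneck_channels = g[["b"]])
    b_exp <- if (is.na(g["b"])) g[["C"]] / 4 else g[["b"]]
    expect_equal(spec$bottleneck_channels, b_exp)
    x <- array(runif(16 * 16 * g[["C"]]), c(16, 16, g[["C"]]))
    y <- ppm_forward(x, spec, ppm_init(spec, seed = 5))
    expect_equal(dim(y), c(16, 16, g[["C"]] + 4 * b_exp))
  }
})

test_that("PPM preserves constants and its 1x1 level is global averaging", {
  C <- 3
  spec1 <- ppm_spec(C, pooled_sizes = 1L, bottleneck_channels = C)
  w <- ppm_init(spec1, seed = 1)
  w[[1]]$W <- array(0, c(1, 1, C, C))
  for (c in seq_len(C)) w[[1]]$W[1, 1, c, c] <- 1
  set.seed(3)
  x <- array(runif(12 * 10 * C), c(12, 10, C))
  y <- ppm_forward(x, spec1, w)
  means <- apply(x, 3, mean)
  for (c in seq_len(C))
    expect_equal(mean(abs(y[, , C + c] - means[c])), 0, tolerance = 1e-4)
  # constant input: every branch is that constant (identity bottleneck)
  xc <- array(0.4, c(8, 8, C))
  spec <- ppm_spec(C, c(4, 2, 1), bottleneck_channels = C)
  w <- ppm_init(spec, seed = 1)
  for (i in seq_along(w)) {
    w[[i]]$W <- array(0, c(1, 1, C, C))
    for (c in seq_len(C)) w[[i]]$W[1, 1, c, c] <- 1
  }
  yc <- ppm_forward(xc, spec, w)
  expect_equal(max(abs(yc - 0.4)), 0, tolerance = 1e-4)
})

test_that("degenerate single-level PPM with identity kernel returns its input", {
  C <- 2
  spec <- ppm_spec(C, pooled_sizes = 9L, bottleneck_channels = C)
  w <- ppm_init(spec, seed = 1)
  w[[1]]$W <- array(0, c(1, 1, C, C))
  for (c in seq_len(C)) w[[1]]$W[1, 1, c, c] <- 1
  x <- array(runif(9 * 9 * C), c(9, 9, C))
  y <- ppm_forward(x, spec, w)
  expect_equal(y[, , C + seq_len(C)], x, tolerance = 1e-4)
})

test_that("PPM rejects pooled sizes exceeding the input side", {
  spec <- ppm_spec(4, c(16, 4, 2, 1))
  x <- array(runif(8 * 8 * 4), c(8, 8, 4))
  expect_error(ppm_forward(x, spec), "exceeds")
  expect_error(ppm_spec(8, c(4, 4, 1)), "strictly decreasing")
})
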