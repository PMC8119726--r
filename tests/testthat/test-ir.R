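rand_masks <- function(n, h = 7, w = 9, p = 0.4, seed = 50) {
  set.seed(seed)
  lapply(seq_len(n), function(i) matrix((runif(h * w) < p) * 1, h, w))
}

test_that("OR merge equals the per-pixel max oracle and its algebra holds", {
  ms <- rand_masks(4)
  merged <- ir_or_merge(ms[[1]], ms[-1])
  expect_identical(merged, oracle_pixel_max(ms))
  # identity / absorbing cases
  empty <- ms[[1]] * 0
  full <- empty + 1
  expect_identical(ir_or_merge(ms[[1]], list(empty, empty)), ms[[1]])
  expect_identical(ir_or_merge(empty, list(full)), full)
  # commutative, associative, idempotent; superset of every input
  expect_identical(ir_or_merge(ms[[2]], ms[c(3, 1, 4)]), merged)
  expect_identical(ir_or_merge(merged, ms), merged)
  for (m in ms) expect_true(all(merged >= m))
  expect_error(ir_or_merge(ms[[1]], list(matrix(0, 2, 2))), "shape")
})

test_that("AND merge equals the per-pixel min oracle and its algebra holds", {
  ms <- rand_masks(3, seed = 51)
  merged <- ir_and_merge(ms)
  expect_identical(merged, oracle_pixel_min(ms))
  expect_identical(ir_and_merge(ms[1]), ms[[1]])            # single mask
  empty <- ms[[1]] * 0
  expect_identical(ir_and_merge(list(ms[[1]], empty)), empty)
  for (m in ms) expect_true(all(merged <= m))               # subset law
  expect_error(ir_and_merge(list()), "non-empty")
})

test_that("IR with an equivariant predictor recovers the single-view mask", {
  # thresholding channel 1 commutes with every group element, so all
  # eight recovered views agree and the OR merge is exactly one view
  set.seed(52)
  fixed <- matrix(0, 16, 16); fixed[4:9, 6:14] <- 1
  img <- array(0, c(16, 16, 3))
  img[, , 1] <- fixed * 0.9 + 0.05
  stub <- function(image) image[, , 1]
  expect_identical(run_ir(stub, img), fixed)
  # empty predictor stays empty; identity-only IR is plain prediction
  expect_identical(run_ir(function(i) i[, , 1] * 0, img), fixed * 0)
  expect_identical(run_ir(stub, img, transforms = list(geom_transform())),
                   (stub(img) >= 0.5) * 1)
})

test_that("IR never shrinks the foreground of the plain prediction", {
  m <- build_cmm_net(tiny_config(input_channels = 3L), seed = 6)
  set.seed(53)
  for (rep in 1:3) {
    img <- array(runif(16 * 16 * 3), c(16, 16, 3))
    plain <- predict(m, img, type = "mask")
    ir <- run_ir(m, img)
    expect_true(all(ir >= plain))
  }
})

test_that("AND across color spaces is a subset of each space's OR merge", {
  m <- build_cmm_net(tiny_config(input_channels = 3L), seed = 9)
  set.seed(54)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  spaces <- c("RGB", "LAB", "SV")
  per_space <- lapply(spaces, function(s)
    run_ir(m, color_variants(img)[[s]]))
  combined <- run_ir(m, img, color_spaces = spaces)
  for (ps in per_space) expect_true(all(combined <= ps))
})
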