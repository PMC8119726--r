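test_that("parameter count is invariant to input size, rates and pyramid", {
  base <- tiny_config()
  n0 <- count_parameters(build_cmm_net(base))
  variants <- list(
    tiny_config(input_height = 32L, input_width = 24L),
    tiny_config(encoder_dilation_rates = c(1L, 1L, 1L, 1L),
                decoder_dilation_rates = c(1L, 1L, 1L)),
    tiny_config(ppm_pooled_sizes = c(4L, 2L, 1L)))
  counts <- vapply(variants, function(cfg)
    count_parameters(build_cmm_net(cfg)), numeric(1))
  # pyramid level count changes channels, so only first two must match
  expect_equal(counts[1], n0)
  expect_equal(counts[2], n0)
  expect_false(counts[3] == n0)  # fewer levels -> fewer concat channels
})

test_that("baseline U-Net is smaller than CMM-Net and near the 7.3 M mark", {
  cfg <- network_config()
  cmm <- count_parameters(build_cmm_net(cfg))
  unet <- count_parameters(build_unet_baseline(cfg))
  expect_lt(unet, cmm)
  expect_lt(abs(unet / 1e6 - 7.3), 0.05)   # soft check on the baseline
})

test_that("forward pass obeys the shape law and softmax normalization", {
  cfg <- tiny_config()
  for (builder in list(build_cmm_net, build_unet_baseline)) {
    m <- builder(cfg, seed = 2)
    for (hw in list(c(16L, 16L), c(24L, 32L))) {
      x <- array(runif(hw[1] * hw[2] * 2), c(hw[1], hw[2], 2))
      p <- predict(m, x, type = "prob")
      expect_equal(dim(p), c(hw, 2L))
      expect_equal(range(rowSums(matrix(p, ncol = 2))), c(1, 1),
                   tolerance = 1e-10)
    }
  }
  # zero image still yields a valid probability map
  p0 <- predict(build_unet_baseline(cfg), array(0, c(16, 16, 2)))
  expect_true(all(is.finite(p0)))
  expect_equal(max(abs(p0[, , 1] + p0[, , 2] - 1)), 0, tolerance = 1e-12)
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(network_config(input_height = 100L), "divisible")
  expect_error(network_config(encoder_dilation_rates = c(1L, 1L)), "length")
  expect_error(network_config(num_classes = 1L), "num_classes")
  expect_error(predict(build_cmm_net(tiny_config()),
                       array(0, c(10, 16, 2))), "divisible")
  expect_error(predict(build_cmm_net(tiny_config()),
                       array(0, c(16, 16, 3))), "channels")
})

test_that("a single optimization step changes the loss (gradient flow)", {
  cfg <- tiny_config()
  m <- build_cmm_net(cfg, seed = 4)
  set.seed(5)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2))
  y <- matrix(0, 16, 16); y[5:11, 6:12] <- 1
  sched <- training_schedule(initial_learning_rate = 1e-3, total_epochs = 1L,
                             batch_size = 1L, seed = 9L)
  l0 <- dice_loss(predict(m, x)[, , 2], y)
  fit <- train_segmenter(m, list(x), list(y), sched)
  l1 <- dice_loss(predict(fit$model, x)[, , 2], y)
  expect_false(isTRUE(all.equal(l0, l1)))
})

test_that("checkpoints round-trip through disk", {
  m <- build_cmm_net(tiny_config(), seed = 8)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(m2$layers, m$layers)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2))
  expect_equal(predict(m2, x), predict(m, x))
})
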