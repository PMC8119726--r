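test_that("dice loss identities: perfect, disjoint, and half overlap", {
  gt <- matrix(0, 6, 6); gt[2:4, 2:5] <- 1       # 12 foreground pixels
  expect_equal(dice_loss(gt, gt), 0, tolerance = 1e-6)
  other <- matrix(0, 6, 6); other[6, 1:3] <- 1   # disjoint, non-empty
  expect_equal(dice_loss(other, gt), 1, tolerance = 1e-6)
  # prediction covering exactly half of gt: L = 1 - 2a/(a + 2a) = 1/3
  half <- matrix(0, 6, 6); half[2:4, 2:3] <- 1
  expect_equal(sum(half * gt), sum(gt) / 2)
  expect_equal(dice_loss(half, gt), 1 / 3, tolerance = 1e-6)
  # brute-force accumulation agrees with the closed form
  acc_i <- 0; acc_p <- 0; acc_g <- 0
  for (i in seq_along(gt)) {
    acc_i <- acc_i + half[i] * gt[i]
    acc_p <- acc_p + half[i]; acc_g <- acc_g + gt[i]
  }
  expect_equal(dice_loss(half, gt),
               1 - (2 * acc_i + 1e-6) / (acc_p + acc_g + 1e-6))
})

test_that("dice loss is the DSC complement on binary inputs", {
  set.seed(21)
  for (rep in 1:10) {
    a <- matrix((runif(64) > 0.5) * 1, 8, 8)
    b <- matrix((runif(64) > 0.4) * 1, 8, 8)
    if (sum(a) + sum(b) == 0) next
    dsc <- unname(scalar_metrics(contingency(a, b))["DSC"]) / 100
    expect_equal(dice_loss(a, b) + dsc, 1, tolerance = 1e-4)
  }
})

test_that("dice loss validates its inputs", {
  expect_error(dice_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shape")
  expect_error(dice_loss(matrix(1.5, 2, 2), matrix(1, 2, 2)), "\\[0, 1\\]")
})

test_that("learning-rate schedule has the stated endpoints", {
  s <- training_schedule(initial_learning_rate = 1e-4,
                         lr_reduction_factor = 10, total_epochs = 100L)
  expect_equal(schedule_lr(s, 1), 1e-4)
  expect_equal(schedule_lr(s, 100), 1e-5)
  lrs <- vapply(1:100, function(e) schedule_lr(s, e), numeric(1))
  expect_true(all(diff(lrs) < 0))
  s30 <- training_schedule(total_epochs = 30L)
  expect_equal(schedule_lr(s30, 30), 1e-5)
})

test_that("training reduces the dice loss on separable phantoms", {
  cfg <- preset_config("phantom")$network
  items <- lapply(1:10, function(i)
    make_lesion(c(48L, 64L), "easy", seed = 300 + i))
  imgs <- lapply(items, `[[`, "image")
  msks <- lapply(items, `[[`, "mask")
  sched <- training_schedule(initial_learning_rate = 3e-3,
                             total_epochs = 3L, batch_size = 5L, seed = 7L)
  fit <- train_segmenter(build_cmm_net(cfg, seed = 7), imgs, msks, sched)
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
  expect_equal(nrow(fit$history), 3L)
})

test_that("training is reproducible under a fixed seed", {
  cfg <- tiny_config()
  set.seed(31)
  imgs <- lapply(1:4, function(i) array(runif(16 * 16 * 2), c(16, 16, 2)))
  msks <- lapply(1:4, function(i)
    matrix((runif(256) > 0.7) * 1, 16, 16))
  sched <- training_schedule(initial_learning_rate = 1e-3,
                             total_epochs = 2L, batch_size = 2L, seed = 5L)
  f1 <- train_segmenter(build_cmm_net(cfg, seed = 5), imgs, msks, sched)
  f2 <- train_segmenter(build_cmm_net(cfg, seed = 5), imgs, msks, sched)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_equal(f1$model$layers, f2$model$layers)
})

test_that("training rejects an empty dataset", {
  expect_error(train_segmenter(build_cmm_net(tiny_config()), list(), list(),
                               training_schedule()),
               "empty|dim")
})
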