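test_that("dermoscopy preprocessing resizes to the working resolution", {
  set.seed(71)
  img <- array(runif(54 * 72 * 3), c(54, 72, 3))
  mask <- matrix(0, 54, 72); mask[10:30, 20:50] <- 1
  pp <- prep_dermoscopy(img, mask, size = c(24L, 32L))
  expect_equal(dim(pp$image), c(24, 32, 3))
  expect_equal(dim(pp$mask), c(24, 32))
  expect_true(is_binary_mask <- all(pp$mask %in% c(0, 1)))
  expect_true(all(pp$image >= 0 & pp$image <= 1))
  # same-size input passes through pixel-identically
  pp2 <- prep_dermoscopy(img, mask, size = c(54L, 72L))
  expect_equal(pp2$image, img)
  expect_equal(pp2$mask, mask)
  # all-foreground mask survives resizing
  ones <- prep_dermoscopy(img, matrix(1, 54, 72), size = c(24L, 32L))$mask
  expect_true(all(ones == 1))
  expect_warning(prep_dermoscopy(img, mask * 0.7, size = c(24L, 32L)),
                 "thresholding")
})

test_that("fundus preprocessing crops to the FOV box and equalizes", {
  H <- 64; W <- 80
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  fov <- (((rr - 32)^2 + (cc - 40)^2) <= 25^2) * 1
  set.seed(72)
  img <- array(runif(H * W * 3), c(H, W, 3))
  pp <- prep_fundus(img, fov)
  # bounding box of a centred disc of radius 25: rows 7..57, cols 15..65
  expect_equal(dim(pp$fov), c(51, 51))
  expect_equal(dim(pp$image), c(51, 51, 3))
  expect_true(all(pp$image >= 0 & pp$image <= 1))
  # constant image: nothing to equalize
  flat <- prep_fundus(array(0.5, c(H, W, 3)), fov)
  expect_true(all(flat$image == 0.5))
  expect_error(prep_fundus(img, fov * 0), "empty")
  expect_error(prep_fundus(img, fov[1:10, 1:10]), "spatial dims")
})

test_that("patch grids have the closed-form size and cover every pixel", {
  img <- matrix(runif(576 * 576), 576, 576)
  r <- extract_patches(img, patch_size = 128L, stride = 64L)
  expect_equal(nrow(r$grid$origins), 64)            # floor((576-128)/64)+1 = 8
  expect_equal(dim(r$patches), c(128, 128, 1, 64))
  cover <- matrix(0, 576, 576)
  for (k in seq_len(nrow(r$grid$origins)))
    cover[r$grid$origins[k, 1] + 1:128, r$grid$origins[k, 2] + 1:128] <- 1
  expect_true(all(cover == 1))
  expect_equal(reconstruct_patches(r$patches, r$grid), img)

  one <- extract_patches(matrix(1, 128, 128), 128L, 64L)
  expect_equal(one$grid$origins, cbind(row = 0L, col = 0L))

  # non-tiling stride anchors the last window at the edge
  img2 <- matrix(runif(130 * 130), 130, 130)
  r2 <- extract_patches(img2, 128L, 64L)
  expect_equal(sort(unique(r2$grid$origins[, 1])), c(0L, 2L))
  expect_equal(reconstruct_patches(r2$patches, r2$grid), img2)
  expect_error(extract_patches(matrix(1, 64, 64), 128L), "exceeds")
})

test_that("exact round trip for tiling grids, averaging for overlaps", {
  set.seed(73)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  tiled <- extract_patches(img, 32L, 32L)
  expect_identical(reconstruct_patches(tiled$patches, tiled$grid), img)
  overl <- extract_patches(img, 32L, 16L)
  expect_equal(reconstruct_patches(overl$patches, overl$grid), img)
})

test_that("MR pipeline selects labelled slices and round-trips the crop", {
  case <- make_tumor_volume(c(60L, 60L, 12L), seed = 5)
  pp <- prep_brats(case, crop = 48L)
  expect_equal(dim(pp$images), c(48, 48, 3, 12))
  expect_true(all(pp$images >= 0 & pp$images <= 1))
  labelled <- which(apply(case$labels, 3, function(s) any(s > 0)))
  expect_identical(pp$training_slices, labelled)
  expect_identical(pp$masks,
                   (case$labels[pp$crop_offset[1] + 1:48,
                                pp$crop_offset[2] + 1:48, , drop = FALSE]
                    > 0) * 1)
  # un-cropping restores original voxel coordinates (tumor inside window)
  back <- uncrop_slices(pp$masks, dim(case$labels), pp$crop_offset)
  expect_identical(back, (case$labels > 0) * 1)
  expect_error(volume_case(case$modalities[c("T1", "T2")], case$labels),
               "missing modality")
})

test_that("image and NIfTI files round-trip through disk", {
  tmp <- tempfile(); dir.create(tmp)
  set.seed(74)
  img <- array(runif(20 * 24 * 3), c(20, 24, 3))
  f <- file.path(tmp, "x.png")
  write_image(img, f)
  expect_equal(read_image(f), img, tolerance = 1 / 255)
  mask <- matrix((runif(20 * 24) > 0.5) * 1, 20, 24)
  fm <- file.path(tmp, "m.png")
  write_mask(mask, fm)
  expect_identical(read_mask(fm), mask)
  case <- make_tumor_volume(c(40L, 40L, 8L), seed = 2)
  d <- file.path(tmp, "case")
  write_volume_case(case, d)
  back <- read_volume_case(d)
  expect_equal(back$modalities$FLAIR, case$modalities$FLAIR,
               tolerance = 1e-6)
  expect_equal(back$labels, case$labels + 0, tolerance = 1e-6)
  unlink(tmp, recursive = TRUE)
})
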