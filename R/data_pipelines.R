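# Dataset-specific preprocessing pipelines and patch handling.

#' Read / write 2-D images and masks
#'
#' Thin wrappers over EBImage's PNG/TIFF/JPEG I/O that convert to this
#' package's `(H, W, C)` row-major convention with values in `[0, 1]`.
#' Masks are single-channel images thresholded at 0.5 into `{0, 1}` and
#' written as 8-bit 0/255 PNGs.
#'
#' @param path Image file path.
#' @param x Image array `(H, W, C)` / `(H, W)` or binary mask matrix.
#' @return `read_image`: `(H, W, C)` array or `(H, W)` matrix;
#'   `read_mask`: 0/1 matrix.
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  d <- dim(a)
  if (length(d) == 2L) return(t(a))
  if (length(d) > 3L) a <- a[, , , 1]            # drop frames
  if (dim(a)[3] > 3L) a <- a[, , 1:3]            # drop alpha
  aperm(a, c(2, 1, 3))
}

#' @rdname read_image
#' @export
write_image <- function(x, path) {
  a <- if (length(dim(x)) == 3L) aperm(x, c(2, 1, 3)) else t(x)
  EBImage::writeImage(EBImage::Image(clip01(a),
                                     colormode = if (length(dim(x)) == 3L)
                                       "Color" else "Grayscale"),
                      path)
  invisible(path)
}

#' @rdname read_image
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  (img >= 0.5) * 1
}

#' @rdname read_image
#' @export
write_mask <- function(x, path) {
  write_image((x > 0) * 1, path)
}

#' Bilinear resampling of an image
#'
#' Half-pixel-centred bilinear interpolation (the same convention used
#' inside the pyramid pooling modules and the decoder).  Resampling to
#' the input size is an exact identity.
#'
#' @param x `(H, W)` matrix or `(H, W, C)` array.
#' @param height,width Target spatial size.
#' @return Resampled array of the requested size.
#' @export
resize_bilinear <- function(x, height, width) {
  nd <- length(dim(x))
  y <- cpp_bilinear_fwd(as_tensor(x), as.integer(height), as.integer(width))
  drop_tensor(y, nd)
}

#' Dermoscopy preprocessing
#'
#' Rescales a lesion image of any size to the working resolution
#' (192 x 256 by default) with bilinear interpolation; the mask is
#' resized the same way and re-binarized at 0.5.  Outputs lie in
#' `[0, 1]`.
#'
#' @param image `(H, W, C)` array in `[0, 1]`.
#' @param mask Optional mask matrix; non-binary input is tolerated and
#'   thresholded with a warning.
#' @param size Target `(height, width)`.
#' @return List with `image` and (when given) `mask`.
#' @export
prep_dermoscopy <- function(image, mask = NULL, size = c(192L, 256L)) {
  out <- list(image = clip01(resize_bilinear(image, size[1], size[2])))
  if (!is.null(mask)) {
    if (!is_binary_mask(mask))
      warning("mask is not binary; thresholding at 0.5")
    m <- resize_bilinear(mask, size[1], size[2])
    out$mask <- (m >= 0.5) * 1
  }
  out
}

# Bounding box (row/col ranges) of a binary mask.
mask_bbox <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (length(rows) == 0) stop("empty mask: no foreground pixels")
  list(rows = range(rows), cols = range(cols))
}

#' Fundus preprocessing: FOV crop and CLAHE
#'
#' Crops a retinal image (and its field-of-view mask) to the FOV's
#' bounding box, applies contrast-limited adaptive histogram
#' equalization per channel (clip limit 2, 8 x 8 tiles), and rescales to
#' `[0, 1]`.  Channels without contrast (constant) pass through
#' unchanged.
#'
#' @param image `(H, W, C)` array or `(H, W)` matrix in `[0, 1]`.
#' @param fov_mask Binary FOV mask of the same spatial size.
#' @param clip_limit CLAHE clip limit.
#' @param tiles Number of CLAHE tiles per side.
#' @return List with `image` and `fov`, both cropped to the FOV box.
#' @export
prep_fundus <- function(image, fov_mask, clip_limit = 2, tiles = 8L) {
  d <- dim(image)
  if (!identical(dim(fov_mask), d[1:2]))
    stop("fov_mask must match the image's spatial dims")
  bb <- mask_bbox(fov_mask)
  ri <- bb$rows[1]:bb$rows[2]
  ci <- bb$cols[1]:bb$cols[2]
  img <- if (length(d) == 3L) image[ri, ci, , drop = FALSE]
         else image[ri, ci, drop = FALSE]
  fov <- fov_mask[ri, ci, drop = FALSE]
  apply_clahe <- function(ch) {
    if (diff(range(ch)) == 0) return(ch)     # nothing to equalize
    # CLAHE needs dims divisible by the tile grid: replicate-pad, then crop
    h <- nrow(ch); w <- ncol(ch)
    h2 <- ceiling(h / tiles) * tiles
    w2 <- ceiling(w / tiles) * tiles
    padded <- ch[c(seq_len(h), rep(h, h2 - h)),
                 c(seq_len(w), rep(w, w2 - w)), drop = FALSE]
    e <- EBImage::clahe(EBImage::Image(t(padded)), nx = tiles, ny = tiles,
                        limit = clip_limit, keep.range = TRUE)
    t(EBImage::imageData(e))[seq_len(h), seq_len(w), drop = FALSE]
  }
  if (length(dim(img)) == 3L) {
    for (c in seq_len(dim(img)[3])) img[, , c] <- apply_clahe(img[, , c])
  } else {
    img <- apply_clahe(img)
  }
  list(image = clip01(img), fov = fov)
}

#' Patch extraction and reconstruction
#'
#' `extract_patches` cuts a row-major grid of square patches (128 px
#' with stride 64 for training, stride 128 for testing in the retinal
#' pipeline).  Origins are 0-based `(row, col)` with half-open windows;
#' when the stride does not tile exactly, a final row/column of patches
#' is anchored to the image edge so every pixel is covered.
#' `reconstruct_patches` restores the source shape, averaging where
#' patches overlap (exact for non-overlapping grids).
#'
#' @param image `(H, W)` matrix or `(H, W, C)` array.
#' @param patch_size Square patch side, `<=` both image dims.
#' @param stride Positive step between patch origins.
#' @param patches `(patch, patch, C, n)` array from `extract_patches`.
#' @param grid The matching `patch_grid` object.
#' @return `extract_patches`: list with `patches`
#'   (`(patch, patch, C, n)` array) and `grid` (class `patch_grid`
#'   carrying `origins` (0-based), `patch_size`, `stride`,
#'   `source_shape`); `reconstruct_patches`: array shaped like the
#'   source.
#' @examples
#' r <- extract_patches(matrix(runif(64), 8, 8), patch_size = 4, stride = 4)
#' dim(r$patches)
#' @export
extract_patches <- function(image, patch_size = 128L, stride = 64L) {
  d <- dim(image)
  nd <- length(d)
  if (patch_size > d[1] || patch_size > d[2])
    stop("patch_size exceeds image dims")
  if (stride < 1) stop("stride must be positive")
  axis_origins <- function(n) {
    o <- seq(0L, n - patch_size, by = stride)
    if (o[length(o)] != n - patch_size) o <- c(o, n - patch_size)
    as.integer(o)
  }
  ro <- axis_origins(d[1])
  co <- axis_origins(d[2])
  origins <- cbind(row = rep(ro, times = length(co)),
                   col = rep(co, each = length(ro)))
  C <- if (nd == 3L) d[3] else 1L
  xt <- as_tensor(image)
  patches <- array(0, c(patch_size, patch_size, C, nrow(origins)))
  for (k in seq_len(nrow(origins))) {
    patches[, , , k] <- xt[origins[k, 1] + seq_len(patch_size),
                           origins[k, 2] + seq_len(patch_size), , 1]
  }
  grid <- structure(list(patch_size = as.integer(patch_size),
                         stride = as.integer(stride), origins = origins,
                         source_shape = d),
                    class = "patch_grid")
  list(patches = patches, grid = grid)
}

#' @rdname extract_patches
#' @export
reconstruct_patches <- function(patches, grid) {
  stopifnot(inherits(grid, "patch_grid"))
  d <- grid$source_shape
  C <- dim(patches)[3]
  ps <- grid$patch_size
  acc <- array(0, c(d[1], d[2], C))
  cnt <- matrix(0, d[1], d[2])
  for (k in seq_len(nrow(grid$origins))) {
    ri <- grid$origins[k, 1] + seq_len(ps)
    ci <- grid$origins[k, 2] + seq_len(ps)
    acc[ri, ci, ] <- acc[ri, ci, ] + patches[, , , k]
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  out <- acc / as.numeric(cnt)
  if (length(d) == 2L) out <- out[, , 1]
  out
}

#' Multi-modal MR volume case
#'
#' @param modalities Named list with 3-D arrays `T1`, `T1Gd`, `T2`,
#'   `FLAIR`, all of one shape.
#' @param labels Integer 3-D label array of the same shape; the whole
#'   tumor is `labels > 0`.
#' @return An object of class `volume_case`.
#' @export
volume_case <- function(modalities, labels) {
  need <- c("T1", "T1Gd", "T2", "FLAIR")
  if (!all(need %in% names(modalities)))
    stop("missing modality: ", paste(setdiff(need, names(modalities)),
                                     collapse = ", "))
  d <- dim(modalities[[need[1]]])
  for (m in need)
    if (!identical(dim(modalities[[m]]), d))
      stop("all modalities must share one shape")
  if (!identical(dim(labels), d))
    stop("labels must match the modality shape")
  structure(list(modalities = modalities[need], labels = labels),
            class = "volume_case")
}

#' MR volume preprocessing for whole-tumor segmentation
#'
#' Center-crops each modality in-plane (240 -> 192 for the standard
#' glioma volumes), stacks (T2, FLAIR, T1Gd) as a 3-channel image per
#' axial slice, min-max normalizes per volume and per modality to
#' `[0, 1]`, and selects the training slices as exactly those with
#' non-empty label annotations; at evaluation time all slices are used
#' and scored as a volume.
#'
#' @param case A [volume_case()].
#' @param crop In-plane output side (must not exceed the input).
#' @return List with `images` (`(crop, crop, 3, S)`), `masks`
#'   (`(crop, crop, S)` whole-tumor 0/1), `training_slices` (indices of
#'   labelled slices), `crop_offset` (0-based `(row, col)` of the crop
#'   window), and `source_shape`.
#' @export
prep_brats <- function(case, crop = 192L) {
  stopifnot(inherits(case, "volume_case"))
  d <- dim(case$labels)
  if (crop > d[1] || crop > d[2]) stop("crop exceeds in-plane dims")
  off <- c((d[1] - crop) %/% 2, (d[2] - crop) %/% 2)
  ri <- off[1] + seq_len(crop)
  ci <- off[2] + seq_len(crop)
  norm01 <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) return(v * 0)
    (v - rng[1]) / diff(rng)
  }
  S <- d[3]
  images <- array(0, c(crop, crop, 3L, S))
  chans <- c("T2", "FLAIR", "T1Gd")
  for (i in seq_along(chans)) {
    v <- norm01(case$modalities[[chans[i]]])
    images[, , i, ] <- v[ri, ci, ]
  }
  masks <- (case$labels[ri, ci, , drop = FALSE] > 0) * 1
  sel <- which(apply(masks, 3, sum) > 0)
  if (length(sel) == 0) warning("no labelled slices in this volume")
  list(images = images, masks = masks, training_slices = sel,
       crop_offset = as.integer(off), source_shape = d)
}

#' Undo the in-plane crop of a slice stack
#'
#' Places cropped slices (e.g. predicted masks) back at their original
#' in-plane coordinates, zero-padding the cropped margins, so voxel
#' coordinates round-trip exactly.
#'
#' @param x `(crop, crop, S)` array.
#' @param source_shape Original `(H, W, S)` shape.
#' @param crop_offset 0-based `(row, col)` offset from [prep_brats()].
#' @return `(H, W, S)` array.
#' @export
uncrop_slices <- function(x, source_shape, crop_offset) {
  out <- array(0, source_shape)
  d <- dim(x)
  out[crop_offset[1] + seq_len(d[1]), crop_offset[2] + seq_len(d[2]), ] <- x
  out
}

#' Read / write a multi-modal MR case as NIfTI files
#'
#' A case directory holds `T1.nii.gz`, `T1Gd.nii.gz`, `T2.nii.gz`,
#' `FLAIR.nii.gz` and `labels.nii.gz`.
#'
#' @param dir Case directory.
#' @param case A [volume_case()].
#' @return `read_volume_case` returns a `volume_case`.
#' @export
read_volume_case <- function(dir) {
  grab <- function(name) {
    for (ext in c(".nii.gz", ".nii")) {
      f <- file.path(dir, paste0(name, ext))
      if (file.exists(f)) return(array(RNifti::readNifti(f),
                                       dim(RNifti::readNifti(f))))
    }
    stop("missing modality: ", name, " in ", dir)
  }
  volume_case(list(T1 = grab("T1"), T1Gd = grab("T1Gd"), T2 = grab("T2"),
                   FLAIR = grab("FLAIR")), grab("labels"))
}

#' @rdname read_volume_case
#' @export
write_volume_case <- function(case, dir) {
  stopifnot(inherits(case, "volume_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(case$modalities))
    RNifti::writeNifti(case$modalities[[m]],
                       file.path(dir, paste0(m, ".nii.gz")))
  RNifti::writeNifti(case$labels, file.path(dir, "labels.nii.gz"))
  invisible(dir)
}
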