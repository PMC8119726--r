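#' Inversion-recovery OR merge
#'
#' Test-time augmentation merge: the segmented map of the original view
#' is updated with the pixelwise logical OR of the segmented maps of all
#' augmented views after each has been recovered (inverse-transformed)
#' to the original orientation, \eqn{I_o = I_o | IR(I_k)}.  The result
#' is therefore a superset of every contributing view.
#'
#' @param original Binary mask of the original view.
#' @param recovered List of binary masks (already recovered to the
#'   original orientation), possibly empty.
#' @return Binary 0/1 mask of the same shape.
#' @export
ir_or_merge <- function(original, recovered = list()) {
  out <- original
  for (m in recovered) {
    if (!identical(dim(m), dim(out)))
      stop("all masks must share one shape")
    out <- pmax(out, m)
  }
  (out > 0) * 1
}

#' Inversion-recovery AND merge
#'
#' Combines per-color-space OR-merged masks with a pixelwise logical
#' AND, keeping only pixels every color space agrees on.
#'
#' @param masks Non-empty list of binary masks of one shape.
#' @return Binary 0/1 mask.
#' @export
ir_and_merge <- function(masks) {
  if (!is.list(masks) || length(masks) == 0)
    stop("masks must be a non-empty list")
  out <- masks[[1]]
  for (m in masks[-1]) {
    if (!identical(dim(m), dim(out)))
      stop("all masks must share one shape")
    out <- pmin(out, m)
  }
  (out > 0) * 1
}

# Foreground-probability prediction for either a cmm_model or a plain
# function(image) -> probability matrix (useful for testing stubs).
predict_fg <- function(model, image) {
  if (is.function(model)) return(model(image))
  p <- predict(model, image, type = "prob")
  p[, , 2L]
}

#' Inversion-recovery evaluation of one image
#'
#' For each transform in the group: transform the image, predict,
#' binarize at `threshold`, recover the mask with the inverse transform,
#' and OR-merge all views.  When several color spaces are requested the
#' OR-merged mask is computed per space and the results are AND-merged.
#' With only the identity transform and one color space this reduces to
#' plain thresholded prediction.
#'
#' @param model A `cmm_model`, or a `function(image)` returning the
#'   foreground-probability matrix (handy for stubs and oracles).
#' @param image `(H, W, C)` array in `[0, 1]`.
#' @param transforms List of `geom_transform`s (default: the full
#'   8-member group).
#' @param threshold Binarization threshold on the foreground
#'   probability.
#' @param color_spaces Optional character subset of
#'   `c("RGB", "LAB", "SV")`; requires a 3-channel image.
#' @return Binary 0/1 mask.
#' @export
run_ir <- function(model, image, transforms = geom_transforms(),
                   threshold = 0.5, color_spaces = NULL) {
  one_space <- function(img) {
    merged <- NULL
    for (t in transforms) {
      view <- apply_geom(img, t)
      m <- (predict_fg(model, view) >= threshold) * 1
      back <- apply_geom(m, invert_geom(t))
      merged <- if (is.null(merged)) back else ir_or_merge(merged, list(back))
    }
    merged
  }
  if (is.null(color_spaces)) return(one_space(image))
  color_spaces <- match.arg(color_spaces, c("RGB", "LAB", "SV"),
                            several.ok = TRUE)
  variants <- color_variants(image)
  ir_and_merge(lapply(variants[color_spaces], one_space))
}
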