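#' Geometric transform from the 8-member rotation/flip group
#'
#' The augmentation family used for both training and test-time
#' augmentation is the dihedral group D4: the four right-angle rotations
#' optionally preceded by a horizontal flip.  A transform first applies
#' the flip (when requested) and then rotates counter-clockwise.
#'
#' @param rotation One of 0, 90, 180, 270 (degrees, counter-clockwise).
#' @param flip Apply a horizontal (left-right) flip before rotating?
#' @return An object of class `geom_transform`.
#' @export
geom_transform <- function(rotation = 0L, flip = FALSE) {
  if (!rotation %in% c(0L, 90L, 180L, 270L))
    stop("rotation must be one of 0, 90, 180, 270")
  structure(list(rotation = as.integer(rotation), flip = isTRUE(flip)),
            class = "geom_transform")
}

#' @export
print.geom_transform <- function(x, ...) {
  cat(sprintf("<geom_transform: rot %d%s>\n", x$rotation,
              if (x$flip) " + hflip" else ""))
  invisible(x)
}

#' The full 8-member transform group
#'
#' @return List of the 8 `geom_transform`s, identity first.
#' @export
geom_transforms <- function() {
  out <- list()
  for (f in c(FALSE, TRUE))
    for (r in c(0L, 90L, 180L, 270L))
      out[[length(out) + 1L]] <- geom_transform(r, f)
  out
}

rot90ccw <- function(x) {
  if (is.matrix(x)) return(t(x)[ncol(x):1, , drop = FALSE])
  d <- dim(x)
  y <- aperm(x, c(2, 1, seq_along(d)[-(1:2)]))
  idx <- rep(list(quote(expr = )), length(d))
  idx[[1]] <- d[2]:1
  do.call(`[`, c(list(y), idx, list(drop = FALSE)))
}

hflip <- function(x) {
  d <- dim(x)
  idx <- rep(list(quote(expr = )), length(d))
  idx[[2]] <- d[2]:1
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Apply or invert a geometric transform
#'
#' `apply_geom` transforms an image or mask (any array whose first two
#' dimensions are spatial); `invert_geom` returns the group inverse, so
#' `apply_geom(apply_geom(x, t), invert_geom(t))` restores `x`
#' bit-exactly.  `compose_geom(a, b)` is the group element equivalent to
#' applying `b` first and then `a`.
#'
#' @param x Matrix or array with spatial first two dims.
#' @param transform,a,b `geom_transform` objects.
#' @return Transformed array / composed or inverted transform.
#' @export
apply_geom <- function(x, transform) {
  stopifnot(inherits(transform, "geom_transform"))
  had_dim <- !is.null(dim(x))
  if (!had_dim) stop("x must be a matrix or array")
  if (transform$flip) x <- hflip(x)
  for (i in seq_len(transform$rotation %/% 90L)) x <- rot90ccw(x)
  x
}

#' @rdname apply_geom
#' @export
invert_geom <- function(transform) {
  stopifnot(inherits(transform, "geom_transform"))
  if (transform$flip) transform
  else geom_transform((360L - transform$rotation) %% 360L, FALSE)
}

#' @rdname apply_geom
#' @export
compose_geom <- function(a, b) {
  stopifnot(inherits(a, "geom_transform"), inherits(b, "geom_transform"))
  # a o b with elements R^r F^f: F R^k = R^-k F
  sgn <- if (a$flip) -1L else 1L
  geom_transform(((a$rotation + sgn * b$rotation) %% 360L + 360L) %% 360L,
                 xor(a$flip, b$flip))
}

#' Eight-fold augmentation of an image/mask pair
#'
#' Applies every element of the rotation/flip group (identity first) to
#' an image and, identically, to its mask, so one labelled item becomes
#' eight.
#'
#' @param image Image array `(H, W, C)` or matrix.
#' @param mask Binary mask matrix `(H, W)`; optional.
#' @return List of 8 lists with elements `image`, `mask`, `transform`.
#' @export
eightfold <- function(image, mask = NULL) {
  lapply(geom_transforms(), function(t) {
    list(image = apply_geom(image, t),
         mask = if (!is.null(mask)) apply_geom(mask, t),
         transform = t)
  })
}

#' Color-space variants of an RGB image
#'
#' Dermoscopy training uses, besides RGB, a CIELAB rendering and a
#' saturation/value rendering of every image as additional samples.
#' All variants are rescaled to `[0, 1]` and keep 3 channels; the
#' 2-channel SV pair is packed as (S, V, V).
#'
#' @param rgb `(H, W, 3)` array with values in `[0, 1]`.
#' @return Named list of `(H, W, 3)` arrays: `RGB`, `LAB`, `SV`.
#' @export
color_variants <- function(rgb) {
  d <- dim(rgb)
  if (length(d) != 3L || d[3] != 3L) stop("rgb must be an (H, W, 3) array")
  px <- matrix(rgb, ncol = 3)
  lab <- grDevices::convertColor(px, from = "sRGB", to = "Lab")
  lab01 <- cbind(lab[, 1] / 100, (lab[, 2] + 110) / 220, (lab[, 3] + 110) / 220)
  hsv <- grDevices::rgb2hsv(t(px), maxColorValue = 1)
  sv <- cbind(hsv["s", ], hsv["v", ], hsv["v", ])
  list(RGB = rgb,
       LAB = clip01(array(lab01, d)),
       SV = clip01(array(sv, d)))
}

# Rescale this package's [0,1]-packed LAB back to Lab axes (internal).
unpack_lab <- function(lab01) {
  px <- matrix(lab01, ncol = 3)
  cbind(px[, 1] * 100, px[, 2] * 220 - 110, px[, 3] * 220 - 110)
}
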