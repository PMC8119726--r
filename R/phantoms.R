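# Seeded synthetic phantoms emulating the three imaging modalities, so
# pipelines, training and IR are testable without clinical data.  Masks
# are exact by construction; a fixed, named RNG makes every phantom a
# stable test vector.

# Low-frequency texture: coarse white noise bilinearly upsampled.
coarse_noise <- function(h, w, grid = c(6L, 8L), sd = 1) {
  resize_bilinear(matrix(rnorm(grid[1] * grid[2], sd = sd), grid[1], grid[2]),
                  h, w)
}

# Star-convex irregular boundary radius as a function of angle.
boundary_radius <- function(theta, base, amp, n_harmonics = 5L) {
  r <- rep(1, length(theta))
  for (k in 2:(n_harmonics + 1)) {
    a <- runif(1, 0, amp)
    phi <- runif(1, 0, 2 * pi)
    r <- r + a * cos(k * theta + phi)
  }
  base * pmax(r, 0.2)
}

difficulty_levels <- function(difficulty) {
  match.arg(difficulty, c("easy", "hard"))
}

#' Synthetic dermoscopy lesion phantom
#'
#' A single irregular dark blob (a polar-perturbed ellipse) on a
#' textured skin-toned background, with thin dark hair-like strokes as
#' artifacts.  The mask marks the blob exactly.
#'
#' @param size `(height, width)` of the output.
#' @param difficulty `"easy"` (low noise, few hairs) or `"hard"`.
#' @param seed Integer seed; identical arguments give bit-identical
#'   output.
#' @return List with `image` (`(H, W, 3)` in `[0, 1]`) and `mask`
#'   (`(H, W)` 0/1).
#' @export
make_lesion <- function(size = c(192L, 256L), difficulty = "easy",
                        seed = 1L) {
  difficulty <- difficulty_levels(difficulty)
  H <- size[1]; W <- size[2]
  noise_sd <- if (difficulty == "easy") 0.015 else 0.05
  amp <- if (difficulty == "easy") 0.10 else 0.22
  n_hair <- if (difficulty == "easy") 2L else 8L
  with_seed(seed, {
    cy <- H * (0.5 + runif(1, -0.08, 0.08))
    cx <- W * (0.5 + runif(1, -0.08, 0.08))
    base_r <- 0.20 * min(H, W) * runif(1, 0.85, 1.2)
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    theta <- atan2(rr - cy, cc - cx)
    dist <- sqrt((rr - cy)^2 + (cc - cx)^2)
    mask <- (dist <= boundary_radius(theta, base_r, amp)) * 1

    skin <- c(0.85, 0.66, 0.55)
    lesion <- c(0.42, 0.26, 0.19)
    tex <- coarse_noise(H, W, sd = 0.05)
    image <- array(0, c(H, W, 3))
    for (c in 1:3)
      image[, , c] <- skin[c] + tex +
        mask * (lesion[c] - skin[c] + 0.5 * tex)
    for (h in seq_len(n_hair)) {
      p0 <- c(runif(1, 1, H), runif(1, 1, W))
      p2 <- c(runif(1, 1, H), runif(1, 1, W))
      p1 <- (p0 + p2) / 2 + c(runif(1, -H / 4, H / 4), runif(1, -W / 4, W / 4))
      t <- seq(0, 1, length.out = 4L * round(sqrt(sum((p2 - p0)^2)) + 2))
      pts <- cbind((1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1],
                   (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2])
      pts <- round(pts)
      keep <- pts[, 1] >= 1 & pts[, 1] <= H & pts[, 2] >= 1 & pts[, 2] <= W
      pts <- pts[keep, , drop = FALSE]
      for (c in 1:3)
        image[cbind(pts, c)] <- image[cbind(pts, c)] - 0.35
    }
    image <- image + array(rnorm(H * W * 3, sd = noise_sd), c(H, W, 3))
    list(image = clip01(image), mask = mask)
  })
}

# Stamp a disk of the given radius onto a logical mask, in place.
stamp_disk <- function(mask, r0, c0, radius, H, W) {
  ir <- max(1L, ceiling(radius))
  rs <- max(1L, floor(r0 - ir)):min(H, ceiling(r0 + ir))
  cs <- max(1L, floor(c0 - ir)):min(W, ceiling(c0 + ir))
  for (i in rs)
    for (j in cs)
      if ((i - r0)^2 + (j - c0)^2 <= radius^2) mask[i, j] <- TRUE
  mask
}

#' Synthetic retinal-vessel phantom
#'
#' A recursively branching tree of thin (1--4 px) curved vessels grown
#' from a root inside a circular field of view, on a textured
#' fundus-like background.  The mask marks the tree exactly; every
#' vessel pixel lies inside the FOV disc.
#'
#' @inheritParams make_lesion
#' @return List with `image` (`(H, W, 3)`), `mask` (0/1 vessel tree)
#'   and `fov` (0/1 disc).
#' @export
make_vessels <- function(size = c(256L, 256L), difficulty = "easy",
                         seed = 1L) {
  difficulty <- difficulty_levels(difficulty)
  H <- size[1]; W <- size[2]
  noise_sd <- if (difficulty == "easy") 0.015 else 0.05
  wobble <- if (difficulty == "easy") 0.12 else 0.22
  with_seed(seed, {
    fc <- c(H, W) / 2
    fr <- 0.46 * min(H, W)
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    dist2 <- (rr - fc[1])^2 + (cc - fc[2])^2
    fov <- (dist2 <= fr^2) * 1

    mask <- matrix(FALSE, H, W)
    root <- fc + c(0, -0.35 * fr)
    n_trunk <- 6L
    # iterative depth-first growth; each queue entry is one branch
    queue <- lapply(seq_len(n_trunk), function(k) {
      list(pos = root, ang = 2 * pi * (k - 0.5) / n_trunk + runif(1, -0.3, 0.3),
           width = runif(1, 2.8, 3.6), depth = 1L,
           steps = round(runif(1, 180, 260)))
    })
    while (length(queue) > 0) {
      br <- queue[[1]]
      queue <- queue[-1]
      pos <- br$pos; ang <- br$ang; width <- br$width
      for (s in seq_len(br$steps)) {
        ang <- ang + rnorm(1, 0, wobble)
        pos <- pos + 1.2 * c(sin(ang), cos(ang))
        if (sum((pos - fc)^2) > (fr - 3)^2) break
        mask <- stamp_disk(mask, pos[1], pos[2], max(width / 2, 0.6), H, W)
        width <- width * 0.9975
        if (width < 0.9) break
        if (br$depth < 3L && runif(1) < 0.015) {
          queue <- c(queue, list(list(pos = pos,
                                      ang = ang + sample(c(-1, 1), 1) *
                                        runif(1, 0.5, 1.0),
                                      width = width * 0.75,
                                      depth = br$depth + 1L,
                                      steps = round(br$steps * 0.6))))
        }
      }
    }
    vmask <- mask * 1

    base <- c(0.78, 0.42, 0.22)
    vignette <- 1 - 0.45 * dist2 / fr^2
    tex <- coarse_noise(H, W, grid = c(8L, 8L), sd = 0.04)
    image <- array(0, c(H, W, 3))
    for (c in 1:3)
      image[, , c] <- fov * (base[c] * vignette + tex - 0.30 * vmask) +
        (1 - fov) * 0.02
    image <- image + array(rnorm(H * W * 3, sd = noise_sd), c(H, W, 3))
    list(image = clip01(image), mask = vmask, fov = fov)
  })
}

#' Synthetic multi-modal brain-tumor volume phantom
#'
#' Four pseudo-modalities (T1, T1Gd, T2, FLAIR) with correlated noise
#' over an elliptical brain region, plus a bright irregular tumor blob
#' occupying a contiguous slab of axial slices; integer labels mark the
#' blob exactly.
#'
#' @param size `(height, width, slices)` of the volume.
#' @inheritParams make_lesion
#' @return A [volume_case()].
#' @export
make_tumor_volume <- function(size = c(240L, 240L, 31L),
                              difficulty = "easy", seed = 1L) {
  difficulty <- difficulty_levels(difficulty)
  H <- size[1]; W <- size[2]; S <- size[3]
  noise_sd <- if (difficulty == "easy") 0.02 else 0.05
  amp <- if (difficulty == "easy") 0.10 else 0.22
  with_seed(seed, {
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    brain <- ((rr - H / 2)^2 / (0.42 * H)^2 +
              (cc - W / 2)^2 / (0.36 * W)^2) <= 1

    slab_len <- max(3L, round(0.4 * S))
    s0 <- sample(seq(2L, max(2L, S - slab_len - 1L)), 1)
    slab <- s0:(s0 + slab_len - 1L)
    mid <- mean(slab)
    cy <- H * runif(1, 0.38, 0.62)
    cx <- W * runif(1, 0.38, 0.62)
    base_r <- 0.13 * min(H, W) * runif(1, 0.9, 1.15)
    theta <- atan2(rr - cy, cc - cx)
    rbound <- boundary_radius(theta, 1, amp)     # unit shape, shared by slices

    labels <- array(0L, c(H, W, S))
    for (z in slab) {
      scale <- sqrt(pmax(1 - ((z - mid) / (slab_len / 2 + 0.5))^2, 0))
      if (scale <= 0) next
      d <- sqrt((rr - cy)^2 + (cc - cx)^2)
      labels[, , z] <- (d <= base_r * scale * rbound & brain) * 1L
    }

    tissue_base <- c(T1 = 0.55, T1Gd = 0.50, T2 = 0.42, FLAIR = 0.48)
    tumor_add <- c(T1 = -0.10, T1Gd = 0.30, T2 = 0.36, FLAIR = 0.40)
    shared <- array(rnorm(H * W * S, sd = noise_sd), c(H, W, S))
    modalities <- lapply(names(tissue_base), function(m) {
      tex <- coarse_noise(H, W, grid = c(7L, 7L), sd = 0.05)
      own <- array(rnorm(H * W * S, sd = noise_sd), c(H, W, S))
      vol <- array(0, c(H, W, S))
      for (z in seq_len(S)) {
        vol[, , z] <- brain * (tissue_base[m] + tex) +
          labels[, , z] * tumor_add[m]
      }
      clip01(vol + 0.6 * shared + 0.4 * own)
    })
    names(modalities) <- names(tissue_base)
    volume_case(modalities, labels)
  })
}
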