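# Internal array plumbing shared across modules.

# Promote an image-like array to the canonical (H, W, C, N) tensor layout.
as_tensor <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected a matrix or array, got a vector")
  if (length(d) == 2L) d <- c(d, 1L, 1L)
  if (length(d) == 3L) d <- c(d, 1L)
  if (length(d) != 4L) stop("expected at most 4 dimensions (H, W, C, N)")
  dim(x) <- d
  x
}

# Drop trailing singleton channel/batch dims again.
drop_tensor <- function(x, ndim) {
  d <- dim(x)
  dim(x) <- d[seq_len(ndim)]
  x
}

# Run code under a fixed, named RNG (Mersenne-Twister / Inversion) and
# restore the caller's RNG state afterwards, so generators are stable
# test vectors that do not disturb the session.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

# Channel-wise concatenation of two (H, W, C, N) tensors.
chan_cat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(length(da) == 4L, all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Per-channel statistic of a (H, W, C, N) tensor: returns length-C vector.
chan_sum <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3], d[4])
  m <- colSums(x)                      # (C, N)
  if (is.matrix(m)) rowSums(m) else sum(m)
}

# Broadcast a length-C vector over a (H, W, C, N) tensor multiplicatively
# (op = "*") or additively (op = "+").  Relies on column-major recycling:
# the (H*W, C) pattern repeats identically for every batch member.
chan_bcast <- function(x, v, op = c("*", "+")) {
  op <- match.arg(op)
  d <- dim(x)
  r <- rep(v, each = d[1] * d[2])
  y <- if (op == "*") x * r else x + r
  dim(y) <- d
  y
}

is_binary_mask <- function(m) {
  is.numeric(m) && all(m %in% c(0, 1))
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
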