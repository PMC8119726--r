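#' Soft dice loss
#'
#' Overlap-based segmentation loss between a predicted foreground
#' probability map `sm` and a binary ground-truth mask `gt`:
#' \deqn{L = 1 - \frac{2\sum sm \cdot gt + \epsilon}
#'                 {\sum sm + \sum gt + \epsilon}}
#' with a small smoothing constant \eqn{\epsilon}.  `L` lies in
#' `[0, 1]`; for binary `sm` it equals `1 - DSC` up to smoothing.
#'
#' @param sm Predicted foreground probabilities in `[0, 1]`, any array
#'   shape.
#' @param gt Binary ground-truth mask of the same shape.
#' @param smooth Smoothing constant (default `1e-6`).
#' @return A scalar loss value.
#' @examples
#' gt <- matrix(c(1, 1, 0, 0), 2)
#' dice_loss(gt, gt)        # ~0
#' dice_loss(1 - gt, gt)    # ~1
#' @export
dice_loss <- function(sm, gt, smooth = 1e-6) {
  if (!identical(dim(sm), dim(gt)) && length(sm) != length(gt))
    stop("sm and gt must have the same shape")
  if (any(sm < 0 | sm > 1)) stop("sm must lie in [0, 1]")
  1 - (2 * sum(sm * gt) + smooth) / (sum(sm) + sum(gt) + smooth)
}

# Gradient of dice_loss w.r.t. sm.
dice_loss_grad <- function(sm, gt, smooth = 1e-6) {
  num <- 2 * sum(sm * gt) + smooth
  den <- sum(sm) + sum(gt) + smooth
  -(2 * gt * den - num) / den^2
}

#' Training schedule
#'
#' Adam optimization with an exponentially decaying learning rate: the
#' rate starts at `initial_learning_rate` and reaches
#' `initial_learning_rate / lr_reduction_factor` at the final epoch
#' (the canonical settings are 1e-4 reduced by a factor of 10 across
#' 100 epochs for 2-D image tasks, 30 epochs for the MR task).
#'
#' @param optimizer Only `"adam"` is supported.
#' @param initial_learning_rate Positive initial learning rate.
#' @param lr_reduction_factor Total reduction factor across training.
#' @param total_epochs Number of epochs.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed controlling shuffling (and hence the run).
#' @return An object of class `training_schedule`.
#' @export
training_schedule <- function(optimizer = "adam",
                              initial_learning_rate = 1e-4,
                              lr_reduction_factor = 10,
                              total_epochs = 100L, batch_size = 20L,
                              seed = 1L) {
  optimizer <- match.arg(optimizer, "adam")
  if (initial_learning_rate <= 0 || lr_reduction_factor <= 0)
    stop("learning-rate settings must be positive")
  if (total_epochs < 1 || batch_size < 1)
    stop("total_epochs and batch_size must be positive integers")
  structure(list(optimizer = optimizer,
                 initial_learning_rate = initial_learning_rate,
                 lr_reduction_factor = lr_reduction_factor,
                 total_epochs = as.integer(total_epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "training_schedule")
}

#' Learning rate at a given epoch
#'
#' @param schedule A [training_schedule()].
#' @param epoch Epoch index in `1..total_epochs`.
#' @return The per-epoch exponentially decayed learning rate;
#'   `lr(1) = initial` and `lr(total_epochs) = initial / factor`.
#' @export
schedule_lr <- function(schedule, epoch) {
  stopifnot(inherits(schedule, "training_schedule"))
  E <- schedule$total_epochs
  if (E == 1L) return(schedule$initial_learning_rate)
  schedule$initial_learning_rate *
    schedule$lr_reduction_factor^(-(epoch - 1) / (E - 1))
}

# ---- parameter flattening -------------------------------------------------

PARAM_FIELDS <- c("W", "b", "gamma", "beta")

flatten_params <- function(model) {
  out <- list()
  for (key in names(model$layers)) {
    lay <- model$layers[[key]]
    out[[paste0(key, ".W")]] <- lay$W
    if (!is.null(lay$b)) out[[paste0(key, ".b")]] <- lay$b
    if (!is.null(lay$bn)) {
      out[[paste0(key, ".gamma")]] <- lay$bn$gamma
      out[[paste0(key, ".beta")]] <- lay$bn$beta
    }
  }
  out
}

set_params <- function(model, params) {
  for (nm in names(params)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    key <- parts[1]; field <- parts[2]
    if (field == "W") model$layers[[key]]$W <- params[[nm]]
    else if (field == "b") model$layers[[key]]$b <- params[[nm]]
    else model$layers[[key]]$bn[[field]] <- params[[nm]]
  }
  model
}

flatten_grads <- function(grads) {
  out <- list()
  for (key in names(grads)) {
    g <- grads[[key]]
    for (f in PARAM_FIELDS)
      if (!is.null(g[[f]])) out[[paste0(key, ".", f)]] <- g[[f]]
  }
  out
}

# Stack a list of (H, W, C) images / (H, W) masks into tensors.
stack_images <- function(images) {
  if (is.list(images)) {
    d <- dim(as_tensor(images[[1]]))
    out <- array(0, c(d[1], d[2], d[3], length(images)))
    for (i in seq_along(images)) out[, , , i] <- as_tensor(images[[i]])
    out
  } else as_tensor(images)
}

stack_masks <- function(masks) {
  if (is.list(masks)) {
    d <- dim(masks[[1]])
    out <- array(0, c(d[1], d[2], length(masks)))
    for (i in seq_along(masks)) out[, , i] <- masks[[i]]
    out
  } else if (length(dim(masks)) == 2L) array(masks, c(dim(masks), 1L))
  else masks
}

#' Train a segmentation model with dice loss
#'
#' Mini-batch Adam optimization of the soft dice loss on the foreground
#' probability channel.  When a validation set is supplied the returned
#' model is the epoch snapshot with the lowest validation dice loss
#' (train = fit, validation = model choice, test = final report).  Runs
#' are reproducible: the schedule seed drives all shuffling.
#'
#' @param model A `cmm_model` from [build_cmm_net()] /
#'   [build_unet_baseline()].
#' @param images Training images: `(H, W, C, N)` array or list of
#'   `(H, W, C)` arrays sized for the model.
#' @param masks Matching binary masks: `(H, W, N)` array or list.
#' @param schedule A [training_schedule()].
#' @param val_images,val_masks Optional validation split in the same
#'   formats.
#' @param verbose Print per-epoch progress.
#' @return A list of class `cmm_fit`: `model` (selected weights),
#'   `history` (data frame with epoch, learning rate, mean training
#'   loss, and validation loss when available).
#' @export
train_segmenter <- function(model, images, masks, schedule,
                            val_images = NULL, val_masks = NULL,
                            verbose = FALSE) {
  stopifnot(inherits(model, "cmm_model"),
            inherits(schedule, "training_schedule"))
  if (length(images) == 0 || length(masks) == 0)
    stop("empty training dataset")
  x <- stack_images(images)
  y <- stack_masks(masks)
  n <- dim(x)[4]
  if (dim(y)[3] != n) stop("images and masks disagree in count")
  has_val <- !is.null(val_images)
  if (has_val) {
    vx <- stack_images(val_images)
    vy <- stack_masks(val_masks)
  }
  opt <- adam_init()
  best <- list(loss = Inf, model = model)
  hist <- data.frame(epoch = integer(), lr = numeric(), loss = numeric(),
                     val_loss = numeric())
  with_seed(schedule$seed, {
    for (epoch in seq_len(schedule$total_epochs)) {
      lr <- schedule_lr(schedule, epoch)
      ord <- sample.int(n)
      starts <- seq(1, n, by = schedule$batch_size)
      losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        take <- ord[starts[bi]:min(starts[bi] + schedule$batch_size - 1, n)]
        xb <- x[, , , take, drop = FALSE]
        yb <- y[, , take, drop = FALSE]
        fw <- net_forward(model, xb, training = TRUE)
        model <- fw$model
        p_fg <- as.numeric(fw$probs[, , 2L, ])
        yb <- as.numeric(yb)
        loss <- dice_loss(p_fg, yb)
        if (!is.finite(loss))
          stop("training diverged: non-finite dice loss at epoch ", epoch,
               ", batch ", bi)
        losses[bi] <- loss
        dprobs <- fw$probs * 0
        dprobs[, , 2L, ] <- dice_loss_grad(p_fg, yb)
        dlogits <- softmax_bwd(fw$probs, dprobs)
        up <- adam_update(flatten_params(model),
                          flatten_grads(net_backward(model, fw$caches,
                                                     dlogits)),
                          opt, lr)
        opt <- up$state
        model <- set_params(model, up$params)
      }
      vloss <- NA_real_
      if (has_val) {
        vp <- net_forward(model, vx, training = FALSE,
                          keep_caches = FALSE)$probs[, , 2L, ]
        vloss <- dice_loss(as.numeric(vp), as.numeric(vy))
        if (vloss < best$loss) best <- list(loss = vloss, model = model)
      }
      hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                     loss = mean(losses), val_loss = vloss))
      if (verbose)
        message(sprintf("epoch %3d  lr %.2e  loss %.4f  val %.4f",
                        epoch, lr, mean(losses), vloss))
    }
  })
  structure(list(model = if (has_val && is.finite(best$loss)) best$model
                         else model,
                 history = hist),
            class = "cmm_fit")
}
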