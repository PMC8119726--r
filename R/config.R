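#' Preset run configurations
#'
#' Shipped presets bundle a network configuration, a training schedule
#' and an IR mode per task:
#' \describe{
#'   \item{`isic2017`}{dermoscopy lesions: 192 x 256 inputs, PPM
#'     bottleneck 64, max pyramid scale 64, dilation rates 6/5/4/3 and
#'     4/5/6, 100 epochs, batch 20, IR with OR across views and AND
#'     across RGB/LAB/SV.}
#'   \item{`drive`}{retinal vessels: 128 x 128 patches, PPM bottleneck
#'     128, max scale 32, dilation rate 1 everywhere (small receptive
#'     fields suit thin vessels), 100 epochs, batch 20, OR-only IR.}
#'   \item{`brats2018`}{whole-tumor MR slices: 192 x 192 x 3 (T2,
#'     FLAIR, T1Gd), PPM bottleneck 64, max scale 48, 30 epochs,
#'     batch 5, IR off (it degrades this task).}
#'   \item{`phantom`}{desk-scale lesion phantoms: 48 x 64 inputs,
#'     reduced widths 8/16/32/64, bottleneck 8, pyramid 12/4/2/1,
#'     dilation rates scaled to the smaller input (2/2/1/1 and 1/2/2),
#'     12 epochs, batch 5, learning rate 3e-3.}
#' }
#'
#' @param name One of `"isic2017"`, `"drive"`, `"brats2018"`,
#'   `"phantom"`.
#' @param seed Integer seed stored in the configuration.
#' @return A `run_config` object.
#' @export
preset_config <- function(name = c("isic2017", "drive", "brats2018",
                                   "phantom"), seed = 1L) {
  name <- match.arg(name)
  cfg <- switch(name,
    isic2017 = run_config(
      task = "dermoscopy",
      network = network_config(192L, 256L, 3L, ppm_bottleneck_channels = 64L,
                               ppm_max_scale = 64L),
      schedule = training_schedule(total_epochs = 100L, batch_size = 20L,
                                   seed = seed),
      ir = "or_and_colorspaces", seed = seed),
    drive = run_config(
      task = "fundus",
      network = network_config(128L, 128L, 3L, ppm_bottleneck_channels = 128L,
                               ppm_max_scale = 32L,
                               encoder_dilation_rates = rep(1L, 4),
                               decoder_dilation_rates = rep(1L, 3)),
      schedule = training_schedule(total_epochs = 100L, batch_size = 20L,
                                   seed = seed),
      ir = "or_only", seed = seed),
    brats2018 = run_config(
      task = "brain",
      network = network_config(192L, 192L, 3L, ppm_bottleneck_channels = 64L,
                               ppm_max_scale = 48L),
      schedule = training_schedule(total_epochs = 30L, batch_size = 5L,
                                   seed = seed),
      ir = "off", seed = seed),
    phantom = run_config(
      task = "phantom",
      network = network_config(48L, 64L, 3L,
                               encoder_channels = c(8L, 16L, 32L, 64L),
                               ppm_bottleneck_channels = 8L,
                               ppm_max_scale = 12L,
                               ppm_pooled_sizes = c(12L, 4L, 2L, 1L),
                               encoder_dilation_rates = c(2L, 2L, 1L, 1L),
                               decoder_dilation_rates = c(1L, 2L, 2L)),
      schedule = training_schedule(initial_learning_rate = 3e-3,
                                   total_epochs = 12L, batch_size = 5L,
                                   seed = seed),
      ir = "or_only", seed = seed))
  cfg
}

RUN_CONFIG_KEYS <- c("task", "network", "schedule", "ir", "paths", "seed")

#' Run configuration
#'
#' Binds a task, a [network_config()], a [training_schedule()], an IR
#' mode and I/O paths into one serializable record.
#'
#' @param task One of `"dermoscopy"`, `"fundus"`, `"brain"`,
#'   `"phantom"`.
#' @param network A [network_config()].
#' @param schedule A [training_schedule()].
#' @param ir One of `"off"`, `"or_only"`, `"or_and_colorspaces"`.
#' @param paths Named list of input/output locations (free-form; the
#'   CLI uses `data_dir` and `out_dir`).
#' @param seed Integer seed.
#' @return A `run_config` object.
#' @export
run_config <- function(task = c("dermoscopy", "fundus", "brain", "phantom"),
                       network = network_config(),
                       schedule = training_schedule(),
                       ir = c("off", "or_only", "or_and_colorspaces"),
                       paths = list(), seed = 1L) {
  task <- match.arg(task)
  ir <- match.arg(ir)
  stopifnot(inherits(network, "network_config"),
            inherits(schedule, "training_schedule"))
  structure(list(task = task, network = network, schedule = schedule,
                 ir = ir, paths = paths, seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration file
#'
#' Configurations round-trip through YAML (`.yml`/`.yaml`) or JSON
#' (`.json`).  Unknown keys at the top level or inside the `network` /
#' `schedule` blocks are rejected.
#'
#' @param path Configuration file path.
#' @param config A `run_config`.
#' @return `read_run_config` returns a validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  extra <- setdiff(names(raw), RUN_CONFIG_KEYS)
  if (length(extra) > 0)
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  check_block <- function(block, fn, label) {
    if (is.null(block)) return(list())
    extra <- setdiff(names(block), names(formals(fn)))
    if (length(extra) > 0)
      stop("unknown ", label, " keys: ", paste(extra, collapse = ", "))
    block
  }
  net <- do.call(network_config, check_block(raw$network, network_config,
                                             "network"))
  sched <- do.call(training_schedule, check_block(raw$schedule,
                                                  training_schedule,
                                                  "schedule"))
  run_config(task = raw$task %||% "phantom", network = net,
             schedule = sched, ir = raw$ir %||% "off",
             paths = raw$paths %||% list(), seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- list(task = config$task,
                network = unclass(config$network),
                schedule = unclass(config$schedule),
                ir = config$ir, paths = config$paths, seed = config$seed)
  if (grepl("\\.json$", path))
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(plain, path)
  invisible(path)
}
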