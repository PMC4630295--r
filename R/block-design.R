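#' Block-design description of an on/off stimulus protocol
#'
#' A block design labels every sample of a run with its stimulus condition.
#' The default is the alternating off/on structure used throughout the
#' simulation machinery: `n_blocks` blocks of `block_duration` seconds each,
#' sampled every `sample_interval` seconds, starting with an "off" block.
#' A hemodynamic delay (seconds) can be attached; it is applied as a backward
#' shift of the condition labels when partitioning samples (see
#' [design_partition()]).
#'
#' @param n_blocks Number of blocks (default 14).
#' @param block_duration Duration of one block in seconds (default 16).
#' @param sample_interval Sampling interval in seconds (1 for single-voxel
#'   simulation; use the TR, e.g. 2, for volume time series).
#' @param hemodynamic_delay Hemodynamic delay in seconds (default 0). Rounded
#'   to the nearest whole number of samples when applied.
#' @param conditions Character vector of condition names cycled over blocks
#'   (default `c("off", "on")`, i.e. alternating starting with "off"). May be
#'   any length for multi-condition designs.
#'
#' @return A `block_design` object: a list with the above fields plus
#'   `labels`, the per-sample condition tag, and `n_timepoints`.
#' @export
#' @examples
#' d <- block_design()
#' d$n_timepoints  # 14 blocks x 16 s at 1 s sampling = 224
block_design <- function(n_blocks = 14, block_duration = 16,
                         sample_interval = 1, hemodynamic_delay = 0,
                         conditions = c("off", "on")) {
  if (n_blocks < 1 || block_duration <= 0 || sample_interval <= 0) {
    stop_config("`n_blocks`, `block_duration` and `sample_interval` must be positive.")
  }
  if (hemodynamic_delay < 0) {
    stop_config("`hemodynamic_delay` must be non-negative.")
  }
  spb <- block_duration / sample_interval
  if (abs(spb - round(spb)) > 1e-9) {
    stop_config("`block_duration` must be a whole number of samples.")
  }
  spb <- as.integer(round(spb))
  block_labels <- rep_len(conditions, n_blocks)
  labels <- rep(block_labels, each = spb)
  structure(
    list(
      n_blocks = as.integer(n_blocks),
      block_duration = block_duration,
      sample_interval = sample_interval,
      hemodynamic_delay = hemodynamic_delay,
      conditions = conditions,
      labels = labels,
      n_timepoints = length(labels)
    ),
    class = "block_design"
  )
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf(
    "<block_design> %d blocks x %g s @ %g s sampling (%d timepoints), delay %g s\n",
    x$n_blocks, x$block_duration, x$sample_interval, x$n_timepoints,
    x$hemodynamic_delay
  ))
  cat("conditions:", paste(x$conditions, collapse = "/"), "\n")
  invisible(x)
}

#' Partition sample indices by condition, honouring the hemodynamic delay
#'
#' The delay is applied as a backward shift of the condition labels by
#' `round(delay / sample_interval)` samples: sample `t` is attributed to the
#' condition presented at time `t - delay`, and the leading samples that have
#' no shifted label are discarded.
#'
#' @param design A [block_design()].
#' @param n_timepoints Length of the series being partitioned (defaults to the
#'   design's own length).
#' @param delay Delay in seconds; defaults to the design's `hemodynamic_delay`.
#' @return A named list of integer index vectors, one per condition present.
#' @export
design_partition <- function(design, n_timepoints = design$n_timepoints,
                             delay = design$hemodynamic_delay) {
  if (n_timepoints != design$n_timepoints) {
    stop_data(sprintf(
      "series has %d timepoints but the design labels %d",
      n_timepoints, design$n_timepoints
    ))
  }
  d <- as.integer(round(delay / design$sample_interval))
  if (d >= n_timepoints) stop_insufficient("delay shift discards the whole run")
  idx <- seq.int(d + 1L, n_timepoints)
  lab <- design$labels[seq_len(n_timepoints - d)]
  split(idx, factor(lab, levels = unique(design$labels)))
}

#' Serialize a block design to, or read one from, a YAML or JSON file
#'
#' The on-disk form records `n_blocks`, `block_duration`, `sample_interval`,
#' `hemodynamic_delay` and the condition order; format is chosen from the
#' file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param design A [block_design()].
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_block_design()` returns `path` invisibly;
#'   `read_block_design()` returns a [block_design()].
#' @export
write_block_design <- function(design, path) {
  fields <- design[c("n_blocks", "block_duration", "sample_interval",
                     "hemodynamic_delay", "conditions")]
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(fields, path)
  } else if (ext == "json") {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop_config("unsupported design file extension: ", ext)
  }
  invisible(path)
}

#' @rdname write_block_design
#' @param path File path to read.
#' @export
read_block_design <- function(path) {
  if (!file.exists(path)) stop_data("design file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  fields <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_config("unsupported design file extension: ", ext)
  }
  block_design(
    n_blocks = fields$n_blocks,
    block_duration = fields$block_duration,
    sample_interval = fields$sample_interval,
    hemodynamic_delay = fields$hemodynamic_delay %||% 0,
    conditions = fields$conditions %||% c("off", "on")
  )
}
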