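#' Write a rendered scene to disk
#'
#' One multi-page 16-bit TIFF per channel (pages = time frames), a label-map
#' TIFF, and a JSON sidecar carrying the time grid, gate timing, channel
#' list, noise parameters, seed and label legend — everything needed to
#' recompute DOCI images from the files alone. Counts are clipped to the
#' 16-bit range on write.
#'
#' @param dir output directory (created if needed)
#' @param stacks named list of [TimeResolvedStack-class]
#' @param labelMap integer label matrix
#' @param legend named integer vector (tissue to code)
#' @param spec the [PhantomSpec-class] the scene came from (for noise/seed)
#' @return invisibly, the sidecar path
#' @seealso [readScene()]
#' @export
writeScene <- function(dir, stacks, labelMap, legend, spec) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  timing <- stacks[[1L]]@timing
  for (st in stacks) {
    # counts are rounded to integers; +0.5 guards against the truncating
    # quantiser in the TIFF writer
    pages <- lapply(seq_len(dim(st@frames)[1L]), function(i)
      (round(pmin(st@frames[i, , ], 65535)) + 0.5) / 65535)
    tiff::writeTIFF(pages, file.path(dir, sprintf("stack_%gnm.tif", st@channel)),
                    bits.per.sample = 16L)
  }
  tiff::writeTIFF((labelMap + 0.5) / 65535, file.path(dir, "labels.tif"),
                  bits.per.sample = 16L)
  sidecar <- list(
    channels = vapply(stacks, channel, numeric(1L)),
    time_grid = stacks[[1L]]@timeGrid,
    timing = list(
      pulse_on = timing@pulseOn, pulse_off = timing@pulseOff,
      steady_gate = timing@steadyGate, decay_gate = timing@decayGate,
      sample_dt = timing@sampleDt
    ),
    noise = spec@noise,
    seed = spec@seed,
    legend = as.list(legend)
  )
  path <- file.path(dir, "sidecar.json")
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scene written by [writeScene()]
#'
#' @param dir directory containing the stack TIFFs, labels.tif and
#'   sidecar.json
#' @return list with `stacks` (named list of [TimeResolvedStack-class]),
#'   `labelMap`, `legend`, `timing` ([PulseTiming-class]) and `meta` (the
#'   parsed sidecar)
#' @export
readScene <- function(dir) {
  path <- file.path(dir, "sidecar.json")
  if (!file.exists(path)) stop("no sidecar.json in ", dir)
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  timing <- PulseTiming(
    pulseOn = meta$timing$pulse_on, pulseOff = meta$timing$pulse_off,
    steadyGate = meta$timing$steady_gate, decayGate = meta$timing$decay_gate,
    sampleDt = meta$timing$sample_dt
  )
  stacks <- list()
  for (ch in meta$channels) {
    pages <- tiff::readTIFF(file.path(dir, sprintf("stack_%gnm.tif", ch)),
                            all = TRUE)
    frames <- array(0, dim = c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
    for (i in seq_along(pages)) frames[i, , ] <- round(pages[[i]] * 65535)
    stacks[[as.character(ch)]] <- new("TimeResolvedStack",
      channel = as.numeric(ch), timeGrid = as.numeric(meta$time_grid),
      frames = frames, timing = timing
    )
  }
  labelMap <- round(tiff::readTIFF(file.path(dir, "labels.tif")) * 65535)
  storage.mode(labelMap) <- "integer"
  legend <- vapply(meta$legend, as.integer, integer(1L))
  list(stacks = stacks, labelMap = labelMap, legend = legend,
       timing = timing, meta = meta)
}

#' Write DOCI images to disk
#'
#' Per channel: the DOCI values as a 32-bit float TIFF and the validity mask
#' as an 8-bit TIFF, plus a small JSON index.
#'
#' @param dir output directory
#' @param dociImages named list of [DOCIImage-class]
#' @return invisibly, the index path
#' @seealso [readDOCIImages()]
#' @export
writeDOCIImages <- function(dir, dociImages) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scales <- numeric(length(dociImages))
  for (i in seq_along(dociImages)) {
    img <- dociImages[[i]]
    # the float TIFF writer only stores [0, 1]; scale down and record the
    # factor in the sidecar
    scales[i] <- max(1, img@values)
    tiff::writeTIFF(img@values / scales[i],
                    file.path(dir, sprintf("doci_%gnm.tif", img@channel)),
                    bits.per.sample = 32L)
    tiff::writeTIFF(img@validMask * 1, file.path(dir, sprintf("mask_%gnm.tif", img@channel)),
                    bits.per.sample = 8L)
  }
  idx <- list(
    channels = vapply(dociImages, channel, numeric(1L)),
    threshold = vapply(dociImages, function(x) x@thresholdUsed, numeric(1L)),
    value_scale = scales
  )
  path <- file.path(dir, "doci_index.json")
  jsonlite::write_json(idx, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read DOCI images written by [writeDOCIImages()]
#'
#' @param dir directory containing doci_*nm.tif, mask_*nm.tif, doci_index.json
#' @return named list of [DOCIImage-class]
#' @export
readDOCIImages <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "doci_index.json"),
                             simplifyVector = TRUE)
  out <- list()
  for (i in seq_along(idx$channels)) {
    ch <- idx$channels[i]
    scale <- if (!is.null(idx$value_scale)) idx$value_scale[i] else 1
    values <- tiff::readTIFF(file.path(dir, sprintf("doci_%gnm.tif", ch))) * scale
    mask <- tiff::readTIFF(file.path(dir, sprintf("mask_%gnm.tif", ch))) > 0.5
    values[!mask] <- 0
    out[[as.character(ch)]] <- new("DOCIImage",
      channel = as.numeric(ch), values = values, validMask = mask,
      thresholdUsed = idx$threshold[i]
    )
  }
  out
}

#' Default run configuration
#'
#' All tunables of the pipeline in one nested list: channels, pulse/gate
#' timing (ns), noise parameters, the per-tissue lifetime/brightness table,
#' the reference tissue, the PNI caller settings (`k`, `min_run`,
#' `calling_channel`) and the seed. Every field can be overridden from a YAML
#' file via [loadConfig()].
#'
#' @return nested configuration list
#' @export
defaultConfig <- function() {
  list(
    channels = dociChannels(),
    timing = list(pulse_on = 0, pulse_off = 100,
                  steady_gate = c(50, 100), decay_gate = c(100, 200),
                  sample_dt = 0.5),
    noise = list(photon_scale = 1e4, read_sigma = 1),
    tissues = list(
      tumor = list(lifetime = 1.5, brightness = 1),
      pni_nerve = list(lifetime = 1.8, brightness = 1),
      muscle = list(lifetime = 2.5, brightness = 1),
      nerve = list(lifetime = 4.0, brightness = 1),
      dat = list(lifetime = 5.0, brightness = 1),
      adipose = list(lifetime = 6.0, brightness = 1)
    ),
    reference_tissue = "tumor",
    pni = list(k = 3, min_run = 5, calling_channel = 465),
    seed = 1
  )
}

# recursive merge of user config over defaults; unknown keys are an error
.mergeConfig <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key ", full, " must be a mapping")
      defaults[[key]] <- .mergeConfig(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

.validateConfig <- function(config) {
  # canonicalise scalar types (YAML reads whole numbers as integers)
  config$channels <- as.numeric(unlist(config$channels))
  config$timing <- lapply(config$timing, as.numeric)
  config$noise <- lapply(config$noise, as.numeric)
  config$tissues <- lapply(config$tissues, function(tc) lapply(tc, as.numeric))
  config$pni <- lapply(config$pni, as.numeric)
  config$seed <- as.numeric(config$seed)
  # constructing the timing object runs its validity checks
  timingFromConfig(config)
  if (config$noise$photon_scale <= 0)
    stop("configuration key noise.photon_scale must be > 0")
  if (config$noise$read_sigma < 0)
    stop("configuration key noise.read_sigma must be >= 0")
  for (nm in names(config$tissues)) {
    tc <- config$tissues[[nm]]
    if (!is.null(tc$lifetime) && any(tc$lifetime < 0))
      stop("configuration key tissues.", nm, ".lifetime must be >= 0")
  }
  if (config$pni$min_run < 1)
    stop("configuration key pni.min_run must be >= 1")
  invisible(config)
}

#' Load a YAML run configuration
#'
#' Reads a (possibly partial) YAML file, rejects unknown keys by name,
#' injects defaults for absent keys, and validates ranges. An empty file
#' yields the full default configuration. [saveConfig()] always writes the
#' fully resolved configuration, so save-then-load is the identity on the
#' value level.
#'
#' @param path YAML file
#' @return validated configuration list
#' @export
loadConfig <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  .validateConfig(.mergeConfig(defaultConfig(), user))
}

#' Save a run configuration as YAML
#'
#' @param config configuration list (defaults are filled in and recorded
#'   explicitly before writing)
#' @param path output YAML file
#' @return invisibly, `path`
#' @export
saveConfig <- function(config, path) {
  config <- .validateConfig(.mergeConfig(defaultConfig(), config))
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build pipeline objects from a configuration
#'
#' `timingFromConfig()` returns the [PulseTiming-class];
#' `tissuesFromConfig()` the named [TissueClass-class] list (plus
#' background).
#'
#' @param config configuration list as from [loadConfig()]
#' @return see above
#' @export
timingFromConfig <- function(config) {
  PulseTiming(
    pulseOn = config$timing$pulse_on, pulseOff = config$timing$pulse_off,
    steadyGate = unlist(config$timing$steady_gate),
    decayGate = unlist(config$timing$decay_gate),
    sampleDt = config$timing$sample_dt
  )
}

#' @rdname timingFromConfig
#' @export
tissuesFromConfig <- function(config) {
  lifetimes <- vapply(config$tissues, function(tc) tc$lifetime, numeric(1L))
  tissues <- defaultTissues(lifetimes = lifetimes)
  for (nm in names(config$tissues)) {
    b <- config$tissues[[nm]]$brightness
    if (!is.null(b)) tissues[[nm]]@brightness <- as.numeric(b)
  }
  tissues
}
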