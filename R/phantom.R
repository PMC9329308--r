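#' Render the tissue label map of a phantom scene
#'
#' Rasterises the scene's region list into an integer label image. Purely
#' deterministic: later regions overwrite earlier ones and unassigned pixels
#' stay background (code 0). A `nerve_band` region is labelled `nerve` up to
#' (but excluding) `transitionCol` and `pni_nerve` from `transitionCol`
#' onwards; a band with `transitionCol = NA` is a uniform control nerve.
#'
#' @param spec a [PhantomSpec-class]
#' @return list with `map` (integer matrix, rows x cols) and `legend` (named
#'   integer vector, tissue name to code; background is 0)
#' @examples
#' spec <- PhantomSpec(c(8, 8), channels = 465,
#'   regions = list(list(tissue = "muscle", shape = "rectangle",
#'                       rows = c(0, 7), cols = c(0, 7))))
#' renderLabelMap(spec)$legend
#' @export
renderLabelMap <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  nr <- spec@shape[1L]
  nc <- spec@shape[2L]
  map <- matrix(0L, nr, nc)
  legend <- c(background = 0L)
  code <- function(tissue) {
    if (!tissue %in% names(legend)) {
      legend[[tissue]] <<- max(legend) + 1L
    }
    legend[[tissue]]
  }
  for (reg in spec@regions) {
    if (reg$shape == "rectangle") {
      map[(reg$rows[1L]:reg$rows[2L]) + 1L, (reg$cols[1L]:reg$cols[2L]) + 1L] <-
        code(reg$tissue)
    } else if (reg$shape == "ellipse") {
      rows <- matrix(0:(nr - 1L), nr, nc)
      cols <- matrix(0:(nc - 1L), nr, nc, byrow = TRUE)
      inside <- ((rows - reg$center[1L]) / reg$radii[1L])^2 +
        ((cols - reg$center[2L]) / reg$radii[2L])^2 <= 1
      map[inside] <- code(reg$tissue)
    } else if (reg$shape == "nerve_band") {
      ri <- (reg$rows[1L]:reg$rows[2L]) + 1L
      ci <- (reg$cols[1L]:reg$cols[2L]) + 1L
      tc <- reg$transitionCol
      if (is.null(tc) || is.na(tc)) {
        map[ri, ci] <- code("nerve")
      } else {
        healthy <- ci[ci - 1L < tc]
        invaded <- ci[ci - 1L >= tc]
        if (length(healthy)) map[ri, healthy] <- code("nerve")
        if (length(invaded)) map[ri, invaded] <- code("pni_nerve")
      }
    }
  }
  list(map = map, legend = legend)
}

# per-channel RNG substream seeds, derived once from the scene seed so that
# rendering a channel subset reproduces the full-render values
.channelSeeds <- function(seed, channels) {
  withr_state <- .Random.seed.exists()
  on.exit(.restoreRandomSeed(withr_state), add = TRUE)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(channels))
  names(seeds) <- as.character(channels)
  seeds
}

.Random.seed.exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restoreRandomSeed <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Render noisy time-resolved stacks for a phantom scene
#'
#' Forward model of the imaging: each pixel's noiseless trace is the
#' square-pulse decay curve of its tissue class at that channel times the
#' class brightness; detected counts are
#' `Poisson(photonScale * trace) + Gaussian(0, readSigma)`, clipped at zero.
#' With `photonScale = Inf` (or `noiseless = TRUE`) the expected counts are
#' returned exactly — the infinite-photon limit. Channels draw from
#' independent RNG substreams derived from the scene seed, so rendering a
#' subset of channels reproduces the corresponding full-render stacks and the
#' same spec and seed give bit-identical output.
#'
#' @param spec a [PhantomSpec-class]
#' @param tissues named list of [TissueClass-class] covering every label in
#'   the scene (see [defaultTissues()])
#' @param timing a [PulseTiming-class]; defaults to [PulseTiming()]
#' @param channels channels to render (default: all in `spec`); must be a
#'   subset of `spec@channels`
#' @param noiseless render expected counts with no shot or read noise
#' @return named list of [TimeResolvedStack-class], keyed by channel (nm)
#' @examples
#' sc <- defaultScene("pni", seed = 7)
#' st <- renderStacks(sc$spec, sc$tissues, channels = 465)
#' @export
renderStacks <- function(spec, tissues, timing = PulseTiming(),
                         channels = NULL, noiseless = FALSE) {
  stopifnot(is(spec, "PhantomSpec"))
  lm <- renderLabelMap(spec)
  if (is.null(channels)) channels <- spec@channels
  if (!all(channels %in% spec@channels))
    stop("channels must be a subset of the spec's channel list")
  tg <- defaultTimeGrid(timing)
  nT <- length(tg)
  nr <- spec@shape[1L]
  nc <- spec@shape[2L]
  scale <- spec@noise$photonScale
  readSigma <- spec@noise$readSigma
  if (noiseless || is.infinite(scale)) {
    noiseless <- TRUE
    scale <- 1
  }
  present <- names(lm$legend)
  missing <- setdiff(present, names(tissues))
  if (length(missing))
    stop("no TissueClass supplied for label(s): ", paste(missing, collapse = ", "))
  seeds <- .channelSeeds(spec@seed, spec@channels)
  prevSeed <- .Random.seed.exists()
  on.exit(.restoreRandomSeed(prevSeed), add = TRUE)
  stacks <- vector("list", length(channels))
  names(stacks) <- as.character(channels)
  for (ch in channels) {
    M <- matrix(0, nT, nr * nc)
    for (tissue in present) {
      tc <- tissues[[tissue]]
      if (tc@brightness == 0) next
      comp <- tissueComponents(tc, ch)
      idx <- which(lm$map == lm$legend[[tissue]])
      if (!length(idx)) next
      tr <- decayTrace(comp, timing, tg) * tc@brightness * scale
      M[, idx] <- tr
    }
    if (!noiseless) {
      set.seed(seeds[[as.character(ch)]])
      counts <- rpois(length(M), M)
      if (readSigma > 0) counts <- counts + rnorm(length(M), 0, readSigma)
      M <- matrix(pmax(counts, 0), nT, nr * nc)
    }
    stacks[[as.character(ch)]] <- new("TimeResolvedStack",
      channel = as.numeric(ch), timeGrid = tg,
      frames = array(M, dim = c(nT, nr, nc)), timing = timing
    )
  }
  stacks
}

#' Default phantom scenes
#'
#' Two canned scenes covering the package's two analyses.
#'
#' `"margin"`: a grid of square tissue blocks on dark background, cycling
#' through tumor, muscle, adipose and DAT so each class appears `nInstances`
#' times (default 15, mirroring 15 tumors); every block is 15 x 15 px, so each
#' ROI instance holds 225 pixels.
#'
#' `"pni"`: two parallel horizontal nerve bands — a control band of uniform
#' healthy nerve and a test band whose label switches to `pni_nerve` at
#' `transitionCol` (default 32) — mirroring the bilateral sciatic design with
#' one PBS-injected and one tumor-injected nerve.
#'
#' @param kind `"margin"` or `"pni"`
#' @param seed integer RNG seed stored in the spec
#' @param nInstances margin scene: ROI instances per tissue class
#' @param photonScale,readSigma noise parameters stored in the spec
#' @param transitionCol pni scene: 0-based column where invasion starts
#' @param channels emission channels (default all nine)
#' @return list with `spec` ([PhantomSpec-class]) and `tissues` (named list of
#'   [TissueClass-class])
#' @examples
#' sc <- defaultScene("margin", seed = 1)
#' table(renderLabelMap(sc$spec)$map)
#' @export
defaultScene <- function(kind = c("margin", "pni"), seed = 1L,
                         nInstances = 15L, photonScale = 1e4, readSigma = 1,
                         transitionCol = 32L, channels = dociChannels()) {
  kind <- match.arg(kind)
  tissues <- defaultTissues()
  noise <- list(photonScale = photonScale, readSigma = readSigma)
  if (kind == "margin") {
    classes <- c("tumor", "muscle", "adipose", "dat")
    nBlocks <- nInstances * length(classes)
    blockSide <- 15L
    gap <- 2L
    nCols <- ceiling(sqrt(nBlocks * 8 / 5))  # roughly 8:5 aspect
    nRows <- ceiling(nBlocks / nCols)
    shape <- c(
      nRows * blockSide + (nRows + 1L) * gap,
      nCols * blockSide + (nCols + 1L) * gap
    )
    regions <- vector("list", nBlocks)
    for (b in seq_len(nBlocks)) {
      r <- (b - 1L) %/% nCols
      cc <- (b - 1L) %% nCols
      r0 <- gap + r * (blockSide + gap)
      c0 <- gap + cc * (blockSide + gap)
      regions[[b]] <- list(
        tissue = classes[((b - 1L) %% length(classes)) + 1L],
        shape = "rectangle",
        rows = c(r0, r0 + blockSide - 1L),
        cols = c(c0, c0 + blockSide - 1L)
      )
    }
  } else {
    shape <- c(32L, 64L)
    regions <- list(
      list(tissue = "nerve", shape = "nerve_band",
           rows = c(4L, 11L), cols = c(0L, shape[2L] - 1L),
           transitionCol = NA_integer_),
      list(tissue = "nerve", shape = "nerve_band",
           rows = c(20L, 27L), cols = c(0L, shape[2L] - 1L),
           transitionCol = as.integer(transitionCol))
    )
  }
  spec <- PhantomSpec(shape, channels = channels, regions = regions,
                      noise = noise, seed = seed)
  list(spec = spec, tissues = tissues)
}

#' Geometry of the nerve bands in a scene
#'
#' Convenience extractor for the `nerve_band` regions of a phantom spec, in
#' the order they appear; used to feed [extractProfile()].
#'
#' @param spec a [PhantomSpec-class]
#' @return list of nerve_band region descriptors
#' @export
nerveBands <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  Filter(function(r) r$shape == "nerve_band", spec@regions)
}
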