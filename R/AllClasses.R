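#' @import methods
NULL

#' Excitation-pulse and gate timing
#'
#' Timing of the square excitation pulse and of the two integration gates used
#' to form a DOCI value: a steady-state gate inside the pulse plateau and a
#' decay gate after pulse turn-off. All times are in nanoseconds. Gates are
#' integration windows `[a, b]` on the sampled time grid; the steady gate must
#' end at or before `pulseOff` and the decay gate must start at or after
#' `pulseOff`.
#'
#' @slot pulseOn time at which the excitation pulse rises (ns)
#' @slot pulseOff time at which the excitation pulse ends (ns)
#' @slot steadyGate numeric(2), steady-state gate `[a, b]` within the pulse
#' @slot decayGate numeric(2), decay gate `[a, b]` after pulse turn-off
#' @slot sampleDt time-sampling step of simulated stacks (ns)
#' @seealso [PulseTiming()]
#' @exportClass PulseTiming
setClass("PulseTiming",
  representation(
    pulseOn = "numeric", pulseOff = "numeric",
    steadyGate = "numeric", decayGate = "numeric", sampleDt = "numeric"
  )
)

setValidity("PulseTiming", function(object) {
  msgs <- character()
  if (length(object@pulseOn) != 1L || length(object@pulseOff) != 1L)
    msgs <- c(msgs, "pulseOn and pulseOff must be scalars")
  else if (!(object@pulseOff > object@pulseOn))
    msgs <- c(msgs, "pulseOff must exceed pulseOn")
  for (nm in c("steadyGate", "decayGate")) {
    g <- slot(object, nm)
    if (length(g) != 2L || !(g[2L] > g[1L]))
      msgs <- c(msgs, sprintf("%s must be a non-empty interval c(a, b) with b > a", nm))
  }
  if (length(msgs) == 0L) {
    if (object@steadyGate[1L] < object@pulseOn)
      msgs <- c(msgs, "steadyGate must start at or after pulseOn")
    if (object@steadyGate[2L] > object@pulseOff)
      msgs <- c(msgs, "steadyGate must end at or before pulseOff")
    if (object@decayGate[1L] < object@pulseOff)
      msgs <- c(msgs, "decayGate must start at or after pulseOff")
  }
  if (length(object@sampleDt) != 1L || !(object@sampleDt > 0))
    msgs <- c(msgs, "sampleDt must be a positive scalar")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PulseTiming
#'
#' Defaults describe a 100 ns square pulse sampled at 0.5 ns, with the
#' steady-state gate over the second half of the plateau and a 100 ns decay
#' gate after turn-off. For nanosecond-scale endogenous fluorophores (NADH,
#' FAD, collagen) a 100 ns pulse reaches its plateau to better than 1e-6 and
#' the decay gate captures essentially the whole tail.
#'
#' @param pulseOn,pulseOff pulse rise/fall times (ns)
#' @param steadyGate,decayGate integration gates, each `c(a, b)` in ns
#' @param sampleDt sampling step (ns)
#' @return a [PulseTiming-class] object
#' @examples
#' PulseTiming()
#' PulseTiming(decayGate = c(100, 400), sampleDt = 0.1)
#' @export
PulseTiming <- function(pulseOn = 0, pulseOff = 100,
                        steadyGate = c(50, 100), decayGate = c(100, 200),
                        sampleDt = 0.5) {
  new("PulseTiming",
    pulseOn = as.numeric(pulseOn), pulseOff = as.numeric(pulseOff),
    steadyGate = as.numeric(steadyGate), decayGate = as.numeric(decayGate),
    sampleDt = as.numeric(sampleDt)
  )
}

setMethod("show", "PulseTiming", function(object) {
  cat(sprintf(
    "PulseTiming: pulse [%g, %g) ns, steady gate [%g, %g], decay gate [%g, %g], dt %g ns\n",
    object@pulseOn, object@pulseOff,
    object@steadyGate[1L], object@steadyGate[2L],
    object@decayGate[1L], object@decayGate[2L], object@sampleDt
  ))
})

#' Tissue decay/spectral parameters
#'
#' A tissue class is a named mixture of exponential decay components plus a
#' brightness (mean plateau photon count per pixel). Components default to
#' being identical at every emission channel; per-channel overrides are
#' possible so that spectral contrast between channels can be configured.
#'
#' @slot name tissue name (e.g. "tumor", "muscle", "nerve")
#' @slot components data.frame with columns `amplitude` and `lifetime` (ns),
#'   used for every channel without a specific override
#' @slot perChannel named list of component data.frames keyed by channel
#'   wavelength (as character, e.g. `"465"`), overriding `components`
#' @slot brightness mean plateau photon count per pixel (>= 0; 0 only for
#'   background)
#' @seealso [TissueClass()], [tissueComponents()], [defaultTissues()]
#' @exportClass TissueClass
setClass("TissueClass",
  representation(
    name = "character", components = "data.frame",
    perChannel = "list", brightness = "numeric"
  )
)

.validComponents <- function(components) {
  if (!is.data.frame(components) ||
      !all(c("amplitude", "lifetime") %in% names(components)))
    return("components must be a data.frame with columns amplitude, lifetime")
  if (nrow(components) < 1L)
    return("a decay mixture needs at least one component")
  if (any(!is.finite(components$amplitude)) || any(components$amplitude < 0))
    return("amplitudes must be finite and >= 0")
  if (any(!is.finite(components$lifetime)) || any(components$lifetime < 0))
    return("lifetimes must be finite and >= 0 ns")
  if (!any(components$amplitude > 0))
    return("a decay mixture needs at least one component with amplitude > 0")
  TRUE
}

setValidity("TissueClass", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "name must be a non-empty string")
  v <- .validComponents(object@components)
  if (!isTRUE(v) && object@name != "background") msgs <- c(msgs, v)
  for (ch in names(object@perChannel)) {
    v <- .validComponents(object@perChannel[[ch]])
    if (!isTRUE(v)) msgs <- c(msgs, sprintf("channel %s: %s", ch, v))
  }
  if (length(object@brightness) != 1L || !is.finite(object@brightness) ||
      object@brightness < 0)
    msgs <- c(msgs, "brightness must be a finite scalar >= 0")
  if (object@brightness == 0 && object@name != "background")
    msgs <- c(msgs, "brightness 0 is only allowed for the background class")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TissueClass
#'
#' @param name tissue name
#' @param components data.frame of decay components (`amplitude`, `lifetime`),
#'   or a single lifetime in ns (shorthand for one unit-amplitude component)
#' @param brightness mean plateau photon count per pixel
#' @param perChannel optional named list of per-channel component overrides;
#'   names are channel wavelengths in nm (coerced to character)
#' @return a [TissueClass-class] object
#' @examples
#' TissueClass("nerve", 4.0)
#' TissueClass("mix", data.frame(amplitude = c(2, 1), lifetime = c(3, 8)))
#' @export
TissueClass <- function(name, components, brightness = 1, perChannel = list()) {
  if (is.numeric(components))
    components <- data.frame(amplitude = 1, lifetime = as.numeric(components))
  if (length(perChannel)) names(perChannel) <- as.character(names(perChannel))
  new("TissueClass",
    name = name, components = components,
    perChannel = perChannel, brightness = as.numeric(brightness)
  )
}

setMethod("show", "TissueClass", function(object) {
  cat(sprintf(
    "TissueClass \"%s\": %d component(s), brightness %g, %d channel override(s)\n",
    object@name, nrow(object@components), object@brightness,
    length(object@perChannel)
  ))
})

#' Scene description for the phantom generator
#'
#' A phantom spec maps pixel regions to tissue names over a fixed frame,
#' together with the emission channel list, the camera noise parameters and
#' the RNG seed. Geometry uses 0-based pixel indices, row-major, origin at the
#' top-left; later regions overwrite earlier ones and unassigned pixels are
#' background.
#'
#' Each element of `regions` is a list with fields:
#' \describe{
#'   \item{tissue}{tissue name}
#'   \item{shape}{one of `"rectangle"`, `"ellipse"`, `"nerve_band"`}
#'   \item{rows, cols}{for rectangle / nerve_band: inclusive 0-based index
#'     ranges `c(from, to)`}
#'   \item{center, radii}{for ellipse: `c(row, col)` center and
#'     `c(row_radius, col_radius)` in pixels}
#'   \item{transitionCol}{nerve_band only: 0-based column at which the label
#'     switches from `nerve` to `pni_nerve`; `NA` for a uniform control band}
#' }
#'
#' @slot shape integer(2), rows x cols of the frame
#' @slot channels numeric vector of emission channel center wavelengths (nm)
#' @slot regions list of region descriptors (see Details)
#' @slot noise list with `photonScale` (photons per intensity unit; `Inf`
#'   renders noiseless expected counts) and `readSigma` (counts)
#' @slot seed integer RNG seed
#' @seealso [PhantomSpec()], [renderLabelMap()], [renderStacks()]
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    shape = "integer", channels = "numeric",
    regions = "list", noise = "list", seed = "integer"
  )
)

.regionExtent <- function(region) {
  if (region$shape == "ellipse") {
    rbind(
      rows = region$center[1L] + c(-1, 1) * region$radii[1L],
      cols = region$center[2L] + c(-1, 1) * region$radii[2L]
    )
  } else {
    rbind(rows = region$rows, cols = region$cols)
  }
}

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  if (length(object@shape) != 2L || any(object@shape < 1L))
    msgs <- c(msgs, "shape must be two positive integers (rows, cols)")
  if (length(object@channels) < 1L || anyDuplicated(object@channels))
    msgs <- c(msgs, "channels must be a non-empty list of distinct wavelengths")
  known <- c("tumor", "muscle", "adipose", "dat", "nerve", "pni_nerve", "background")
  for (i in seq_along(object@regions)) {
    reg <- object@regions[[i]]
    if (!all(c("tissue", "shape") %in% names(reg))) {
      msgs <- c(msgs, sprintf("region %d lacks tissue/shape", i)); next
    }
    if (!reg$tissue %in% known)
      msgs <- c(msgs, sprintf("region %d: unknown tissue \"%s\"", i, reg$tissue))
    if (!reg$shape %in% c("rectangle", "ellipse", "nerve_band")) {
      msgs <- c(msgs, sprintf("region %d: unknown shape \"%s\"", i, reg$shape)); next
    }
    ext <- .regionExtent(reg)
    if (ext["rows", 1L] < 0 || ext["cols", 1L] < 0 ||
        ext["rows", 2L] > object@shape[1L] - 1L ||
        ext["cols", 2L] > object@shape[2L] - 1L)
      msgs <- c(msgs, sprintf("region %d lies outside the %dx%d frame", i,
                              object@shape[1L], object@shape[2L]))
    if (reg$shape == "nerve_band" && !is.null(reg$transitionCol) &&
        !is.na(reg$transitionCol) &&
        (reg$transitionCol < reg$cols[1L] || reg$transitionCol > reg$cols[2L]))
      msgs <- c(msgs, sprintf("region %d: transitionCol %d outside band columns [%d, %d]",
                              i, reg$transitionCol, reg$cols[1L], reg$cols[2L]))
  }
  if (!all(c("photonScale", "readSigma") %in% names(object@noise)))
    msgs <- c(msgs, "noise must contain photonScale and readSigma")
  else if (!(object@noise$photonScale > 0) || object@noise$readSigma < 0)
    msgs <- c(msgs, "photonScale must be > 0 and readSigma >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PhantomSpec
#'
#' @param shape frame size `c(rows, cols)` in pixels
#' @param channels emission channel wavelengths (nm); defaults to the nine
#'   band-pass channels used throughout the package
#' @param regions list of region descriptors, see [PhantomSpec-class]
#' @param noise list with `photonScale` and `readSigma`
#' @param seed integer RNG seed
#' @return a [PhantomSpec-class] object
#' @export
PhantomSpec <- function(shape, channels = dociChannels(), regions = list(),
                        noise = list(photonScale = 1e4, readSigma = 1),
                        seed = 1L) {
  new("PhantomSpec",
    shape = as.integer(shape), channels = as.numeric(channels),
    regions = regions, noise = noise, seed = as.integer(seed)
  )
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d x %d px, %d channel(s), %d region(s), photonScale %g, readSigma %g, seed %d\n",
    object@shape[1L], object@shape[2L], length(object@channels),
    length(object@regions), object@noise$photonScale, object@noise$readSigma,
    object@seed
  ))
})

#' The nine band-pass emission channels
#'
#' Center wavelengths (nm) of the emission band-pass filters under 365 nm
#' excitation.
#'
#' @return numeric vector of nine wavelengths
#' @export
dociChannels <- function() c(405, 415, 434, 465, 494, 520, 542, 572, 605)

#' Time-resolved image stack for one emission channel
#'
#' Detected counts over time for every pixel of one channel, with the time
#' grid and pulse timing the stack was simulated (or acquired) under.
#'
#' @slot channel emission wavelength (nm)
#' @slot timeGrid strictly increasing sample times (ns)
#' @slot frames numeric array time x row x col of non-negative counts
#' @slot timing a [PulseTiming-class]
#' @seealso [renderStacks()], [computeDOCI()]
#' @exportClass TimeResolvedStack
setClass("TimeResolvedStack",
  representation(
    channel = "numeric", timeGrid = "numeric",
    frames = "array", timing = "PulseTiming"
  )
)

setValidity("TimeResolvedStack", function(object) {
  msgs <- character()
  if (length(dim(object@frames)) != 3L)
    msgs <- c(msgs, "frames must be a 3-D array (time x row x col)")
  else if (dim(object@frames)[1L] != length(object@timeGrid))
    msgs <- c(msgs, "first dimension of frames must match timeGrid length")
  if (is.unsorted(object@timeGrid, strictly = TRUE))
    msgs <- c(msgs, "timeGrid must be strictly increasing")
  if (any(object@frames < 0))
    msgs <- c(msgs, "frames must be non-negative")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TimeResolvedStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "TimeResolvedStack: channel %g nm, %d frames of %d x %d px, t in [%g, %g] ns\n",
    object@channel, d[1L], d[2L], d[3L],
    object@timeGrid[1L], object@timeGrid[length(object@timeGrid)]
  ))
})

#' Per-channel DOCI image
#'
#' The DOCI value of a pixel is the aggregate decay-gate intensity divided by
#' the aggregate steady-state-gate intensity: a dimensionless relative
#' lifetime. Pixels whose steady-state aggregate falls below the low-signal
#' threshold are masked out (`validMask` `FALSE`, value 0 by convention).
#'
#' @slot channel emission wavelength (nm)
#' @slot values numeric matrix of DOCI values (>= 0 where valid)
#' @slot validMask logical matrix, `FALSE` where signal was below threshold
#' @slot thresholdUsed the steady-state aggregate threshold applied (counts.ns)
#' @seealso [computeDOCI()]
#' @exportClass DOCIImage
setClass("DOCIImage",
  representation(
    channel = "numeric", values = "matrix",
    validMask = "matrix", thresholdUsed = "numeric"
  )
)

setValidity("DOCIImage", function(object) {
  msgs <- character()
  if (!identical(dim(object@values), dim(object@validMask)))
    msgs <- c(msgs, "values and validMask must share dimensions")
  if (!is.logical(object@validMask))
    msgs <- c(msgs, "validMask must be logical")
  v <- object@values[object@validMask]
  if (length(v) && (any(!is.finite(v)) || any(v < 0)))
    msgs <- c(msgs, "values must be finite and >= 0 wherever validMask is TRUE")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "DOCIImage", function(object) {
  v <- object@values[object@validMask]
  cat(sprintf(
    "DOCIImage: channel %g nm, %d x %d px, %.1f%% valid%s\n",
    object@channel, nrow(object@values), ncol(object@values),
    100 * mean(object@validMask),
    if (length(v)) sprintf(", DOCI range [%.4g, %.4g]", min(v), max(v)) else ""
  ))
})

#' Labelled regions of interest
#'
#' A label map plus legend naming each label, and the reference tissue against
#' which other tissues are normalised ("tumor" for margin analyses,
#' "pni_nerve" for the perineural-invasion analysis). One connected region of
#' a label is one ROI instance — the statistical sampling unit, mirroring one
#' animal/tumor.
#'
#' @slot labelMap integer matrix of region labels (0 = background)
#' @slot legend named integer vector mapping tissue name to label code
#' @slot referenceTissue name of the reference tissue
#' @seealso [ROISet()], [roiMeans()], [significanceSweep()]
#' @exportClass ROISet
setClass("ROISet",
  representation(
    labelMap = "matrix", legend = "integer", referenceTissue = "character"
  )
)

setValidity("ROISet", function(object) {
  msgs <- character()
  if (is.null(names(object@legend)) || any(!nzchar(names(object@legend))))
    msgs <- c(msgs, "legend must be a named integer vector (tissue -> code)")
  if (!object@referenceTissue %in% names(object@legend))
    msgs <- c(msgs, sprintf("reference tissue \"%s\" absent from legend",
                            object@referenceTissue))
  codes <- unique(as.vector(object@labelMap))
  if (!all(codes %in% c(0L, object@legend)))
    msgs <- c(msgs, "labelMap contains codes missing from the legend")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ROISet
#'
#' @param labelMap integer matrix of labels
#' @param legend named integer vector, tissue name to label code
#' @param referenceTissue reference tissue name (default "tumor")
#' @return an [ROISet-class]
#' @export
ROISet <- function(labelMap, legend, referenceTissue = "tumor") {
  storage.mode(labelMap) <- "integer"
  new("ROISet",
    labelMap = labelMap, legend = vapply(legend, as.integer, integer(1L)),
    referenceTissue = referenceTissue
  )
}

setMethod("show", "ROISet", function(object) {
  cat(sprintf(
    "ROISet: %d x %d px, %d tissue label(s), reference \"%s\"\n",
    nrow(object@labelMap), ncol(object@labelMap), length(object@legend),
    object@referenceTissue
  ))
})

#' Per-tissue, per-channel DOCI statistics
#'
#' Result of [significanceSweep()]: one row per tissue per channel with the
#' ROI-instance count, mean DOCI, reference-normalised mean, one-sample t-test
#' against 1 (raw p, plus BH-adjusted q as an extra column), and per-channel
#' contrast scores used to rank channels.
#'
#' @slot table data.frame with columns tissue, channel_nm, n, mean_doci,
#'   normalized_mean, t, df, p, q, neglog10p, significant
#' @slot contrast data.frame with columns channel_nm, score
#' @slot referenceTissue reference tissue name
#' @slot alpha significance level used for the `significant` flag
#' @exportClass ROIStatsTable
setClass("ROIStatsTable",
  representation(
    table = "data.frame", contrast = "data.frame",
    referenceTissue = "character", alpha = "numeric"
  )
)

setMethod("show", "ROIStatsTable", function(object) {
  tab <- object@table
  nsig <- sum(tab$significant, na.rm = TRUE)
  ntest <- sum(!is.na(tab$p))
  cat(sprintf(
    "ROIStatsTable: %d tissue(s) x %d channel(s), reference \"%s\"; %d/%d tests significant at alpha = %g\n",
    length(unique(tab$tissue)), length(unique(tab$channel_nm)),
    object@referenceTissue, nsig, ntest, object@alpha
  ))
  cat(sprintf("best contrast channel: %g nm\n", bestChannel(object)))
})

#' DOCI profile along a nerve axis
#'
#' Mean DOCI across the band width at each axial position of a nerve band,
#' for one emission channel. Positions are 0-based frame column (or row)
#' indices; positions whose pixels are all masked are dropped.
#'
#' @slot positions strictly increasing 0-based axial indices
#' @slot values finite mean DOCI per position
#' @slot channel emission wavelength (nm)
#' @seealso [extractProfile()], [callPNI()]
#' @exportClass NerveProfile
setClass("NerveProfile",
  representation(positions = "integer", values = "numeric", channel = "numeric")
)

setValidity("NerveProfile", function(object) {
  msgs <- character()
  if (length(object@positions) != length(object@values))
    msgs <- c(msgs, "positions and values must have equal length")
  if (is.unsorted(object@positions, strictly = TRUE))
    msgs <- c(msgs, "positions must be strictly increasing")
  if (any(!is.finite(object@values)))
    msgs <- c(msgs, "values must be finite")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "NerveProfile", function(object) {
  cat(sprintf(
    "NerveProfile: channel %g nm, %d positions [%d..%d], DOCI mean %.4g\n",
    object@channel, length(object@positions),
    object@positions[1L], object@positions[length(object@positions)],
    mean(object@values)
  ))
})

#' Perineural-invasion call for one nerve
#'
#' @slot label `"control"` or `"pni"`
#' @slot score mean DOCI over the whole nerve band
#' @slot threshold decision boundary used (calls below indicate invasion)
#' @slot transitionIndex 0-based axial position where the first qualifying
#'   below-threshold run starts; `NA` for control calls
#' @slot minRun run-length persistence used by the caller
#' @seealso [callPNI()], [evaluateDetection()]
#' @exportClass PNICallResult
setClass("PNICallResult",
  representation(
    label = "character", score = "numeric", threshold = "numeric",
    transitionIndex = "integer", minRun = "integer"
  )
)

setValidity("PNICallResult", function(object) {
  msgs <- character()
  if (!object@label %in% c("control", "pni"))
    msgs <- c(msgs, "label must be \"control\" or \"pni\"")
  if (object@label == "control" && !is.na(object@transitionIndex))
    msgs <- c(msgs, "transitionIndex must be NA for control calls")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PNICallResult", function(object) {
  cat(sprintf(
    "PNICallResult: %s (score %.4g vs threshold %.4g%s)\n",
    object@label, object@score, object@threshold,
    if (!is.na(object@transitionIndex))
      sprintf(", transition at position %d", object@transitionIndex) else ""
  ))
})
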