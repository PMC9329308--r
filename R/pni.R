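#' Extract the DOCI profile along a nerve band
#'
#' Means the unmasked DOCI values across the band width at every axial
#' position of an axis-aligned nerve band, yielding a 1-D relative-lifetime
#' profile along the nerve. Positions whose pixels are all masked are
#' dropped; a fully masked band is an error.
#'
#' @param doci a [DOCIImage-class]
#' @param band a nerve_band region descriptor (as in [PhantomSpec-class];
#'   see [nerveBands()]) with 0-based inclusive `rows` and `cols`
#' @return a [NerveProfile-class]; positions are 0-based column indices
#' @examples
#' sc <- defaultScene("pni", seed = 4)
#' st <- renderStacks(sc$spec, sc$tissues, channels = 465)
#' extractProfile(computeDOCI(st[[1]]), nerveBands(sc$spec)[[2]])
#' @export
extractProfile <- function(doci, band) {
  stopifnot(is(doci, "DOCIImage"))
  if (is.null(band$rows) || is.null(band$cols))
    stop("band must carry 0-based rows and cols ranges")
  ri <- (band$rows[1L]:band$rows[2L]) + 1L
  ci <- (band$cols[1L]:band$cols[2L]) + 1L
  if (max(ri) > nrow(doci@values) || max(ci) > ncol(doci@values) ||
      min(ri) < 1L || min(ci) < 1L)
    stop("band lies outside the image")
  positions <- integer(0)
  values <- numeric(0)
  for (j in ci) {
    sel <- doci@validMask[ri, j]
    if (!any(sel)) next
    positions <- c(positions, j - 1L)
    values <- c(values, mean(doci@values[ri, j][sel]))
  }
  if (!length(positions)) stop("nerve band is fully masked")
  new("NerveProfile",
    positions = positions, values = values, channel = doci@channel
  )
}

#' Calibrate the PNI decision threshold from control nerves
#'
#' Pools all positions of the control profiles and returns
#' `mean - k * sd`. Invaded nerve runs *below* healthy nerve in relative
#' lifetime, so calls below the threshold indicate PNI. With zero control
#' variance (noiseless phantoms) the threshold degenerates to the control
#' mean, with a warning.
#'
#' @param controlProfiles list of at least two [NerveProfile-class] from
#'   control (healthy) nerves
#' @param k multiplier on the control standard deviation (default 3)
#' @return the threshold (DOCI units)
#' @examples
#' sc <- defaultScene("pni", seed = 11)
#' st <- renderStacks(sc$spec, sc$tissues, channels = 465)
#' d <- computeDOCI(st[[1]])
#' ctl <- extractProfile(d, nerveBands(sc$spec)[[1]])
#' calibrateThreshold(list(ctl, ctl))
#' @export
calibrateThreshold <- function(controlProfiles, k = 3) {
  if (length(controlProfiles) < 2L)
    stop("at least two control profiles are required")
  vals <- unlist(lapply(controlProfiles, profileValues))
  s <- sd(vals)
  if (!is.finite(s) || s == 0) {
    if (k > 0)
      warning("zero control variance: threshold degenerates to the control mean")
    return(mean(vals))
  }
  mean(vals) - k * s
}

#' Call perineural invasion on a nerve profile
#'
#' A nerve is called `pni` iff at least `minRun` consecutive axial positions
#' fall strictly below the threshold; the run-length persistence suppresses
#' isolated noise dips. The transition index is the first position of the
#' first qualifying run. The score — the mean DOCI over the whole band, the
#' way a surgeon would interrogate an intact nerve — is always reported.
#'
#' @param profile a [NerveProfile-class]
#' @param threshold decision boundary from [calibrateThreshold()]
#' @param minRun minimum run length of below-threshold positions (default 5)
#' @return a [PNICallResult-class]
#' @export
callPNI <- function(profile, threshold, minRun = 5L) {
  stopifnot(is(profile, "NerveProfile"))
  if (!length(profile@values)) stop("empty profile")
  below <- profile@values < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= minRun)
  if (length(hit)) {
    label <- "pni"
    transition <- profile@positions[starts[hit[1L]]]
  } else {
    label <- "control"
    transition <- NA_integer_
  }
  new("PNICallResult",
    label = label, score = mean(profile@values),
    threshold = as.numeric(threshold),
    transitionIndex = as.integer(transition), minRun = as.integer(minRun)
  )
}

#' Detection metrics of a set of PNI calls
#'
#' Standard 2x2 confusion metrics (`pni` is the positive class) against
#' ground-truth labels, plus a one-sample t-test of the control-normalised
#' PNI scores against 1 — the statistical companion to the accuracy figure.
#' Metrics whose class is absent from the truth are reported `NA`.
#'
#' @param calls list of [PNICallResult-class] (or character labels)
#' @param truth character vector of `"control"` / `"pni"`, same length
#' @return list with `accuracy`, `sensitivity`, `specificity`, counts
#'   (`tp`, `tn`, `fp`, `fn`) and `scoreTest` (the [oneSampleT()] result on
#'   normalised PNI scores, `NULL` when scores are unavailable)
#' @examples
#' evaluateDetection(c("pni", "control"), c("pni", "control"))$accuracy
#' @export
evaluateDetection <- function(calls, truth) {
  labels <- vapply(calls, function(x)
    if (is(x, "PNICallResult")) pniLabel(x) else as.character(x),
    character(1L))
  if (length(labels) != length(truth))
    stop("calls and ground-truth labels differ in length")
  if (!all(truth %in% c("control", "pni")))
    stop("truth labels must be \"control\" or \"pni\"")
  tp <- sum(labels == "pni" & truth == "pni")
  tn <- sum(labels == "control" & truth == "control")
  fp <- sum(labels == "pni" & truth == "control")
  fn <- sum(labels == "control" & truth == "pni")
  acc <- (tp + tn) / length(truth)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  scoreTest <- NULL
  if (all(vapply(calls, is, logical(1L), "PNICallResult"))) {
    scores <- vapply(calls, pniScore, numeric(1L))
    ctl <- scores[truth == "control"]
    pni <- scores[truth == "pni"]
    if (length(ctl) >= 1L && length(pni) >= 2L && mean(ctl) > 0)
      scoreTest <- oneSampleT(pni / mean(ctl), null = 1)
  }
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       tp = tp, tn = tn, fp = fp, fn = fn, scoreTest = scoreTest)
}
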