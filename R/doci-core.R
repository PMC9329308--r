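#' Gated trapezoidal aggregate of a time-resolved stack
#'
#' Per-pixel trapezoidal integral of the frames over the samples lying in the
#' gate `[a, b]` (counts.ns). The gate is treated as a closed integration
#' window on the grid, so a constant frame value of 1 over a 50 ns gate
#' aggregates to 50 and adjacent steady/decay gates share their boundary
#' sample with half weight each, as the trapezoid rule implies. Deterministic.
#'
#' @param stack a [TimeResolvedStack-class]
#' @param gate numeric(2), gate `c(a, b)` in ns; must contain at least two
#'   grid samples
#' @return numeric matrix (rows x cols) of aggregates
#' @examples
#' sc <- defaultScene("pni")
#' st <- renderStacks(sc$spec, sc$tissues, channels = 465, noiseless = TRUE)
#' agg <- gatedAggregate(st[[1]], c(100, 200))
#' @export
gatedAggregate <- function(stack, gate) {
  stopifnot(is(stack, "TimeResolvedStack"))
  if (length(gate) != 2L || !(gate[2L] > gate[1L]))
    stop("gate must be c(a, b) with b > a")
  tg <- stack@timeGrid
  idx <- which(tg >= gate[1L] & tg <= gate[2L])
  if (length(idx) < 2L)
    stop(sprintf("gate [%g, %g] contains fewer than two samples", gate[1L], gate[2L]))
  tt <- tg[idx]
  n <- length(tt)
  w <- numeric(n)
  w[1L] <- (tt[2L] - tt[1L]) / 2
  w[n] <- (tt[n] - tt[n - 1L]) / 2
  if (n > 2L) w[2:(n - 1L)] <- (tt[3:n] - tt[1:(n - 2L)]) / 2
  d <- dim(stack@frames)
  M <- matrix(stack@frames, d[1L], d[2L] * d[3L])
  agg <- as.vector(w %*% M[idx, , drop = FALSE])
  matrix(agg, d[2L], d[3L])
}

#' Default low-signal threshold for the steady-state aggregate
#'
#' Five times the read-noise standard deviation of the steady-gate integral,
#' `5 * readSigma * sqrt(Wss * dt)`: pixels whose steady aggregate is not
#' clearly above the noise floor carry no usable lifetime information.
#'
#' @param timing a [PulseTiming-class]
#' @param readSigma Gaussian read-noise sd per frame (counts)
#' @return threshold in counts.ns
#' @export
defaultMinSteady <- function(timing, readSigma = 1) {
  stopifnot(is(timing, "PulseTiming"))
  wss <- diff(timing@steadyGate)
  5 * readSigma * sqrt(wss * timing@sampleDt)
}

#' Compute the DOCI image of one channel
#'
#' The DOCI value of a pixel is the aggregate decay-gate intensity divided by
#' the aggregate steady-state intensity — a dimensionless relative lifetime.
#' Pixels whose steady aggregate falls below `minSteady` (or is not strictly
#' positive) are masked invalid and carry value 0 by convention; negative
#' numerators arising from read noise are clipped to 0. Low signal is a mask
#' state, never an error.
#'
#' @param stack a [TimeResolvedStack-class]
#' @param timing gate timing; defaults to the stack's own timing
#' @param minSteady low-signal threshold on the steady aggregate (counts.ns);
#'   `NULL` uses [defaultMinSteady()] at `readSigma`
#' @param readSigma read-noise sd used for the default threshold
#' @return a [DOCIImage-class]
#' @examples
#' sc <- defaultScene("pni", seed = 3)
#' st <- renderStacks(sc$spec, sc$tissues, channels = 465)
#' computeDOCI(st[[1]])
#' @export
computeDOCI <- function(stack, timing = NULL, minSteady = NULL, readSigma = 1) {
  stopifnot(is(stack, "TimeResolvedStack"))
  if (is.null(timing)) timing <- stack@timing
  if (is.null(minSteady)) minSteady <- defaultMinSteady(timing, readSigma)
  steady <- gatedAggregate(stack, timing@steadyGate)
  decay <- gatedAggregate(stack, timing@decayGate)
  valid <- steady >= minSteady & steady > 0
  values <- matrix(0, nrow(steady), ncol(steady))
  values[valid] <- pmax(decay[valid], 0) / steady[valid]
  new("DOCIImage",
    channel = stack@channel, values = values, validMask = valid,
    thresholdUsed = as.numeric(minSteady)
  )
}

#' Compute DOCI images for all channels
#'
#' Applies [computeDOCI()] to each stack independently (no cross-channel
#' normalisation), preserving input order. Duplicate channels are an error.
#'
#' @param stacks list of [TimeResolvedStack-class]
#' @inheritParams computeDOCI
#' @return named list of [DOCIImage-class], keyed by channel (nm)
#' @export
computeAllChannels <- function(stacks, timing = NULL, minSteady = NULL,
                               readSigma = 1) {
  chs <- vapply(stacks, channel, numeric(1L))
  if (anyDuplicated(chs))
    stop("duplicate channels: ", paste(chs[duplicated(chs)], collapse = ", "))
  out <- lapply(stacks, computeDOCI, timing = timing, minSteady = minSteady,
                readSigma = readSigma)
  names(out) <- as.character(chs)
  out
}
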