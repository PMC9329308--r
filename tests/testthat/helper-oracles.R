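# independent numerical oracles, deliberately not using the package's
# integration path

# plain trapezoid rule over (t, y)
trapz <- function(t, y) {
  n <- length(t)
  sum(diff(t) * (y[-1L] + y[-n]) / 2)
}

# gated trapezoid of a continuous function f over [a, b] at step dt
gatedTrapzFun <- function(f, a, b, dt) {
  t <- seq(a, b, by = dt)
  trapz(t, f(t))
}

# direct evaluation of the square-pulse decay curve (re-derived here, not
# calling decayTrace)
pulseCurve <- function(t, a, tau, on = 0, off = 100) {
  y <- numeric(length(t))
  for (i in seq_along(a)) {
    if (tau[i] == 0) {
      y <- y + ifelse(t >= on & t < off, a[i], 0)
    } else {
      rise <- t >= on & t < off
      post <- t >= off
      y[rise] <- y[rise] + a[i] * (1 - exp(-(t[rise] - on) / tau[i]))
      y[post] <- y[post] + a[i] * (1 - exp(-(off - on) / tau[i])) *
        exp(-(t[post] - off) / tau[i])
    }
  }
  y
}

# wrap a single pixel's decay mixture as a TimeResolvedStack
pixelStack <- function(components, timing, channel = 465) {
  tg <- defaultTimeGrid(timing)
  y <- decayTrace(components, timing, tg)
  new("TimeResolvedStack",
    channel = channel, timeGrid = tg,
    frames = array(y, dim = c(length(tg), 1L, 1L)), timing = timing
  )
}

# uniform-value DOCIImage helper for ROI/profile tests
uniformDOCI <- function(values, mask = NULL, channel = 465) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  new("DOCIImage",
    channel = channel, values = values, validMask = mask, thresholdUsed = 0
  )
}
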