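tm <- PulseTiming()

test_that("profiles average across the band width and honour the mask", {
  values <- matrix(0.08, 16, 32)
  band <- list(shape = "nerve_band", rows = c(2, 9), cols = c(0, 31))
  p <- extractProfile(uniformDOCI(values), band)
  expect_equal(profileValues(p), rep(0.08, 32))
  expect_equal(profilePositions(p), 0:31)
  # width-1 band equals the pixel row
  values[5, ] <- seq(0.01, 0.32, by = 0.01)
  p1 <- extractProfile(uniformDOCI(values), list(rows = c(4, 4), cols = c(0, 31)))
  expect_equal(profileValues(p1), values[5, ])
  # all-masked positions dropped; fully masked band errors
  mask <- matrix(TRUE, 16, 32)
  mask[3:10, 7] <- FALSE
  pd <- extractProfile(uniformDOCI(values, mask), band)
  expect_false(6 %in% profilePositions(pd))
  expect_length(profilePositions(pd), 31)
  expect_error(extractProfile(uniformDOCI(values, mask & FALSE), band), "masked")
})

test_that("noiseless default scene yields a step exactly at the transition column", {
  sc <- defaultScene("pni", seed = 1)
  st <- renderStacks(sc$spec, sc$tissues, tm, channels = 465, noiseless = TRUE)
  d <- computeDOCI(st[[1]], minSteady = 1e-9)
  p <- extractProfile(d, nerveBands(sc$spec)[[2]])
  v <- profileValues(p)
  expect_lt(diff(range(v[1:32])), 1e-12)
  expect_lt(diff(range(v[33:64])), 1e-12)
  expect_lt(v[33], v[32])  # invaded side sits below healthy nerve
})

test_that("threshold calibration is mean minus k sd of pooled control values", {
  mk <- function(values) new("NerveProfile", positions = seq_along(values) - 1L,
                             values = values, channel = 465)
  ctl <- list(mk(rep(c(3.9, 4.1), 10)), mk(rep(c(3.9, 4.1), 10)))
  pooled <- rep(c(3.9, 4.1), 20)
  expect_equal(calibrateThreshold(ctl, k = 3), mean(pooled) - 3 * sd(pooled))
  expect_equal(calibrateThreshold(ctl, k = 0), 4.0)
  expect_warning(thr <- calibrateThreshold(list(mk(rep(4, 5)), mk(rep(4, 5)))), "variance")
  expect_equal(thr, 4)
  expect_error(calibrateThreshold(ctl[1]))
})

test_that("the run-length rule calls invasion and locates the transition", {
  mk <- function(values) new("NerveProfile", positions = seq_along(values) - 1L,
                             values = values, channel = 465)
  flat <- mk(rep(4, 64))
  ctl <- callPNI(flat, threshold = 3.7)
  expect_equal(pniLabel(ctl), "control")
  expect_true(is.na(transitionIndex(ctl)))
  step <- mk(c(rep(4, 32), rep(2, 32)))
  call <- callPNI(step, threshold = 3.7)
  expect_equal(pniLabel(call), "pni")
  expect_equal(transitionIndex(call), 32L)
  # brute-force oracle: first index opening a >= 5-long below-threshold run
  v <- profileValues(step)
  runs <- sapply(seq_along(v), function(i)
    i + 4 <= length(v) && all(v[i:(i + 4)] < 3.7))
  expect_equal(transitionIndex(call), which(runs)[1] - 1L)
  # an isolated dip shorter than minRun stays control
  dip <- mk(c(rep(4, 30), 2, rep(4, 33)))
  expect_equal(pniLabel(callPNI(dip, threshold = 3.7)), "control")
  expect_equal(pniLabel(callPNI(dip, threshold = 3.7, minRun = 1L)), "pni")
})

test_that("raising k never converts a control call into a pni call", {
  set.seed(606)
  sc <- defaultScene("pni", seed = 91, photonScale = 1e3)
  st <- renderStacks(sc$spec, sc$tissues, tm, channels = 465)
  d <- computeDOCI(st[[1]])
  ctl <- extractProfile(d, nerveBands(sc$spec)[[1]])
  vals <- profileValues(ctl)
  labels <- vapply(c(0.5, 1, 2, 3, 5), function(k)
    pniLabel(callPNI(ctl, mean(vals) - k * sd(vals))), character(1))
  firstControl <- match("control", labels)
  expect_true(all(labels[firstControl:length(labels)] == "control"))
})

test_that("detection metrics implement the 2x2 confusion arithmetic", {
  truth <- rep(c("control", "pni"), each = 6)
  perfect <- evaluateDetection(truth, truth)
  expect_equal(perfect$accuracy, 1)
  inverted <- evaluateDetection(rev(truth), truth)
  expect_equal(inverted$accuracy, 0)
  expect_equal(inverted$sensitivity, 0)
  calls <- c(rep("control", 6), rep("pni", 5), "control")
  m <- evaluateDetection(calls, truth)
  expect_equal(m$accuracy, 11 / 12)
  expect_equal(m$sensitivity, 5 / 6)
  expect_equal(m$specificity, 1)
  expect_error(evaluateDetection(calls[-1], truth), "length")
  # one-class truth leaves the other metric absent
  expect_true(is.na(evaluateDetection(rep("pni", 3), rep("pni", 3))$specificity))
})

test_that("control and invaded value distributions separate cleanly at high photon counts", {
  gaps <- vapply(1:10, function(s) {
    sc <- defaultScene("pni", seed = 700 + s)
    st <- renderStacks(sc$spec, sc$tissues, tm, channels = 465)
    d <- computeDOCI(st[[1]])
    ctl <- profileValues(extractProfile(d, nerveBands(sc$spec)[[1]]))
    tst <- extractProfile(d, nerveBands(sc$spec)[[2]])
    invaded <- profileValues(tst)[profilePositions(tst) >= 32]
    min(ctl) - max(invaded)
  }, numeric(1))
  expect_true(all(gaps > 0))
})
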