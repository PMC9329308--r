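tm <- PulseTiming()

test_that("ROI instance means are plain within-instance averages of valid pixels", {
  values <- matrix(2, 8, 8)
  values[, 5:8] <- 4
  labels <- matrix(1L, 8, 8)
  rois <- ROISet(labels, c(background = 0L, tumor = 1L), "tumor")
  m <- roiMeans(uniformDOCI(values), rois)
  expect_equal(m$tumor, 3)
  # two disconnected instances -> two samples
  labels2 <- matrix(0L, 8, 8)
  labels2[1:3, 1:3] <- 1L
  labels2[6:8, 6:8] <- 1L
  rois2 <- ROISet(labels2, c(background = 0L, tumor = 1L), "tumor")
  m2 <- roiMeans(uniformDOCI(values), rois2)
  expect_equal(sort(m2$tumor), c(2, 4))
  # all-masked instance dropped with a warning
  mask <- matrix(TRUE, 8, 8)
  mask[6:8, 6:8] <- FALSE
  expect_warning(m3 <- roiMeans(uniformDOCI(values, mask), rois2), "dropped")
  expect_equal(m3$tumor, 2)
})

test_that("noiseless instances of one tissue reproduce the closed form exactly", {
  tmFine <- PulseTiming(sampleDt = 0.1)
  sc <- defaultScene("margin", seed = 2, nInstances = 5)
  st <- renderStacks(sc$spec, sc$tissues, tmFine, channels = 465,
                     noiseless = TRUE)
  lm <- renderLabelMap(sc$spec)
  means <- roiMeans(computeDOCI(st[[1]]), ROISet(lm$map, lm$legend))
  expect_length(means$muscle, 5)
  expect_lt(diff(range(means$muscle)), 1e-12)
  expected <- dociClosedForm(tissueComponents(sc$tissues$muscle, 465), tmFine)
  expect_equal(means$muscle[1], expected, tolerance = 5e-3)
})

test_that("reference normalisation scales by the reference grand mean and is idempotent", {
  norm <- normalizeToReference(list(tumor = c(2, 2), nerve = c(4, 6)), "tumor")
  expect_equal(norm$tumor, c(1, 1))
  expect_equal(norm$nerve, c(2, 3))
  expect_equal(normalizeToReference(norm, "tumor"), norm)
  same <- normalizeToReference(list(tumor = c(3, 5), other = c(3, 5)), "tumor")
  expect_equal(mean(same$tumor), 1)
  expect_equal(same$other, same$tumor)
  expect_error(normalizeToReference(list(tumor = c(0, 0), x = 1), "tumor"))
  expect_error(normalizeToReference(list(x = 1), "tumor"))
  # default-scene nerve/tumor ratio in the long-gate limit ~ 4.0/1.5
  tmLong <- PulseTiming(pulseOff = 500, steadyGate = c(450, 500),
                        decayGate = c(500, 2000), sampleDt = 0.5)
  ts <- defaultTissues()
  ratio <- dociClosedForm(tissueComponents(ts$nerve, 465), tmLong) /
    dociClosedForm(tissueComponents(ts$tumor, 465), tmLong)
  expect_equal(ratio, 4.0 / 1.5, tolerance = 1e-6)
})

test_that("one-sample t-test matches the closed form and an independent implementation", {
  at0 <- oneSampleT(c(0.9, 1.1))
  expect_equal(at0$t, 0)
  expect_equal(at0$p, 1)
  r <- oneSampleT(c(0.8, 0.85, 0.9))
  expect_equal(r$t, -5.196, tolerance = 1e-4)
  expect_equal(r$df, 2)
  expect_equal(r$p, 0.0351, tolerance = 1e-3)
  ref <- t.test(c(0.8, 0.85, 0.9), mu = 1)
  expect_equal(r$t, unname(ref$statistic))
  expect_equal(r$p, ref$p.value)
  tight <- oneSampleT(c(1.05, 1.06, 1.04, 1.05))
  expect_equal(tight$p, t.test(c(1.05, 1.06, 1.04, 1.05), mu = 1)$p.value)
  expect_equal(tight$p, 0.00117222, tolerance = 1e-5)
  # degenerate inputs report an absent p, not an error
  expect_true(is.na(oneSampleT(1)$p))
  expect_true(is.na(oneSampleT(rep(2, 5))$p))
})

test_that("the sweep has one test per non-reference tissue per channel", {
  sc <- defaultScene("margin", seed = 12, nInstances = 3)
  st <- renderStacks(sc$spec, sc$tissues, tm, channels = 465)
  lm <- renderLabelMap(sc$spec)
  sweep <- significanceSweep(computeAllChannels(st), ROISet(lm$map, lm$legend))
  tab <- statsTable(sweep)
  expect_equal(sum(!is.na(tab$p)), 3)  # 4 tissues minus the reference
  expect_equal(tab$normalized_mean[tab$tissue == "tumor"], 1)
  expect_true(all(tab$p[!is.na(tab$p)] >= 0 & tab$p[!is.na(tab$p)] <= 1))
  expect_true(bestChannel(sweep) %in% 465)
})

test_that("identically distributed tissue and well-estimated reference give uniform p", {
  # instance-level simulation of the normalize + t-test chain; the reference
  # is given many instances so its grand mean is effectively fixed (see the
  # methods vignette for why equal small n would inflate the test)
  set.seed(404)
  ps <- replicate(200, {
    m <- list(tumor = rnorm(100, 0.05, 0.004), other = rnorm(8, 0.05, 0.004))
    oneSampleT(normalizeToReference(m, "tumor")$other)$p
  })
  expect_equal(mean(ps), 0.5, tolerance = 0.07)
  expect_gt(min(ps), 0)
})

test_that("rejection rate grows with separation and sample size", {
  set.seed(505)
  rate <- function(delta, n) {
    mean(replicate(200, {
      m <- list(tumor = rnorm(100, 0.05, 0.004),
                other = rnorm(n, 0.05 * (1 + delta), 0.004))
      oneSampleT(normalizeToReference(m, "tumor")$other)$p < 0.05
    }))
  }
  bySep <- c(rate(0, 8), rate(0.05, 8), rate(0.15, 8))
  expect_true(all(diff(bySep) >= 0))
  byN <- c(rate(0.05, 4), rate(0.05, 16))
  expect_true(byN[2] >= byN[1])
})
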