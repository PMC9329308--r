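tm <- PulseTiming()

test_that("continuous rendering maps values through the colormap and masks black", {
  values <- matrix(0.075, 4, 4)
  d <- uniformDOCI(values)
  policy <- colorPolicy("continuous", colormapRange = c(0, 0.15))
  img <- renderPseudocolor(d, policy)
  expect_equal(dim(img), c(4, 4, 3))
  # uniform input -> one color, the ramp at fraction 0.5
  for (k in 1:3) expect_equal(length(unique(as.vector(img[, , k]))), 1)
  ramp <- grDevices::colorRamp(grDevices::hcl.colors(256, "Viridis"))
  expect_equal(as.vector(img[1, 1, ]), as.vector(round(ramp(0.5))))
  # fully masked -> all black
  dMasked <- uniformDOCI(values, matrix(FALSE, 4, 4))
  expect_true(all(renderPseudocolor(dMasked, policy) == 0))
})

test_that("classified rendering paints tumor pixels the configured tumor color", {
  tmFine <- PulseTiming(sampleDt = 0.1)
  sc <- defaultScene("margin", seed = 4, nInstances = 2)
  st <- renderStacks(sc$spec, sc$tissues, tmFine, channels = 465, noiseless = TRUE)
  d <- computeDOCI(st[[1]], minSteady = 1e-9)
  lm <- renderLabelMap(sc$spec)
  cls <- classifyPixels(d, sc$tissues, tmFine)
  # per-pixel nearest-class oracle on a sample of pixels
  classDoci <- vapply(names(cls$legend), function(nm)
    dociClosedForm(tissueComponents(sc$tissues[[nm]], 465), tmFine), numeric(1))
  idx <- which(validMask(d))[seq(1, sum(validMask(d)), by = 97)]
  for (i in idx) {
    expect_equal(cls$map[i],
                 unname(cls$legend[which.min(abs(dociValues(d)[i] - classDoci))]))
  }
  img <- renderPseudocolor(d, colorPolicy("tissue_classified"), classes = cls)
  tumorPx <- lm$map == lm$legend[["tumor"]]
  green <- grDevices::col2rgb("green")
  for (k in 1:3) expect_true(all(img[, , k][tumorPx] == green[k]))
  expect_error(
    renderPseudocolor(d, colorPolicy("tissue_classified",
                                     classColors = c(tumor = "green")),
                      classes = cls),
    "no color configured"
  )
})

test_that("rendering never alters the analysis values", {
  values <- matrix(runif(16, 0, 0.15), 4, 4)
  d <- uniformDOCI(values)
  before <- dociValues(d)
  invisible(renderPseudocolor(d, colorPolicy("continuous")))
  expect_identical(dociValues(d), before)
})

test_that("configs round-trip, inject defaults, and reject bad keys/values", {
  empty <- tempfile(fileext = ".yaml")
  writeLines("", empty)
  expect_equal(loadConfig(empty), defaultConfig())
  cfgFile <- tempfile(fileext = ".yaml")
  cfg <- defaultConfig()
  cfg$pni$k <- 2.5
  cfg$tissues$nerve$lifetime <- 3.5
  saveConfig(cfg, cfgFile)
  expect_equal(loadConfig(cfgFile), cfg)
  # partial file gets defaults injected
  writeLines("pni:\n  k: 2", cfgFile)
  got <- loadConfig(cfgFile)
  expect_equal(got$pni$k, 2)
  expect_equal(got$channels, dociChannels())
  # unknown key named in the error
  writeLines("pulse_width: 3", cfgFile)
  expect_error(loadConfig(cfgFile), "pulse_width")
  # decay gate before pulse_off violates the timing invariant
  writeLines("timing:\n  decay_gate: [90, 200]", cfgFile)
  expect_error(loadConfig(cfgFile), "decayGate")
})

test_that("scenes and DOCI images survive a disk round trip", {
  sc <- defaultScene("pni", seed = 42)
  st <- renderStacks(sc$spec, sc$tissues, tm, channels = c(465, 520))
  lm <- renderLabelMap(sc$spec)
  dir <- file.path(tempdir(), "scene-rt")
  writeScene(dir, st, lm$map, lm$legend, sc$spec)
  back <- readScene(dir)
  expect_equal(stackFrames(back$stacks[["465"]]),
               round(stackFrames(st[["465"]])))
  expect_identical(back$labelMap, lm$map)
  expect_identical(back$legend, lm$legend)
  expect_equal(back$timing@steadyGate, tm@steadyGate)
  imgs <- computeAllChannels(st)
  ddir <- file.path(tempdir(), "doci-rt")
  writeDOCIImages(ddir, imgs)
  back2 <- readDOCIImages(ddir)
  expect_identical(validMask(back2[["465"]]), validMask(imgs[["465"]]))
  expect_equal(dociValues(back2[["465"]]), dociValues(imgs[["465"]]),
               tolerance = 1e-6)  # float32 storage
  unlink(c(dir, ddir), recursive = TRUE)
})
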