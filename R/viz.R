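#' Color policy for pseudo-color rendering
#'
#' `tissue_classified` mode paints each pixel by its nearest tissue class in
#' DOCI space (tumor green, muscle blue, adipose red by default, matching the
#' margin figures); `continuous` mode maps a single channel's DOCI values
#' through a colormap over `colormapRange`.
#'
#' @param mode `"tissue_classified"` or `"continuous"`
#' @param classColors named vector of colors (any R color spec), one per
#'   tissue class; must be pairwise distinct
#' @param colormapRange numeric(2) `c(lo, hi)` DOCI values spanned by the
#'   continuous colormap
#' @param palette colormap name passed to [grDevices::hcl.colors()] for
#'   continuous mode
#' @return a list of class `ColorPolicy`
#' @export
colorPolicy <- function(mode = c("tissue_classified", "continuous"),
                        classColors = c(tumor = "green", muscle = "blue",
                                        adipose = "red", dat = "orange",
                                        nerve = "cyan", pni_nerve = "magenta"),
                        colormapRange = c(0, 0.15),
                        palette = "Viridis") {
  mode <- match.arg(mode)
  rgb <- grDevices::col2rgb(classColors)
  if (anyDuplicated(t(rgb)))
    stop("class colors must be pairwise distinct")
  if (!(colormapRange[1L] < colormapRange[2L]))
    stop("colormapRange must satisfy lo < hi")
  structure(
    list(mode = mode, classColors = classColors,
         colormapRange = colormapRange, palette = palette),
    class = "ColorPolicy"
  )
}

#' Classify pixels by nearest tissue DOCI value
#'
#' Assigns each valid pixel of a single-channel DOCI image to the configured
#' tissue class whose analytic DOCI value (from [dociClosedForm()] at this
#' channel) is nearest. This single-channel nearest-class rule is a declared
#' surrogate for multi-channel color composition. Masked pixels get code 0.
#'
#' @param doci a [DOCIImage-class]
#' @param tissues named list of [TissueClass-class]; background is ignored
#' @param timing a [PulseTiming-class] for the analytic class values
#' @return list with `map` (integer matrix, 0 = masked) and `legend`
#'   (named integer vector, tissue to code)
#' @export
classifyPixels <- function(doci, tissues, timing = PulseTiming()) {
  stopifnot(is(doci, "DOCIImage"))
  tissues <- tissues[setdiff(names(tissues), "background")]
  if (!length(tissues)) stop("no non-background tissue classes supplied")
  classDoci <- vapply(tissues, function(tc)
    dociClosedForm(tissueComponents(tc, doci@channel), timing), numeric(1L))
  map <- matrix(0L, nrow(doci@values), ncol(doci@values))
  idx <- which(doci@validMask)
  if (length(idx)) {
    d <- abs(outer(doci@values[idx], classDoci, "-"))
    map[idx] <- max.col(-d, ties.method = "first")
  }
  legend <- seq_along(tissues)
  names(legend) <- names(tissues)
  list(map = map, legend = legend)
}

#' Pseudo-color rendering of DOCI images
#'
#' Renders a DOCI image to an 8-bit RGB array. Continuous mode maps the
#' values of one channel linearly over the policy's `colormapRange` (clipped)
#' through its colormap; classified mode paints each pixel with its tissue
#' class color, using `classes` if supplied or computing the nearest-class
#' assignment via [classifyPixels()] otherwise. Masked pixels render black.
#' Pure view layer: never alters analysis values.
#'
#' @param doci a [DOCIImage-class] (a single channel)
#' @param policy a [colorPolicy()]
#' @param classes optional precomputed `list(map, legend)` from
#'   [classifyPixels()]
#' @param tissues,timing used to classify when `classes` is absent in
#'   classified mode
#' @return integer array rows x cols x 3 with values in 0..255
#' @examples
#' sc <- defaultScene("pni", seed = 9)
#' st <- renderStacks(sc$spec, sc$tissues, channels = 465)
#' img <- renderPseudocolor(computeDOCI(st[[1]]),
#'                          colorPolicy("continuous"))
#' @export
renderPseudocolor <- function(doci, policy, classes = NULL,
                              tissues = defaultTissues(),
                              timing = PulseTiming()) {
  stopifnot(is(doci, "DOCIImage"), inherits(policy, "ColorPolicy"))
  nr <- nrow(doci@values)
  nc <- ncol(doci@values)
  out <- array(0L, dim = c(nr, nc, 3L))
  if (policy$mode == "continuous") {
    lo <- policy$colormapRange[1L]
    hi <- policy$colormapRange[2L]
    frac <- pmin(pmax((doci@values - lo) / (hi - lo), 0), 1)
    ramp <- grDevices::colorRamp(grDevices::hcl.colors(256L, policy$palette))
    cols <- ramp(as.vector(frac))
    for (k in 1:3) {
      plane <- matrix(as.integer(round(cols[, k])), nr, nc)
      plane[!doci@validMask] <- 0L
      out[, , k] <- plane
    }
  } else {
    if (is.null(classes)) classes <- classifyPixels(doci, tissues, timing)
    unknown <- setdiff(names(classes$legend), names(policy$classColors))
    if (length(unknown))
      stop("no color configured for tissue(s): ", paste(unknown, collapse = ", "))
    rgb <- grDevices::col2rgb(policy$classColors)
    for (tissue in names(classes$legend)) {
      sel <- classes$map == classes$legend[[tissue]] & doci@validMask
      for (k in 1:3) {
        plane <- out[, , k]
        plane[sel] <- as.integer(rgb[k, tissue])
        out[, , k] <- plane
      }
    }
  }
  out
}

#' Manhattan plot of the significance sweep
#'
#' Plots `-log10(p)` per tissue across channels with the significance
#' threshold line, the standard presentation of per-channel tissue-vs-reference
#' tests.
#'
#' @param stats an [ROIStatsTable-class]
#' @param main plot title
#' @return invisibly, the plotted data.frame
#' @export
plotManhattan <- function(stats, main = "Tissue vs reference significance") {
  tab <- statsTable(stats)
  tab <- tab[!is.na(tab$p), , drop = FALSE]
  tissues <- unique(tab$tissue)
  cols <- grDevices::hcl.colors(max(3L, length(tissues)), "Dark 3")
  ylim <- range(c(tab$neglog10p, -log10(stats@alpha)), finite = TRUE)
  plot(NA, xlim = range(tab$channel_nm), ylim = ylim,
       xlab = "channel (nm)", ylab = expression(-log[10](p)), main = main)
  for (i in seq_along(tissues)) {
    sub <- tab[tab$tissue == tissues[i], , drop = FALSE]
    graphics::points(sub$channel_nm, sub$neglog10p, col = cols[i], pch = 19)
    graphics::lines(sub$channel_nm, sub$neglog10p, col = cols[i])
  }
  graphics::abline(h = -log10(stats@alpha), col = "grey", lty = 2)
  graphics::legend("topright", legend = tissues, col = cols[seq_along(tissues)],
                   pch = 19, bty = "n")
  invisible(tab)
}

#' Plot a nerve DOCI profile
#'
#' @param profile a [NerveProfile-class]
#' @param threshold optional decision threshold to draw
#' @param main plot title
#' @return invisibly, `NULL`
#' @export
plotProfile <- function(profile, threshold = NULL, main = "Nerve DOCI profile") {
  plot(profilePositions(profile), profileValues(profile), type = "l",
       xlab = "axial position (px)", ylab = "DOCI", main = main)
  if (!is.null(threshold))
    graphics::abline(h = threshold, col = "red", lty = 2)
  invisible(NULL)
}
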