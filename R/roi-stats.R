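#' Per-instance ROI mean DOCI values
#'
#' Splits each tissue label into connected components (ROI instances, via
#' \code{EBImage::bwlabel}) and returns the mean unmasked DOCI value of each
#' instance. One instance is one experimental sample, mirroring one
#' animal/tumor — per-pixel sampling would wildly inflate significance.
#' Instances with no valid pixel are dropped with a warning; the background
#' label is ignored.
#'
#' @param doci a [DOCIImage-class]
#' @param rois an [ROISet-class]
#' @return named list, tissue name to numeric vector of instance means
#' @examples
#' sc <- defaultScene("margin", seed = 2, nInstances = 4)
#' st <- renderStacks(sc$spec, sc$tissues, channels = 465)
#' lm <- renderLabelMap(sc$spec)
#' rois <- ROISet(lm$map, lm$legend)
#' roiMeans(computeDOCI(st[[1]]), rois)
#' @export
roiMeans <- function(doci, rois) {
  stopifnot(is(doci, "DOCIImage"), is(rois, "ROISet"))
  if (!identical(dim(doci@values), dim(rois@labelMap)))
    stop("DOCI image and label map dimensions differ")
  tissues <- setdiff(names(rois@legend), "background")
  out <- vector("list", length(tissues))
  names(out) <- tissues
  for (tissue in tissues) {
    mask <- rois@labelMap == rois@legend[[tissue]]
    if (!any(mask)) next
    cc <- EBImage::bwlabel(mask)
    means <- numeric(0)
    dropped <- 0L
    for (inst in seq_len(max(cc))) {
      sel <- cc == inst & doci@validMask
      if (!any(sel)) {
        dropped <- dropped + 1L
        next
      }
      means <- c(means, mean(doci@values[sel]))
    }
    if (dropped > 0L)
      warning(sprintf("%d \"%s\" ROI instance(s) had no valid pixels and were dropped",
                      dropped, tissue))
    out[[tissue]] <- means
  }
  out[!vapply(out, is.null, logical(1L))]
}

#' Normalise ROI means to a reference tissue
#'
#' Divides every sample by the grand mean of the reference tissue, so the
#' reference samples normalise to mean exactly 1 and other tissues are
#' expressed as relative lifetimes with respect to it (tumor for margin
#' analyses, PNI+ nerve for the invasion analysis). Idempotent: normalising
#' already-normalised data is the identity.
#'
#' @param meansByTissue named list of per-instance mean vectors, as returned
#'   by [roiMeans()]
#' @param referenceTissue name of the reference tissue
#' @return named list of the same shape, values divided by the reference mean
#' @examples
#' normalizeToReference(list(tumor = c(2, 2), nerve = c(4, 6)), "tumor")
#' @export
normalizeToReference <- function(meansByTissue, referenceTissue = "tumor") {
  if (!referenceTissue %in% names(meansByTissue))
    stop(sprintf("reference tissue \"%s\" has no ROI means", referenceTissue))
  ref <- mean(meansByTissue[[referenceTissue]])
  if (!is.finite(ref) || ref <= 0)
    stop(sprintf("reference tissue \"%s\" mean is not positive (%g)",
                 referenceTissue, ref))
  lapply(meansByTissue, function(x) x / ref)
}

#' One-sample t-test against a null value
#'
#' `t = (mean(x) - null) / (sd(x)/sqrt(n))` with `df = n - 1` and a two-sided
#' p-value from the t distribution. With fewer than two samples or zero
#' sample variance the p-value is reported absent (`NA`), not raised as an
#' error, so that noiseless degenerate inputs remain processable.
#'
#' @param x numeric samples (typically reference-normalised ROI means)
#' @param null null-hypothesis mean (default 1, the normalised reference)
#' @return list with `t`, `df`, `p` (each `NA` when undefined) and `n`
#' @examples
#' oneSampleT(c(0.8, 0.85, 0.9))  # t = -5.196, p ~ 0.035
#' @export
oneSampleT <- function(x, null = 1) {
  n <- length(x)
  if (n < 2L) return(list(t = NA_real_, df = NA_real_, p = NA_real_, n = n))
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    return(list(t = NA_real_, df = n - 1, p = NA_real_, n = n))
  t <- (mean(x) - null) / (s / sqrt(n))
  df <- n - 1
  list(t = t, df = df, p = 2 * pt(-abs(t), df), n = n)
}

#' Tissue-vs-reference significance sweep across channels
#'
#' For every channel: per-instance ROI means, reference normalisation, and a
#' one-sample t-test of each non-reference tissue's normalised means against
#' 1. Emits the full per-tissue, per-channel table (with `-log10(p)` for
#' Manhattan-style plotting and a BH-adjusted `q` column, which is reported
#' but not used for the significance flag — significance is the raw
#' `p < alpha`, per-channel), plus a per-channel contrast score: the mean
#' pairwise absolute difference of normalised tissue means, used to rank
#' channels by how well they separate tissues.
#'
#' @param dociImages named list of [DOCIImage-class] (one per channel)
#' @param rois an [ROISet-class]; its `referenceTissue` defines the comparison
#' @param alpha significance level for the flag column (default 0.05)
#' @return an [ROIStatsTable-class]
#' @examples
#' sc <- defaultScene("margin", seed = 5, nInstances = 5)
#' st <- renderStacks(sc$spec, sc$tissues, channels = c(434, 465))
#' lm <- renderLabelMap(sc$spec)
#' sweep <- significanceSweep(computeAllChannels(st), ROISet(lm$map, lm$legend))
#' statsTable(sweep)
#' @export
significanceSweep <- function(dociImages, rois, alpha = 0.05) {
  stopifnot(is(rois, "ROISet"))
  rows <- list()
  contrast <- data.frame(channel_nm = numeric(0), score = numeric(0))
  for (img in dociImages) {
    ch <- channel(img)
    means <- roiMeans(img, rois)
    norm <- normalizeToReference(means, rois@referenceTissue)
    normMeans <- vapply(norm, mean, numeric(1L))
    pairs <- utils::combn(length(normMeans), 2L)
    score <- mean(abs(normMeans[pairs[1L, ]] - normMeans[pairs[2L, ]]))
    contrast <- rbind(contrast, data.frame(channel_nm = ch, score = score))
    for (tissue in names(norm)) {
      isRef <- tissue == rois@referenceTissue
      tt <- if (isRef) list(t = NA_real_, df = NA_real_, p = NA_real_,
                            n = length(norm[[tissue]]))
            else oneSampleT(norm[[tissue]], null = 1)
      rows[[length(rows) + 1L]] <- data.frame(
        tissue = tissue, channel_nm = ch, n = tt$n,
        mean_doci = mean(means[[tissue]]),
        normalized_mean = mean(norm[[tissue]]),
        t = tt$t, df = tt$df, p = tt$p
      )
    }
  }
  tab <- do.call(rbind, rows)
  tab$q <- NA_real_
  tested <- !is.na(tab$p)
  tab$q[tested] <- p.adjust(tab$p[tested], method = "BH")
  tab$neglog10p <- -log10(tab$p)
  tab$significant <- !is.na(tab$p) & tab$p < alpha
  rownames(tab) <- NULL
  new("ROIStatsTable",
    table = tab, contrast = contrast,
    referenceTissue = rois@referenceTissue, alpha = alpha
  )
}
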