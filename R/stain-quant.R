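## Computerized image analysis of fluorescence sections and cultured cells:
## tumor masking from the nuclear (DAPI) channel, stained-area/tumor-area
## ratios at a fixed shared intensity threshold, nucleus counting with
## optional watershed splitting, and stain-per-nucleus quantification.
## Low-level raster operations (thresholding, hole filling, labeling,
## distance-transform watershed) are delegated to EBImage.

.otsuThreshold <- function(m) {
  hi <- max(m)
  if (hi <= 0) stop("cannot threshold an all-zero image")
  EBImage::otsu(EBImage::Image(m / hi), range = c(0, 1)) * hi
}

.binarize <- function(m, method, fixedThreshold) {
  thr <- if (method == "fixed") {
    if (is.null(fixedThreshold))
      stop("method 'fixed' requires 'fixedThreshold'")
    fixedThreshold
  } else {
    .otsuThreshold(m)
  }
  list(mask = m >= thr, threshold = thr)   # thresholds are inclusive
}

#' Segment the tumor region from the nuclear channel
#'
#' Binarizes the DAPI channel (Otsu's method by default, or a fixed
#' threshold), fills holes, and removes connected components smaller than
#' `minComponentPx`; the remaining components form the tumor mask, with the
#' area reported both in pixels and in square millimetres.
#'
#' @param nuclear nuclear-channel intensity matrix.
#' @param pixelSizeUm pixel edge length in micrometres.
#' @param method `"otsu"` or `"fixed"`.
#' @param fixedThreshold intensity threshold when `method = "fixed"`.
#' @param minComponentPx smallest component kept (default 50 px).
#' @return a [MaskResult-class].
#' @export
tumorMask <- function(nuclear, pixelSizeUm, method = c("otsu", "fixed"),
                      fixedThreshold = NULL, minComponentPx = 50L) {
  method <- match.arg(method)
  assertNumber(pixelSizeUm, "pixelSizeUm", lower = 1e-9)
  if (length(nuclear) == 0L || all(nuclear <= 0))
    stop("empty mask: the nuclear image carries no signal")
  b <- .binarize(nuclear, method, fixedThreshold)
  if (!any(b$mask)) stop("empty mask: no pixel reaches the threshold")
  filled <- EBImage::fillHull(EBImage::Image(b$mask * 1))
  labels <- EBImage::bwlabel(filled)
  sizes <- tabulate(as.integer(EBImage::imageData(labels)))
  keep <- which(sizes >= minComponentPx)
  if (length(keep) == 0L)
    stop("empty mask: all components smaller than minComponentPx")
  mask <- matrix(as.integer(EBImage::imageData(labels)) %in% keep,
                 nrow(nuclear), ncol(nuclear))
  areaPx <- sum(mask)
  new("MaskResult", mask = mask, areaPx = as.integer(areaPx),
      areaMm2 = areaPx * (pixelSizeUm / 1000)^2,
      thresholdUsed = b$threshold)
}

#' Stained-area to tumor-area ratio
#'
#' The fraction of tumor-mask pixels whose marker intensity reaches a fixed
#' threshold. The threshold is a configuration value meant to be shared
#' across every image of a comparison ("same intensity settings
#' irrespective of treatment").
#'
#' @param marker marker-channel intensity matrix.
#' @param tumor a [MaskResult-class] from [tumorMask()].
#' @param threshold marker intensity threshold (inclusive).
#' @return ratio in \[0, 1\].
#' @export
stainedAreaRatio <- function(marker, tumor, threshold) {
  stopifnot(is(tumor, "MaskResult"))
  if (!identical(dim(marker), dim(tumor@mask)))
    stop("marker and tumor mask shapes differ")
  if (tumor@areaPx == 0L) stop("tumor mask is empty")
  sum(marker >= threshold & tumor@mask) / tumor@areaPx
}

#' Count stained nuclei
#'
#' Binarizes the nuclear channel, fills holes, labels connected components
#' and discards those below `minAreaPx`. With `watershed = TRUE` (default)
#' touching nuclei are first split by a distance-transform watershed.
#' A blank image counts zero.
#'
#' @param nuclear nuclear-channel intensity matrix.
#' @param minAreaPx smallest component counted as a nucleus (default 20).
#' @param method `"otsu"` or `"fixed"` thresholding.
#' @param fixedThreshold threshold when `method = "fixed"`.
#' @param watershed split touching nuclei (default TRUE).
#' @return integer nucleus count.
#' @export
countNuclei <- function(nuclear, minAreaPx = 20L,
                        method = c("otsu", "fixed"), fixedThreshold = NULL,
                        watershed = TRUE) {
  method <- match.arg(method)
  if (length(nuclear) == 0L || all(nuclear <= 0)) return(0L)
  b <- .binarize(nuclear, method, fixedThreshold)
  if (!any(b$mask)) return(0L)
  filled <- EBImage::fillHull(EBImage::Image(b$mask * 1))
  labels <- if (isTRUE(watershed)) {
    EBImage::watershed(EBImage::distmap(filled))
  } else {
    EBImage::bwlabel(filled)
  }
  sizes <- tabulate(as.integer(EBImage::imageData(labels)))
  sum(sizes >= minAreaPx)
}

#' Marker stain per nucleus
#'
#' Marker-positive pixel count over the whole image divided by the number
#' of DAPI-stained nuclei (the cultured-cell readout). Undefined when no
#' nucleus is detected.
#'
#' @param marker marker-channel intensity matrix.
#' @param nuclear nuclear-channel intensity matrix (same shape).
#' @param markerThreshold marker intensity threshold (inclusive).
#' @param ... passed to [countNuclei()].
#' @return list with `stainedPx`, `nNuclei`, `perNucleus` (NA when
#'   `nNuclei == 0`).
#' @export
stainPerNucleus <- function(marker, nuclear, markerThreshold, ...) {
  if (!identical(dim(marker), dim(nuclear)))
    stop("marker and nuclear shapes differ")
  stained <- sum(marker >= markerThreshold)
  n <- countNuclei(nuclear, ...)
  list(stainedPx = as.integer(stained), nNuclei = n,
       perNucleus = if (n == 0L) NA_real_ else stained / n)
}

#' Compare per-image quantifications between groups
#'
#' Pairwise Mann-Whitney U tests over per-image (per-section) values, one
#' observation per image, as in a design with several sections per animal
#' and several animals per group.
#'
#' @param values numeric vector of per-image measurements.
#' @param groups group label per value (at least two groups, each
#'   non-empty).
#' @return data.frame with one row per group pair: `group_a`, `group_b`,
#'   `n_a`, `n_b`, `U`, `p_two_sided`, `method`.
#' @export
compareGroups <- function(values, groups) {
  if (length(values) != length(groups))
    stop("values and groups must have equal length")
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) < 2L) stop("need at least two groups")
  pairs <- utils::combn(lev, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    tr <- mannWhitneyU(values[groups == a], values[groups == b])
    data.frame(group_a = a, group_b = b, n_a = tr@n1, n_b = tr@n2,
               U = tr@statistic, p_two_sided = tr@pTwoSided,
               method = tr@method, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
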