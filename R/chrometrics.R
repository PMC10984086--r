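# Nuclear segmentation and chrometric feature extraction.

#' The chrometric feature registry
#'
#' Fourteen per-nucleus descriptors of DNA-stain intensity distribution and
#' nuclear morphology used by the DZ/LZ classifier: intensity
#' minimum/maximum/mean/SD, histogram entropy, the 80-to-20 percentile
#' ratio, the heterochromatin-to-euchromatin pixel ratio, and area,
#' perimeter, equivalent radius, circularity, eccentricity, aspect ratio
#' and solidity. The raw 20/50/80 intensity percentiles are carried in the
#' feature table (see \code{\link{extractChrometricFeatures}}) but kept out
#' of the registry: as location statistics they are confounded with
#' staining/illumination, whereas their ratio is scale-free. New features
#' can be added here without touching callers.
#'
#' @return Character vector of feature column names.
#' @export
chrometricFeatureNames <- function() {
  c("min_intensity", "max_intensity", "mean_intensity", "sd_intensity",
    "entropy", "ratio_p80_p20", "hc_ec_ratio",
    "area_um2", "perimeter_um", "radius_um", "circularity",
    "eccentricity", "aspect_ratio", "solidity")
}

#' Segment nuclei from a single-channel image
#'
#' Foreground is found by global thresholding, connected components below
#' \code{minArea} pixels are dropped, and touching nuclei can optionally be
#' split by a distance-transform watershed. Deterministic.
#'
#' @param image numeric matrix (rows = y, columns = x), non-negative.
#' @param thresholdMethod \code{"otsu"} or \code{"mean"} (mean + 2 SD of all
#'   pixels).
#' @param minArea minimum component area in pixels.
#' @param watershed logical; split touching nuclei via distance-transform
#'   watershed.
#' @param pixelSize micrometers per pixel (for centroid/area reporting).
#' @return A list with \code{mask} (integer label matrix, 0 = background)
#'   and \code{nuclei} (data.frame: \code{nucleus_id}, \code{area_px},
#'   \code{area_um2}, centroid \code{x_um}, \code{y_um}).
#' @export
segmentNuclei <- function(image, thresholdMethod = c("otsu", "mean"),
                          minArea = 50, watershed = FALSE, pixelSize = 1) {
  thresholdMethod <- match.arg(thresholdMethod)
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a 2D numeric matrix")
  if (any(image < 0)) stop("image must be non-negative")
  empty <- list(mask = matrix(0L, nrow(image), ncol(image)),
                nuclei = data.frame(nucleus_id = integer(),
                                    area_px = integer(),
                                    area_um2 = numeric(),
                                    x_um = numeric(), y_um = numeric()))
  rng <- range(image)
  if (diff(rng) == 0) return(empty)
  scaled <- (image - rng[1]) / diff(rng)
  thrScaled <- if (thresholdMethod == "otsu") otsu(Image(t(scaled)))
  else mean(scaled) + 2 * sd(as.vector(scaled))
  bw <- scaled > thrScaled
  if (!any(bw)) return(empty)
  # fill enclosed holes (dark intranuclear regions) before labelling
  bw <- t(imageData(fillHull(Image(t(bw * 1))))) > 0
  lab <- if (watershed) {
    dm <- distmap(Image(t(bw)))
    t(imageData(EBImage::watershed(dm)))
  } else {
    t(imageData(bwlabel(Image(t(bw)))))
  }
  lab <- matrix(as.integer(lab), nrow(lab))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minArea)
  if (!length(keep)) return(empty)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  mask <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0L
  mask[pos] <- relab[lab[pos]]
  idx <- which(mask > 0L, arr.ind = TRUE)
  labv <- mask[mask > 0L]
  areaPx <- tabulate(labv, nbins = length(keep))
  # pixel centers at (index - 0.5) * pixelSize, 0-based image coordinates
  xum <- vapply(split((idx[, 2] - 0.5) * pixelSize, labv), mean, 0)
  yum <- vapply(split((idx[, 1] - 0.5) * pixelSize, labv), mean, 0)
  list(mask = mask,
       nuclei = data.frame(nucleus_id = seq_along(keep),
                           area_px = areaPx,
                           area_um2 = areaPx * pixelSize^2,
                           x_um = as.numeric(xum), y_um = as.numeric(yum)))
}

#' Extract chrometric features for each labelled nucleus
#'
#' Intensities are min-max normalized per image (making features comparable
#' across images) before per-nucleus statistics are computed. Percentiles
#' use linear interpolation on sorted pixel values. Nuclei with fewer than
#' 10 pixels are flagged and get missing features.
#'
#' @param image numeric intensity matrix.
#' @param mask integer label matrix of the same size (0 = background).
#' @param pixelSize micrometers per pixel.
#' @param k_sd HC/EC threshold multiplier passed to \code{\link{hcEcRatio}}.
#' @param normalize min-max normalize the image first (default TRUE).
#' @return A data.frame with one row per nucleus: \code{nucleus_id},
#'   centroid \code{x_um}/\code{y_um}, \code{flagged}, and the
#'   \code{\link{chrometricFeatureNames}} columns.
#' @export
extractChrometricFeatures <- function(image, mask, pixelSize = 1,
                                      k_sd = 1, normalize = TRUE) {
  stopifnot(is.matrix(image), is.matrix(mask),
            identical(dim(image), dim(mask)))
  rng <- range(image)
  norm <- if (normalize && diff(rng) > 0)
    (image - rng[1]) / diff(rng) else image
  pos <- which(mask > 0L)
  idxList <- split(pos, mask[pos])
  labs <- as.integer(names(idxList))
  hc <- hcEcRatio(image, mask, k_sd = k_sd)
  out <- lapply(labs, function(l) {
    lin <- idxList[[as.character(l)]]
    px <- norm[lin]
    idx <- arrayInd(lin, dim(mask))
    cx <- mean((idx[, 2] - 0.5) * pixelSize)
    cy <- mean((idx[, 1] - 0.5) * pixelSize)
    base <- data.frame(nucleus_id = l, x_um = cx, y_um = cy)
    if (length(px) < 10) {
      allCols <- c("min_intensity", "max_intensity", "mean_intensity",
                   "sd_intensity", "entropy", "p20", "p50", "p80",
                   "ratio_p80_p20", "hc_ec_ratio", "area_um2",
                   "perimeter_um", "radius_um", "circularity",
                   "eccentricity", "aspect_ratio", "solidity")
      feats <- as.data.frame(as.list(setNames(
        rep(NA_real_, length(allCols)), allCols)))
      return(cbind(base, flagged = TRUE, feats))
    }
    p <- pctl(px, c(0.2, 0.5, 0.8))
    h <- tabulate(pmin(64L, floor(px * 64) + 1L), nbins = 64L)
    pr <- h[h > 0] / length(px)
    shp <- nucleusShape(idx, pixelSize)
    area <- length(px) * pixelSize^2
    perim <- boundaryPixelCount(mask, l, idx) * pixelSize
    feats <- data.frame(
      min_intensity = min(px), max_intensity = max(px),
      mean_intensity = mean(px), sd_intensity = sd(px),
      entropy = -sum(pr * log2(pr)),
      p20 = p[1], p50 = p[2], p80 = p[3],
      ratio_p80_p20 = if (p[1] > 0) p[3] / p[1] else NA_real_,
      hc_ec_ratio = hc$hc_ec_ratio[match(l, hc$nucleus_id)],
      area_um2 = area,
      perimeter_um = perim,
      radius_um = sqrt(area / pi),
      circularity = 4 * pi * area / max(perim, 1e-12)^2,
      eccentricity = shp[1], aspect_ratio = shp[3], solidity = shp[2])
    cbind(base, flagged = FALSE, feats)
  })
  do.call(rbind, out)
}

# eccentricity from central second moments and solidity from the pixel
# convex hull (pixels treated as unit squares for the hull area)
nucleusShape <- function(idx, pixelSize) {
  x <- idx[, 2]; y <- idx[, 1]
  mx <- x - mean(x); my <- y - mean(y)
  mxx <- mean(mx^2) + 1 / 12; myy <- mean(my^2) + 1 / 12
  mxy <- mean(mx * my)
  tr <- mxx + myy
  det <- sqrt(max(0, (mxx - myy)^2 + 4 * mxy^2))
  l1 <- (tr + det) / 2; l2 <- (tr - det) / 2
  ecc <- if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
  aspect <- if (l2 <= 0) 1 else sqrt(l1 / l2)
  corners <- rbind(cbind(x - 0.5, y - 0.5), cbind(x + 0.5, y - 0.5),
                   cbind(x - 0.5, y + 0.5), cbind(x + 0.5, y + 0.5))
  h <- chull(corners)
  hullArea <- polygonArea(corners[h, , drop = FALSE])
  c(ecc, min(1, length(x) / hullArea), aspect)
}

boundaryPixelCount <- function(mask, label, idx = NULL) {
  if (is.null(idx)) idx <- which(mask == label, arr.ind = TRUE)
  # crop to the nucleus bounding box before the neighbour test
  r0 <- min(idx[, 1]); c0 <- min(idx[, 2])
  sel <- matrix(FALSE, max(idx[, 1]) - r0 + 1L, max(idx[, 2]) - c0 + 1L)
  sel[cbind(idx[, 1] - r0 + 1L, idx[, 2] - c0 + 1L)] <- TRUE
  pad <- rbind(FALSE, cbind(FALSE, sel, FALSE), FALSE)
  core <- pad[2:(nrow(pad) - 1), 2:(ncol(pad) - 1)]
  up <- pad[1:(nrow(pad) - 2), 2:(ncol(pad) - 1)]
  dn <- pad[3:nrow(pad), 2:(ncol(pad) - 1)]
  lf <- pad[2:(nrow(pad) - 1), 1:(ncol(pad) - 2)]
  rt <- pad[2:(nrow(pad) - 1), 3:ncol(pad)]
  sum(core & !(up & dn & lf & rt))
}

#' Per-nucleus heterochromatin-to-euchromatin pixel ratio
#'
#' For each nucleus, heterochromatin pixels are those brighter than
#' \code{mean + k_sd * sd} of that nucleus's own pixels; the ratio is
#' |HC| / |EC| with EC the remaining nucleus pixels. The per-nucleus
#' adaptive threshold avoids inter-image illumination confounds and is
#' invariant to affine intensity rescaling. A nucleus with no pixel above
#' threshold gets ratio 0; a constant (zero-spread) nucleus gets ratio 0
#' and is flagged.
#'
#' @param image numeric intensity matrix.
#' @param mask integer label matrix (0 = background).
#' @param k_sd threshold multiplier (default 1).
#' @return data.frame: \code{nucleus_id}, \code{hc_ec_ratio},
#'   \code{flagged}.
#' @export
hcEcRatio <- function(image, mask, k_sd = 1) {
  stopifnot(is.matrix(image), is.matrix(mask),
            identical(dim(image), dim(mask)))
  pos <- which(mask > 0L)
  idxList <- split(pos, mask[pos])
  labs <- as.integer(names(idxList))
  res <- lapply(labs, function(l) {
    px <- image[idxList[[as.character(l)]]]
    s <- sd(px)
    if (is.na(s) || s == 0)
      return(data.frame(nucleus_id = l, hc_ec_ratio = 0, flagged = TRUE))
    nHC <- sum(px > mean(px) + k_sd * s)
    data.frame(nucleus_id = l,
               hc_ec_ratio = if (nHC == 0) 0 else nHC / (length(px) - nHC),
               flagged = FALSE)
  })
  if (!length(res))
    return(data.frame(nucleus_id = integer(), hc_ec_ratio = numeric(),
                      flagged = logical()))
  do.call(rbind, res)
}

#' Welch two-sample comparison of a chrometric feature
#'
#' @param featuresA,featuresB feature tables (data.frames) or numeric
#'   vectors for the two groups.
#' @param feature feature column name when tables are given.
#' @return A list with the Welch \code{statistic}, two-sided \code{p.value},
#'   degrees of freedom and per-group summaries (n, mean, sd).
#' @export
featureGroupTest <- function(featuresA, featuresB, feature = NULL) {
  pull <- function(f) {
    if (is.data.frame(f)) {
      if (is.null(feature)) stop("feature name required for table input")
      f[[feature]]
    } else f
  }
  a <- pull(featuresA); b <- pull(featuresB)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 finite values")
  ht <- t.test(a, b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       df = unname(ht$parameter),
       groupA = c(n = length(a), mean = mean(a), sd = sd(a)),
       groupB = c(n = length(b), mean = mean(b), sd = sd(b)))
}
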