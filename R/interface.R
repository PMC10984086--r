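# DZ/LZ interface delineation, signed distances, band density profiles and
# range-normalized distances.

#' Delineate the DZ/LZ interface from the DZ point cloud
#'
#' The DZ region is estimated as the morphological closing (dilation then
#' erosion with a disc of radius \code{alpha}) of the rasterized DZ point
#' cloud -- a concave, alpha-shape-like hull whose boundary follows the
#' outermost DZ points. The interface is the part of the region contour
#' that does not coincide with the GC polygon (the outward-facing edge of
#' the DZ cells). Signed distances on the raster are negative on the DZ
#' side; the interface band is \code{|d| <= bandWidth / 2} (a 100 um-wide
#' band has 50 um-deep inner and outer layers).
#'
#' @param object a \linkS4class{CellMap}, or an n x 2 matrix of DZ point
#'   coordinates (then \code{polygon} is required).
#' @param dzType phenotype label(s) defining DZ points when \code{object}
#'   is a CellMap.
#' @param bandWidth total band width in micrometers (default 100).
#' @param alpha closing radius in micrometers; defaults to twice the median
#'   DZ nearest-neighbour spacing.
#' @param pixelSize raster resolution in micrometers per pixel.
#' @param polygon GC polygon (n x 2 matrix) when \code{object} is a matrix.
#' @return A \linkS4class{GCInterface}.
#' @export
delineateInterface <- function(object, dzType = "B_DZ", bandWidth = 100,
                               alpha = NULL, pixelSize = 2,
                               polygon = NULL) {
  if (is(object, "CellMap")) {
    pts <- phenotypePoints(object, dzType)
    polygon <- gcPolygon(object)
  } else {
    pts <- as.matrix(object)
    if (is.null(polygon)) stop("polygon required for matrix input")
    polygon <- as.matrix(polygon)
  }
  if (nrow(pts) < 3) stop("need at least 3 DZ points")
  sv <- svd(scale(pts, scale = FALSE))$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) stop("DZ points are collinear")
  if (is.null(alpha)) alpha <- 2 * median(.cppNNSelf(pts))
  ps <- pixelSize
  pad <- alpha + 3 * ps
  xr <- range(polygon[, 1]) + c(-pad, pad)
  yr <- range(polygon[, 2]) + c(-pad, pad)
  ncolpx <- ceiling(diff(xr) / ps)
  nrowpx <- ceiling(diff(yr) / ps)
  origin <- c(xr[1] + ps / 2, yr[1] + ps / 2)
  colOf <- function(x) pmin(ncolpx, pmax(1L, round((x - origin[1]) / ps) + 1L))
  rowOf <- function(y) pmin(nrowpx, pmax(1L, round((y - origin[2]) / ps) + 1L))
  raster <- matrix(0, nrowpx, ncolpx)
  raster[cbind(rowOf(pts[, 2]), colOf(pts[, 1]))] <- 1
  # Close with radius alpha; a sparse (Poisson-gapped) cloud can stay
  # fragmented at the default radius, so the radius is doubled (at most
  # three times) until the largest component holds >= 80% of the region.
  for (grow in 0:3) {
    bw <- 2L * as.integer(floor(alpha / ps)) + 1L
    brush <- makeBrush(bw, "disc")
    mask <- erode(dilate(raster, brush), brush) > 0
    if (!any(mask)) stop("empty DZ region after closing")
    lab <- t(imageData(bwlabel(Image(t(mask)))))
    sizes <- tabulate(lab[lab > 0L])
    if (max(sizes) >= 0.99 * sum(sizes) || grow == 3) break
    alpha <- 2 * alpha
  }
  # solid region: keep the largest component, then seal cracks and edge
  # pockets left by Poisson gaps with a coarser closing (3 * alpha; the
  # bridging chords sag by far less than the pocket depth), fill holes
  mask <- lab == which.max(sizes)
  bw2 <- 2L * as.integer(floor(3 * alpha / ps)) + 1L
  brush2 <- makeBrush(bw2, "disc")
  mask <- erode(dilate(mask * 1, brush2), brush2) > 0
  mask <- t(imageData(fillHull(Image(t(mask * 1))))) > 0
  xs <- origin[1] + (seq_len(ncolpx) - 1) * ps
  ys <- origin[2] + (seq_len(nrowpx) - 1) * ps
  gx <- matrix(xs, nrowpx, ncolpx, byrow = TRUE)
  gy <- matrix(ys, nrowpx, ncolpx)
  inPoly <- matrix(pointInPolygon(as.vector(gx), as.vector(gy), polygon),
                   nrowpx, ncolpx)
  cl <- contourLines(xs, ys, t(mask * 1), levels = 0.5)
  if (!length(cl)) stop("no DZ boundary contour found")
  closedPoly <- rbind(polygon, polygon[1, ])
  pieces <- list()
  for (cc in cl) {
    v <- cbind(x = cc$x, y = cc$y)
    # contour vertices hugging the GC outline are the GC edge, not the
    # DZ/LZ interface; the region edge can trail the outermost points by
    # up to a Poisson edge-pocket depth, hence the 2.5 * alpha tolerance
    tol <- max(2.5 * ps, 2.5 * alpha)
    keep <- distToPolyline(v[, 1], v[, 2], closedPoly) > tol &
      pointInPolygon(v[, 1], v[, 2], polygon)
    if (!any(keep)) next
    runs <- rle(keep)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (i in which(runs$values)) {
      seg <- v[starts[i]:ends[i], , drop = FALSE]
      if (nrow(seg) >= 2) pieces[[length(pieces) + 1L]] <- seg
    }
  }
  if (!length(pieces))
    stop("interface is empty: DZ region boundary coincides with the GC edge")
  plen <- vapply(pieces, function(b)
    sum(sqrt(diff(b[, 1])^2 + diff(b[, 2])^2)), 0)
  pieces <- pieces[plen >= 0.15 * max(plen)]
  # signed distance (um) to the interface polyline itself (not the region
  # edge, which also runs along the GC outline): negative on the DZ side
  dPoly <- rep(Inf, length(gx))
  for (pc in pieces)
    dPoly <- pmin(dPoly, distToPolyline(as.vector(gx), as.vector(gy), pc))
  signed <- matrix(dPoly, nrowpx, ncolpx) * ifelse(mask, -1, 1)
  new("GCInterface", boundary = pieces, signedDist = signed,
      insidePolygon = inPoly, origin = origin, pixelSize = ps,
      bandWidth = bandWidth, alpha = alpha, polygon = polygon)
}

#' Signed distance to the DZ/LZ interface at arbitrary points
#'
#' Looks up the raster signed distance (micrometers, negative on the DZ
#' side) at the nearest raster pixel.
#'
#' @param interface a \linkS4class{GCInterface}.
#' @param x,y point coordinates in micrometers (vectors).
#' @return Numeric vector of signed distances.
#' @export
signedDistanceAt <- function(interface, x, y) {
  stopifnot(is(interface, "GCInterface"))
  ps <- interface@pixelSize
  o <- interface@origin
  d <- dim(interface@signedDist)
  row <- pmin(d[1], pmax(1L, round((y - o[2]) / ps) + 1L))
  col <- pmin(d[2], pmax(1L, round((x - o[1]) / ps) + 1L))
  interface@signedDist[cbind(row, col)]
}

#' Cell density profile across the DZ/LZ interface band
#'
#' Bins the signed distance to the interface into half-open intervals
#' \code{[lo, hi)} tiling the band and reports per-phenotype cell counts
#' divided by bin areas. Bin areas are measured on the raster (pixels
#' inside the GC polygon whose signed distance falls in the bin, times the
#' pixel area); the method is recorded in the output attributes.
#'
#' @param cellmap a \linkS4class{CellMap}.
#' @param interface a \linkS4class{GCInterface}.
#' @param binWidth bin width in micrometers (> 0).
#' @param phenotype phenotypes to profile (default: all present).
#' @return data.frame: \code{phenotype}, \code{bin_lo}, \code{bin_hi}
#'   (signed distance, micrometers; negative = DZ side), \code{count},
#'   \code{area_um2}, \code{density} (cells per square micrometer), with
#'   attribute \code{area_method = "raster"}.
#' @export
densityProfile <- function(cellmap, interface, binWidth = 10,
                           phenotype = NULL) {
  stopifnot(is(cellmap, "CellMap"), is(interface, "GCInterface"))
  if (binWidth <= 0) stop("binWidth must be positive")
  half <- interface@bandWidth / 2
  edges <- seq(-half, half, by = binWidth)
  if (max(edges) < half) edges <- c(edges, half)
  cells <- cellTable(cellmap)
  if (is.null(phenotype)) phenotype <- sort(unique(cells$phenotype))
  d <- signedDistanceAt(interface, cells$x_um, cells$y_um)
  dpx <- interface@signedDist[interface@insidePolygon]
  out <- NULL
  for (ph in phenotype) {
    dph <- d[cells$phenotype == ph]
    for (i in seq_len(length(edges) - 1L)) {
      lo <- edges[i]; hi <- edges[i + 1L]
      areaPx <- sum(dpx >= lo & dpx < hi)
      area <- areaPx * interface@pixelSize^2
      cnt <- sum(dph >= lo & dph < hi)
      out <- rbind(out, data.frame(phenotype = ph, bin_lo = lo,
                                   bin_hi = hi, count = cnt,
                                   area_um2 = area,
                                   density = if (area > 0) cnt / area
                                   else NA_real_,
                                   stringsAsFactors = FALSE))
    }
  }
  attr(out, "area_method") <- "raster"
  out
}

#' Range-normalized distance to the interface with close/distant labels
#'
#' Absolute signed distance divided by the maximum absolute signed distance
#' of the cell's compartment (or of all cells when
#' \code{perCompartment = FALSE}), giving values in [0, 1]: 0 at the
#' boundary, 1 for the deepest cell. Cells are labelled \code{close} when
#' the value falls below \code{threshold} (default 0.4).
#'
#' @param cellmap a \linkS4class{CellMap}.
#' @param interface a \linkS4class{GCInterface}.
#' @param perCompartment normalize within each compartment (default TRUE).
#'   Compartments come from the map's \code{compartment_true} when present,
#'   otherwise from the sign of the distance.
#' @param threshold close/distant cut on the normalized value.
#' @return data.frame: \code{cell_id}, \code{phenotype},
#'   \code{compartment}, \code{signed_um}, \code{value}, \code{close},
#'   \code{flagged} (TRUE when a compartment had a single cell, leaving the
#'   normalization undefined).
#' @export
rangeNormalizedDistance <- function(cellmap, interface,
                                    perCompartment = TRUE,
                                    threshold = 0.4) {
  stopifnot(is(cellmap, "CellMap"), is(interface, "GCInterface"))
  cells <- cellTable(cellmap)
  d <- signedDistanceAt(interface, cells$x_um, cells$y_um)
  comp <- cells$compartment_true
  if (!perCompartment) comp <- rep("all", nrow(cells))
  if (any(is.na(comp))) comp[is.na(comp)] <- ifelse(d[is.na(comp)] < 0,
                                                    "DZ", "LZ")
  value <- rep(NA_real_, length(d))
  flagged <- logical(length(d))
  for (cp in unique(comp)) {
    sel <- comp == cp
    if (sum(sel) < 2) {
      flagged[sel] <- TRUE
      next
    }
    mx <- max(abs(d[sel]))
    value[sel] <- if (mx > 0) abs(d[sel]) / mx else 0
  }
  data.frame(cell_id = cells$cell_id, phenotype = cells$phenotype,
             compartment = comp, signed_um = d, value = value,
             close = !is.na(value) & value < threshold, flagged = flagged,
             stringsAsFactors = FALSE)
}
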