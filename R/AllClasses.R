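# S4 classes for the central data objects and result containers.

#' CellMap: a point set of cells inside a germinal-center polygon
#'
#' Holds per-cell coordinates (micrometers), marker-level phenotype labels
#' (e.g. \code{"B_DZ"}, \code{"B_LZ"}, \code{"T"}, \code{"gdT"}), optional
#' true compartment labels, and the GC region-of-interest polygon.
#'
#' @slot cells data.frame with columns \code{cell_id}, \code{x_um},
#'   \code{y_um}, \code{phenotype} and optionally \code{compartment_true}.
#' @slot polygon numeric matrix (n x 2) of polygon vertices in micrometers.
#' @exportClass CellMap
setClass("CellMap", slots = c(cells = "data.frame", polygon = "matrix"))

setValidity("CellMap", function(object) {
  msg <- character()
  req <- c("cell_id", "x_um", "y_um", "phenotype")
  missing <- setdiff(req, colnames(object@cells))
  if (length(missing))
    msg <- c(msg, paste0("missing cell column(s): ",
                         paste(missing, collapse = ", ")))
  else {
    if (anyDuplicated(object@cells$cell_id))
      msg <- c(msg, "duplicate cell_id values")
    if (!is.numeric(object@cells$x_um) || !is.numeric(object@cells$y_um))
      msg <- c(msg, "coordinates must be numeric")
  }
  if (ncol(object@polygon) != 2 || nrow(object@polygon) < 3)
    msg <- c(msg, "polygon must be an n x 2 matrix with n >= 3")
  if (!length(msg) && nrow(object@cells)) {
    tol <- 1e-6 * max(1, diff(range(object@polygon[, 1])))
    inside <- pointInPolygon(object@cells$x_um, object@cells$y_um,
                             object@polygon)
    near <- distToPolyline(object@cells$x_um, object@cells$y_um,
                           rbind(object@polygon, object@polygon[1, ])) <= tol
    if (!all(inside | near))
      msg <- c(msg, sprintf("%d cell(s) fall outside the GC polygon",
                            sum(!(inside | near))))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CellMap
#'
#' @param cells data.frame with columns \code{cell_id}, \code{x_um},
#'   \code{y_um}, \code{phenotype} and optionally \code{compartment_true}.
#' @param polygon n x 2 numeric matrix of GC polygon vertices (micrometers).
#'   If \code{NULL}, the convex hull of the cells is used.
#' @return A \linkS4class{CellMap}.
#' @export
CellMap <- function(cells, polygon = NULL) {
  cells <- as.data.frame(cells)
  if (is.null(polygon)) {
    if (nrow(cells) < 3)
      stop("polygon required when fewer than 3 cells are given")
    h <- chull(cells$x_um, cells$y_um)
    polygon <- cbind(cells$x_um[h], cells$y_um[h])
  }
  polygon <- as.matrix(polygon)
  colnames(polygon) <- c("x", "y")
  if (!"compartment_true" %in% colnames(cells))
    cells$compartment_true <- NA_character_
  new("CellMap", cells = cells, polygon = polygon)
}

#' NucleiImage: a rendered nuclear-stain image with its label mask
#'
#' @slot image numeric matrix, single-channel intensities in [0, 1].
#' @slot mask integer matrix of the same size; 0 = background, positive
#'   integers label nuclei.
#' @slot pixelSize micrometers per pixel.
#' @slot nuclei data.frame of per-nucleus ground truth (ids, centroids,
#'   compartment, requested and rendered heterochromatin fraction).
#' @exportClass NucleiImage
setClass("NucleiImage",
         slots = c(image = "matrix", mask = "matrix",
                   pixelSize = "numeric", nuclei = "data.frame"))

setValidity("NucleiImage", function(object) {
  msg <- character()
  if (!identical(dim(object@image), dim(object@mask)))
    msg <- c(msg, "image and mask dimensions differ")
  if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a positive scalar")
  labs <- setdiff(unique(as.vector(object@mask)), 0L)
  if (nrow(object@nuclei) && !setequal(labs, object@nuclei$nucleus_id))
    msg <- c(msg, "mask labels do not match nucleus records")
  if (length(msg)) msg else TRUE
})

#' GCInterface: DZ/LZ boundary with signed-distance geometry
#'
#' The DZ region is estimated as the morphological closing of the rasterized
#' DZ point cloud (a concave, alpha-shape-like hull); the interface is the
#' part of its contour that does not coincide with the GC polygon. Signed
#' distances are negative on the DZ side.
#'
#' @slot boundary list of k x 2 matrices (polyline pieces, micrometers).
#' @slot signedDist numeric matrix of signed distances (micrometers) on the
#'   raster grid; negative inside the DZ region.
#' @slot insidePolygon logical matrix marking raster pixels inside the GC.
#' @slot origin coordinates (micrometers) of the center of pixel [1, 1].
#' @slot pixelSize raster resolution, micrometers per pixel.
#' @slot bandWidth total interface band width in micrometers (the band is
#'   \code{|d| <= bandWidth/2}).
#' @slot alpha closing radius (micrometers) used to build the DZ region.
#' @slot polygon the GC polygon.
#' @exportClass GCInterface
setClass("GCInterface",
         slots = c(boundary = "list", signedDist = "matrix",
                   insidePolygon = "matrix", origin = "numeric",
                   pixelSize = "numeric", bandWidth = "numeric",
                   alpha = "numeric", polygon = "matrix"))

setValidity("GCInterface", function(object) {
  msg <- character()
  if (object@bandWidth <= 0) msg <- c(msg, "bandWidth must be positive")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  if (!length(object@boundary)) msg <- c(msg, "empty boundary polyline")
  if (length(msg)) msg else TRUE
})

# ---- result containers -----------------------------------------------------

#' Result of the nearest-neighbour randomization test
#'
#' @slot observed observed A-to-B nearest-neighbour distances (micrometers).
#' @slot nullDist pooled null distances over label permutations.
#' @slot permMedians per-permutation median A-to-B distance.
#' @slot direction one of \code{"segregation"}, \code{"aggregation"},
#'   \code{"none"}.
#' @slot pValue calibrated two-sided permutation p-value on the median
#'   A-to-B distance (add-one estimator, doubled smaller tail).
#' @slot pooledP two-sided rank-sum p-value of observed vs pooled null
#'   distances (the CDF-style comparison; overstates precision because
#'   pooled distances are correlated).
#' @slot types the query (A) and reference (B) phenotypes.
#' @slot nPerm,seed,alpha provenance.
#' @exportClass RandomizationTestResult
setClass("RandomizationTestResult",
         slots = c(observed = "numeric", nullDist = "numeric",
                   permMedians = "numeric", direction = "character",
                   pValue = "numeric", pooledP = "numeric",
                   types = "character", nPerm = "integer",
                   seed = "integer", alpha = "numeric"))

setValidity("RandomizationTestResult", function(object) {
  msg <- character()
  if (any(object@observed < 0) || any(object@nullDist < 0))
    msg <- c(msg, "distances must be non-negative")
  if (!object@direction %in% c("segregation", "aggregation", "none"))
    msg <- c(msg, "invalid direction")
  if (length(msg)) msg else TRUE
})

#' Cross-validation result for the DZ/LZ nucleus classifier
#'
#' @slot foldConfusion list of per-fold row-normalized confusion matrices.
#' @slot meanConfusion average of the row-normalized fold matrices.
#' @slot foldAccuracy per-fold held-out accuracies.
#' @slot accuracy mean cross-validated accuracy.
#' @slot nir no-information rate (majority-class prior).
#' @slot nirP one-sided signed-rank p-value of fold accuracies against NIR.
#' @slot k,seed provenance.
#' @exportClass CVResult
setClass("CVResult",
         slots = c(foldConfusion = "list", meanConfusion = "matrix",
                   foldAccuracy = "numeric", accuracy = "numeric",
                   nir = "numeric", nirP = "numeric",
                   k = "integer", seed = "integer"))

setValidity("CVResult", function(object) {
  msg <- character()
  rows <- rowSums(object@meanConfusion)
  if (any(abs(rows - 1) > 1e-9))
    msg <- c(msg, "confusion-matrix rows must sum to 1")
  if (object@accuracy < 0 || object@accuracy > 1)
    msg <- c(msg, "accuracy out of [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Correlation estimate with permutation p-value and bootstrap CI
#'
#' @slot method \code{"pearson"} or \code{"kendall"}.
#' @slot estimate the correlation point estimate.
#' @slot permP two-sided permutation p-value (add-one estimator, or exact
#'   when the permutation space was enumerated).
#' @slot ci percentile bootstrap confidence interval.
#' @slot confLevel,nPerm,bBoot,n,seed,exhaustive provenance.
#' @exportClass CorrelationResult
setClass("CorrelationResult",
         slots = c(method = "character", estimate = "numeric",
                   permP = "numeric", ci = "numeric", confLevel = "numeric",
                   nPerm = "integer", bBoot = "integer", n = "integer",
                   seed = "integer", exhaustive = "logical"))

setValidity("CorrelationResult", function(object) {
  msg <- character()
  if (abs(object@estimate) > 1 + 1e-12)
    msg <- c(msg, "estimate out of [-1, 1]")
  if (length(object@ci) == 2 &&
      (object@estimate < object@ci[1] - 1e-12 ||
       object@estimate > object@ci[2] + 1e-12))
    msg <- c(msg, "CI must contain the point estimate")
  if (length(msg)) msg else TRUE
})

#' Running-sum enrichment result
#'
#' @slot es enrichment score in [-1, 1].
#' @slot permP gene-permutation p-value (add-one, two-sided on |ES|).
#' @slot leadingEdge genes driving the extremum of the running sum.
#' @slot signature,nPerm,weight,seed provenance.
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
         slots = c(es = "numeric", permP = "numeric",
                   leadingEdge = "character", signature = "character",
                   nPerm = "integer", weight = "numeric", seed = "integer"))

setValidity("EnrichmentResult", function(object) {
  msg <- character()
  if (abs(object@es) > 1 + 1e-12) msg <- c(msg, "ES out of [-1, 1]")
  if (object@permP <= 0 || object@permP > 1)
    msg <- c(msg, "p must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
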