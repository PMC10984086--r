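# Generics and accessor/show methods.

#' @rdname CellMap-class
#' @param object,x a \linkS4class{CellMap}
#' @export
setGeneric("cellTable", function(x) standardGeneric("cellTable"))

#' @rdname CellMap-class
#' @export
setMethod("cellTable", "CellMap", function(x) x@cells)

#' @rdname CellMap-class
#' @export
setGeneric("gcPolygon", function(x) standardGeneric("gcPolygon"))

#' @rdname CellMap-class
#' @export
setMethod("gcPolygon", "CellMap", function(x) x@polygon)

#' @rdname CellMap-class
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname CellMap-class
#' @export
setMethod("phenotypes", "CellMap", function(x) x@cells$phenotype)

#' @rdname CellMap-class
#' @export
setGeneric("compartments", function(x) standardGeneric("compartments"))

#' @rdname CellMap-class
#' @export
setMethod("compartments", "CellMap", function(x) x@cells$compartment_true)

#' Coordinates of the cells (micrometers)
#' @rdname CellMap-class
#' @export
setGeneric("cellCoords", function(x) standardGeneric("cellCoords"))

#' @rdname CellMap-class
#' @export
setMethod("cellCoords", "CellMap",
          function(x) cbind(x = x@cells$x_um, y = x@cells$y_um))

setMethod("show", "CellMap", function(object) {
  tab <- table(object@cells$phenotype)
  cat("CellMap with", nrow(object@cells), "cells inside a",
      nrow(object@polygon), "-vertex GC polygon\n")
  cat("  phenotypes:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
})

setMethod("show", "NucleiImage", function(object) {
  cat("NucleiImage:", paste(dim(object@image), collapse = " x "),
      "pixels at", object@pixelSize, "um/px;",
      nrow(object@nuclei), "nuclei\n")
})

setMethod("show", "GCInterface", function(object) {
  cat("GCInterface: band width", object@bandWidth, "um, closing radius",
      round(object@alpha, 1), "um,",
      length(object@boundary), "boundary polyline piece(s)\n")
})

setMethod("show", "RandomizationTestResult", function(object) {
  cat("Nearest-neighbour randomization test (", object@types[1], " -> ",
      object@types[2], ")\n", sep = "")
  cat(sprintf("  observed median %.2f um vs null median %.2f um (%d perms)\n",
              median(object@observed), median(object@nullDist),
              object@nPerm))
  cat(sprintf("  direction: %s; permutation p = %.3g; pooled rank-sum p = %.3g\n",
              object@direction, object@pValue, object@pooledP))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf(
    "%d-fold stratified CV: Acc = %.3f (NIR = %.3f, signed-rank p = %.3g)\n",
    object@k, object@accuracy, object@nir, object@nirP))
  cat("  mean row-normalized confusion matrix:\n")
  print(round(object@meanConfusion, 3))
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("%s correlation: r = %.4f, permutation p = %.3g (n = %d)\n",
              object@method, object@estimate, object@permP, object@n))
  cat(sprintf("  %d%% bootstrap CI [%.4f, %.4f] (b = %d)\n",
              round(100 * object@confLevel), object@ci[1], object@ci[2],
              object@bBoot))
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("Enrichment: ES = %.3f, permutation p = %.3g (%d perms)\n",
              object@es, object@permP, object@nPerm))
  cat("  leading edge:", length(object@leadingEdge), "gene(s)\n")
})
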