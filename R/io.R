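# File I/O: cell tables, GC polygons, expression matrices, GMT gene sets.

sepForPath <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a cell table (CSV/TSV) into a CellMap
#'
#' Requires columns \code{cell_id}, \code{x_um}, \code{y_um},
#' \code{phenotype}; \code{compartment_true} is carried along when
#' present. Duplicate ids and non-numeric coordinates are rejected with
#' the offending id / row number.
#'
#' @param path cell table path (.csv or .tsv).
#' @param polygonPath optional polygon vertex table (columns \code{x},
#'   \code{y} or \code{x_um}, \code{y_um}); when absent the convex hull of
#'   the cells is used.
#' @return A \linkS4class{CellMap}.
#' @export
readCellTable <- function(path, polygonPath = NULL) {
  df <- read.delim(path, sep = sepForPath(path), stringsAsFactors = FALSE,
                   colClasses = "character")
  req <- c("cell_id", "x_um", "y_um", "phenotype")
  missing <- setdiff(req, colnames(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  for (cc in c("x_um", "y_um")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad))
      stop(sprintf("non-numeric %s at row %d", cc, bad[1]))
    df[[cc]] <- v
  }
  if (anyDuplicated(df$cell_id))
    stop("duplicate cell_id: ",
         df$cell_id[duplicated(df$cell_id)][1])
  poly <- NULL
  if (!is.null(polygonPath)) {
    pp <- read.delim(polygonPath, sep = sepForPath(polygonPath))
    cn <- colnames(pp)
    xcol <- intersect(c("x", "x_um"), cn)[1]
    ycol <- intersect(c("y", "y_um"), cn)[1]
    if (is.na(xcol) || is.na(ycol))
      stop("polygon file needs x/y (or x_um/y_um) columns")
    poly <- cbind(pp[[xcol]], pp[[ycol]])
  }
  CellMap(df, poly)
}

#' Write a CellMap as CSV (cells) plus polygon CSV
#'
#' @param cellmap a \linkS4class{CellMap}.
#' @param path cell table output path.
#' @param polygonPath optional polygon output path.
#' @return The paths, invisibly.
#' @export
writeCellTable <- function(cellmap, path, polygonPath = NULL) {
  stopifnot(is(cellmap, "CellMap"))
  write.csv(cellTable(cellmap), path, row.names = FALSE, quote = FALSE)
  if (!is.null(polygonPath)) {
    poly <- gcPolygon(cellmap)
    write.csv(data.frame(x_um = poly[, 1], y_um = poly[, 2]), polygonPath,
              row.names = FALSE, quote = FALSE)
  }
  invisible(c(path, polygonPath))
}

#' Read an expression TSV (genes x samples) into a SummarizedExperiment
#'
#' The first column holds gene ids; duplicate gene ids are an error (the
#' declared default; collapse upstream if needed). An optional design
#' sidecar TSV (first column = sample id) populates the colData.
#'
#' @param path expression TSV path.
#' @param designPath optional design sidecar TSV.
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} with one
#'   \code{log2} assay.
#' @export
readExpression <- function(path, designPath = NULL) {
  df <- read.delim(path, sep = sepForPath(path), check.names = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene id: ", genes[duplicated(genes)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values")
  rownames(m) <- genes
  cd <- DataFrame(row.names = colnames(m))
  if (!is.null(designPath)) {
    dd <- read.delim(designPath, sep = sepForPath(designPath),
                     stringsAsFactors = FALSE)
    rn <- as.character(dd[[1]])
    mi <- match(colnames(m), rn)
    if (anyNA(mi)) stop("design file misses sample(s): ",
                        paste(colnames(m)[is.na(mi)], collapse = ", "))
    cd <- DataFrame(dd[mi, -1, drop = FALSE], row.names = colnames(m))
  }
  SummarizedExperiment(assays = list(log2 = m), colData = cd)
}

#' Write a SummarizedExperiment as expression TSV plus design TSV
#'
#' @param se the object to write (first assay used).
#' @param path expression TSV output path.
#' @param designPath optional design output path.
#' @return The paths, invisibly.
#' @export
writeExpression <- function(se, path, designPath = NULL) {
  m <- exprMatrix(se)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(designPath) && is(se, "SummarizedExperiment")) {
    cd <- as.data.frame(colData(se))
    dd <- data.frame(sample = rownames(cd), cd, check.names = FALSE)
    write.table(dd, designPath, sep = "\t", row.names = FALSE,
                quote = FALSE)
  }
  invisible(c(path, designPath))
}

#' Read / write GMT gene-set files
#'
#' GMT lines are \code{name<TAB>description<TAB>gene1<TAB>gene2...}; empty
#' gene sets are rejected.
#'
#' @param path GMT file path.
#' @return \code{readGMT}: a named list of \code{\link{geneSignature}}
#'   objects.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("empty gene set in GMT: ", f[1])
    geneSignature(f[1], f[-(1:2)])
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' @rdname readGMT
#' @param signatures named list of \code{\link{geneSignature}} objects (or
#'   character vectors).
#' @export
writeGMT <- function(signatures, path) {
  lines <- vapply(names(signatures), function(nm) {
    paste(c(nm, nm, signatureGenes(signatures[[nm]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
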