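# Synthetic germinal-center point patterns with planted ground truth.

#' Configuration for the synthetic GC tissue map
#'
#' Defaults describe a mid-sized tonsillar GC: a 350 um-radius disc split
#' into equal-area DZ (left) and LZ (right) half-planes, densely packed with
#' B cells and sparsely permeated by T cells whose entry into the DZ is
#' limited by independent thinning.
#'
#' @param gc_radius GC disc radius (micrometers).
#' @param dz_fraction proportion of GC area assigned to the DZ half-plane,
#'   in (0, 1).
#' @param n_b_cells number of B cells, placed uniformly over the GC.
#' @param t_intensity T-cell intensity (points per square micrometer) of the
#'   homogeneous parent process.
#' @param dz_t_retention probability in [0, 1] that a T cell falling in the
#'   DZ is kept (the repulsion knob; 1 = no repulsion, 0 = full exclusion).
#' @param gdt_intensity parent intensity of gamma-delta-T-like cells.
#' @param gdt_dz_enrichment multiplicative DZ intensity factor (>= 0) for
#'   gamma-delta-T-like cells.
#' @param seed integer seed for the map sub-stream.
#' @return A validated list of class \code{TissueSimConfig}.
#' @export
TissueSimConfig <- function(gc_radius = 350, dz_fraction = 0.5,
                            n_b_cells = 1500, t_intensity = 5e-4,
                            dz_t_retention = 0.2, gdt_intensity = 2e-5,
                            gdt_dz_enrichment = 3, seed = 1L) {
  cfg <- list(gc_radius = gc_radius, dz_fraction = dz_fraction,
              n_b_cells = n_b_cells, t_intensity = t_intensity,
              dz_t_retention = dz_t_retention, gdt_intensity = gdt_intensity,
              gdt_dz_enrichment = gdt_dz_enrichment, seed = as.integer(seed))
  if (!is.numeric(gc_radius) || gc_radius <= 0)
    stop("gc_radius must be positive")
  if (dz_fraction <= 0 || dz_fraction >= 1)
    stop("dz_fraction must lie in (0, 1)")
  if (!isCount(n_b_cells)) stop("n_b_cells must be a non-negative count")
  if (t_intensity < 0 || gdt_intensity < 0)
    stop("intensities must be non-negative")
  if (dz_t_retention < 0 || dz_t_retention > 1)
    stop("dz_t_retention must lie in [0, 1]")
  if (gdt_dz_enrichment < 0) stop("gdt_dz_enrichment must be >= 0")
  structure(cfg, class = "TissueSimConfig")
}

#' Simulate a germinal-center cell map
#'
#' B cells are uniform over the GC disc and labelled by their compartment
#' (\code{B_DZ} / \code{B_LZ}, mirroring AID+ and EGR1+ marker identities).
#' T cells are drawn from a homogeneous Poisson process over the GC and then
#' independently thinned inside the DZ with retention
#' \code{dz_t_retention}. Gamma-delta-T-like cells use
#' \code{gdt_dz_enrichment} as a DZ intensity multiplier.
#'
#' @param cfg a \code{\link{TissueSimConfig}}.
#' @return A list with elements \code{map} (a \linkS4class{CellMap}) and
#'   \code{truth} (per-cell true compartments, the DZ chord position, and
#'   the config).
#' @export
simulateGCMap <- function(cfg = TissueSimConfig()) {
  stopifnot(inherits(cfg, "TissueSimConfig"))
  R <- cfg$gc_radius
  xcut <- chordForAreaFraction(R, cfg$dz_fraction)
  poly <- discPolygon(R)
  # uniform sampling inside the polygonal GC outline (rejection from disc)
  runifGC <- function(n) {
    out <- matrix(numeric(0), 0, 2)
    while (nrow(out) < n) {
      cand <- runifDisc(2 * (n - nrow(out)) + 16L, R)
      ok <- pointInPolygon(cand[, 1], cand[, 2], poly)
      out <- rbind(out, cand[ok, , drop = FALSE])
    }
    out[seq_len(n), , drop = FALSE]
  }
  withSeed(deriveSeed(cfg$seed, "gc-map"), {
    b <- runifGC(cfg$n_b_cells)
    area <- polygonArea(poly)
    nT <- rpois(1, cfg$t_intensity * area)
    tt <- runifGC(nT)
    inDZ <- tt[, 1] < xcut
    keep <- !inDZ | (runif(nT) < cfg$dz_t_retention)
    tt <- tt[keep, , drop = FALSE]
    # gamma-delta-like cells: thinning from the dominating intensity
    gmax <- cfg$gdt_intensity * max(1, cfg$gdt_dz_enrichment)
    nG <- rpois(1, gmax * area)
    gg <- runifGC(nG)
    gRate <- ifelse(gg[, 1] < xcut,
                    cfg$gdt_intensity * cfg$gdt_dz_enrichment,
                    cfg$gdt_intensity)
    gg <- gg[runif(nG) < gRate / gmax, , drop = FALSE]
  })
  xy <- rbind(b, tt, gg)
  comp <- ifelse(xy[, 1] < xcut, "DZ", "LZ")
  pheno <- c(ifelse(b[, 1] < xcut, "B_DZ", "B_LZ"),
             rep("T", nrow(tt)), rep("gdT", nrow(gg)))
  cells <- data.frame(cell_id = sprintf("c%05d", seq_len(nrow(xy))),
                      x_um = xy[, 1], y_um = xy[, 2],
                      phenotype = pheno, compartment_true = comp,
                      stringsAsFactors = FALSE)
  map <- CellMap(cells, poly)
  truth <- list(compartment = setNames(comp, cells$cell_id),
                dz_x_cut = xcut, config = cfg)
  list(map = map, truth = truth)
}

#' Lay out a cell map on a regular grid
#'
#' Convenience generator for nucleus-rendering fixtures: places
#' \code{n_dz + n_lz} cells on a square grid with guaranteed spacing, DZ
#' cells on the left block and LZ cells on the right, inside a rectangular
#' polygon. Spacing must exceed twice the nucleus radius used downstream.
#'
#' @param n_dz,n_lz number of DZ and LZ cells.
#' @param spacing grid spacing in micrometers.
#' @return A \linkS4class{CellMap}.
#' @export
gridCellMap <- function(n_dz, n_lz, spacing = 30) {
  n <- n_dz + n_lz
  ncol <- ceiling(sqrt(n))
  nrow <- ceiling(n / ncol)
  ij <- expand.grid(col = seq_len(ncol), row = seq_len(nrow))[seq_len(n), ]
  x <- ij$col * spacing
  y <- ij$row * spacing
  comp <- c(rep("DZ", n_dz), rep("LZ", n_lz))
  cells <- data.frame(cell_id = sprintf("g%05d", seq_len(n)),
                      x_um = x, y_um = y,
                      phenotype = ifelse(comp == "DZ", "B_DZ", "B_LZ"),
                      compartment_true = comp, stringsAsFactors = FALSE)
  pad <- spacing
  poly <- cbind(x = c(0, max(x) + pad, max(x) + pad, 0),
                y = c(0, 0, max(y) + pad, max(y) + pad))
  CellMap(cells, poly)
}
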