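# Interface delineation on a known half-plane geometry: DZ points fill the
# left half of a square, so the true interface is the vertical midline.
halfSquareMap <- function(nDz = 8000, nOther = 300, side = 1000, seed = 1) {
  set.seed(seed)
  dz <- cbind(runif(nDz, 0, side / 2), runif(nDz, 0, side))
  oth <- cbind(runif(nOther, 0, side), runif(nOther, 0, side))
  cells <- data.frame(
    cell_id = sprintf("h%05d", seq_len(nDz + nOther)),
    x_um = c(dz[, 1], oth[, 1]), y_um = c(dz[, 2], oth[, 2]),
    phenotype = c(rep("B_DZ", nDz), rep("T", nOther)),
    compartment_true = c(rep("DZ", nDz),
                         ifelse(oth[, 1] < side / 2, "DZ", "LZ")))
  CellMap(cells, cbind(c(0, side, side, 0), c(0, 0, side, side)))
}

test_that("the delineated boundary tracks the true midline within 20 um", {
  cm <- halfSquareMap()
  iface <- delineateInterface(cm, pixelSize = 4)
  verts <- do.call(rbind, iface@boundary)
  expect_gt(nrow(verts), 10)
  # directed Hausdorff distance from boundary vertices to the x = 500 line
  expect_lt(max(abs(verts[, 1] - 500)), 20)
})

test_that("signed distance is negative exactly on the DZ side and
          continuous across the midline", {
  cm <- halfSquareMap()
  iface <- delineateInterface(cm, pixelSize = 4)
  xs <- seq(100, 900, by = 25)
  d <- signedDistanceAt(iface, xs, rep(500, length(xs)))
  expect_true(all(d[xs < 480] < 0))
  expect_true(all(d[xs > 520] > 0))
  # |signed distance| approximates distance to the midline
  expect_lt(max(abs(abs(d) - abs(xs - 500))), 25)
  # continuity: sampling every 2 um across the boundary, steps stay small
  fine <- seq(450, 550, by = 2)
  df <- signedDistanceAt(iface, fine, rep(500, length(fine)))
  expect_lt(max(abs(diff(df))), 3 * iface@pixelSize)
  # a vertex of the boundary polyline itself sits at distance ~0
  v <- iface@boundary[[1]][1, ]
  expect_lt(abs(signedDistanceAt(iface, v[1], v[2])), 1.5 * 4)
})

test_that("interface rejects degenerate point sets", {
  poly <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_error(delineateInterface(matrix(c(1, 1, 2, 2), 2), polygon = poly),
               "3 DZ points")
  col <- cbind(c(1, 2, 3), c(1, 2, 3))
  expect_error(delineateInterface(col, polygon = poly), "collinear")
})

test_that("the band is centered with layers bandWidth/2 deep each", {
  cm <- halfSquareMap()
  iface <- delineateInterface(cm, bandWidth = 100, pixelSize = 4)
  prof <- densityProfile(cm, iface, binWidth = 10, phenotype = "T")
  expect_equal(min(prof$bin_lo), -50)
  expect_equal(max(prof$bin_hi), 50)
  # half-open bins tile the band without overlap
  expect_equal(prof$bin_lo[-1], prof$bin_hi[-nrow(prof)])
})

test_that("a uniform phenotype yields a flat density profile", {
  cm <- halfSquareMap(nOther = 4000, seed = 3)
  iface <- delineateInterface(cm, pixelSize = 4)
  prof <- densityProfile(cm, iface, binWidth = 20, phenotype = "T")
  prof <- prof[prof$area_um2 > 0, ]
  expect_gt(chisq.test(prof$count,
                       p = prof$area_um2 / sum(prof$area_um2))$p.value,
            0.01)
})

test_that("a planted T-cell decay into the DZ shows up in the inner
          bins while outer bins stay flat", {
  set.seed(8)
  side <- 1000
  nDz <- 2500
  dz <- cbind(runif(nDz, 0, side / 2), runif(nDz, 0, side))
  # T cells: uniform on the LZ side, exponential decay (30 um scale)
  # of depth into the DZ side
  nT <- 4000
  x <- runif(nT, 0, side)
  keep <- x >= side / 2 | runif(nT) < exp(-(side / 2 - x) / 30)
  x <- x[keep]
  tcells <- cbind(x, runif(length(x), 0, side))
  cells <- data.frame(
    cell_id = sprintf("d%05d", seq_len(nDz + nrow(tcells))),
    x_um = c(dz[, 1], tcells[, 1]), y_um = c(dz[, 2], tcells[, 2]),
    phenotype = c(rep("B_DZ", nDz), rep("T", nrow(tcells))))
  cm <- CellMap(cells, cbind(c(0, side, side, 0), c(0, 0, side, side)))
  iface <- delineateInterface(cm, pixelSize = 4)
  prof <- densityProfile(cm, iface, binWidth = 20, phenotype = "T")
  inner <- prof[prof$bin_hi <= 0, ]
  outer <- prof[prof$bin_lo >= 0 & prof$area_um2 > 0, ]
  # densities fall strictly with depth on the DZ side
  expect_true(all(diff(inner$density) > 0))  # bins ordered deep -> shallow
  # outer side flat within Poisson error
  expect_gt(chisq.test(outer$count,
                       p = outer$area_um2 / sum(outer$area_um2))$p.value,
            0.01)
})

test_that("an absent phenotype gives an all-zero profile", {
  cm <- halfSquareMap(nOther = 100, seed = 5)
  iface <- delineateInterface(cm, pixelSize = 4)
  prof <- densityProfile(cm, iface, binWidth = 25, phenotype = "gdT")
  expect_true(all(prof$count == 0))
  expect_error(densityProfile(cm, iface, binWidth = 0), "positive")
})

test_that("range-normalized distances span [0, 1] with the declared
          close/distant threshold semantics", {
  cm <- halfSquareMap(nOther = 1000, seed = 6)
  iface <- delineateInterface(cm, pixelSize = 4)
  rnd <- rangeNormalizedDistance(cm, iface)
  ok <- !is.na(rnd$value)
  expect_true(all(rnd$value[ok] >= 0 & rnd$value[ok] <= 1))
  # deepest cell of each compartment sits at exactly 1, labelled distant
  for (cp in c("DZ", "LZ")) {
    sub <- rnd[ok & rnd$compartment == cp, ]
    deepest <- sub[which.max(sub$value), ]
    expect_equal(deepest$value, 1)
    expect_false(deepest$close)
  }
  # cells hugging the boundary score near 0 and are labelled close
  near <- rnd[ok & abs(rnd$signed_um) < 10, ]
  expect_true(all(near$close))
  # T cells uniform in depth: threshold 0.4 splits ~40/60
  tsub <- rnd[ok & rnd$phenotype == "T", ]
  expect_lt(abs(mean(tsub$close) - 0.4), 0.07)
})

test_that("single-cell compartments are flagged as undefined", {
  set.seed(9)
  dz <- cbind(runif(300, 0, 250), runif(300, 0, 500))
  cells <- data.frame(cell_id = as.character(1:301),
                      x_um = c(dz[, 1], 480), y_um = c(dz[, 2], 250),
                      phenotype = c(rep("B_DZ", 300), "T"),
                      compartment_true = c(rep("DZ", 300), "LZ"))
  cm <- CellMap(cells, cbind(c(0, 500, 500, 0), c(0, 0, 500, 500)))
  iface <- delineateInterface(cm, pixelSize = 4)
  rnd <- rangeNormalizedDistance(cm, iface)
  expect_true(rnd$flagged[301])
  expect_true(is.na(rnd$value[301]))
})
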