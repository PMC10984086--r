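# Shared fixtures, all generated in code.

# CSR map on a square: n points, labels assigned at random
csrMap <- function(n, seed, side = 500, types = c("T", "B_DZ"),
                   prop = 0.5) {
  set.seed(seed)
  xy <- matrix(runif(2 * n, 0, side), ncol = 2)
  nA <- round(n * prop)
  ph <- sample(c(rep(types[1], nA), rep(types[2], n - nA)))
  CellMap(data.frame(cell_id = sprintf("s%04d", seq_len(n)),
                     x_um = xy[, 1], y_um = xy[, 2], phenotype = ph,
                     stringsAsFactors = FALSE),
          polygon = cbind(c(0, side, side, 0), c(0, 0, side, side)))
}

# rasterized disc image: values `fg` inside radius r around (cx, cy)
discImage <- function(nrow, ncol, cx, cy, r, fg = 1, img = NULL) {
  if (is.null(img)) img <- matrix(0, nrow, ncol)
  for (i in seq_len(nrow)) for (j in seq_len(ncol)) {
    if ((j - cx)^2 + (i - cy)^2 <= r^2) img[i, j] <- fg
  }
  img
}

# labelled feature table with gaussian features; optionally one
# informative column separated by `delta`
gaussianFeatureTable <- function(n, p = 14, delta = 0, seed = 1) {
  set.seed(seed)
  lab <- rep(c("DZ", "LZ"), length.out = n)
  X <- matrix(rnorm(n * p), n)
  X[, 1] <- X[, 1] + ifelse(lab == "DZ", delta, 0)
  colnames(X) <- sprintf("f%02d", seq_len(p))
  cbind(data.frame(nucleus_id = seq_len(n), label = lab), as.data.frame(X))
}

# chrometric feature table from a rendered nuclei grid, labelled by the
# planted compartment (features computed on the generator's label mask)
renderedFeatureTable <- function(nDz, nLz, cfg) {
  g <- gridCellMap(nDz, nLz, spacing = 30)
  ni <- simulateNucleiImage(g, cfg)
  f <- extractChrometricFeatures(ni@image, ni@mask,
                                 pixelSize = cfg$pixel_size)
  truth <- ni@nuclei
  m <- match(f$nucleus_id, truth$nucleus_id)
  f$cell_id <- truth$cell_id[m]
  f$label <- truth$compartment_true[m]
  list(features = f, map = g, image = ni)
}

# independent R-level O(n^2) nearest-neighbour oracle
bruteNN <- function(query, reference) {
  apply(query, 1, function(q)
    min(sqrt((reference[, 1] - q[1])^2 + (reference[, 2] - q[2])^2)))
}

# independent recursive permutation enumerator (for correlation oracle)
enumPerms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in enumPerms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}
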