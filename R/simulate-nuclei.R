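# Synthetic nuclear-stain images with planted heterochromatin fractions.

#' Configuration for the synthetic nuclei renderer
#'
#' Nuclei are discs with three intensity phases that emulate a DNA stain of
#' increasingly compacted chromatin: a euchromatin baseline, bright
#' non-overlapping heterochromatin (HC) foci covering area fraction
#' \code{f_hc} at \code{hc_intensity_ratio} times the baseline, and dark
#' interchromatin voids (DNA-depleted channels) covering
#' \code{void_fraction * f_hc} of the area at baseline intensity scaled by
#' \code{(1 - f_hc)^void_depth}. Compaction therefore raises the bright
#' tail and deepens the dark floor of the intensity distribution while
#' leaving its bulk in place -- the minimum DNA intensity and the 80/20
#' percentile ratio carry the class signal. Each nucleus is scaled by a
#' log-normal staining efficiency factor (coefficient of variation
#' \code{stain_cv}), as in real slides where absolute intensities are not
#' comparable across nuclei, and pixel noise is added.
#'
#' @param pixel_size micrometers per pixel.
#' @param nucleus_radius nucleus radius in micrometers.
#' @param f_hc_dz,f_hc_lz heterochromatin area fractions in [0, 1) for
#'   planted DZ and LZ (and other) nuclei.
#' @param hc_intensity_ratio HC focus intensity relative to euchromatin
#'   (> 1).
#' @param noise_sd additive Gaussian pixel noise scale (intensity units;
#'   the noise-free image lies in [0, 1]).
#' @param base_intensity euchromatin baseline intensity.
#' @param focus_radius_frac HC focus radius as a fraction of the nucleus
#'   radius; voids use half that radius.
#' @param void_fraction void area as a multiple of \code{f_hc}.
#' @param void_depth exponent of the void darkening
#'   \code{(1 - f_hc)^void_depth}.
#' @param stain_cv log-scale SD of the per-nucleus staining factor.
#' @param seed integer seed for the nuclei sub-stream.
#' @return A validated list of class \code{NucleiSimConfig}.
#' @export
NucleiSimConfig <- function(pixel_size = 0.5, nucleus_radius = 10,
                            f_hc_dz = 0.35, f_hc_lz = 0.15,
                            hc_intensity_ratio = 2, noise_sd = 0.02,
                            base_intensity = 0.42,
                            focus_radius_frac = 1 / 7,
                            void_fraction = 0.5, void_depth = 5,
                            stain_cv = 0.3, seed = 1L) {
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (nucleus_radius <= 0) stop("nucleus_radius must be positive")
  if (f_hc_dz < 0 || f_hc_dz >= 1 || f_hc_lz < 0 || f_hc_lz >= 1)
    stop("f_hc fractions must lie in [0, 1)")
  if (hc_intensity_ratio <= 1) stop("hc_intensity_ratio must exceed 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (void_fraction < 0 || void_depth < 0 || stain_cv < 0)
    stop("void/stain parameters must be non-negative")
  structure(list(pixel_size = pixel_size, nucleus_radius = nucleus_radius,
                 f_hc_dz = f_hc_dz, f_hc_lz = f_hc_lz,
                 hc_intensity_ratio = hc_intensity_ratio,
                 noise_sd = noise_sd, base_intensity = base_intensity,
                 focus_radius_frac = focus_radius_frac,
                 void_fraction = void_fraction, void_depth = void_depth,
                 stain_cv = stain_cv, seed = as.integer(seed)),
            class = "NucleiSimConfig")
}

# dart-throw nFoci disc centers of radius fr inside a nucleus of radius
# Rpx, avoiding discs already in `avoid` (matrix: x, y, r); returns centers
throwFoci <- function(nFoci, Rpx, fr, avoid = NULL, maxTries = 20000L) {
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centers) < nFoci && tries < maxTries) {
    tries <- tries + 1L
    rr <- (Rpx - fr) * sqrt(runif(1))
    th <- runif(1, 0, 2 * pi)
    cand <- c(rr * cos(th), rr * sin(th))
    ok <- TRUE
    if (nrow(centers) &&
        any((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 <
            (2 * fr)^2)) ok <- FALSE
    if (ok && !is.null(avoid) && nrow(avoid) &&
        any((avoid[, 1] - cand[1])^2 + (avoid[, 2] - cand[2])^2 <
            (avoid[, 3] + fr)^2)) ok <- FALSE
    if (ok) centers <- rbind(centers, cand)
  }
  centers
}

#' Render a nuclear-stain image for a cell map
#'
#' Each cell becomes a disc-shaped nucleus; planted DZ nuclei receive
#' heterochromatin fraction \code{f_hc_dz}, all others \code{f_hc_lz}.
#' HC foci and interchromatin voids are placed by dart-throwing without
#' overlap, fully inside the nucleus. The label mask assigns one positive
#' integer per nucleus (0 = background) and the rendered per-nucleus HC
#' pixel fraction is recorded as ground truth.
#'
#' @param cellmap a \linkS4class{CellMap} whose cells fit in the frame
#'   without overlap at the requested radius.
#' @param cfg a \code{\link{NucleiSimConfig}}.
#' @return A \linkS4class{NucleiImage}.
#' @export
simulateNucleiImage <- function(cellmap, cfg = NucleiSimConfig()) {
  stopifnot(is(cellmap, "CellMap"), inherits(cfg, "NucleiSimConfig"))
  cells <- cellTable(cellmap)
  n <- nrow(cells)
  if (n == 0) stop("cell map is empty")
  R <- cfg$nucleus_radius
  if (n > 1) {
    d <- as.matrix(dist(cbind(cells$x_um, cells$y_um)))
    d[upper.tri(d, diag = TRUE)] <- Inf
    hit <- which(d < 2 * R, arr.ind = TRUE)
    if (nrow(hit))
      stop(sprintf("nuclei %s and %s overlap at radius %g um",
                   cells$cell_id[hit[1, 1]], cells$cell_id[hit[1, 2]], R))
  }
  ps <- cfg$pixel_size
  Rpx <- R / ps
  ncolpx <- ceiling(max(cells$x_um + R) / ps) + 2L
  nrowpx <- ceiling(max(cells$y_um + R) / ps) + 2L
  if (any(cells$x_um - R < 0) || any(cells$y_um - R < 0))
    stop("cells do not fit in the image frame at the given pixel size")
  img <- matrix(0, nrowpx, ncolpx)
  mask <- matrix(0L, nrowpx, ncolpx)
  fr <- max(cfg$focus_radius_frac * Rpx, 1.5)   # HC focus radius, px
  vr <- max(fr / 2, 1)                          # void radius, px
  comp <- cells$compartment_true
  fhc <- ifelse(!is.na(comp) & comp == "DZ", cfg$f_hc_dz, cfg$f_hc_lz)
  rendered <- numeric(n)
  withSeed(deriveSeed(cfg$seed, "nuclei-image"), {
    noise <- if (cfg$noise_sd > 0)
      matrix(rnorm(nrowpx * ncolpx, 0, cfg$noise_sd), nrowpx) else NULL
    stain <- if (cfg$stain_cv > 0) exp(rnorm(n, 0, cfg$stain_cv))
    else rep(1, n)
    for (i in seq_len(n)) {
      cx <- cells$x_um[i] / ps + 0.5
      cy <- cells$y_um[i] / ps + 0.5
      cols <- max(1L, floor(cx - Rpx - 1)):min(ncolpx, ceiling(cx + Rpx + 1))
      rows <- max(1L, floor(cy - Rpx - 1)):min(nrowpx, ceiling(cy + Rpx + 1))
      gx <- matrix(cols, nrow = length(rows), ncol = length(cols),
                   byrow = TRUE) - cx
      gy <- matrix(rows, nrow = length(rows), ncol = length(cols)) - cy
      innuc <- gx^2 + gy^2 <= Rpx^2
      f <- fhc[i]
      ec <- cfg$base_intensity
      hc <- cfg$hc_intensity_ratio * ec
      void <- ec * (1 - f)^cfg$void_depth
      vals <- matrix(0, length(rows), length(cols))
      vals[innuc] <- ec
      nHC <- 0L
      if (f > 0) {
        nFoci <- round(f * (Rpx / fr)^2)
        foci <- throwFoci(nFoci, Rpx, fr)
        for (k in seq_len(nrow(foci))) {
          inf <- (gx - foci[k, 1])^2 + (gy - foci[k, 2])^2 <= fr^2
          vals[inf & innuc] <- hc
        }
        nHC <- sum(vals == hc & innuc)
        nVoid <- round(cfg$void_fraction * f * (Rpx / vr)^2)
        if (nVoid > 0) {
          avoid <- cbind(foci, rep(fr, nrow(foci)))
          voids <- throwFoci(nVoid, Rpx, vr, avoid = avoid)
          for (k in seq_len(nrow(voids))) {
            inv <- (gx - voids[k, 1])^2 + (gy - voids[k, 2])^2 <= vr^2
            vals[inv & innuc] <- void
          }
        }
      }
      rendered[i] <- if (sum(innuc)) nHC / sum(innuc) else NA_real_
      sub <- img[rows, cols]
      sub[innuc] <- vals[innuc] * stain[i]
      img[rows, cols] <- sub
      msub <- mask[rows, cols]
      msub[innuc] <- i
      mask[rows, cols] <- msub
    }
    if (!is.null(noise)) img <- img + noise
  })
  img <- pmin(pmax(img, 0), 1)
  nuclei <- data.frame(nucleus_id = seq_len(n), cell_id = cells$cell_id,
                       x_um = cells$x_um, y_um = cells$y_um,
                       compartment_true = comp, f_hc = fhc,
                       f_hc_rendered = rendered, stringsAsFactors = FALSE)
  new("NucleiImage", image = img, mask = mask, pixelSize = ps,
      nuclei = nuclei)
}

#' Write / read a NucleiImage as 16-bit TIFF pair
#'
#' The intensity image and the integer label mask are written as
#' single-channel 16-bit TIFFs (mask labels stored verbatim, background 0).
#'
#' @param x a \linkS4class{NucleiImage}.
#' @param imagePath,maskPath output file paths.
#' @return \code{writeNucleiImage} returns the paths invisibly;
#'   \code{readNucleiTiff} returns a list with \code{image} and \code{mask}
#'   matrices.
#' @export
writeNucleiImage <- function(x, imagePath, maskPath) {
  stopifnot(is(x, "NucleiImage"))
  writeImage(Image(t(x@image)), imagePath, type = "tiff",
             bits.per.sample = 16L)
  writeImage(Image(t(x@mask) / 65535), maskPath, type = "tiff",
             bits.per.sample = 16L)
  invisible(c(image = imagePath, mask = maskPath))
}

#' @rdname writeNucleiImage
#' @export
readNucleiTiff <- function(imagePath, maskPath = NULL) {
  img <- t(imageData(readImage(imagePath)))
  out <- list(image = img, mask = NULL)
  if (!is.null(maskPath)) {
    m <- t(imageData(readImage(maskPath)))
    out$mask <- matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  }
  out
}
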