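test_that("config validation rejects out-of-range parameters", {
  expect_error(TissueSimConfig(gc_radius = -1), "gc_radius")
  expect_error(TissueSimConfig(dz_fraction = 1), "dz_fraction")
  expect_error(TissueSimConfig(t_intensity = -1), "non-negative")
  expect_error(TissueSimConfig(dz_t_retention = 1.2), "dz_t_retention")
  expect_error(NucleiSimConfig(hc_intensity_ratio = 1), "exceed 1")
  expect_error(NucleiSimConfig(f_hc_dz = 1), "f_hc")
  expect_error(ExpressionSimConfig(n_de = 10, n_genes = 5), "exceed")
  expect_error(ExpressionSimConfig(gene_sd = 0), "gene_sd")
})

test_that("GC maps are reproducible and respect the geometry", {
  cfg <- TissueSimConfig(n_b_cells = 400, seed = 7)
  s1 <- simulateGCMap(cfg)
  s2 <- simulateGCMap(cfg)
  expect_identical(cellTable(s1$map), cellTable(s2$map))
  cells <- cellTable(s1$map)
  expect_true(all(gcniche:::pointInPolygon(cells$x_um, cells$y_um,
                                 gcPolygon(s1$map)) |
                  sqrt(cells$x_um^2 + cells$y_um^2) <= cfg$gc_radius))
  # compartment label consistent with the planted chord
  expect_identical(cells$compartment_true,
                   ifelse(cells$x_um < s1$truth$dz_x_cut, "DZ", "LZ"))
})

test_that("no repulsion puts about half the T cells in the DZ; full
          exclusion empties it", {
  sim <- simulateGCMap(TissueSimConfig(dz_t_retention = 1,
                                       t_intensity = 2e-3, n_b_cells = 10,
                                       seed = 11))
  cells <- cellTable(sim$map)
  tt <- cells[cells$phenotype == "T", ]
  frac <- mean(tt$compartment_true == "DZ")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(tt)))
  sim0 <- simulateGCMap(TissueSimConfig(dz_t_retention = 0,
                                        t_intensity = 2e-3,
                                        n_b_cells = 10, seed = 12))
  c0 <- cellTable(sim0$map)
  expect_identical(sum(c0$phenotype == "T" & c0$compartment_true == "DZ"),
                   0L)
})

test_that("DZ T-cell counts match the analytic thinning expectation", {
  cfg <- TissueSimConfig(gc_radius = 200, dz_t_retention = 0.2,
                         t_intensity = 1e-3, n_b_cells = 5, seed = 0)
  counts <- vapply(1:400, function(s) {
    cfg$seed <- s
    cells <- cellTable(simulateGCMap(cfg)$map)
    sum(cells$phenotype == "T" & cells$compartment_true == "DZ")
  }, 0)
  expected <- 0.2 * 1e-3 * 0.5 * gcniche:::polygonArea(gcniche:::discPolygon(200))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("gdT DZ enrichment shifts gamma-delta cells into the DZ", {
  cfg <- TissueSimConfig(gdt_intensity = 4e-4, gdt_dz_enrichment = 4,
                         n_b_cells = 10, seed = 3)
  cells <- cellTable(simulateGCMap(cfg)$map)
  g <- cells[cells$phenotype == "gdT", ]
  # expected DZ fraction = 4 / (4 + 1)
  expect_lt(abs(mean(g$compartment_true == "DZ") - 0.8),
            3 * sqrt(0.8 * 0.2 / nrow(g)))
})

test_that("rendered nuclei honour the requested heterochromatin fraction", {
  g <- gridCellMap(8, 8, spacing = 30)
  ni <- simulateNucleiImage(g, NucleiSimConfig(f_hc_dz = 0.3, f_hc_lz = 0.3,
                                               noise_sd = 0, seed = 2))
  # radius 10 um at 0.5 um/px = 20 px >= the rasterization-tolerance bound
  expect_true(all(abs(ni@nuclei$f_hc_rendered - 0.3) <= 0.02))
  # f_hc = 0, no noise: constant nucleus intensity
  ni0 <- simulateNucleiImage(g, NucleiSimConfig(f_hc_dz = 0, f_hc_lz = 0,
                                                noise_sd = 0, seed = 2))
  px <- ni0@image[ni0@mask == 1]
  expect_identical(length(unique(px)), 1L)
  f <- extractChrometricFeatures(ni0@image, ni0@mask, pixelSize = 0.5)
  expect_true(all(abs(f$ratio_p80_p20 - 1) < 1e-12))
})

test_that("overlapping nuclei are rejected naming the colliding pair", {
  cells <- data.frame(cell_id = c("n1", "n2"), x_um = c(30, 42),
                      y_um = c(30, 30), phenotype = "B_DZ",
                      compartment_true = "DZ")
  cm <- CellMap(cells, cbind(c(0, 80, 80, 0), c(0, 0, 60, 60)))
  expect_error(simulateNucleiImage(cm, NucleiSimConfig()),
               "n[12].*n[12].*overlap")
})

test_that("nuclei image round-trips through 16-bit TIFF", {
  g <- gridCellMap(2, 2, spacing = 30)
  ni <- simulateNucleiImage(g, NucleiSimConfig(seed = 9))
  ip <- tempfile(fileext = ".tiff"); mp <- tempfile(fileext = ".tiff")
  writeNucleiImage(ni, ip, mp)
  back <- readNucleiTiff(ip, mp)
  expect_identical(dim(back$image), dim(ni@image))
  expect_identical(back$mask, ni@mask)
  expect_lt(max(abs(back$image - ni@image)), 1 / 65535)
})

test_that("planted DZ/LZ chromatin gap separates minimum DNA intensity", {
  tab <- renderedFeatureTable(60, 60, NucleiSimConfig(seed = 21))$features
  ht <- featureGroupTest(tab[tab$label == "DZ", ], tab[tab$label == "LZ", ],
                         "min_intensity")
  expect_lt(ht$p.value, 0.01)
  expect_lt(ht$groupA[["mean"]], ht$groupB[["mean"]])
})

test_that("paired ROI simulation plants the promised effect structure", {
  cfg <- ExpressionSimConfig(n_genes = 300, n_de = 40, seed = 5)
  sim <- simulatePairedROI(cfg)
  se <- sim$se
  expect_identical(dim(se), c(300L, 20L))
  expect_identical(length(sim$truth$de_genes), 40L)
  # identical pair offsets cancel: within-pair difference variance is
  # 2 * gene_sd^2 regardless of pair_effect_sd
  for (pes in c(0.1, 5)) {
    cfg2 <- ExpressionSimConfig(n_genes = 2000, n_de = 0,
                                pair_effect_sd = pes, seed = 8)
    s <- simulatePairedROI(cfg2)
    x <- SummarizedExperiment::assay(s$se)
    zone <- s$se$zone; pr <- s$se$pair
    d <- vapply(unique(pr), function(p)
      x[, zone == "DZ" & pr == p] - x[, zone == "LZ" & pr == p],
      numeric(nrow(x)))
    expect_lt(abs(mean(apply(d, 1, var)) - 2 * cfg2$gene_sd^2), 0.05)
  }
})

test_that("global-null paired design yields essentially no discoveries", {
  sim <- simulatePairedROI(ExpressionSimConfig(n_de = 0, seed = 31))
  de <- moderatedTPairedDE(sim$se)
  expect_lte(sum(de$significant), 3)
})

test_that("cohort simulation couples DZ activity and T-cell fraction as
          planted", {
  sig <- sprintf("G%04d", 1:80)
  # beta = 0: no coupling
  c0 <- simulateCohort(ExpressionSimConfig(n_genes = 600, n_samples = 500,
                                           cohort_beta = 0, seed = 13),
                       signature = sig)
  score0 <- scoreSignature(c0$se, sig, "mean_z")
  expect_lt(abs(cor(score0, c0$truth$t_fraction)), 0.1)
  # beta = -2: strong anti-correlation
  c2 <- simulateCohort(ExpressionSimConfig(n_genes = 600, n_samples = 300,
                                           seed = 14), signature = sig)
  score2 <- scoreSignature(c2$se, sig, "mean_z")
  ct <- cor.test(score2, c2$truth$t_fraction)
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 1e-3)
  expect_gt(cor(score2, c2$truth$dz_activity), 0.9)
  # tertile-high vs -low DZ score groups differ in the planted direction
  ter <- tertileStratify(score2)
  expect_lt(mean(c2$truth$t_fraction[ter == "high"]),
            mean(c2$truth$t_fraction[ter == "low"]))
})

test_that("same seed gives bit-identical images and matrices", {
  g <- gridCellMap(4, 4, spacing = 30)
  cfg <- NucleiSimConfig(seed = 17)
  expect_identical(simulateNucleiImage(g, cfg)@image,
                   simulateNucleiImage(g, cfg)@image)
  ecfg <- ExpressionSimConfig(n_genes = 100, n_de = 10, seed = 17)
  expect_identical(SummarizedExperiment::assay(simulatePairedROI(ecfg)$se),
                   SummarizedExperiment::assay(simulatePairedROI(ecfg)$se))
})
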