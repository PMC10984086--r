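test_that("balanced subsampling equalizes classes and is reproducible", {
  tab <- gaussianFeatureTable(150, seed = 1)
  tab$label <- c(rep("DZ", 100), rep("LZ", 50))
  b <- balancedSubsample(tab, seed = 3)
  expect_identical(unname(table(b$label)), table(c(rep(1, 50), rep(2, 50))) |>
                     unname())
  expect_identical(balancedSubsample(tab, seed = 3), b)
  expect_error(balancedSubsample(tab, seed = 3, size = 60), "exceeds")
})

test_that("majority-class rows are selected uniformly across seeds", {
  tab <- gaussianFeatureTable(150, seed = 2)
  tab$label <- c(rep("DZ", 100), rep("LZ", 50))
  counts <- integer(100)
  for (s in 1:2000) {
    b <- balancedSubsample(tab, seed = s)
    picked <- b$nucleus_id[b$label == "DZ"]
    counts[picked] <- counts[picked] + 1L
  }
  gof <- chisq.test(counts)
  expect_gt(gof$p.value, 0.01)
})

test_that("a perfectly separating feature yields CV accuracy 1", {
  tab <- gaussianFeatureTable(100, p = 1, seed = 3)
  tab$f01 <- ifelse(tab$label == "DZ", 1, -1) + rnorm(100, 0, 0.01)
  cv <- runStratifiedCV(tab, k = 5, nTrees = 100, seed = 1)
  expect_equal(cv@accuracy, 1)
  expect_equal(cv@nir, 0.5)
})

test_that("label-permuted features give chance-level accuracy and
          row-stochastic confusion matrices", {
  tab <- gaussianFeatureTable(1000, seed = 4)  # labels independent of X
  cv <- runStratifiedCV(tab, k = 10, nTrees = 200, seed = 2)
  expect_lt(abs(cv@accuracy - 0.5), 0.05)
  expect_true(all(abs(rowSums(cv@meanConfusion) - 1) < 1e-9))
  for (cm in cv@foldConfusion)
    expect_true(all(abs(rowSums(cm) - 1) < 1e-9))
  expect_equal(cv@nir, 0.5)
})

test_that("CV input contracts are enforced", {
  tab <- gaussianFeatureTable(30, seed = 5)
  expect_error(runStratifiedCV(tab, k = 1), "at least 2")
  expect_error(runStratifiedCV(tab, k = 20), "at least k")
  tab$label <- "DZ"
  expect_error(runStratifiedCV(tab, k = 5), "both classes")
  tab2 <- gaussianFeatureTable(30, seed = 5)
  tab2$f01[1] <- NA
  expect_error(runStratifiedCV(tab2, k = 5), "missing")
})

test_that("signed-rank NIR test reproduces exact reference values", {
  # all 10 folds above the NIR: exact one-sided p = 1 / 2^10
  allUp <- nirWilcoxonTest(0.5 + (1:10) / 100, 0.5)
  expect_equal(allUp$p.value, 1 / 1024)
  expect_identical(allUp$method, "exact")
  # all folds at the NIR: zero differences dropped, p = 1 by convention
  flat <- nirWilcoxonTest(rep(0.5, 10), 0.5)
  expect_equal(flat$p.value, 1)
  expect_true(flat$flagged)
  # balanced up/down with symmetric magnitudes: p near 1/2
  sym <- nirWilcoxonTest(0.5 + c(1:5, -(1:5)) / 100, 0.5)
  expect_lt(abs(sym$p.value - 0.5), 0.1)
  # enumeration agrees with psignrank when both apply
  acc <- 0.5 + c(0.01, 0.03, -0.02, 0.05, 0.04, 0.07, -0.06, 0.08, 0.09,
                 0.11)
  exact <- nirWilcoxonTest(acc, 0.5)
  d <- acc - 0.5
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  expect_equal(exact$p.value, 1 - psignrank(W - 1, 10))
})

test_that("importance ranking finds the informative feature", {
  hits <- 0
  for (s in 1:100) {
    tab <- gaussianFeatureTable(300, p = 14, delta = 1.5, seed = s)
    fit <- trainForest(tab, nTrees = 100, seed = s)
    hits <- hits + (featureImportanceRanking(fit)$feature[1] == "f01")
  }
  expect_gte(hits, 95)
})

test_that("all-noise features get near-flat importances", {
  tab <- gaussianFeatureTable(2000, p = 14, delta = 0, seed = 77)
  fit <- trainForest(tab, nTrees = 200, seed = 77)
  imp <- featureImportanceRanking(fit)
  expect_equal(sum(imp$importance), 1)
  expect_lt(max(imp$importance) / min(imp$importance), 3)
  expect_error(featureImportanceRanking(lm(1 ~ 1)), "forest")
})

test_that("compaction features dominate on the rendered DZ/LZ fixture", {
  tab <- renderedFeatureTable(60, 60, NucleiSimConfig(seed = 33))$features
  tab <- tab[!tab$flagged, c("label", chrometricFeatureNames())]
  fit <- trainForest(tab, nTrees = 300, seed = 1)
  top3 <- featureImportanceRanking(fit)$feature[1:3]
  expect_true(all(c("min_intensity", "ratio_p80_p20") %in% top3))
})

test_that("holdout prediction maps cells and respects separability", {
  tab <- gaussianFeatureTable(100, p = 3, seed = 9)
  tab$f01 <- ifelse(tab$label == "DZ", 2, -2)
  cells <- data.frame(cell_id = tab$nucleus_id,
                      x_um = runif(100, 0, 100),
                      y_um = runif(100, 0, 100), phenotype = "B")
  cm <- CellMap(cells, cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
  tab$cell_id <- tab$nucleus_id
  pred <- holdoutSpatialPrediction(tab, cm, k = 5, nTrees = 100, seed = 2)
  expect_identical(pred$predicted, pred$label)
  expect_identical(nrow(pred), 100L)
  # determinism
  pred2 <- holdoutSpatialPrediction(tab, cm, k = 5, nTrees = 100, seed = 2)
  expect_identical(pred, pred2)
  # unjoinable ids are warned about and skipped
  tab$cell_id[1] <- 99999
  expect_warning(p3 <- holdoutSpatialPrediction(tab, cm, k = 5,
                                                nTrees = 50, seed = 2),
                 "unjoinable")
  expect_identical(nrow(p3), 99L)
})

test_that("null features give spatially uninformative holdout maps", {
  tab <- gaussianFeatureTable(1000, seed = 10)
  cells <- data.frame(cell_id = tab$nucleus_id,
                      x_um = runif(1000, 0, 500),
                      y_um = runif(1000, 0, 500), phenotype = "B")
  cm <- CellMap(cells, cbind(c(0, 500, 500, 0), c(0, 0, 500, 500)))
  tab$cell_id <- tab$nucleus_id
  pred <- holdoutSpatialPrediction(tab, cm, k = 5, nTrees = 100, seed = 3)
  mcc <- function(t, p) {
    tp <- as.numeric(sum(t == "DZ" & p == "DZ"))
    tn <- as.numeric(sum(t == "LZ" & p == "LZ"))
    fp <- as.numeric(sum(t == "LZ" & p == "DZ"))
    fn <- as.numeric(sum(t == "DZ" & p == "LZ"))
    (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  }
  expect_lt(abs(mcc(pred$label, pred$predicted)), 0.1)
})

test_that("CV accuracy grows with the planted chromatin gap", {
  accs <- vapply(c(0, 0.1, 0.2), function(gap) {
    cfg <- NucleiSimConfig(f_hc_dz = 0.15 + gap, f_hc_lz = 0.15, seed = 55)
    tab <- renderedFeatureTable(50, 50, cfg)$features
    tab <- tab[!tab$flagged, c("label", chrometricFeatureNames())]
    runStratifiedCV(tab, k = 5, nTrees = 200, seed = 4)@accuracy
  }, 0)
  expect_true(all(diff(accs) > -sqrt(0.25 / 100)))  # one-SE tolerance
  expect_gt(accs[3], accs[1])
})
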