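library(SummarizedExperiment)

test_that("moderated t matches the limma empirical-Bayes oracle on the
          paired design", {
  skip_if_not_installed("limma")
  sim <- simulatePairedROI(ExpressionSimConfig(seed = 11))
  de <- moderatedTPairedDE(sim$se)
  x <- assay(sim$se); zone <- sim$se$zone; pair <- sim$se$pair
  d <- vapply(unique(pair), function(p)
    x[, zone == "DZ" & pair == p] - x[, zone == "LZ" & pair == p],
    numeric(nrow(x)))
  fit <- limma::eBayes(limma::lmFit(d, matrix(1, ncol(d))))
  expect_lt(max(abs(de$statistic - fit$t[, 1])), 0.01)
  expect_lt(max(abs(de$p.value - fit$p.value[, 1])), 1e-3)
  expect_equal(de$logFC, unname(fit$coefficients[, 1]))
})

test_that("shrinkage endpoints behave: full pooling ranks by |logFC|,
          d0 = 0 recovers the ordinary paired t exactly", {
  sim <- simulatePairedROI(ExpressionSimConfig(n_genes = 50, n_de = 10,
                                               seed = 21))
  # equal true variances at scale: the estimated prior df is large
  big <- moderatedTPairedDE(simulatePairedROI(
    ExpressionSimConfig(seed = 22))$se)
  expect_true(is.infinite(attr(big, "d0")) || attr(big, "d0") > 20)
  # full pooling: posterior variance constant, ordering equals |logFC|
  deInf <- moderatedTPairedDE(sim$se, priorDf = Inf)
  expect_identical(order(abs(deInf$statistic)), order(abs(deInf$logFC)))
  # ordinary paired t oracle
  x <- assay(sim$se); zone <- sim$se$zone; pair <- sim$se$pair
  d <- vapply(unique(pair), function(p)
    x[, zone == "DZ" & pair == p] - x[, zone == "LZ" & pair == p],
    numeric(nrow(x)))
  tOrd <- apply(d, 1, function(v) t.test(v)$statistic)
  # forcing d0 = 0: posterior variance collapses to the gene variance
  de0 <- moderatedTPairedDE(sim$se, priorDf = 0)
  expect_equal(unname(de0$statistic), unname(tOrd), tolerance = 1e-12)
  expect_equal(de0$s2_post, de0$s2)
})

test_that("moderated t enforces the paired-design contracts", {
  sim <- simulatePairedROI(ExpressionSimConfig(n_genes = 20, n_de = 0,
                                               seed = 2))
  se <- sim$se
  expect_error(moderatedTPairedDE(se[, -1]), "incomplete pair")
  expect_error(moderatedTPairedDE(assay(se)), "zone")
  # BH monotonicity: adjusted p is non-decreasing in raw p
  de <- moderatedTPairedDE(se)
  expect_true(all(diff(de$adj.p[order(de$p.value)]) >= -1e-15))
  expect_true(all(de$adj.p >= de$p.value))
})

test_that("rank-sum variant applies the printed significance filters", {
  set.seed(5)
  x <- matrix(rnorm(100 * 20), 100)
  rownames(x) <- sprintf("G%03d", 1:100)
  colnames(x) <- sprintf("S%02d", 1:20)
  grp <- rep(c("DZ", "LZ"), each = 10)
  x[1:5, grp == "DZ"] <- x[1:5, grp == "DZ"] + 3    # strong, big logFC
  x[6, grp == "DZ"] <- x[6, grp == "DZ"] + 0.15     # below the lfc filter
  de <- moderatedTPairedDE(x, zone = grp, method = "rank_sum",
                           lfcCutoff = 0.25)
  expect_true(all(de$significant[1:5]))
  expect_false(de$significant[6] && abs(de$logFC[6]) <= 0.25)
  expect_true(all(abs(de$logFC[de$significant]) > 0.25))
  expect_true(all(de$adj.p[de$significant] < 0.05))
})

test_that("signature scores follow their definitions and invariances", {
  set.seed(3)
  x <- matrix(rnorm(50 * 12, 7), 50)
  rownames(x) <- sprintf("G%03d", 1:50)
  colnames(x) <- sprintf("S%02d", 1:12)
  # single-gene mean_z equals that gene's z-score
  s1 <- scoreSignature(x, "G005", "mean_z")
  expect_equal(as.numeric(s1), unname((x["G005", ] - mean(x["G005", ])) /
                                        sd(x["G005", ])))
  # mean_z is invariant to gene-wise affine rescaling
  sig <- sprintf("G%03d", 1:10)
  y <- x * rep(runif(50, 0.5, 2), 12) + rep(rnorm(50), 12)
  expect_equal(scoreSignature(x, sig, "mean_z"),
               scoreSignature(y, sig, "mean_z"))
  # total is the plain sum
  expect_equal(as.numeric(scoreSignature(x, sig, "total")),
               unname(colSums(x[sig, ])))
  # constant matrix: mean_z errors, total = n * c
  const <- matrix(2, 5, 4, dimnames = list(sprintf("G%03d", 1:5), 1:4))
  expect_error(scoreSignature(const, sprintf("G%03d", 1:5), "mean_z"),
               "zero-variance")
  expect_equal(as.numeric(scoreSignature(const, sprintf("G%03d", 1:5),
                                         "total")), rep(10, 4))
  # missing genes reported
  expect_warning(scoreSignature(x, c("G001", "nope"), "total"), "absent")
  expect_error(scoreSignature(x, c("no1", "no2")), "no signature gene")
})

test_that("tertile stratification follows the lower-stratum tie rule", {
  expect_identical(as.character(tertileStratify(c(9, 1, 5, 2, 8, 3, 7, 4,
                                                  6))),
                   c("high", "low", "mid", "low", "high", "low", "high",
                     "mid", "mid"))
  # documented tie case: {1,1,1,2,3,3} -> lows at the boundary
  expect_identical(as.character(tertileStratify(c(1, 1, 1, 2, 3, 3))),
                   c("low", "low", "low", "mid", "high", "high"))
  expect_error(tertileStratify(rep(2, 5)), "identical")
  expect_error(tertileStratify(1:2), "at least 3")
})

test_that("enrichment score reproduces hand-computed and extreme cases", {
  stats <- setNames(8:1, letters[1:8])
  # signature occupying the top ranks attains the maximal ES of 1
  top <- enrichmentScore(stats, c("a", "b", "c"), nPerm = 99, seed = 1)
  expect_equal(top@es, 1)
  # hand-computed running sum for a spread signature:
  # hits a(8), c(6), f(3), weights |stat|/17, misses decrement 1/5
  toy <- enrichmentScore(stats, c("a", "c", "f"), nPerm = 99, seed = 1)
  expect_equal(toy@es, 14 / 17 - 1 / 5)
  expect_identical(toy@leadingEdge, c("a", "c"))
  expect_error(enrichmentScore(stats, c("x", "y"), nPerm = 9), "intersect")
  expect_error(enrichmentScore(setNames(1:3, c("a", "a", "b")), "a"),
               "unique")
})

test_that("reversed rankings mirror the enrichment score", {
  set.seed(4)
  stats <- setNames(sort(rnorm(10), decreasing = TRUE), letters[1:10])
  sig <- names(stats)[c(1, 2, 5)]
  e1 <- enrichmentScore(stats, sig, nPerm = 19, seed = 1)@es
  revStats <- -stats
  mirrored <- names(sort(revStats, decreasing = TRUE))[c(10, 9, 6)]
  e2 <- enrichmentScore(revStats, mirrored, nPerm = 19, seed = 1)@es
  expect_equal(e2, -e1)
})

test_that("random signatures give calibrated enrichment p-values", {
  set.seed(6)
  stats <- setNames(rnorm(80), sprintf("g%02d", 1:80))
  rej <- 0
  for (b in 1:200) {
    sig <- sample(names(stats), 8)
    es <- enrichmentScore(stats, sig, nPerm = 99, seed = b)
    rej <- rej + (es@permP <= 0.05)
  }
  expect_gte(rej / 200, 0.02)
  expect_lte(rej / 200, 0.09)
})

test_that("cross-cohort selection recovers planted genes and respects the
          threshold semantics", {
  sig <- sprintf("G%04d", 1:60)
  tc <- sprintf("G%04d", 441:480)
  cohorts <- lapply(1:4, function(i)
    simulateCohort(ExpressionSimConfig(n_genes = 480, n_samples = 120,
                                       seed = i), signature = sig,
                   tcellGenes = tc)$se)
  cc <- crossCohortGeneCorrelations(cohorts, sig, tc, minDatasets = 3)
  expect_gte(mean(sig %in% cc$selected), 0.9)
  # monotone in the threshold: selection at k is a superset of k+1
  for (k in 1:3) {
    sk <- crossCohortGeneCorrelations(cohorts, sig, tc, minDatasets = k)
    sk1 <- crossCohortGeneCorrelations(cohorts, sig, tc,
                                       minDatasets = k + 1)
    expect_true(all(sk1$selected %in% sk$selected))
  }
  # impossible threshold: empty selection
  over <- crossCohortGeneCorrelations(cohorts, sig, tc, minDatasets = 5)
  expect_identical(length(over$selected), 0L)
  # small cohorts are excluded with a warning
  tiny <- cohorts
  tiny[[5]] <- cohorts[[1]][, 1:5]
  expect_warning(crossCohortGeneCorrelations(tiny, sig, tc), "< 10")
  expect_error(crossCohortGeneCorrelations(cohorts[1], sig, tc),
               "at least 2")
})

test_that("DZ-like/LZ-like assignment follows the delta-tertile rule", {
  set.seed(8)
  dz <- rnorm(30)
  # dz = -lz: assignment equals tertiles of dz alone
  g <- dzLzGroupAssignment(dz, -dz)
  ter <- tertileStratify(dz)
  expect_identical(as.character(g),
                   c("LZ-like", "Intermediate", "DZ-like")[as.integer(ter)])
  expect_error(dzLzGroupAssignment(dz, rnorm(10)), "mismatch")
  expect_error(dzLzGroupAssignment(rep(1, 5), rep(2, 5)), "degenerate")
  # two planted clusters are recovered with high purity
  dz2 <- c(rnorm(40, 2), rnorm(40, -2))
  lz2 <- c(rnorm(40, -2), rnorm(40, 2))
  # purity of the assigned labels with respect to the planted clusters
  g2 <- dzLzGroupAssignment(dz2, lz2)
  expect_gte(mean(which(g2 == "DZ-like") <= 40), 0.9)
  expect_gte(mean(which(g2 == "LZ-like") > 40), 0.9)
})
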