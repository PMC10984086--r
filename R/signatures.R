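# Signature derivation (paired moderated t), scoring, stratification,
# enrichment and cross-cohort correlation analyses.

#' A named gene signature
#'
#' @param name signature name.
#' @param genes character vector of unique gene ids (non-empty).
#' @param direction optional named vector of +1/-1 per gene.
#' @return A list of class \code{GeneSignature}.
#' @export
geneSignature <- function(name, genes, direction = NULL) {
  genes <- as.character(genes)
  if (!length(genes)) stop("signature must be non-empty")
  if (anyDuplicated(genes)) stop("duplicate gene ids in signature")
  if (!is.null(direction)) {
    stopifnot(all(names(direction) %in% genes))
  }
  structure(list(name = name, genes = genes, direction = direction),
            class = "GeneSignature")
}

signatureGenes <- function(signature) {
  if (inherits(signature, "GeneSignature")) signature$genes
  else as.character(signature)
}

exprMatrix <- function(expr) {
  if (is(expr, "SummarizedExperiment")) assay(expr) else as.matrix(expr)
}

# Newton solve of trigamma(y) = x (decreasing, convex); standard
# empirical-Bayes ingredient for the variance-prior df.
trigammaInverse <- function(x) {
  vapply(x, function(xi) {
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif) < 1e-8 * y) break
    }
    y
  }, 0)
}

#' Paired DZ/LZ differential expression with a moderated t-statistic
#'
#' The paired design is reduced to per-gene within-pair differences
#' (DZ minus LZ); a one-sample t-test with empirical-Bayes variance
#' shrinkage is applied: the posterior variance is
#' \code{(d0 s0^2 + d_g s_g^2) / (d0 + d_g)}, with the prior
#' \code{(d0, s0^2)} estimated by method-of-moments on the log gene
#' variances (closed form via the digamma/trigamma moments of the scaled
#' chi-square). P-values use \code{d0 + d_g} degrees of freedom and are
#' BH-adjusted. The \code{rank_sum} variant instead compares the two
#' groups per gene by a two-sided rank-sum test with an absolute log-FC
#' filter, as used for single-cell contrasts.
#'
#' @param expr a \link[SummarizedExperiment]{SummarizedExperiment} with a
#'   log2 assay and colData columns \code{zone} and \code{pair}, or a
#'   genes x samples matrix (then supply \code{zone} and, for the paired
#'   path, \code{pair}).
#' @param zone,pair optional vectors overriding the colData columns.
#' @param alpha BH-adjusted significance cut (default 0.05).
#' @param method \code{"moderated_t"} (paired) or \code{"rank_sum"}.
#' @param lfcCutoff absolute log-FC filter applied to the significance
#'   call (default 0; the single-cell convention is 0.25).
#' @param dzLevel zone level treated as the positive direction.
#' @param trim trimming fraction for a heavy-tail-robust prior fit
#'   (default 0, the plain method-of-moments).
#' @param priorDf optional override of the prior degrees of freedom d0
#'   (0 recovers the ordinary paired t; \code{Inf} fully pools variances;
#'   \code{NULL}, the default, estimates d0 from the data).
#' @return data.frame (one row per gene): \code{gene}, \code{logFC},
#'   \code{statistic}, \code{s2}, \code{s2_post}, \code{p.value},
#'   \code{adj.p}, \code{direction}, \code{significant}; prior estimates
#'   are attached as attributes \code{d0} and \code{s02}.
#' @export
moderatedTPairedDE <- function(expr, zone = NULL, pair = NULL,
                               alpha = 0.05,
                               method = c("moderated_t", "rank_sum"),
                               lfcCutoff = 0, dzLevel = "DZ", trim = 0,
                               priorDf = NULL) {
  method <- match.arg(method)
  x <- exprMatrix(expr)
  if (is(expr, "SummarizedExperiment")) {
    cd <- colData(expr)
    if (is.null(zone)) zone <- cd$zone
    if (is.null(pair) && "pair" %in% colnames(cd)) pair <- cd$pair
  }
  if (is.null(zone)) stop("zone labels required")
  zone <- as.character(zone)
  lev <- unique(zone)
  if (length(lev) != 2) stop("exactly two zones required")
  other <- setdiff(lev, dzLevel)
  if (!dzLevel %in% lev) stop("dzLevel not found among zones")
  genes <- rownames(x)
  if (anyDuplicated(genes)) stop("duplicate gene ids")

  if (method == "moderated_t") {
    if (is.null(pair)) stop("pair ids required for the paired path")
    pair <- as.character(pair)
    bad <- names(which(vapply(split(zone, pair), function(z)
      !(sum(z == dzLevel) == 1 && sum(z == other) == 1), TRUE)))
    if (length(bad))
      stop("incomplete pair(s): ", paste(bad, collapse = ", "))
    pairs <- unique(pair)
    P <- length(pairs)
    if (P < 2) stop("need at least 2 complete pairs")
    d <- vapply(pairs, function(p)
      x[, zone == dzLevel & pair == p] - x[, zone == other & pair == p],
      numeric(nrow(x)))
    logFC <- rowMeans(d)
    df <- P - 1
    s2 <- apply(d, 1, var)
    ok <- s2 > 0
    z <- log(s2[ok])
    e <- z - digamma(df / 2) + log(df / 2)
    emean <- mean(e, trim = trim)
    evar <- if (trim > 0) {
      q <- pctl(e, c(trim, 1 - trim))
      var(e[e >= q[1] & e <= q[2]])
    } else var(e)
    gap <- evar - trigamma(df / 2)
    if (is.na(gap) || gap <= 0) {
      d0 <- Inf
      s02 <- exp(emean)
    } else {
      d0 <- 2 * trigammaInverse(gap)
      s02 <- exp(emean - digamma(d0 / 2) + log(d0 / 2))
    }
    if (!is.null(priorDf)) {
      d0 <- priorDf
      if (is.infinite(d0)) s02 <- exp(emean)
    }
    s2post <- if (is.infinite(d0)) rep(s02, length(s2))
    else if (d0 == 0) s2
    else (d0 * s02 + df * s2) / (d0 + df)
    tstat <- logFC / sqrt(s2post / P)
    dfTotal <- df + d0
    p <- 2 * pt(-abs(tstat), df = dfTotal)
    adj <- p.adjust(p, "BH")
    res <- data.frame(gene = genes, logFC = logFC, statistic = tstat,
                      s2 = s2, s2_post = s2post, p.value = p, adj.p = adj,
                      direction = ifelse(logFC >= 0, "up", "down"),
                      significant = adj < alpha & abs(logFC) >= lfcCutoff,
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(res, "d0") <- d0
    attr(res, "s02") <- s02
  } else {
    g1 <- zone == dzLevel
    if (sum(g1) < 3 || sum(!g1) < 3)
      stop("rank_sum path needs at least 3 samples per group")
    logFC <- rowMeans(x[, g1, drop = FALSE]) -
      rowMeans(x[, !g1, drop = FALSE])
    stat <- numeric(nrow(x)); p <- numeric(nrow(x))
    for (i in seq_len(nrow(x))) {
      wt <- wilcox.test(x[i, g1], x[i, !g1], exact = FALSE)
      stat[i] <- unname(wt$statistic); p[i] <- wt$p.value
    }
    adj <- p.adjust(p, "BH")
    res <- data.frame(gene = genes, logFC = logFC, statistic = stat,
                      s2 = NA_real_, s2_post = NA_real_, p.value = p,
                      adj.p = adj,
                      direction = ifelse(logFC >= 0, "up", "down"),
                      significant = adj < alpha & abs(logFC) > lfcCutoff,
                      row.names = NULL, stringsAsFactors = FALSE)
  }
  attr(res, "alpha") <- alpha
  attr(res, "method") <- method
  attr(res, "lfcCutoff") <- lfcCutoff
  res
}

#' Score a gene signature in each sample
#'
#' \code{mean_z}: average of per-gene z-scores (gene-wise standardization
#' across samples), invariant to gene-wise affine rescaling.
#' \code{total}: sum of log2 values over the signature genes.
#'
#' @param expr SummarizedExperiment or genes x samples matrix.
#' @param signature a \code{\link{geneSignature}} or character vector.
#' @param method \code{"mean_z"} or \code{"total"}.
#' @return Named numeric vector of per-sample scores; genes absent from
#'   the matrix are reported in attribute \code{missing_genes} (with a
#'   warning).
#' @export
scoreSignature <- function(expr, signature,
                           method = c("mean_z", "total")) {
  method <- match.arg(method)
  x <- exprMatrix(expr)
  genes <- signatureGenes(signature)
  present <- intersect(genes, rownames(x))
  if (!length(present)) stop("no signature gene present in the matrix")
  missing <- setdiff(genes, present)
  if (length(missing))
    warning(length(missing), " signature gene(s) absent from the matrix")
  sub <- x[present, , drop = FALSE]
  score <- if (method == "mean_z") {
    sds <- apply(sub, 1, sd)
    if (any(sds == 0))
      stop("zero-variance signature gene(s): mean_z undefined")
    colMeans((sub - rowMeans(sub)) / sds)
  } else colSums(sub)
  attr(score, "missing_genes") <- missing
  attr(score, "method") <- method
  score
}

#' Tertile stratification of sample scores
#'
#' Cuts at the empirical 1/3 and 2/3 quantiles (linear-interpolation
#' convention); boundary ties are assigned to the lower stratum.
#'
#' @param scores numeric vector (>= 3 values, not all identical).
#' @return Factor with levels \code{low < mid < high}.
#' @export
tertileStratify <- function(scores) {
  if (length(scores) < 3) stop("need at least 3 samples")
  if (diff(range(scores)) == 0) stop("all scores identical")
  q <- pctl(scores, c(1 / 3, 2 / 3))
  labels <- ifelse(scores <= q[1], "low",
                   ifelse(scores <= q[2], "mid", "high"))
  factor(labels, levels = c("low", "mid", "high"), ordered = TRUE)
}

#' Weighted running-sum enrichment score with gene-permutation p-value
#'
#' Kolmogorov-Smirnov-style running sum over the ranked statistics: hits
#' advance by \code{|stat|^weight} (normalized), misses decrement
#' uniformly; the enrichment score is the signed maximum deviation. The
#' p-value permutes the signature positions over the ranked list
#' (add-one estimator, two-sided on |ES|).
#'
#' @param rankedStats named numeric vector of per-gene statistics (sorted
#'   internally in decreasing order; names must be unique).
#' @param signature a \code{\link{geneSignature}} or character vector;
#'   must intersect the ranked list.
#' @param nPerm number of permutations.
#' @param weight hit-weight exponent (default 1; 0 = unweighted KS).
#' @param seed integer seed.
#' @return An \linkS4class{EnrichmentResult}.
#' @export
enrichmentScore <- function(rankedStats, signature, nPerm = 999,
                            weight = 1, seed = 1L) {
  if (is.null(names(rankedStats)) || anyDuplicated(names(rankedStats)))
    stop("rankedStats must have unique names")
  genes <- signatureGenes(signature)
  ord <- order(rankedStats, decreasing = TRUE)
  stats <- rankedStats[ord]
  hit <- names(stats) %in% genes
  if (!any(hit)) stop("signature does not intersect the ranked list")
  N <- length(stats); nh <- sum(hit)
  if (nh == N) stop("signature covers the whole ranked list")
  w <- abs(stats)^weight
  runningES <- function(hitv) {
    wh <- sum(w[hitv])
    inc <- if (wh > 0) ifelse(hitv, w / wh, 0) else
      ifelse(hitv, 1 / sum(hitv), 0)
    run <- cumsum(inc - ifelse(hitv, 0, 1 / (N - nh)))
    i <- which.max(abs(run))
    c(run[i], i)
  }
  obs <- runningES(hit)
  es <- obs[1]; iMax <- obs[2]
  leading <- if (es >= 0) names(stats)[seq_len(iMax)][hit[seq_len(iMax)]]
  else names(stats)[iMax:N][hit[iMax:N]]
  esNull <- withSeed(deriveSeed(seed, "es-perm"),
                     vapply(seq_len(nPerm), function(b) {
                       hv <- logical(N)
                       hv[sample.int(N, nh)] <- TRUE
                       runningES(hv)[1]
                     }, 0))
  p <- (1 + sum(abs(esNull) >= abs(es) - 1e-12)) / (1 + nPerm)
  new("EnrichmentResult", es = es, permP = p, leadingEdge = leading,
      signature = genes, nPerm = as.integer(nPerm), weight = weight,
      seed = as.integer(seed))
}

#' Cross-cohort correlation of signature genes with a T-cell score
#'
#' In each cohort (>= 10 samples; smaller cohorts are excluded with a
#' warning), every DZ signature gene is correlated with the per-sample
#' mean-z T-cell signature score; genes with a significant negative
#' correlation (BH within cohort) are flagged, flags are counted per gene
#' across cohorts, and genes flagged in at least \code{minDatasets}
#' cohorts are selected.
#'
#' @param cohorts named list of SummarizedExperiments or matrices.
#' @param dzSignature,tcellSignature gene signatures (character vectors or
#'   \code{\link{geneSignature}} objects).
#' @param minDatasets selection threshold on the per-gene flag count.
#' @param alpha BH-adjusted significance level within each cohort.
#' @param method correlation method (default \code{"pearson"}).
#' @return A list: \code{r}, \code{adj.p}, \code{flag} (genes x cohorts
#'   matrices), \code{counts} (per-gene flag counts), \code{selected}
#'   (gene ids with count >= minDatasets), \code{nCohorts}.
#' @export
crossCohortGeneCorrelations <- function(cohorts, dzSignature,
                                        tcellSignature, minDatasets = 3,
                                        alpha = 0.05,
                                        method = "pearson") {
  if (length(cohorts) < 2) stop("need at least 2 cohorts")
  if (is.null(names(cohorts)))
    names(cohorts) <- sprintf("cohort%02d", seq_along(cohorts))
  dzGenes <- signatureGenes(dzSignature)
  keep <- vapply(cohorts, function(co) ncol(exprMatrix(co)) >= 10, TRUE)
  if (!all(keep)) {
    warning("excluding cohort(s) with < 10 samples: ",
            paste(names(cohorts)[!keep], collapse = ", "))
    cohorts <- cohorts[keep]
    if (length(cohorts) < 2) stop("fewer than 2 usable cohorts")
  }
  nC <- length(cohorts)
  r <- adj <- matrix(NA_real_, length(dzGenes), nC,
                     dimnames = list(dzGenes, names(cohorts)))
  flag <- matrix(FALSE, length(dzGenes), nC,
                 dimnames = list(dzGenes, names(cohorts)))
  for (j in seq_len(nC)) {
    x <- exprMatrix(cohorts[[j]])
    tScore <- scoreSignature(x, tcellSignature, method = "mean_z")
    present <- intersect(dzGenes, rownames(x))
    if (!length(present))
      stop("DZ signature absent from cohort ", names(cohorts)[j])
    pv <- rv <- setNames(rep(NA_real_, length(present)), present)
    for (g in present) {
      ct <- cor.test(x[g, ], tScore, method = method)
      rv[g] <- unname(ct$estimate); pv[g] <- ct$p.value
    }
    av <- p.adjust(pv, "BH")
    r[present, j] <- rv
    adj[present, j] <- av
    flag[present, j] <- !is.na(av) & av < alpha & rv < 0
  }
  counts <- rowSums(flag)
  list(r = r, adj.p = adj, flag = flag, counts = counts,
       selected = dzGenes[counts >= minDatasets], nCohorts = nC)
}

#' Assign samples to DZ-like / LZ-like / Intermediate groups
#'
#' The difference score \code{delta = standardize(dz) - standardize(lz)}
#' is split into tertiles: top = DZ-like, middle = Intermediate,
#' bottom = LZ-like. The rule is recorded in the output attributes.
#'
#' @param dzScores,lzScores per-sample signature scores on the same
#'   samples.
#' @return Factor with levels \code{LZ-like, Intermediate, DZ-like};
#'   attribute \code{delta} holds the difference score.
#' @export
dzLzGroupAssignment <- function(dzScores, lzScores) {
  if (length(dzScores) != length(lzScores)) stop("length mismatch")
  delta <- as.numeric(scale(dzScores)) - as.numeric(scale(lzScores))
  if (any(!is.finite(delta))) stop("degenerate scores (zero spread)")
  ter <- tertileStratify(delta)
  out <- factor(c("LZ-like", "Intermediate", "DZ-like")[as.integer(ter)],
                levels = c("LZ-like", "Intermediate", "DZ-like"))
  names(out) <- names(dzScores)
  attr(out, "delta") <- delta
  attr(out, "rule") <- "tertiles of standardized(dz) - standardized(lz)"
  out
}
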