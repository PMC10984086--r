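# Random-forest DZ/LZ nucleus classifier: balancing, stratified CV,
# NIR signed-rank test, importance ranking, spatial holdout prediction.

labeledTableCheck <- function(table) {
  stopifnot(is.data.frame(table), "label" %in% colnames(table))
  feats <- setdiff(colnames(table), c("nucleus_id", "cell_id", "label"))
  if (!length(feats)) stop("no feature columns")
  if (length(unique(table$label)) < 2)
    stop("both classes must be present")
  if (anyNA(table[feats]))
    stop("missing feature values; filter flagged rows first")
  feats
}

#' Balanced subsample of a labelled feature table
#'
#' Draws, without replacement, an equal number of rows per class: the
#' minority-class size by default, or a smaller requested per-class size.
#'
#' @param table data.frame with a \code{label} column and feature columns.
#' @param seed integer seed.
#' @param size optional per-class size (must not exceed any class size).
#' @return The balanced subsample (row order: class blocks).
#' @export
balancedSubsample <- function(table, seed = 1L, size = NULL) {
  labeledTableCheck(table)
  split_ <- split(seq_len(nrow(table)), table$label)
  nmin <- min(lengths(split_))
  if (is.null(size)) size <- nmin
  if (size > nmin)
    stop(sprintf("requested size %d exceeds smallest class size %d",
                 size, nmin))
  idx <- withSeed(deriveSeed(seed, "balanced-subsample"),
                  unlist(lapply(split_, sample, size = size),
                         use.names = FALSE))
  table[idx, , drop = FALSE]
}

# fold assignment preserving class ratios
stratifiedFolds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  withSeed(deriveSeed(seed, "cv-folds"), {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  folds
}

#' Stratified k-fold cross-validation of the DZ/LZ random forest
#'
#' Features are z-scored over the input table, folds preserve class ratios,
#' and per-fold confusion matrices on held-out data are row-normalized and
#' then averaged. The no-information rate (NIR) is the majority-class
#' prior; fold accuracies are tested against it with the one-sided
#' signed-rank test of \code{\link{nirWilcoxonTest}}.
#'
#' @param table data.frame with \code{label} plus feature columns (and
#'   optionally id columns, ignored for training).
#' @param k number of folds (>= 2; each class needs >= k rows).
#' @param nTrees number of trees per forest.
#' @param mtry features tried per split (default \code{sqrt(p)}).
#' @param maxnodes optional maximum number of terminal nodes (default
#'   unlimited).
#' @param seed integer seed controlling folds and forests.
#' @return A \linkS4class{CVResult}.
#' @export
runStratifiedCV <- function(table, k = 10, nTrees = 500, mtry = NULL,
                            maxnodes = NULL, seed = 1L) {
  feats <- labeledTableCheck(table)
  if (k < 2) stop("k must be at least 2")
  y <- factor(table$label)
  if (any(table(y) < k)) stop("each class needs at least k examples")
  X <- scale(as.matrix(table[feats]))
  X[is.nan(X)] <- 0  # constant feature: contributes nothing after z-score
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  folds <- stratifiedFolds(as.character(y), k, seed)
  lev <- levels(y)
  conf <- vector("list", k)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    rf <- withSeed(deriveSeed(seed, paste0("rf-fold-", f)),
                   randomForest(X[tr, , drop = FALSE], y[tr],
                                ntree = nTrees, mtry = mtry,
                                maxnodes = maxnodes))
    pred <- predict(rf, X[!tr, , drop = FALSE])
    tb <- table(factor(y[!tr], lev), factor(pred, lev))
    cm <- matrix(as.numeric(tb), nrow(tb), dimnames = dimnames(tb))
    conf[[f]] <- cm / pmax(rowSums(cm), 1)
    acc[f] <- mean(pred == y[!tr])
  }
  meanConf <- Reduce(`+`, conf) / k
  nir <- max(table(y)) / length(y)
  nirTest <- nirWilcoxonTest(acc, nir)
  new("CVResult", foldConfusion = conf, meanConfusion = meanConf,
      foldAccuracy = acc, accuracy = mean(acc), nir = nir,
      nirP = nirTest$p.value, k = as.integer(k), seed = as.integer(seed))
}

#' One-sided signed-rank test of fold accuracies against the NIR
#'
#' Tests whether per-fold accuracies exceed the no-information rate. Zero
#' differences are dropped (declared convention). With untied absolute
#' differences and at most 25 informative folds the exact signed-rank null
#' is used; with ties, the null is enumerated exactly for up to 15 folds
#' and a tie-corrected normal approximation is used beyond that. All fold
#' accuracies above the NIR with 10 folds give p = 1/1024.
#'
#' @param foldAccuracies numeric vector of per-fold accuracies (>= 5).
#' @param nir the no-information rate to test against.
#' @return List: \code{p.value} (one-sided, greater), \code{statistic}
#'   (signed-rank W+), \code{n} (informative folds), \code{method},
#'   \code{flagged} (TRUE when all differences were zero; then p = 1).
#' @export
nirWilcoxonTest <- function(foldAccuracies, nir) {
  stopifnot(length(foldAccuracies) >= 5, length(nir) == 1)
  d <- foldAccuracies - nir
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(p.value = 1, statistic = 0, n = 0L,
                method = "degenerate", flagged = TRUE))
  r <- rank(abs(d))  # midranks
  W <- sum(r[d > 0])
  ties <- anyDuplicated(r) > 0
  if (!ties && n <= 25) {
    p <- 1 - psignrank(W - 1, n)
    method <- "exact"
  } else if (n <= 15) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wnull <- as.vector(signs %*% r)
    p <- mean(Wnull >= W - 1e-12)
    method <- "exact-enumeration"
  } else {
    mu <- n * (n + 1) / 4
    tie <- sum(tapply(r, r, length)^3 - tapply(r, r, length))
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tie / 48)
    p <- pnorm((W - mu - 0.5) / sig, lower.tail = FALSE)
    method <- "normal-approximation"
  }
  list(p.value = p, statistic = W, n = as.integer(n), method = method,
       flagged = FALSE)
}

#' Train a DZ/LZ random forest on a full labelled table
#'
#' @inheritParams runStratifiedCV
#' @return A \code{randomForest} fit (features z-scored; scaling attributes
#'   attached as \code{attr(fit, "scaling")}).
#' @export
trainForest <- function(table, nTrees = 500, mtry = NULL, maxnodes = NULL,
                        seed = 1L) {
  feats <- labeledTableCheck(table)
  X <- scale(as.matrix(table[feats]))
  X[is.nan(X)] <- 0
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  fit <- withSeed(deriveSeed(seed, "rf-full"),
                  randomForest(X, factor(table$label), ntree = nTrees,
                               mtry = mtry, maxnodes = maxnodes,
                               importance = FALSE))
  attr(fit, "scaling") <- list(center = attr(X, "scaled:center"),
                               scale = attr(X, "scaled:scale"))
  fit
}

#' Feature importance ranking of a fitted forest
#'
#' Mean impurity-decrease (Gini) importances, normalized to sum to one and
#' sorted decreasingly.
#'
#' @param fit a fitted \code{randomForest} model.
#' @return data.frame: \code{feature}, \code{importance} (sums to 1),
#'   sorted by decreasing importance.
#' @export
featureImportanceRanking <- function(fit) {
  if (!inherits(fit, "randomForest")) stop("fit must be a trained forest")
  imp <- importance(fit)[, "MeanDecreaseGini"]
  if (sum(imp) <= 0) imp[] <- 1
  imp <- imp / sum(imp)
  ord <- order(imp, decreasing = TRUE)
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Per-cell labels predicted with the cell held out of training
#'
#' k-fold holdout: each nucleus is predicted by a forest that never saw it,
#' and predictions are joined to the cell map coordinates for rendering a
#' predicted spatial map.
#'
#' @param table labelled feature table carrying a \code{cell_id} (or
#'   \code{nucleus_id} matching the cell map ids) column.
#' @param cellmap a \linkS4class{CellMap}.
#' @inheritParams runStratifiedCV
#' @return data.frame: \code{cell_id}, \code{x_um}, \code{y_um},
#'   \code{label}, \code{predicted}. Unjoinable ids are dropped with a
#'   warning naming them.
#' @export
holdoutSpatialPrediction <- function(table, cellmap, k = 10, nTrees = 500,
                                     seed = 1L) {
  feats <- labeledTableCheck(table)
  ids <- if ("cell_id" %in% colnames(table)) table$cell_id
  else table$nucleus_id
  cells <- cellTable(cellmap)
  m <- match(ids, cells$cell_id)
  if (anyNA(m)) {
    bad <- unique(ids[is.na(m)])
    warning("skipping unjoinable id(s): ",
            paste(head(bad, 10), collapse = ", "))
    table <- table[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
  }
  y <- factor(table$label)
  X <- scale(as.matrix(table[feats]))
  X[is.nan(X)] <- 0
  mtry <- max(1L, floor(sqrt(ncol(X))))
  folds <- stratifiedFolds(as.character(y), k, seed)
  pred <- factor(rep(levels(y)[1], nrow(X)), levels(y))
  for (f in seq_len(k)) {
    tr <- folds != f
    rf <- withSeed(deriveSeed(seed, paste0("rf-holdout-", f)),
                   randomForest(X[tr, , drop = FALSE], y[tr],
                                ntree = nTrees, mtry = mtry))
    pred[!tr] <- predict(rf, X[!tr, , drop = FALSE])
  }
  data.frame(cell_id = cells$cell_id[m], x_um = cells$x_um[m],
             y_um = cells$y_um[m], label = as.character(y),
             predicted = as.character(pred), stringsAsFactors = FALSE)
}
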