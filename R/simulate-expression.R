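# Synthetic expression designs: paired DZ/LZ ROIs and tumor cohorts.

#' Configuration for synthetic expression matrices
#'
#' Defaults mirror the scale of a curated-panel spatial profiling design:
#' 1,800 genes over 10 matched DZ/LZ ROI pairs with 150 planted
#' differentially expressed genes of |log2FC| = 1, and, for cohort
#' simulations, 300 samples per cohort in which a latent DZ-activity
#' variable is anti-correlated with a latent T-cell fraction
#' (\code{cohort_beta} = -2).
#'
#' @param n_genes number of genes in the simulated universe.
#' @param n_pairs number of matched DZ/LZ ROI pairs (paired design).
#' @param n_samples number of samples (cohort design).
#' @param n_de number of planted DE genes (paired design), \code{<= n_genes}.
#' @param logfc planted effect size (log2 scale); half the genes go up in
#'   DZ, half up in LZ.
#' @param gene_sd residual SD of log2 expression.
#' @param pair_effect_sd SD of the shared per-pair offset (cancels within
#'   pairs).
#' @param cohort_beta linear coefficient linking DZ activity to the latent
#'   T-cell fraction on the logit scale (negative = anti-correlation).
#' @param sig_loading loading of the DZ-activity latent on signature genes.
#' @param tcell_loading loading of the (standardized) T-cell fraction on the
#'   T-cell gene block.
#' @param seed integer seed for the expression sub-stream.
#' @return A validated list of class \code{ExpressionSimConfig}.
#' @export
ExpressionSimConfig <- function(n_genes = 1800, n_pairs = 10,
                                n_samples = 300, n_de = 150, logfc = 1,
                                gene_sd = 0.5, pair_effect_sd = 1,
                                cohort_beta = -2, sig_loading = 1,
                                tcell_loading = 1, seed = 1L) {
  if (!isCount(n_genes) || n_genes < 1) stop("n_genes must be a count >= 1")
  if (!isCount(n_pairs)) stop("n_pairs must be a non-negative count")
  if (!isCount(n_samples)) stop("n_samples must be a non-negative count")
  if (!isCount(n_de)) stop("n_de must be a non-negative count")
  if (n_de > n_genes) stop("n_de must not exceed n_genes")
  if (gene_sd <= 0) stop("gene_sd must be positive")
  if (pair_effect_sd < 0) stop("pair_effect_sd must be non-negative")
  structure(list(n_genes = n_genes, n_pairs = n_pairs,
                 n_samples = n_samples, n_de = n_de, logfc = logfc,
                 gene_sd = gene_sd, pair_effect_sd = pair_effect_sd,
                 cohort_beta = cohort_beta, sig_loading = sig_loading,
                 tcell_loading = tcell_loading, seed = as.integer(seed)),
            class = "ExpressionSimConfig")
}

#' Simulate paired DZ/LZ ROI expression with planted log-fold-changes
#'
#' Gene \code{g} in pair \code{i} has log2 expression
#' \code{mu_g + b_i +/- logfc/2 * planted(g) + eps}, with
#' \code{eps ~ N(0, gene_sd)}; the pair offset \code{b_i} is shared by both
#' members of a pair (so it cancels in within-pair differences). The first
#' half of planted genes is up in DZ, the second half up in LZ.
#'
#' @param cfg an \code{\link{ExpressionSimConfig}}.
#' @return A list with \code{se} (a
#'   \link[SummarizedExperiment]{SummarizedExperiment} with colData columns
#'   \code{zone} and \code{pair}) and \code{truth} (planted gene ids and
#'   signs).
#' @export
simulatePairedROI <- function(cfg = ExpressionSimConfig()) {
  stopifnot(inherits(cfg, "ExpressionSimConfig"))
  G <- cfg$n_genes; P <- cfg$n_pairs
  if (P < 2) stop("need at least 2 pairs")
  genes <- sprintf("G%04d", seq_len(G))
  de <- if (cfg$n_de > 0) genes[seq_len(cfg$n_de)] else character()
  sign <- rep(0, G)
  if (cfg$n_de > 0) {
    nUp <- ceiling(cfg$n_de / 2)
    sign[seq_len(nUp)] <- 1
    if (cfg$n_de > nUp) sign[(nUp + 1):cfg$n_de] <- -1
  }
  withSeed(deriveSeed(cfg$seed, "paired-roi"), {
    mu <- rnorm(G, 7, 1.5)
    b <- rnorm(P, 0, cfg$pair_effect_sd)
    dz <- mu + outer(sign * cfg$logfc / 2, rep(1, P)) +
      outer(rep(1, G), b) + matrix(rnorm(G * P, 0, cfg$gene_sd), G)
    lz <- mu - outer(sign * cfg$logfc / 2, rep(1, P)) +
      outer(rep(1, G), b) + matrix(rnorm(G * P, 0, cfg$gene_sd), G)
  })
  expr <- cbind(dz, lz)
  rownames(expr) <- genes
  colnames(expr) <- c(sprintf("DZ_%02d", seq_len(P)),
                      sprintf("LZ_%02d", seq_len(P)))
  cd <- DataFrame(zone = rep(c("DZ", "LZ"), each = P),
                  pair = rep(sprintf("p%02d", seq_len(P)), 2),
                  row.names = colnames(expr))
  se <- SummarizedExperiment(assays = list(log2 = expr), colData = cd)
  truth <- list(de_genes = de, de_sign = setNames(sign[sign != 0],
                                                  genes[sign != 0]),
                config = cfg)
  list(se = se, truth = truth)
}

#' Simulate a tumor cohort with DZ activity anti-correlated to T-cell load
#'
#' Each sample carries a latent DZ activity \code{a ~ N(0, 1)} loading
#' positively on the given signature genes; the latent T-cell fraction is
#' \code{plogis(cohort_beta * a + noise)} and loads on a dedicated T-cell
#' gene block. All latents are recorded.
#'
#' @param cfg an \code{\link{ExpressionSimConfig}}.
#' @param signature character vector of DZ signature gene ids; must be a
#'   subset of the simulated universe \code{G0001..}. Defaults to the first
#'   100 genes.
#' @param tcellGenes character vector of T-cell block gene ids (defaults to
#'   the last 50 genes of the universe).
#' @return A list with \code{se} (SummarizedExperiment; colData holds the
#'   latent \code{dz_activity} and \code{t_fraction}) and \code{truth}.
#' @export
simulateCohort <- function(cfg = ExpressionSimConfig(),
                           signature = NULL, tcellGenes = NULL) {
  stopifnot(inherits(cfg, "ExpressionSimConfig"))
  G <- cfg$n_genes; N <- cfg$n_samples
  genes <- sprintf("G%04d", seq_len(G))
  if (is.null(signature)) signature <- genes[seq_len(min(100, G))]
  if (is.null(tcellGenes))
    tcellGenes <- genes[(G - min(50, G %/% 4) + 1):G]
  if (!length(signature)) stop("empty signature")
  if (!all(signature %in% genes))
    stop("signature genes must be a subset of the simulated universe")
  if (length(intersect(signature, tcellGenes)))
    stop("signature and T-cell block must be disjoint")
  withSeed(deriveSeed(cfg$seed, "cohort"), {
    a <- rnorm(N)
    tfrac <- plogis(cfg$cohort_beta * a + rnorm(N))
    mu <- rnorm(G, 7, 1.5)
    expr <- matrix(rnorm(G * N, 0, cfg$gene_sd), G) + mu
    iSig <- match(signature, genes)
    iT <- match(tcellGenes, genes)
    expr[iSig, ] <- expr[iSig, ] +
      outer(rep(cfg$sig_loading, length(iSig)), a)
    zfrac <- as.numeric(scale(tfrac))
    expr[iT, ] <- expr[iT, ] +
      outer(rep(cfg$tcell_loading, length(iT)), zfrac)
  })
  rownames(expr) <- genes
  colnames(expr) <- sprintf("S%04d", seq_len(N))
  cd <- DataFrame(dz_activity = a, t_fraction = tfrac,
                  row.names = colnames(expr))
  se <- SummarizedExperiment(assays = list(log2 = expr), colData = cd)
  truth <- list(dz_activity = setNames(a, colnames(expr)),
                t_fraction = setNames(tfrac, colnames(expr)),
                signature = signature, tcell_genes = tcellGenes,
                config = cfg)
  list(se = se, truth = truth)
}
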