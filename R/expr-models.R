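#' Training configuration for expression models
#'
#' @param alpha elastic-net mixing parameter in \eqn{(0, 1]}; default 0.5,
#'   balancing the sparsity (L1) and grouping (L2) penalties.
#' @param nFolds number of cross-validation folds (default 5).
#' @param lambdaGrid optional decreasing penalty grid; \code{NULL} lets the
#'   solver build its own path.
#' @param seed RNG seed for fold assignment.
#' @param similarityExponentGrid grid of exponents for the tissue-similarity
#'   observation weights; \code{Inf} hard-thresholds to the test tissue
#'   only. Default \code{c(0, 1, 2, 4, Inf)}.
#' @return a list of class \code{"TrainingConfig"}.
#' @export
trainingConfig <- function(alpha = 0.5, nFolds = 5L, lambdaGrid = NULL,
                           seed = NULL,
                           similarityExponentGrid = c(0, 1, 2, 4, Inf)) {
  stopifnot(alpha > 0, alpha <= 1, nFolds >= 2)
  if (!is.null(lambdaGrid) && is.unsorted(rev(lambdaGrid)))
    stop("lambdaGrid must be decreasing")
  structure(list(alpha = alpha, nFolds = as.integer(nFolds),
                 lambdaGrid = lambdaGrid, seed = seed,
                 similarityExponentGrid = similarityExponentGrid),
            class = "TrainingConfig")
}

#' Tissue similarity matrices
#'
#' @param expressionSimilarity,regulatorySimilarity symmetric tissue x
#'   tissue matrices in \eqn{[0, 1]} with unit diagonal (expression-profile
#'   and regulatory-profile similarity).
#' @return a list of class \code{"TissueSimilarity"}.
#' @export
tissueSimilarity <- function(expressionSimilarity,
                             regulatorySimilarity = expressionSimilarity) {
  for (m in list(expressionSimilarity, regulatorySimilarity)) {
    stopifnot(isSquareSymmetric(m), all(m >= 0 & m <= 1),
              all(abs(diag(m) - 1) < 1e-12))
  }
  stopifnot(identical(dimnames(expressionSimilarity),
                      dimnames(regulatorySimilarity)))
  structure(list(tissues = rownames(expressionSimilarity),
                 expressionSimilarity = expressionSimilarity,
                 regulatorySimilarity = regulatorySimilarity),
            class = "TissueSimilarity")
}

# donor-stratified fold ids: the same donor never spans train/test
donorFolds <- function(donors, nFolds, seed = NULL) {
  u <- unique(donors)
  if (length(u) < nFolds)
    stop("fewer donors than cross-validation folds")
  withSeed(seed, {
    fold <- sample(rep_len(seq_len(nFolds), length(u)))
  })
  setNames(fold, u)[donors]
}

# similarity^Inf hard-thresholds to exact similarity 1 (the test tissue)
powWeight <- function(s, h) {
  if (is.infinite(h)) as.numeric(s == 1) else s^h
}

#' Train a weighted elastic-net expression model
#'
#' Cross-tissue model of one gene's expression from segment or cis-window
#' variants. Observations from all tissues are stacked; the observation in
#' tissue \eqn{s} receives weight
#' \eqn{w = sim_e(t, s)^{h_1} \, sim_r(t, s)^{h_2}} toward the test tissue
#' \eqn{t}, and the weighted elastic-net objective
#' \deqn{\tfrac12 \sum_i w_i (g_i - x_i^T\beta)^2 +
#'   \lambda\left(\tfrac{1-\alpha}{2}\|\beta\|_2^2 +
#'   \alpha\|\beta\|_1\right)}
#' is solved over a penalty path with donor-stratified K-fold
#' cross-validation (one-standard-error rule for \eqn{\lambda}). The
#' exponents \eqn{(h_1, h_2)} are tuned on
#' \code{config$similarityExponentGrid} by the cross-validated Pearson r of
#' the test-tissue observations. With in-tissue weights 1 and all
#' cross-tissue weights 0 (e.g. a single tissue, or exponent \code{Inf})
#' the fit reduces to the single-tissue elastic-net model.
#'
#' Reported cross-validation metrics come from the held-out predictions at
#' the selected penalty, so the squared metric estimates the proportion of
#' expression variance the model's variants explain (a segment
#' heritability when the variants are segment-restricted).
#'
#' @param genotypes a \linkS4class{GenotypeMatrix} of candidate predictors
#'   (MAF-filtered; segment-restricted for a reduced-scope model).
#' @param expression named list: tissue -> named numeric vector of
#'   residualized expression (names are donor/sample ids present in
#'   \code{genotypes}).
#' @param testTissue the tissue being predicted.
#' @param similarity a \code{\link{tissueSimilarity}} object, or \code{NULL}
#'   for single-tissue training.
#' @param config a \code{\link{trainingConfig}}.
#' @param gene gene identifier stored on the model.
#' @param scope \code{"full"} or \code{"reduced"}.
#' @param obsWeights optional user-supplied per-tissue weights (named
#'   numeric, one entry per tissue); bypasses exponent tuning.
#' @return an \linkS4class{ExpressionModel}.
#' @export
trainWeightedElasticNet <- function(genotypes, expression, testTissue,
                                    similarity = NULL,
                                    config = trainingConfig(),
                                    gene = "gene",
                                    scope = c("full", "reduced"),
                                    obsWeights = NULL) {
  scope <- match.arg(scope)
  stopifnot(is.list(expression), testTissue %in% names(expression))
  X <- dosages(genotypes)
  vt <- variantTable(genotypes)
  if (ncol(X) < 2L)
    stop("at least 2 candidate variants are required")
  yTest <- expression[[testTissue]]
  if (length(unique(yTest)) == 1L)
    stop("all-constant expression in the test tissue")

  tissues <- names(expression)
  obs <- do.call(rbind, lapply(tissues, function(tt) {
    y <- expression[[tt]]
    donors <- names(y)
    if (is.null(donors)) stop("expression vectors must be named by donor")
    miss <- setdiff(donors, rownames(X))
    if (length(miss))
      stop("expression donors absent from genotypes: ",
           paste(head(miss, 3), collapse = ", "))
    data.frame(tissue = tt, donor = donors, y = as.numeric(y),
               stringsAsFactors = FALSE)
  }))

  weightSettings <- if (!is.null(obsWeights)) {
    list(list(h = c(NA, NA), w = obsWeights[obs$tissue]))
  } else if (is.null(similarity) || length(tissues) == 1L) {
    list(list(h = c(0, 0), w = as.numeric(obs$tissue == testTissue)))
  } else {
    se <- similarity$expressionSimilarity[testTissue, obs$tissue]
    sr <- similarity$regulatorySimilarity[testTissue, obs$tissue]
    grid <- expand.grid(h1 = config$similarityExponentGrid,
                        h2 = config$similarityExponentGrid)
    lapply(seq_len(nrow(grid)), function(i) {
      list(h = c(grid$h1[i], grid$h2[i]),
           w = powWeight(se, grid$h1[i]) * powWeight(sr, grid$h2[i]))
    })
  }

  testIdx <- which(obs$tissue == testTissue)
  best <- NULL
  for (ws in weightSettings) {
    keep <- which(ws$w > 0)
    if (!all(testIdx %in% keep)) next
    foldsKeep <- donorFolds(obs$donor[keep], config$nFolds,
                            seed = config$seed)
    if (length(unique(foldsKeep)) < 2L) next
    Xk <- X[obs$donor[keep], , drop = FALSE]
    fit <- tryCatch(
      cv.glmnet(Xk, obs$y[keep], weights = ws$w[keep],
                alpha = config$alpha, lambda = config$lambdaGrid,
                foldid = as.integer(factor(foldsKeep)), keep = TRUE,
                standardize = TRUE, grouped = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) next
    li <- match(fit$lambda.1se, fit$lambda)
    preval <- fit$fit.preval[, li]
    testPos <- match(testIdx, keep)
    perf <- if (fit$nzero[li] == 0L) {
      # intercept-only selection: the gene is not imputable at this
      # setting; fold-specific intercepts would otherwise fake a signal
      list(r = 0, r2 = 0, p = 1)
    } else {
      cvPerformance(obs$y[testIdx], preval[testPos])
    }
    if (is.null(best) || perf$r > best$perf$r) {
      best <- list(ws = ws, fit = fit, perf = perf, keep = keep)
    }
  }
  if (is.null(best)) stop("no admissible weight setting could be fit")

  coefs <- drop(coef(best$fit$glmnet.fit, s = best$fit$lambda.1se))[-1]
  nz <- which(coefs != 0)
  w <- setNames(coefs[nz], colnames(X)[nz])
  vi <- vt[match(names(w), vt$id), , drop = FALSE]
  new("ExpressionModel", gene = gene, tissue = testTissue, weights = w,
      scope = scope, cvR = best$perf$r, cvR2 = best$perf$r2,
      cvP = best$perf$p, nPredictors = ncol(X),
      variantInfo = data.frame(id = vi$id, chrom = vi$chrom, pos = vi$pos,
                               ea = vi$alt, oa = vi$ref, maf = vi$maf,
                               stringsAsFactors = FALSE))
}

#' Cross-validated prediction performance
#'
#' Pearson correlation between observed and (held-out) predicted
#' expression, its square — the proportion-of-variance estimate — and the
#' correlation-test p-value. A zero-variance prediction is reported as
#' \code{r = 0, p = 1} (gene not imputable) rather than propagating
#' \code{NaN}.
#'
#' @param observed,predicted equal-length numeric vectors (length >= 3).
#' @return list with elements \code{r}, \code{r2}, \code{p}.
#' @export
cvPerformance <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  if (sd(observed) == 0) stop("observed expression has zero variance")
  if (sd(predicted) == 0 || !all(is.finite(predicted)))
    return(list(r = 0, r2 = 0, p = 1))
  ct <- cor.test(observed, predicted, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, r2 = r^2, p = ct$p.value)
}

#' Imputable-gene (iGene) filter
#'
#' A gene is imputable when its cross-validated performance satisfies
#' \code{r > 0.1} and \code{p < 0.05} (both strict; a negative r always
#' fails).
#'
#' @param x an \linkS4class{ExpressionModel}, or the cross-validated r.
#' @param p correlation-test p-value (when \code{x} is numeric).
#' @return logical.
#' @export
iGeneFilter <- function(x, p = NULL) {
  if (is(x, "ExpressionModel")) return(x@cvR > 0.1 && x@cvP < 0.05)
  stopifnot(!is.null(p))
  x > 0.1 & p < 0.05
}

#' Concentration of heritability in the segment
#'
#' \eqn{\psi = h^2_{reduced}\, p_{full} / (h^2_{full}\, p_{reduced})}:
#' per-SNP heritability of the reduced (segment-restricted) model as a
#' multiple of the per-SNP heritability of the full cis-window model.
#' \eqn{\psi > 1} indicates heritability concentrated in the segment.
#'
#' @param h2Reduced,h2Full model heritability estimates
#'   (\eqn{h^2_{full} > 0}).
#' @param pFull,pReduced predictor counts (\eqn{p_{reduced} > 0}).
#' @return a \linkS4class{ConcentrationStat}.
#' @export
concentrationStatistic <- function(h2Reduced, pFull, h2Full, pReduced) {
  if (h2Full <= 0) stop("h2Full must be positive")
  if (pReduced <= 0) stop("pReduced must be positive")
  new("ConcentrationStat",
      psi = h2Reduced * pFull / (h2Full * pReduced),
      h2Reduced = h2Reduced, h2Full = h2Full,
      pReduced = as.integer(pReduced), pFull = as.integer(pFull))
}

# train a reduced-scope model on the variants inside `segment`
reducedModelR2 <- function(genotypes, y, segment, config, gene, tissue) {
  sub <- subsetBySegment(genotypes, segment)
  if (nrow(sub) < 2L) return(NA_real_)
  m <- trainWeightedElasticNet(sub, setNames(list(y), tissue), tissue,
                               config = config, gene = gene,
                               scope = "reduced")
  m@cvR2
}

#' Random-segment null for segment-restricted prediction
#'
#' For each gene, compares the reduced-model performance of the focal
#' segment against segments of the same length placed uniformly at random
#' within the gene's cis-window. Returns the per-gene observed \eqn{r^2},
#' the per-gene median of the null \eqn{r^2} values, and a two-sided
#' Wilcoxon matched-pairs signed-rank test across genes.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix} covering the cis-region.
#' @param expressionByGene named list: gene -> named numeric expression
#'   vector (single tissue).
#' @param segment the focal \linkS4class{Segment}.
#' @param cisWindows data.frame (gene, chrom, start, end): 1-based
#'   placement window per gene. Random segments are redrawn until at least
#'   2 variants fall inside (up to 50 attempts each).
#' @param nSegments number of random segments per gene (default 100).
#' @param config a \code{\link{trainingConfig}}.
#' @param tissue tissue label.
#' @param seed RNG seed for segment placement.
#' @return list with \code{table} (gene, observed_r2, null_median_r2) and
#'   \code{wilcoxonP}.
#' @export
randomSegmentNull <- function(genotypes, expressionByGene, segment,
                              cisWindows, nSegments = 100L,
                              config = trainingConfig(), tissue = "tissue",
                              seed = NULL) {
  len <- segmentLength(segment)
  genes <- names(expressionByGene)
  withSeed(seed, {
    rows <- lapply(genes, function(g) {
      y <- expressionByGene[[g]]
      cw <- cisWindows[cisWindows$gene == g, ]
      if (nrow(cw) != 1L) stop("cis-window missing for gene ", g)
      if (cw$end - cw$start + 1 < len)
        stop("segment longer than the cis-region for gene ", g)
      obs <- reducedModelR2(genotypes, y, segment, config, g, tissue)
      nulls <- vapply(seq_len(nSegments), function(i) {
        for (try in 1:50) {
          s0 <- floor(runif(1, cw$start, cw$end - len + 1))
          rs <- new("Segment", chrom = cw$chrom, start = s0 - 1,
                    end = s0 - 1 + len)
          vt <- variantTable(genotypes)
          if (sum(segmentContains(rs, vt$chrom, vt$pos)) >= 2L) {
            return(reducedModelR2(genotypes, y, rs, config, g, tissue))
          }
        }
        NA_real_
      }, numeric(1))
      data.frame(gene = g, observed_r2 = obs,
                 null_median_r2 = median(nulls, na.rm = TRUE))
    })
  })
  tab <- do.call(rbind, rows)
  wp <- if (all(tab$observed_r2 == tab$null_median_r2)) 1 else
    wilcox.test(tab$observed_r2, tab$null_median_r2, paired = TRUE,
                alternative = "two.sided", exact = FALSE)$p.value
  list(table = tab, wilcoxonP = wp)
}

#' Segment-dilation experiment
#'
#' Retrains the reduced model on symmetric dilations of the focal segment
#' (e.g. 100 kb and 500 kb each side) and reports \eqn{r^2} per gene and
#' extension. Extension 0 reproduces the reduced model; an extension
#' covering the whole cis-window approaches the full model.
#'
#' @inheritParams randomSegmentNull
#' @param extensions nonnegative extensions in bp (default
#'   \code{c(0, 1e5, 5e5)}).
#' @return data.frame (gene, tissue, extension, r2).
#' @export
dilationExperiment <- function(genotypes, expressionByGene, segment,
                               extensions = c(0, 1e5, 5e5),
                               config = trainingConfig(),
                               tissue = "tissue") {
  stopifnot(all(extensions >= 0))
  rows <- lapply(names(expressionByGene), function(g) {
    do.call(rbind, lapply(extensions, function(ext) {
      r2 <- reducedModelR2(genotypes, expressionByGene[[g]],
                           dilateSegment(segment, ext), config, g, tissue)
      data.frame(gene = g, tissue = tissue, extension = ext, r2 = r2)
    }))
  })
  do.call(rbind, rows)
}
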