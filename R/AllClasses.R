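#' Segment: a contiguous genomic interval of interest
#'
#' Internally stored 0-based half-open; the text form
#' (\code{"chr3:45,859,651-45,909,024"}) is 1-based inclusive. Use
#' \code{\link{parseSegment}} to construct from text and
#' \code{\link{formatSegment}} (or \code{as.character}) to serialize.
#'
#' @slot chrom chromosome name, e.g. \code{"chr3"}.
#' @slot start 0-based start (inclusive).
#' @slot end 0-based end (exclusive); \code{end - start} is the length in bp.
#' @slot label free-text label.
#' @export
setClass("Segment",
  representation(chrom = "character", start = "numeric", end = "numeric",
                 label = "character"),
  prototype(label = ""))

setValidity("Segment", function(object) {
  if (length(object@chrom) != 1L || !nzchar(object@chrom))
    return("'chrom' must be a single non-empty string")
  if (object@start < 0) return("'start' must be >= 0")
  if (object@start >= object@end) return("'start' must be < 'end'")
  if (object@start != round(object@start) || object@end != round(object@end))
    return("coordinates must be whole numbers")
  TRUE
})

#' GenotypeMatrix: sample-by-variant dosages with variant metadata
#'
#' Extends \linkS4class{RangedSummarizedExperiment}: rows are variants
#' (with \code{rowRanges} holding positions and \code{rowData} columns
#' \code{id}, \code{ref}, \code{alt}, \code{maf}), columns are samples, and
#' the single assay \code{"dosage"} holds alternate-allele dosages in
#' \eqn{[0, 2]}. \code{\link{dosages}} returns the transposed
#' (sample x variant) numeric matrix used by the statistical routines.
#'
#' @seealso \code{\link{GenotypeMatrix}} (constructor),
#'   \code{\link{mafFilter}}, \code{\link{empiricalLD}}
#' @export
setClass("GenotypeMatrix",
  contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  ds <- SummarizedExperiment::assay(object, "dosage")
  if (anyNA(ds)) return("dosages must not contain missing values")
  if (any(ds < 0 | ds > 2)) return("dosages must lie in [0, 2]")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("id", "ref", "alt", "maf")
  if (!all(need %in% colnames(rd)))
    return(paste("rowData must contain:", paste(need, collapse = ", ")))
  if (any(rd$ref == rd$alt)) return("ref and alt alleles must differ")
  if (any(rd$maf < 0 | rd$maf > 0.5)) return("maf must lie in [0, 0.5]")
  f <- rowMeans(ds) / 2
  if (max(abs(pmin(f, 1 - f) - rd$maf)) > 1e-9)
    return("stored maf disagrees with dosage-derived maf")
  TRUE
})

#' GwasSummary: per-variant GWAS summary statistics for one trait
#'
#' Wraps a per-variant table with columns \code{snp}, \code{chr}, \code{pos},
#' \code{ea} (effect allele), \code{oa} (other allele), \code{beta},
#' \code{se}, \code{z}, \code{n}. When \code{beta}, \code{se} and \code{z}
#' are all present they must satisfy \code{z = beta / se}.
#'
#' @slot table data.frame of per-variant records.
#' @slot trait trait identifier.
#' @seealso \code{\link{readGwasTsv}}, \code{\link{gwasSummary}}
#' @export
setClass("GwasSummary",
  representation(table = "data.frame", trait = "character"),
  prototype(trait = "trait"))

setValidity("GwasSummary", function(object) {
  tab <- object@table
  need <- c("snp", "chr", "pos", "ea", "oa", "beta", "se", "z", "n")
  if (!all(need %in% colnames(tab)))
    return(paste("table must contain columns:", paste(need, collapse = ", ")))
  if (any(!is.na(tab$se) & tab$se <= 0)) return("se must be positive")
  if (any(!is.na(tab$n) & tab$n <= 0)) return("n must be positive")
  ok <- !is.na(tab$beta) & !is.na(tab$se) & !is.na(tab$z)
  if (any(ok) && max(abs(tab$z[ok] - tab$beta[ok] / tab$se[ok])) >= 1e-6)
    return("z must equal beta/se (within 1e-6) where all three are present")
  TRUE
})

#' ExpressionModel: sparse variant weights predicting one gene in one tissue
#'
#' @slot gene,tissue identifiers.
#' @slot weights named numeric vector of nonzero variant weights (names are
#'   variant ids).
#' @slot scope \code{"full"} (cis-window model) or \code{"reduced"}
#'   (segment-restricted model).
#' @slot cvR,cvR2,cvP cross-validated Pearson r, its square, and the
#'   correlation-test p-value.
#' @slot nPredictors number of candidate predictors offered to the solver.
#' @slot variantInfo data.frame (id, chrom, pos, ea, oa, maf) for the model's
#'   nonzero-weight variants; \code{ea} is the dosage-counted allele.
#' @export
setClass("ExpressionModel",
  representation(gene = "character", tissue = "character",
                 weights = "numeric", scope = "character",
                 cvR = "numeric", cvR2 = "numeric", cvP = "numeric",
                 nPredictors = "integer", variantInfo = "data.frame"))

setValidity("ExpressionModel", function(object) {
  if (!object@scope %in% c("full", "reduced"))
    return("scope must be 'full' or 'reduced'")
  if (length(object@weights) && is.null(names(object@weights)))
    return("weights must be named by variant id")
  if (length(object@cvR) && length(object@cvR2) &&
      is.finite(object@cvR) && abs(object@cvR2 - object@cvR^2) > 1e-12)
    return("cvR2 must equal cvR^2")
  TRUE
})

#' ConcentrationStat: per-SNP heritability concentration psi
#'
#' \eqn{\psi = h^2_{reduced} \, p_{full} / (h^2_{full} \, p_{reduced})}: the
#' per-SNP heritability of the segment-restricted model as a multiple of the
#' per-SNP heritability of the full cis-window model.
#'
#' @slot psi the statistic.
#' @slot h2Reduced,h2Full model heritabilities.
#' @slot pReduced,pFull predictor counts.
#' @seealso \code{\link{concentrationStatistic}}
#' @export
setClass("ConcentrationStat",
  representation(psi = "numeric", h2Reduced = "numeric", h2Full = "numeric",
                 pReduced = "integer", pFull = "integer"))

setValidity("ConcentrationStat", function(object) {
  expect <- object@h2Reduced * object@pFull /
    (object@h2Full * object@pReduced)
  if (abs(object@psi - expect) > 1e-12)
    return("psi is inconsistent with its components")
  TRUE
})

#' LDMatrix: an observed variant correlation matrix
#'
#' @slot variants variant ids (row/column order of \code{Chat}).
#' @slot Chat p x p Pearson correlation matrix of dosages.
#' @slot nPanel number of samples it was estimated from.
#' @slot rank numerical rank (SVD with relative tolerance \code{tol}).
#' @slot tol relative singular-value tolerance used for the rank.
#' @seealso \code{\link{empiricalLD}}, \code{\link{ldScores}}
#' @export
setClass("LDMatrix",
  representation(variants = "character", Chat = "matrix", nPanel = "integer",
                 rank = "integer", tol = "numeric"),
  prototype(tol = 1e-8))

setValidity("LDMatrix", function(object) {
  C <- object@Chat
  if (!isSquareSymmetric(C)) return("C must be square and symmetric")
  if (length(object@variants) != nrow(C))
    return("variants must match the dimension of C")
  if (max(abs(diag(C) - 1)) > 1e-6) return("C must have unit diagonal")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6 * max(abs(ev), 1))
    return("C must be positive semi-definite (up to tolerance)")
  TRUE
})

#' ProjectedLD: Ledoit-Wolf projection of an observed LD matrix
#'
#' The optimized LD matrix
#' \deqn{\pi(C) = (b^2 m / d^2)\, I + (a^2 / d^2)\, \hat C}
#' where \eqn{m} is the (p-normalized) Frobenius inner product of
#' \eqn{\hat C} with the identity, \eqn{d^2 = \|\hat C - mI\|^2},
#' \eqn{b^2} estimates the sampling-error energy from the per-subject
#' outer products, and \eqn{a^2 = d^2 - b^2}.
#'
#' @slot base the observed \linkS4class{LDMatrix}.
#' @slot m,d2,b2,a2 scalar shrinkage components.
#' @slot piC the projected matrix.
#' @seealso \code{\link{ledoitWolfProject}}
#' @export
setClass("ProjectedLD",
  representation(base = "LDMatrix", m = "numeric", d2 = "numeric",
                 b2 = "numeric", a2 = "numeric", piC = "matrix"))

setValidity("ProjectedLD", function(object) {
  if (abs(object@a2 - (object@d2 - object@b2)) > 1e-10)
    return("a2 must equal d2 - b2")
  if (object@b2 > object@d2 + 1e-12) return("b2 must be <= d2")
  if (object@b2 < -1e-12 || object@d2 < -1e-12)
    return("b2 and d2 must be nonnegative")
  if (object@d2 > 1e-12) {
    expect <- (object@b2 * object@m / object@d2) * diag(nrow(object@piC)) +
      (object@a2 / object@d2) * object@base@Chat
    if (max(abs(object@piC - expect)) > 1e-8)
      return("piC is inconsistent with its shrinkage components")
  }
  TRUE
})

#' HeritabilityEstimate: summary-statistics local heritability
#'
#' @slot r2Local point estimate (may be negative by sampling noise).
#' @slot variance analytic sampling variance.
#' @slot n GWAS sample size.
#' @slot p number of variants.
#' @slot qRank effective number of variants (rank of the LD matrix) actually
#'   used in the estimator.
#' @slot ldMode one of \code{"observed"}, \code{"projected"}, \code{"true"}.
#' @seealso \code{\link{estimateLocalH2}}, \code{\link{varianceLocalH2}}
#' @export
setClass("HeritabilityEstimate",
  representation(r2Local = "numeric", variance = "numeric", n = "integer",
                 p = "integer", qRank = "integer", ldMode = "character"))

setValidity("HeritabilityEstimate", function(object) {
  if (!object@ldMode %in% c("observed", "projected", "true"))
    return("ldMode must be 'observed', 'projected' or 'true'")
  if (object@variance < 0) return("variance must be nonnegative")
  expect <- varianceLocalH2(object@r2Local, object@n, object@qRank)
  if (abs(object@variance - expect) > 1e-12)
    return("stored variance disagrees with recomputation")
  TRUE
})

#' IVSet: harmonized, clumped instruments for Mendelian randomization
#'
#' @slot table per-instrument records: \code{variant}, \code{betaExposure},
#'   \code{seExposure}, \code{pExposure}, \code{betaOutcome},
#'   \code{seOutcome}, \code{ldScore}.
#' @slot ld correlation matrix among the surviving instruments.
#' @slot removed records dropped during harmonization/clumping with a
#'   \code{reason} column (\code{"palindromic"}, \code{"mismatch"},
#'   \code{"clumped"}, \code{"p_threshold"}).
#' @seealso \code{\link{buildIvSet}}, \code{\link{ivw}}, \code{\link{mrJti}}
#' @export
setClass("IVSet",
  representation(table = "data.frame", ld = "matrix",
                 removed = "data.frame"))

setValidity("IVSet", function(object) {
  need <- c("variant", "betaExposure", "seExposure", "pExposure",
            "betaOutcome", "seOutcome", "ldScore")
  if (!all(need %in% colnames(object@table)))
    return(paste("table must contain:", paste(need, collapse = ", ")))
  if (nrow(object@table) != nrow(object@ld))
    return("ld dimension must match the number of instruments")
  TRUE
})

#' MRFit: penalized Mendelian randomization fit
#'
#' Solution of the penalized objective
#' \deqn{\min_{u, v, w} \sum_j (\hat\theta_j - u\hat\beta_j - v_j - w l_j)^2
#'   + \lambda(\|v\|_1 + |u| + |w|)}
#' where \eqn{u} is the gene causal effect, \eqn{v_j} per-instrument
#' heterogeneity and \eqn{w} the LD-score coefficient.
#'
#' @slot alphaHat causal-effect estimate (relaxed-refit value when
#'   \code{relaxed = TRUE} was requested).
#' @slot alphaPenalized the raw penalized estimate at the selected lambda.
#' @slot vHat named per-instrument heterogeneity estimates.
#' @slot wHat LD-score coefficient.
#' @slot lambda CV-selected penalty.
#' @slot ciLow,ciHigh percentile bootstrap confidence bounds.
#' @slot nBoot,seed bootstrap settings.
#' @slot relaxed whether alphaHat is the relaxed (OLS-on-support) refit.
#' @slot bootEstimates the bootstrap draws of the causal effect.
#' @seealso \code{\link{mrJti}}
#' @export
setClass("MRFit",
  representation(alphaHat = "numeric", alphaPenalized = "numeric",
                 vHat = "numeric", wHat = "numeric", lambda = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", nBoot = "integer",
                 seed = "numeric", relaxed = "logical",
                 bootEstimates = "numeric"))

setValidity("MRFit", function(object) {
  if (length(object@ciLow) && length(object@ciHigh) &&
      !is.na(object@ciLow) && !is.na(object@ciHigh) &&
      object@ciLow > object@ciHigh)
    return("ciLow must be <= ciHigh")
  TRUE
})

#' MediationResult: segment share of the expression-mediated causal effect
#'
#' @slot piC the proportion of expression-mediated causal effect explained
#'   by the segment; \code{NA} when the full-model mediated effect is not
#'   distinguishable from noise.
#' @slot psiE per-SNP concentration of the mediated effect,
#'   \code{piC * qFull / qReduced}.
#' @slot alphaHat causal effect used.
#' @slot qFull,qReduced ranks of the full/reduced LD matrices.
#' @slot n GWAS sample size.
#' @slot indirectEffect per-variant indirect (unmediated) effects when a
#'   GWAS effect vector was supplied; otherwise empty.
#' @slot outOfRange TRUE iff piC falls outside [0, 1].
#' @slot degenerate TRUE when the ratio is driven by rank terms alone
#'   (e.g. alphaHat = 0) or the denominator is nonpositive.
#' @slot note human-readable qualifier.
#' @seealso \code{\link{piC}}, \code{\link{mediatedDecomposition}}
#' @export
setClass("MediationResult",
  representation(piC = "numeric", psiE = "numeric", alphaHat = "numeric",
                 qFull = "integer", qReduced = "integer", n = "integer",
                 indirectEffect = "numeric", outOfRange = "logical",
                 degenerate = "logical", note = "character"),
  prototype(indirectEffect = numeric(0), note = ""))

setValidity("MediationResult", function(object) {
  if (!is.na(object@piC)) {
    expectFlag <- object@piC < 0 || object@piC > 1
    if (object@outOfRange != expectFlag)
      return("outOfRange flag inconsistent with piC")
  }
  TRUE
})
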