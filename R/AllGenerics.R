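#' @rdname dosages
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname variantTable
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))

#' @rdname mafs
#' @export
setGeneric("mafs", function(x) standardGeneric("mafs"))

#' @rdname gwasTable
#' @export
setGeneric("gwasTable", function(x) standardGeneric("gwasTable"))

#' @rdname ivTable
#' @export
setGeneric("ivTable", function(x) standardGeneric("ivTable"))

#' @rdname alphaHat
#' @export
setGeneric("alphaHat", function(x) standardGeneric("alphaHat"))

#' @rdname ldScores
#' @export
setGeneric("ldScores", function(x) standardGeneric("ldScores"))

#' @rdname ldMatrix
#' @export
setGeneric("ldMatrix", function(x) standardGeneric("ldMatrix"))

#' Extract the sample-by-variant dosage matrix
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @return numeric matrix (samples in rows, variants in columns).
#' @rdname dosages
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) {
  t(SummarizedExperiment::assay(x, "dosage"))
})

#' Variant metadata as a data.frame
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @return data.frame with columns id, chrom, pos, ref, alt, maf.
#' @rdname variantTable
#' @export
setMethod("variantTable", "GenotypeMatrix", function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  rd <- SummarizedExperiment::rowData(x)
  data.frame(id = rd$id,
             chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             ref = rd$ref, alt = rd$alt, maf = rd$maf,
             row.names = NULL, stringsAsFactors = FALSE)
})

#' Minor allele frequencies
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @return named numeric vector of MAFs.
#' @rdname mafs
#' @export
setMethod("mafs", "GenotypeMatrix", function(x) {
  setNames(SummarizedExperiment::rowData(x)$maf,
           SummarizedExperiment::rowData(x)$id)
})

#' GWAS summary table
#'
#' @param x a \linkS4class{GwasSummary}.
#' @return the per-variant data.frame.
#' @rdname gwasTable
#' @export
setMethod("gwasTable", "GwasSummary", function(x) x@table)

#' Instrument table of an IVSet
#'
#' @param x an \linkS4class{IVSet}.
#' @return the per-instrument data.frame.
#' @rdname ivTable
#' @export
setMethod("ivTable", "IVSet", function(x) x@table)

#' Causal-effect estimate
#'
#' @param x an \linkS4class{MRFit} or \linkS4class{MediationResult}.
#' @return the causal-effect point estimate.
#' @rdname alphaHat
#' @export
setMethod("alphaHat", "MRFit", function(x) x@alphaHat)

#' @rdname alphaHat
#' @export
setMethod("alphaHat", "MediationResult", function(x) x@alphaHat)

#' Underlying correlation matrix
#'
#' @param x an \linkS4class{LDMatrix} or \linkS4class{ProjectedLD}; for a
#'   \code{ProjectedLD} the projected matrix \eqn{\pi(C)} is returned.
#' @return numeric correlation matrix.
#' @rdname ldMatrix
#' @export
setMethod("ldMatrix", "LDMatrix", function(x) x@Chat)

#' @rdname ldMatrix
#' @export
setMethod("ldMatrix", "ProjectedLD", function(x) x@piC)

#' @rdname ldMatrix
#' @export
setMethod("ldMatrix", "matrix", function(x) x)

setMethod("show", "Segment", function(object) {
  cat(sprintf("Segment %s (%s, %d bp)\n", formatSegment(object),
              if (nzchar(object@label)) object@label else "unlabeled",
              as.integer(object@end - object@start)))
})

setMethod("show", "GwasSummary", function(object) {
  cat(sprintf("GwasSummary '%s': %d variants\n", object@trait,
              nrow(object@table)))
})

setMethod("show", "ExpressionModel", function(object) {
  cat(sprintf(
    "ExpressionModel %s / %s [%s]: %d nonzero of %d predictors, cv r = %.3f (r2 = %.3f, p = %.3g)\n",
    object@gene, object@tissue, object@scope, length(object@weights),
    object@nPredictors, object@cvR, object@cvR2, object@cvP))
})

setMethod("show", "ConcentrationStat", function(object) {
  cat(sprintf(
    "ConcentrationStat psi = %.4g (h2 reduced %.4g over %d SNPs vs full %.4g over %d SNPs)\n",
    object@psi, object@h2Reduced, object@pReduced, object@h2Full,
    object@pFull))
})

setMethod("show", "LDMatrix", function(object) {
  cat(sprintf("LDMatrix: %d variants, n = %d, rank = %d\n",
              nrow(object@Chat), object@nPanel, object@rank))
})

setMethod("show", "ProjectedLD", function(object) {
  shrink <- if (object@d2 > 1e-12) object@b2 / object@d2 else 0
  cat(sprintf(
    "ProjectedLD: %d variants, m = %.4g, d2 = %.4g, b2 = %.4g, a2 = %.4g (shrinkage %.1f%%)\n",
    nrow(object@piC), object@m, object@d2, object@b2, object@a2,
    100 * shrink))
})

setMethod("show", "HeritabilityEstimate", function(object) {
  cat(sprintf(
    "Local h2 [%s LD]: %.5g (se %.3g), n = %d, p = %d, q = %d\n",
    object@ldMode, object@r2Local, sqrt(object@variance), object@n,
    object@p, object@qRank))
})

setMethod("show", "IVSet", function(object) {
  cat(sprintf("IVSet: %d instruments (%d removed)\n",
              nrow(object@table), nrow(object@removed)))
})

setMethod("show", "MRFit", function(object) {
  cat(sprintf(
    "MRFit: alpha = %.4g [%.4g, %.4g], lambda = %.3g, %d bootstrap draws%s\n",
    object@alphaHat, object@ciLow, object@ciHigh, object@lambda,
    object@nBoot, if (object@relaxed) " (relaxed refit)" else ""))
})

setMethod("show", "MediationResult", function(object) {
  cat(sprintf("MediationResult: pi_c = %.4g%s, psi_e = %.4g, alpha = %.4g\n",
              object@piC,
              if (isTRUE(object@outOfRange)) " (outside [0,1])"
              else if (isTRUE(object@degenerate)) " (degenerate)" else "",
              object@psiE, object@alphaHat))
})
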