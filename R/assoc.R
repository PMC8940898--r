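#' Summary-statistics gene-trait association
#'
#' Weighted-Z statistic for the association between genetically predicted
#' expression and a trait:
#' \deqn{z_{gene} = \frac{\sum_j w_j \sigma_j z_j}{\sigma_g}, \qquad
#'   \sigma_g = \sqrt{w^T \mathrm{diag}(\sigma)\, C\,
#'   \mathrm{diag}(\sigma)\, w}}
#' where \eqn{w_j} are the model weights, \eqn{z_j} the (allele-aligned)
#' GWAS z-scores, \eqn{\sigma_j = \sqrt{2 f_j (1 - f_j)}} the dosage SD
#' implied by the MAF under Hardy-Weinberg equilibrium, and \eqn{C} the
#' variant LD matrix. Under the null the statistic is standard normal for
#' any fixed weights; the two-sided normal p-value is reported. Alleles are
#' harmonized first (swapped alleles flip the z sign; palindromic or
#' irreconcilable variants are dropped).
#'
#' @param model an \linkS4class{ExpressionModel} with nonzero weights.
#' @param gwas a \linkS4class{GwasSummary}.
#' @param ld LD matrix covering the model variants (matrix with variant-id
#'   dimnames, \linkS4class{LDMatrix} or \linkS4class{ProjectedLD}).
#' @return one-row data.frame: gene, tissue, trait, z, p, n_snps_used.
#' @export
geneTraitAssociation <- function(model, gwas, ld) {
  w <- model@weights
  if (!length(w) || all(w == 0))
    stop("zero predicted-expression variance: model has no nonzero weights")
  tab <- gwasTable(gwas)
  vi <- model@variantInfo
  idx <- match(vi$id, tab$snp)
  present <- !is.na(idx)
  if (!any(present))
    stop("no overlapping predictors between model and GWAS")
  vi <- vi[present, , drop = FALSE]
  w <- w[present]
  sub <- tab[idx[present], , drop = FALSE]
  harm <- harmonizeAlleles(vi$ea, vi$oa, sub$ea, sub$oa, sub$z)
  keep <- harm$action %in% c("keep", "flip")
  if (!any(keep))
    stop("no overlapping predictors survive allele harmonization")
  vi <- vi[keep, , drop = FALSE]
  w <- w[keep]
  z <- harm$beta[keep]
  C <- ldMatrix(ld)
  ci <- match(vi$id, rownames(C))
  if (anyNA(ci)) stop("LD matrix does not cover all model predictors")
  C <- C[ci, ci, drop = FALSE]
  sig <- sqrt(2 * vi$maf * (1 - vi$maf))
  ws <- w * sig
  varG <- drop(crossprod(ws, C %*% ws))
  if (varG <= 0) stop("zero predicted-expression variance")
  zGene <- sum(ws * z) / sqrt(varG)
  data.frame(gene = model@gene, tissue = model@tissue, trait = gwas@trait,
             z = zGene, p = 2 * pnorm(-abs(zGene)),
             n_snps_used = length(w), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR control
#'
#' Standard step-up adjustment; a discovery is flagged when the adjusted
#' p-value falls below \code{q}.
#'
#' @param pvalues p-values in \eqn{(0, 1]}.
#' @param q FDR level (default 0.05).
#' @return data.frame with \code{p}, \code{p_fdr} and \code{pass}.
#' @export
bhFdr <- function(pvalues, q = 0.05) {
  if (!length(pvalues))
    return(data.frame(p = numeric(), p_fdr = numeric(), pass = logical()))
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  adj <- p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, p_fdr = adj, pass = adj < q)
}

#' Phenome scan across traits
#'
#' Runs the gene-trait association for every (model, trait) pair, keeping
#' binary traits with at least \code{minCases} cases, and restricting to
#' genes whose reduced-scope model passes the iGene filter in at least one
#' tissue (associations themselves are computed with the full-scope
#' models). BH-FDR is applied jointly across the scanned gene x tissue x
#' trait results.
#'
#' @param fullModels list of full-scope \linkS4class{ExpressionModel}.
#' @param reducedModels list of reduced-scope models used for gene
#'   selection; \code{NULL} skips the selection step.
#' @param traits named list of \linkS4class{GwasSummary}; each may carry a
#'   case count in \code{x@table} attribute \code{nCases} or via
#'   \code{caseCounts}.
#' @param ld LD matrix covering all model variants.
#' @param caseCounts named numeric vector of case counts per trait
#'   (\code{NA} or missing = not case/control, always kept).
#' @param minCases minimum number of cases (default 50).
#' @param q FDR level (default 0.05).
#' @return data.frame of associations with \code{p_fdr} and \code{pass}.
#' @export
phenomeScan <- function(fullModels, reducedModels = NULL, traits, ld,
                        caseCounts = NULL, minCases = 50L, q = 0.05) {
  if (!is.null(caseCounts)) {
    keepTrait <- vapply(names(traits), function(tn) {
      nc <- caseCounts[tn]
      is.na(nc) || nc >= minCases
    }, logical(1))
    traits <- traits[keepTrait]
  }
  if (!is.null(reducedModels)) {
    okGenes <- unique(vapply(
      Filter(iGeneFilter, reducedModels), slot, character(1), "gene"))
    fullModels <- Filter(function(m) m@gene %in% okGenes, fullModels)
  }
  rows <- list()
  for (tr in traits) {
    for (m in fullModels) {
      res <- tryCatch(geneTraitAssociation(m, tr, ld),
                      error = function(e) NULL)
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows))
    return(data.frame(gene = character(), tissue = character(),
                      trait = character(), z = numeric(), p = numeric(),
                      n_snps_used = integer(), p_fdr = numeric(),
                      pass = logical()))
  out <- do.call(rbind, rows)
  fdr <- bhFdr(out$p, q = q)
  out$p_fdr <- fdr$p_fdr
  out$pass <- fdr$pass
  out
}
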