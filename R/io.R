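#' Construct a GwasSummary from a data.frame
#'
#' Required columns: \code{snp}, \code{chr}, \code{pos}, \code{ea},
#' \code{oa}, and at least two of \code{beta}, \code{se}, \code{z} (the
#' third is filled in via \code{z = beta / se}); \code{n} is the per-variant
#' sample size.
#'
#' @param table per-variant data.frame.
#' @param trait trait identifier.
#' @return a \linkS4class{GwasSummary}.
#' @export
gwasSummary <- function(table, trait = "trait") {
  need <- c("snp", "chr", "pos", "ea", "oa")
  if (!all(need %in% colnames(table)))
    stop("missing required columns: ",
         paste(setdiff(need, colnames(table)), collapse = ", "))
  for (col in c("beta", "se", "z", "n"))
    if (!col %in% colnames(table)) table[[col]] <- NA_real_
  fill <- is.na(table$z) & !is.na(table$beta) & !is.na(table$se)
  table$z[fill] <- table$beta[fill] / table$se[fill]
  fill <- is.na(table$beta) & !is.na(table$z) & !is.na(table$se)
  table$beta[fill] <- table$z[fill] * table$se[fill]
  fill <- is.na(table$se) & !is.na(table$z) & !is.na(table$beta) &
    table$z != 0
  table$se[fill] <- table$beta[fill] / table$z[fill]
  new("GwasSummary", table = as.data.frame(table), trait = trait)
}

#' Read GWAS summary statistics from TSV
#'
#' Header columns \code{snp}, \code{chr}, \code{pos}, \code{ea}, \code{oa}
#' are required; \code{beta}, \code{se}, \code{z}, \code{n} are used when
#' present.
#'
#' @param path file path.
#' @param trait trait identifier (defaults to the file name).
#' @return a \linkS4class{GwasSummary}.
#' @export
readGwasTsv <- function(path, trait = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  gwasSummary(tab, trait = if (is.null(trait))
    sub("\\.[^.]*$", "", basename(path)) else trait)
}

#' Write GWAS summary statistics to TSV
#' @param gwas a \linkS4class{GwasSummary}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGwasTsv <- function(gwas, path) {
  write.table(gwasTable(gwas), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Standardized marginal effects from a GwasSummary
#'
#' Returns per-SD-unit effects \code{z / sqrt(n)}, the scale assumed by the
#' local-heritability estimator.
#'
#' @param gwas a \linkS4class{GwasSummary}.
#' @return named numeric vector (names are variant ids).
#' @export
standardizedEffects <- function(gwas) {
  tab <- gwasTable(gwas)
  setNames(tab$z / sqrt(tab$n), tab$snp)
}

PALINDROMIC_PAIRS <- c(A = "T", T = "A", C = "G", G = "C")

isPalindromic <- function(ea, oa) {
  toupper(oa) == unname(PALINDROMIC_PAIRS[toupper(ea)]) & !is.na(ea)
}

#' Harmonize effect alleles between a model/eQTL record and a GWAS record
#'
#' Vectorized. For each variant: if the effect alleles agree the GWAS effect
#' is kept as-is (\code{action = "keep"}); if effect and other alleles are
#' swapped the GWAS effect sign is flipped (\code{"flip"}); palindromic
#' (A/T or C/G) variants are flagged for removal (\code{"palindromic"}),
#' since strand cannot be resolved; anything else is \code{"mismatch"}.
#'
#' @param eaModel,oaModel effect/other allele of the model or eQTL record.
#' @param eaGwas,oaGwas effect/other allele of the GWAS record.
#' @param betaGwas GWAS effect sizes (or z-scores) to be aligned.
#' @param posModel,posGwas optional positions; if both are given they must
#'   agree elementwise (the records must describe the same site).
#' @return data.frame with columns \code{action} and \code{beta} (the
#'   aligned effect; \code{NA} for dropped variants).
#' @examples
#' harmonizeAlleles("A", "G", "G", "A", 0.2) # flipped to -0.2
#' harmonizeAlleles("A", "T", "A", "T", 0.2) # palindromic, dropped
#' @export
harmonizeAlleles <- function(eaModel, oaModel, eaGwas, oaGwas, betaGwas,
                             posModel = NULL, posGwas = NULL) {
  n <- length(eaModel)
  stopifnot(length(oaModel) == n, length(eaGwas) == n,
            length(oaGwas) == n, length(betaGwas) == n)
  if (!is.null(posModel) && !is.null(posGwas) &&
      any(posModel != posGwas))
    stop("position mismatch between model and GWAS records")
  eaModel <- toupper(eaModel); oaModel <- toupper(oaModel)
  eaGwas <- toupper(eaGwas); oaGwas <- toupper(oaGwas)
  action <- rep("mismatch", n)
  beta <- rep(NA_real_, n)
  same <- eaModel == eaGwas & oaModel == oaGwas
  swapped <- eaModel == oaGwas & oaModel == eaGwas
  action[same] <- "keep"; beta[same] <- betaGwas[same]
  action[swapped] <- "flip"; beta[swapped] <- -betaGwas[swapped]
  pal <- isPalindromic(eaModel, oaModel)
  action[pal] <- "palindromic"; beta[pal] <- NA_real_
  data.frame(action = action, beta = beta, stringsAsFactors = FALSE)
}

#' Read a residualized expression matrix from TSV
#'
#' Layout: first column \code{gene}, remaining columns one per sample.
#'
#' @param path file path.
#' @param tissue tissue label.
#' @return list with elements \code{tissue}, \code{genes}, \code{samples}
#'   and \code{values} (genes x samples numeric matrix).
#' @export
readExpressionTsv <- function(path, tissue = "tissue") {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (colnames(tab)[1] != "gene")
    stop("expression TSV must have 'gene' as its first column")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- tab$gene
  if (any(!is.finite(vals))) stop("expression values must be finite")
  list(tissue = tissue, genes = tab$gene, samples = colnames(vals),
       values = vals)
}

#' Write expression models to a TSV store with a JSON metrics sidecar
#'
#' The TSV holds one row per (gene, tissue, variant, weight); the sidecar
#' \code{<path>.json} records cross-validation metrics, scope and predictor
#' counts per model.
#'
#' @param models list of \linkS4class{ExpressionModel}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readModelStore}}
#' @export
writeModelStore <- function(models, path) {
  rows <- do.call(rbind, lapply(models, function(m) {
    if (!length(m@weights)) return(NULL)
    vi <- m@variantInfo
    data.frame(gene = m@gene, tissue = m@tissue,
               variant = names(m@weights), weight = unname(m@weights),
               ea = vi$ea[match(names(m@weights), vi$id)],
               oa = vi$oa[match(names(m@weights), vi$id)],
               maf = vi$maf[match(names(m@weights), vi$id)],
               chrom = vi$chrom[match(names(m@weights), vi$id)],
               pos = vi$pos[match(names(m@weights), vi$id)],
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(gene = character(), tissue = character(),
                       variant = character(), weight = numeric(),
                       ea = character(), oa = character(), maf = numeric(),
                       chrom = character(), pos = integer())
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- lapply(models, function(m) list(
    gene = m@gene, tissue = m@tissue, scope = m@scope, cv_r = m@cvR,
    cv_r2 = m@cvR2, cv_p = m@cvP, n_predictors = m@nPredictors))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read expression models from a TSV store
#'
#' @param path TSV path written by \code{\link{writeModelStore}}.
#' @return list of \linkS4class{ExpressionModel}.
#' @export
readModelStore <- function(path) {
  rows <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  lapply(meta, function(mm) {
    sel <- rows$gene == mm$gene & rows$tissue == mm$tissue
    sub <- rows[sel, , drop = FALSE]
    new("ExpressionModel", gene = mm$gene, tissue = mm$tissue,
        weights = setNames(sub$weight, sub$variant), scope = mm$scope,
        cvR = as.numeric(mm$cv_r), cvR2 = as.numeric(mm$cv_r2),
        cvP = as.numeric(mm$cv_p),
        nPredictors = as.integer(mm$n_predictors),
        variantInfo = data.frame(id = sub$variant, chrom = sub$chrom,
                                 pos = sub$pos, ea = sub$ea, oa = sub$oa,
                                 maf = sub$maf, stringsAsFactors = FALSE))
  })
}

#' Read/write a square LD matrix as TSV
#'
#' Square layout with a variant-id header row and first column.
#'
#' @param path file path.
#' @return numeric matrix with variant-id dimnames.
#' @export
readLdTsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                    check.names = FALSE)
  as.matrix(tab)
}

#' @rdname readLdTsv
#' @param ld square correlation matrix (or \linkS4class{LDMatrix} /
#'   \linkS4class{ProjectedLD}).
#' @export
writeLdTsv <- function(ld, path) {
  m <- ldMatrix(ld)
  write.table(data.frame(variant = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
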