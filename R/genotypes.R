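#' Construct a GenotypeMatrix
#'
#' Builds the package's genotype container from a sample-by-variant dosage
#' matrix and a variant metadata table. Missing dosages are mean-imputed per
#' variant before construction; stored MAFs are recomputed from the
#' (imputed) dosages.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns,
#'   values in \eqn{[0, 2]} (alternate-allele dosage). \code{NA}s allowed.
#' @param variants data.frame with columns \code{id}, \code{chrom},
#'   \code{pos} (1-based), \code{ref}, \code{alt}; one row per dosage
#'   column, in column order.
#' @param samples sample ids; defaults to the dosage rownames.
#' @return a \linkS4class{GenotypeMatrix}.
#' @examples
#' gt <- GenotypeMatrix(
#'   matrix(c(0, 1, 2, 1, 0, 1), nrow = 3,
#'          dimnames = list(paste0("s", 1:3), NULL)),
#'   data.frame(id = c("v1", "v2"), chrom = "chr1", pos = c(100L, 200L),
#'              ref = "A", alt = c("G", "C")))
#' mafs(gt)
#' @export
GenotypeMatrix <- function(dosages, variants, samples = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos", "ref", "alt") %in%
                  colnames(variants)),
            nrow(variants) == ncol(dosages))
  if (is.null(samples)) samples <- paste0("sample", seq_len(nrow(dosages)))
  dosages <- meanImputeDosages(dosages)
  f <- colMeans(dosages) / 2
  maf <- pmin(f, 1 - f)
  rr <- GenomicRanges::GRanges(
    variants$chrom, IRanges::IRanges(variants$pos, width = 1L))
  names(rr) <- variants$id
  rd <- S4Vectors::DataFrame(id = variants$id, ref = variants$ref,
                             alt = variants$alt, maf = unname(maf))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = t(dosages)), rowRanges = rr,
    colData = S4Vectors::DataFrame(row.names = samples))
  SummarizedExperiment::rowData(se) <- rd
  new("GenotypeMatrix", se)
}

# per-variant mean imputation of missing dosages
meanImputeDosages <- function(dosages) {
  if (!anyNA(dosages)) return(dosages)
  mu <- colMeans(dosages, na.rm = TRUE)
  idx <- which(is.na(dosages), arr.ind = TRUE)
  dosages[idx] <- mu[idx[, 2L]]
  dosages
}

#' Filter variants by minor allele frequency
#'
#' Retains variants with MAF greater than or equal to \code{threshold}
#' (inclusive, so a variant at exactly the threshold survives). Idempotent.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param threshold MAF threshold in \eqn{[0, 0.5]}; default 0.05, the
#'   common-variant convention used for model training.
#' @return a \linkS4class{GenotypeMatrix} with the surviving variants; may
#'   have zero variants (with a warning).
#' @export
mafFilter <- function(genotypes, threshold = 0.05) {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  checkFraction(threshold, "threshold")
  keep <- SummarizedExperiment::rowData(genotypes)$maf >= threshold
  if (!any(keep)) warning("no variants pass the MAF filter")
  genotypes[keep, ]
}

#' Subset a GenotypeMatrix to a genomic segment
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param segment a \linkS4class{Segment}.
#' @return the variants whose position falls inside the segment.
#' @export
subsetBySegment <- function(genotypes, segment) {
  vt <- variantTable(genotypes)
  genotypes[segmentContains(segment, vt$chrom, vt$pos), ]
}

#' Read a dosage matrix from TSV
#'
#' Expected layout: columns \code{id}, \code{chrom}, \code{pos}, \code{ref},
#' \code{alt} followed by one numeric column per sample (variants in rows).
#'
#' @param path file path.
#' @return a \linkS4class{GenotypeMatrix}.
#' @seealso \code{\link{writeDosageTsv}}
#' @export
readDosageTsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(meta %in% colnames(tab)))
    stop("dosage TSV must contain columns: ", paste(meta, collapse = ", "))
  sampleCols <- setdiff(colnames(tab), meta)
  ds <- t(as.matrix(tab[, sampleCols, drop = FALSE]))
  rownames(ds) <- sampleCols
  GenotypeMatrix(ds, tab[, meta])
}

#' Write a GenotypeMatrix to TSV
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeDosageTsv <- function(genotypes, path) {
  vt <- variantTable(genotypes)
  out <- cbind(vt[, c("id", "chrom", "pos", "ref", "alt")],
               as.data.frame(SummarizedExperiment::assay(genotypes,
                                                         "dosage")))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotype dosages from a VCF file
#'
#' Uses the \code{DS} FORMAT field when present, otherwise derives dosages
#' from \code{GT} (count of alternate alleles; missing genotypes are
#' mean-imputed). Multi-allelic sites are dropped.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param genome genome tag passed to the VCF parser.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
readGenotypeVcf <- function(path, genome = "unknown") {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("readGenotypeVcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path, genome = genome)
  alt <- VariantAnnotation::alt(vcf)
  biallelic <- S4Vectors::elementNROWS(alt) == 1L
  if (!all(biallelic)) {
    message(sum(!biallelic), " multi-allelic site(s) dropped")
    vcf <- vcf[biallelic, ]
    alt <- alt[biallelic]
  }
  gen <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(gen)) {
    ds <- t(gen$DS)
  } else if ("GT" %in% names(gen)) {
    gtChar <- gen$GT
    cnt <- function(g) {
      if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    }
    ds <- t(apply(gtChar, c(1, 2), cnt))
  } else stop("VCF has neither DS nor GT genotype fields")
  rr <- SummarizedExperiment::rowRanges(vcf)
  variants <- data.frame(
    id = names(rr),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(unlist(alt)),
    stringsAsFactors = FALSE)
  GenotypeMatrix(ds, variants)
}
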