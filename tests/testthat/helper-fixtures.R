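# shared fixture builders; everything is generated in code at test time

# tiny genotype matrix with hand-set dosages
toyGenotypes <- function() {
  ds <- matrix(c(0, 1, 2, 1,
                 2, 1, 0, 1,
                 0, 0, 1, 2,
                 1, 2, 1, 0),
               nrow = 4, byrow = FALSE,
               dimnames = list(paste0("s", 1:4), NULL))
  GenotypeMatrix(ds, data.frame(
    id = paste0("v", 1:4), chrom = "chr1",
    pos = c(100L, 200L, 300L, 400L), ref = "A",
    alt = c("G", "C", "G", "C"), stringsAsFactors = FALSE))
}

# one-row-per-variant GWAS table builder
toyGwas <- function(snp, z, ea = "G", oa = "A", n = 1000,
                    chr = "chr1", pos = seq_along(snp) * 100L,
                    trait = "trait") {
  gwasSummary(data.frame(snp = snp, chr = chr, pos = pos,
                         ea = ea, oa = oa, z = z, n = n,
                         beta = NA_real_, se = NA_real_,
                         stringsAsFactors = FALSE), trait = trait)
}

toyModel <- function(weights, mafs = rep(0.3, length(weights)),
                     gene = "geneA", tissue = "tissueA",
                     scope = "full", cvR = 0.5, cvP = 0.001,
                     ea = rep("G", length(weights)),
                     oa = rep("A", length(weights))) {
  ids <- names(weights)
  new("ExpressionModel", gene = gene, tissue = tissue,
      weights = weights, scope = scope, cvR = cvR, cvR2 = cvR^2,
      cvP = cvP, nPredictors = length(weights),
      variantInfo = data.frame(id = ids, chrom = "chr1",
                               pos = seq_along(ids) * 100L,
                               ea = ea, oa = oa, maf = mafs,
                               stringsAsFactors = FALSE))
}

# random symmetric positive-definite matrix
randomSpd <- function(p, jitter = 0.5) {
  A <- matrix(rnorm(p * p), p)
  S <- crossprod(A) / p + jitter * diag(p)
  S
}
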