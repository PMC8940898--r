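test_that("single-predictor model reduces to the variant z-score", {
  m <- toyModel(c(v1 = 1))
  g <- toyGwas("v1", z = 2.5)
  ld <- matrix(1, 1, 1, dimnames = list("v1", "v1"))
  res <- geneTraitAssociation(m, g, ld)
  expect_equal(res$z, 2.5)
  expect_equal(res$p, 2 * pnorm(-2.5))
  expect_equal(res$n_snps_used, 1L)
})

test_that("two independent equal-weight predictors give z * sqrt(2)", {
  m <- toyModel(c(v1 = 0.3, v2 = 0.3), mafs = c(0.25, 0.25))
  g <- toyGwas(c("v1", "v2"), z = c(1.2, 1.2))
  ld <- diag(2); dimnames(ld) <- list(c("v1", "v2"), c("v1", "v2"))
  res <- geneTraitAssociation(m, g, ld)
  expect_equal(res$z, 1.2 * sqrt(2))
})

test_that("gene z is invariant to positive rescaling of weights", {
  set.seed(14)
  ids <- paste0("v", 1:4)
  w <- setNames(rnorm(4), ids)
  m1 <- toyModel(w, mafs = runif(4, 0.1, 0.5))
  m2 <- m1; m2@weights <- 3.7 * w
  g <- toyGwas(ids, z = rnorm(4))
  C <- cov2cor(randomSpd(4)); dimnames(C) <- list(ids, ids)
  expect_equal(geneTraitAssociation(m1, g, C)$z,
               geneTraitAssociation(m2, g, C)$z)
})

test_that("allele flips change the z sign and palindromes drop out", {
  m <- toyModel(c(v1 = 1), ea = "G", oa = "A")
  gFlip <- toyGwas("v1", z = 2, ea = "A", oa = "G")
  res <- geneTraitAssociation(m, gFlip, matrix(1, 1, 1,
                                               dimnames = list("v1", "v1")))
  expect_equal(res$z, -2)

  mPal <- toyModel(c(v1 = 1), ea = "A", oa = "T")
  gPal <- toyGwas("v1", z = 2, ea = "A", oa = "T")
  expect_error(geneTraitAssociation(mPal, gPal,
                                    matrix(1, 1, 1,
                                           dimnames = list("v1", "v1"))),
               "harmonization")
})

test_that("degenerate association inputs raise errors", {
  m0 <- toyModel(c(v1 = 0))
  g <- toyGwas("v1", z = 1)
  expect_error(geneTraitAssociation(m0, g, diag(1)),
               "zero predicted-expression variance")
  mMiss <- toyModel(c(nope = 1))
  expect_error(geneTraitAssociation(mMiss, g, diag(1)), "overlapping")
})

test_that("gene z-score is standard normal under the null", {
  set.seed(29)
  ids <- paste0("v", 1:5)
  w <- setNames(runif(5, -1, 1), ids)
  m <- toyModel(w, mafs = runif(5, 0.1, 0.5))
  C <- diag(5); dimnames(C) <- list(ids, ids)
  sig <- sqrt(2 * m@variantInfo$maf * (1 - m@variantInfo$maf))
  ws <- unname(w) * sig
  zGene <- (matrix(rnorm(4000 * 5), 4000) %*% ws) / sqrt(sum(ws^2))
  expect_gt(ks.test(zGene, "pnorm")$p.value, 0.01)
  # spot-check a few draws against the package computation
  for (i in 1:3) {
    z <- rnorm(5)
    res <- geneTraitAssociation(m, toyGwas(ids, z = z), C)
    expect_equal(res$z, sum(ws * z) / sqrt(sum(ws^2)))
  }
})

test_that("BH adjustment matches the step-up procedure", {
  res <- bhFdr(c(0.01, 0.02, 0.04, 0.9), q = 0.05)
  # manual step-up: 0.01*4/1=0.04, 0.02*4/2=0.04, 0.04*4/3=0.0533, 0.9
  expect_equal(res$p_fdr, c(0.04, 0.04, 0.04 * 4 / 3, 0.9))
  expect_equal(sum(res$pass), 2L)

  resAll <- bhFdr(rep(0.001, 10))
  expect_true(all(resAll$pass))

  res1 <- bhFdr(0.06)
  expect_equal(res1$p_fdr, 0.06)
  expect_false(res1$pass)

  expect_equal(nrow(bhFdr(numeric(0))), 0L)

  # monotone: lowering q never adds rejections
  set.seed(6)
  p <- runif(50)
  expect_true(all(bhFdr(p, 0.01)$pass <= bhFdr(p, 0.05)$pass))
  expect_true(all(res$p_fdr >= res$p))
})

test_that("phenome scan filters traits by case count and genes by iGene", {
  ids <- c("v1", "v2")
  C <- diag(2); dimnames(C) <- list(ids, ids)
  full <- list(toyModel(c(v1 = 1), gene = "gA"),
               toyModel(c(v2 = 1), gene = "gB"))
  reduced <- list(toyModel(c(v1 = 0.5), gene = "gA",
                           scope = "reduced", cvR = 0.3, cvP = 1e-4),
                  toyModel(c(v2 = 0.5), gene = "gB",
                           scope = "reduced", cvR = 0.05, cvP = 0.5))
  traits <- list(big = toyGwas(ids, z = c(3, 1), trait = "big"),
                 rare = toyGwas(ids, z = c(2, 2), trait = "rare"))
  res <- phenomeScan(full, reduced, traits, C,
                     caseCounts = c(big = 500, rare = 10))
  expect_true(all(res$trait == "big"))        # < 50 cases excluded
  expect_true(all(res$gene == "gA"))          # gB fails the iGene filter
  expect_true(all(c("p_fdr", "pass") %in% colnames(res)))

  # single trait reduces to association + BH over genes
  res1 <- phenomeScan(full, NULL, traits["big"], C)
  direct <- rbind(geneTraitAssociation(full[[1]], traits$big, C),
                  geneTraitAssociation(full[[2]], traits$big, C))
  expect_equal(res1$z, direct$z)
  expect_equal(res1$p_fdr, bhFdr(direct$p)$p_fdr)
})

test_that("phenome scan on permuted null traits controls FDR", {
  set.seed(44)
  nPairs <- 60
  fdrHat <- vapply(1:40, function(s) {
    p <- 2 * pnorm(-abs(rnorm(nPairs)))   # null gene-level p-values
    mean(bhFdr(p, 0.05)$pass) * 0 + sum(bhFdr(p, 0.05)$pass) /
      max(1, sum(bhFdr(p, 0.05)$pass))
  }, numeric(1))
  # under the complete null every rejection is false: FDR = P(any rejection)
  rejAny <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    p <- 2 * pnorm(-abs(rnorm(nPairs)))
    any(bhFdr(p, 0.05)$pass)
  }, logical(1))
  expect_lte(mean(rejAny), 0.05 + 2 * sqrt(0.05 * 0.95 / 100))
})
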