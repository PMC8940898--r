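test_that("generators are bit-reproducible under a fixed seed", {
  g1 <- simulateGenotypes(50, maf = c(0.2, 0.4), seed = 33)
  g2 <- simulateGenotypes(50, maf = c(0.2, 0.4), seed = 33)
  expect_identical(dosages(g1), dosages(g2))

  s1 <- simulateMultitissueExpression(seed = 12)
  s2 <- simulateMultitissueExpression(seed = 12)
  expect_identical(s1$expression, s2$expression)

  r1 <- simulateLocalH2Study(h2Levels = 0.02, nReps = 2, nGwas = 2000,
                             nPanel = 100, nVariants = 20, seed = 5)
  r2 <- simulateLocalH2Study(h2Levels = 0.02, nReps = 2, nGwas = 2000,
                             nPanel = 100, nVariants = 20, seed = 5)
  expect_identical(r1, r2)

  m1 <- simulateMrStudy(alphaGrid = 0.2, nGenes = 2, nGwas = 2000,
                        seed = 9)
  m2 <- simulateMrStudy(alphaGrid = 0.2, nGenes = 2, nGwas = 2000,
                        seed = 9)
  expect_identical(m1, m2)
})

test_that("generated dosages match requested allele frequencies", {
  gt <- simulateGenotypes(50000, maf = c(0.3, 0.1), seed = 2)
  expect_lt(max(abs(mafs(gt) - c(0.3, 0.1))), 0.01)
  expect_true(all(dosages(gt) %in% c(0, 1, 2)))
})

test_that("independent targets yield near-zero empirical correlation", {
  ok <- vapply(1:20, function(s) {
    gt <- simulateGenotypes(50000, maf = rep(0.3, 2), targetLd = diag(2),
                            seed = 400 + s)
    abs(cor(dosages(gt))[1, 2]) < 0.02
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("empirical LD tracks the target and the implied truth", {
  tgt <- arBlockCorrelation(30, seed = 6)
  maf <- withr::with_seed(6, runif(30, 0.05, 0.5))
  gt <- simulateGenotypes(10000, maf = maf, targetLd = tgt, seed = 7)
  emp <- ldMatrix(empiricalLD(gt))
  expect_lt(mean(abs(emp - tgt)), 0.05)
  imp <- impliedDosageLD(tgt, maf)
  # the implied matrix is the exact population LD of the generator
  expect_lt(mean(abs(emp - imp)), mean(abs(emp - tgt)) + 1e-9)
  expect_lt(max(abs(emp - imp)), 0.06)
  ev <- eigen(imp, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("generator rejects invalid inputs", {
  expect_error(simulateGenotypes(0, maf = 0.3), "positive")
  expect_error(simulateGenotypes(10), "supply")
  bad <- matrix(c(1, 2, 2, 1), 2)   # not PSD
  expect_error(simulateGenotypes(10, maf = c(0.3, 0.3), targetLd = bad),
               "positive semi-definite")
})

test_that("local-h2 study is unbiased with the true LD matrix", {
  res <- simulateLocalH2Study(h2Levels = c(0, 0.02), nReps = 12,
                              nGwas = 20000, nPanel = 300,
                              nVariants = 40, seed = 77)
  tr <- subset(res, ld_mode == "true")
  for (h2 in c(0, 0.02)) {
    x <- tr$h2_hat[tr$h2_true == h2]
    mcse <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - h2), 2.5 * mcse + 1e-3)
  }
  # projected panel estimates are less inflated than raw panel estimates
  agg <- tapply(res$h2_hat[res$h2_true == 0.02],
                res$ld_mode[res$h2_true == 0.02], mean)
  expect_lt(abs(agg[["projected"]] - 0.02), abs(agg[["observed"]] - 0.02))
})

test_that("MR study: estimators agree without pleiotropy, diverge with it", {
  quiet <- simulateMrStudy(alphaGrid = 0.4, nGenes = 8, nIv = 15,
                           invalidFrac = 0, nGwas = 20000, seed = 3)
  expect_lt(abs(mean(quiet$alpha_ivw - quiet$alpha_mrjti)), 0.02)

  loud <- simulateMrStudy(alphaGrid = 0.4, nGenes = 8, nIv = 15,
                          invalidFrac = 0.2, nGwas = 20000, seed = 4)
  expect_gt(abs(mean(loud$alpha_ivw) - 0.4),
            abs(mean(loud$alpha_mrjti) - 0.4))
})

test_that("multi-tissue generator respects similarity and heritability", {
  simSame <- simulateMultitissueExpression(nTissues = 2,
                                           nPerTissue = 200,
                                           similarity = 1, h2Expr = 0.4,
                                           nCausal = 3, nVariants = 12,
                                           seed = 50)
  gA <- simSame$truth$genetic$tissue1
  gB <- simSame$truth$genetic$tissue2
  expect_equal(cor(gA, gB), 1, tolerance = 1e-9)

  cors <- vapply(1:10, function(s) {
    sim0 <- simulateMultitissueExpression(nTissues = 2, nPerTissue = 100,
                                          similarity = 0, h2Expr = 0.4,
                                          nCausal = 3, nVariants = 12,
                                          seed = 60 + s)
    cor(sim0$truth$genetic$tissue1, sim0$truth$genetic$tissue2)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 2.5 * sd(cors) / sqrt(10) + 0.05)

  # per-tissue genetic variance equals the requested heritability
  expect_equal(var(gA) * (200 * 2 - 1) / (200 * 2), 0.4,
               tolerance = 0.05)
})

test_that("cross-validated r2 estimates the generated expression heritability", {
  r2s <- vapply(1:12, function(s) {
    sim <- simulateMultitissueExpression(nTissues = 1, nPerTissue = 400,
                                         similarity = 1, h2Expr = 0.3,
                                         nCausal = 3, nVariants = 20,
                                         seed = 200 + s)
    m <- trainWeightedElasticNet(sim$genotypes, sim$expression,
                                 "tissue1",
                                 config = trainingConfig(seed = s),
                                 gene = "g")
    m@cvR2
  }, numeric(1))
  expect_lt(abs(mean(r2s) - 0.3), 0.05)
})
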