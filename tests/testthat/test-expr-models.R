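test_that("cv performance handles exact, inverted and degenerate inputs", {
  p <- cvPerformance(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(p$r, 1)
  expect_equal(p$r2, 1)

  p <- cvPerformance(c(1, 2, 3, 4), -c(1, 2, 3, 4))
  expect_equal(p$r, -1)
  expect_equal(p$r2, 1)   # squared metric ignores sign

  # affine invariance of r2
  set.seed(2)
  o <- rnorm(30); pr <- o + rnorm(30, sd = 0.5)
  expect_equal(cvPerformance(o, pr)$r2,
               cvPerformance(o, 3 * pr - 7)$r2)

  p <- cvPerformance(rnorm(10), rep(1, 10))
  expect_equal(p$r, 0)
  expect_equal(p$p, 1)
  expect_error(cvPerformance(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("independent predictions score near zero r2", {
  set.seed(41)
  r2s <- vapply(1:40, function(i)
    cvPerformance(rnorm(1000), rnorm(1000))$r2, numeric(1))
  expect_gt(mean(r2s < 0.01), 0.9)
})

test_that("iGene filter uses strict thresholds on signed r", {
  expect_true(iGeneFilter(0.2, 0.01))
  expect_false(iGeneFilter(0.1, 0.001))     # boundary r fails
  expect_false(iGeneFilter(0.2, 0.05))      # boundary p fails
  expect_false(iGeneFilter(-0.5, 1e-9))     # negative r fails
  expect_true(iGeneFilter(toyModel(c(v1 = 1), cvR = 0.2, cvP = 0.01)))
})

test_that("concentration statistic evaluates and validates", {
  cs <- concentrationStatistic(0.1, 100, 0.2, 10)
  expect_equal(cs@psi, 5)
  # equal per-SNP heritability gives psi = 1
  expect_equal(concentrationStatistic(0.02, 100, 0.2, 10)@psi, 1)
  expect_equal(concentrationStatistic(0, 50, 0.2, 5)@psi, 0)
  expect_error(concentrationStatistic(0.1, 100, 0, 10), "positive")
  expect_error(concentrationStatistic(0.1, 100, 0.2, 0), "positive")
})

test_that("a perfect predictor gets the weight and near-unit cv r2", {
  set.seed(12)
  n <- 80
  ds <- cbind(rbinom(n, 2, 0.4), rbinom(n, 2, 0.3), rbinom(n, 2, 0.2))
  rownames(ds) <- paste0("d", 1:n)
  gt <- GenotypeMatrix(ds, data.frame(
    id = paste0("v", 1:3), chrom = "chr1", pos = c(10L, 20L, 30L),
    ref = "A", alt = "G"))
  y <- setNames(2 * ds[, 1] + rnorm(n, sd = 1e-3), rownames(ds))
  m <- trainWeightedElasticNet(
    gt, list(t1 = y), "t1",
    config = trainingConfig(seed = 1,
                            lambdaGrid = 10^seq(-1, -5, length.out = 30)),
    gene = "g")
  expect_true("v1" %in% names(m@weights))
  expect_gt(m@cvR2, 0.99)
})

test_that("permuted expression fails the iGene filter", {
  set.seed(77)
  n <- 150
  ds <- matrix(rbinom(n * 6, 2, 0.3), n, 6,
               dimnames = list(paste0("d", 1:n), NULL))
  gt <- GenotypeMatrix(ds, data.frame(
    id = paste0("v", 1:6), chrom = "chr1", pos = 1:6 * 10L,
    ref = "A", alt = "G"))
  r2s <- vapply(1:15, function(s) {
    y <- setNames(rnorm(n), rownames(ds))   # independent of genotypes
    m <- trainWeightedElasticNet(gt, list(t1 = y), "t1",
                                 config = trainingConfig(seed = s),
                                 gene = "g")
    m@cvR2
  }, numeric(1))
  expect_lt(median(r2s), 0.02)
})

test_that("single-tissue weights reduce the joint model to the single-tissue fit", {
  sim <- simulateMultitissueExpression(nTissues = 2, nPerTissue = c(80, 60),
                                       similarity = 0.8, h2Expr = 0.4,
                                       nCausal = 2, nVariants = 10,
                                       seed = 21)
  cfg <- trainingConfig(seed = 3)
  mJoint <- trainWeightedElasticNet(
    sim$genotypes, sim$expression, "tissue1",
    config = cfg, gene = "g",
    obsWeights = c(tissue1 = 1, tissue2 = 0))
  mSingle <- trainWeightedElasticNet(
    sim$genotypes, sim$expression["tissue1"], "tissue1",
    config = cfg, gene = "g")
  expect_equal(mJoint@weights, mSingle@weights, tolerance = 1e-6)
  expect_equal(mJoint@cvR, mSingle@cvR, tolerance = 1e-9)
})

test_that("cross-tissue borrowing improves a small tissue's prediction", {
  # shared causal architecture, 300 vs 60 samples, similarity 0.9
  deltas <- vapply(1:8, function(s) {
    sim <- simulateMultitissueExpression(
      nTissues = 2, nPerTissue = c(300, 60), similarity = 0.9,
      h2Expr = 0.3, nCausal = 2, nVariants = 20, seed = 100 + s)
    sm <- matrix(c(1, 0.9, 0.9, 1), 2,
                 dimnames = list(c("tissue1", "tissue2"),
                                 c("tissue1", "tissue2")))
    cfg <- trainingConfig(seed = s, similarityExponentGrid = c(0, 1, Inf))
    mJ <- trainWeightedElasticNet(sim$genotypes, sim$expression,
                                  "tissue2", similarity = tissueSimilarity(sm),
                                  config = cfg, gene = "g")
    mS <- trainWeightedElasticNet(sim$genotypes, sim$expression["tissue2"],
                                  "tissue2", config = cfg, gene = "g")
    mJ@cvR2 - mS@cvR2
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("training rejects degenerate inputs", {
  gt <- toyGenotypes()
  yConst <- setNames(rep(1, 4), paste0("s", 1:4))
  expect_error(trainWeightedElasticNet(gt, list(t = yConst), "t"),
               "all-constant")
  yFew <- setNames(rnorm(2), c("s1", "s2"))
  expect_error(trainWeightedElasticNet(
    gt, list(t = yFew), "t", config = trainingConfig(nFolds = 5)),
    "fewer donors")
})

test_that("dilation at zero extension reproduces the reduced model", {
  set.seed(55)
  n <- 120
  ds <- matrix(rbinom(n * 8, 2, 0.35), n, 8,
               dimnames = list(paste0("d", 1:n), NULL))
  gt <- GenotypeMatrix(ds, data.frame(
    id = paste0("v", 1:8), chrom = "chr1",
    pos = as.integer(seq(1000, 8000, length.out = 8)),
    ref = "A", alt = "G"))
  seg <- parseSegment("chr1:1500-4500")
  y <- setNames(ds[, 3] * 0.8 + rnorm(n, sd = 0.6), rownames(ds))
  cfg <- trainingConfig(seed = 2)
  tab <- dilationExperiment(gt, list(gA = y), seg,
                            extensions = c(0, 10000), config = cfg)
  sub <- subsetBySegment(gt, seg)
  mRed <- trainWeightedElasticNet(sub, list(tissue = y), "tissue",
                                  config = cfg, gene = "gA",
                                  scope = "reduced")
  expect_equal(tab$r2[tab$extension == 0], mRed@cvR2)
  # the widest extension covers all variants: equals the full model
  mFull <- trainWeightedElasticNet(gt, list(tissue = y), "tissue",
                                   config = cfg, gene = "gA")
  expect_equal(tab$r2[tab$extension == 10000], mFull@cvR2)
})

test_that("random-segment null detects signal concentrated in the segment", {
  set.seed(66)
  n <- 150; p <- 24
  ds <- matrix(rbinom(n * p, 2, 0.35), n, p,
               dimnames = list(paste0("d", 1:n), NULL))
  gt <- GenotypeMatrix(ds, data.frame(
    id = paste0("v", 1:p), chrom = "chr1",
    pos = as.integer(seq(1000, 48000, length.out = p)),
    ref = "A", alt = "G"))
  seg <- parseSegment("chr1:20000-28000")   # contains ~4 variants
  vt <- variantTable(gt)
  inSeg <- which(vt$pos >= seg@start + 1 & vt$pos <= seg@end)
  genes <- paste0("g", 1:6)
  expr <- setNames(lapply(seq_along(genes), function(i) {
    setNames(ds[, inSeg[1 + (i %% length(inSeg))]] * 1.0 +
               rnorm(n, sd = 0.8), rownames(ds))
  }), genes)
  cis <- data.frame(gene = genes, chrom = "chr1",
                    start = 1000, end = 48000)
  res <- randomSegmentNull(gt, expr, seg, cis, nSegments = 12,
                           config = trainingConfig(seed = 4), seed = 8)
  expect_equal(nrow(res$table), 6L)
  expect_gt(mean(res$table$observed_r2 > res$table$null_median_r2), 0.5)
  expect_lt(res$wilcoxonP, 0.05)
})
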