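test_that("mediated decomposition conserves the total effect", {
  d <- mediatedDecomposition(c(0.3, 0.1), 0.4, c(0.5, 0))
  expect_equal(d$mediated, c(0.2, 0))
  expect_equal(d$indirect, c(0.1, 0.1))

  # theta = alpha * beta exactly: fully mediated
  b <- c(0.2, -0.1, 0.05)
  d <- mediatedDecomposition(0.6 * b, 0.6, b)
  expect_equal(d$indirect, rep(0, 3))

  # alpha = 0: everything is indirect
  th <- c(0.4, -0.2)
  d <- mediatedDecomposition(th, 0, c(1, 1))
  expect_equal(d$indirect, th)

  # conservation holds for arbitrary inputs
  set.seed(3)
  th <- rnorm(6); b <- rnorm(6); a <- rnorm(1)
  d <- mediatedDecomposition(th, a, b)
  expect_equal(d$mediated + d$indirect, th)

  expect_error(mediatedDecomposition(1:3, 0.5, 1:2), "equal length")
})

test_that("pi_c is 1 when reduced equals full, and matches direct arithmetic", {
  b <- c(0.1, 0.1, 0.1, 0.1)
  res <- piC(1, b, b, diag(4), diag(4), n = 10000)
  expect_equal(res@piC, 1)
  expect_false(res@outOfRange)

  # printed-form evaluation: 2-of-4 split with identity matrices
  res2 <- piC(1, b, b[1:2], diag(4), diag(2), n = 10000)
  num <- 0.02 - 2 / 1e4
  den <- 0.04 - 4 / 1e4
  expect_equal(res2@piC, (num / den) * (1e4 - 4) / (1e4 - 2))
  expect_equal(res2@piC, 0.4999, tolerance = 1e-4)
  expect_equal(res2@psiE, res2@piC * 4 / 2)
})

test_that("pi_c flags degenerate and out-of-range results", {
  b <- c(0.1, 0.1)
  # alpha = 0 with equal ranks: rank terms alone give 1, flagged
  res <- piC(0, b, b, diag(2), diag(2), n = 1000)
  expect_equal(res@piC, 1)
  expect_true(res@degenerate)

  # nonpositive denominator: undefined
  tiny <- c(1e-6, 1e-6)
  res2 <- piC(1e-6, tiny, tiny[1], diag(2), diag(1), n = 100)
  expect_true(is.na(res2@piC))
  expect_true(res2@degenerate)

  # rank correction can push pi_c above 1 when the extra full-model
  # variant contributes nearly nothing
  res3 <- piC(1, c(0.1, 0.001), c(0.1), diag(2), diag(1), n = 300)
  expect_true(res3@piC > 1)
  expect_true(res3@outOfRange)
})

test_that("pi_c becomes scale-free in alpha as n grows", {
  set.seed(8)
  bF <- rnorm(6, sd = 0.2); bR <- bF[1:3]
  r1 <- piC(0.4, bF, bR, diag(6), diag(3), n = 1e9)
  r2 <- piC(4.0, bF, bR, diag(6), diag(3), n = 1e9)
  expect_equal(r1@piC, r2@piC, tolerance = 1e-5)
  expect_equal(r1@piC, sum(bR^2) / sum(bF^2), tolerance = 1e-4)
})

test_that("pi_c uses base-matrix ranks from projected LD objects", {
  gt <- simulateGenotypes(60, maf = runif(8, 0.2, 0.5), seed = 5)
  plF <- ledoitWolfProject(gt)
  plR <- ledoitWolfProject(gt[, ])  # same panel; reduced = full here
  b <- rnorm(8, sd = 0.1)
  res <- piC(0.5, b, b, plF, plR, n = 50000)
  expect_equal(res@qFull, plF@base@rank)
  expect_equal(res@piC, 1)
})

test_that("indirect effects are attached when theta is supplied", {
  bF <- c(0.2, 0.1); th <- c(0.15, 0.02)
  res <- piC(0.5, bF, bF[1], diag(2), diag(1), n = 10000, theta = th)
  expect_equal(res@indirectEffect, th - 0.5 * bF)
})

test_that("GDE scores are weighted dosage sums with the archaic rule", {
  m <- toyModel(c(v1 = 0.5, v2 = -0.25))
  s <- gdeScore(m, c(v1 = 2, v2 = 1))
  expect_false(s$suppressed)
  expect_equal(s$score, 2 * 0.5 - 0.25)
  expect_equal(s$n_predictors_used, 2L)

  # all-zero dosages score zero
  expect_equal(gdeScore(m, c(v1 = 0, v2 = 0))$score, 0)

  # archaic rule: a single genotyped predictor is suppressed
  s1 <- gdeScore(m, c(v1 = 2), minPredictors = 2)
  expect_true(s1$suppressed)
  expect_true(is.na(s1$score))
  expect_match(s1$reason, "1 of 2")

  # missing predictors contribute zero, not imputed values
  s2 <- gdeScore(m, c(v1 = 2, v2 = NA))
  expect_equal(s2$score, 1)
  expect_equal(s2$n_predictors_used, 1L)

  # linearity over the shared predictor set
  d1 <- c(v1 = 1, v2 = 2); d2 <- c(v1 = 2, v2 = 0)
  expect_equal(gdeScore(m, 2 * d1 + 3 * d2)$score,
               2 * gdeScore(m, d1)$score + 3 * gdeScore(m, d2)$score)
})

test_that("population GDE distributions place an archaic profile", {
  set.seed(30)
  n <- 120
  ds <- matrix(rbinom(n * 4, 2, 0.4), n, 4,
               dimnames = list(paste0("s", 1:n), NULL))
  gt <- GenotypeMatrix(ds, data.frame(
    id = paste0("v", 1:4), chrom = "chr1", pos = 1:4 * 100L,
    ref = "A", alt = "G"))
  pops <- setNames(rep(c("AFR", "EUR", "EAS"), length.out = n),
                   rownames(ds))
  m <- toyModel(setNames(c(-0.8, -0.5, 0.2, 0.1), paste0("v", 1:4)))

  # archaic equal to a panel subject lands at that subject's quantile
  subj <- "s10"
  prof <- setNames(ds[subj, ], paste0("v", 1:4))
  res <- populationGdeDistributions(m, gt, pops, archaicProfile = prof)
  expect_equal(sort(unique(res$scores$population)),
               c("AFR", "EAS", "EUR"))
  sAfr <- res$scores$score[res$scores$population == "AFR"]
  expect_equal(res$archaic$quantile[["AFR"]],
               ecdf(sAfr)(res$scores$score[res$scores$subject == subj]))

  # strongest negative-weight alleles put the archaic in the low tail
  worst <- setNames(c(2, 2, 0, 0), paste0("v", 1:4))
  res2 <- populationGdeDistributions(m, gt, pops, archaicProfile = worst)
  expect_true(all(res2$archaic$quantile < 0.05))

  # suppression propagates: one genotyped predictor -> no archaic output
  res3 <- populationGdeDistributions(m, gt, pops,
                                     archaicProfile = c(v1 = 2))
  expect_null(res3$archaic)

  # identical panels give identical per-population distributions
  res4 <- populationGdeDistributions(m, gt, pops,
                                     archaicProfile = prof)
  expect_equal(res4$summary, res$summary)
})
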