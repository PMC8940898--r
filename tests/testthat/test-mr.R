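mkEqtl <- function(snp, beta, se, pos, ea = "G", oa = "A") {
  gwasSummary(data.frame(snp = snp, chr = "chr1", pos = pos, ea = ea,
                         oa = oa, beta = beta, se = se, n = 670,
                         stringsAsFactors = FALSE), trait = "expr")
}

test_that("IV building removes palindromes and clumps greedily", {
  snp <- c("a", "b", "c")
  eqtl <- mkEqtl(snp, beta = c(0.6, 0.4, 0.5), se = c(0.1, 0.1, 0.1),
                 pos = c(100L, 200L, 300L),
                 ea = c("G", "G", "A"), oa = c("A", "A", "T"))
  gwas <- toyGwas(snp, z = c(2, 1, 5), ea = c("G", "G", "A"),
                  oa = c("A", "A", "T"), pos = c(100L, 200L, 300L))
  C <- matrix(c(1, 0.8, 0, 0.8, 1, 0, 0, 0, 1), 3,
              dimnames = list(snp, snp))
  iv <- buildIvSet(eqtl, gwas, C)
  tab <- ivTable(iv)
  # c is palindromic (A/T) despite the smallest p; a beats b at r2 = 0.64
  expect_false("c" %in% tab$variant)
  expect_equal(tab$variant, "a")
  expect_setequal(iv@removed$reason[iv@removed$variant == "c"],
                  "palindromic")
  expect_equal(iv@removed$reason[iv@removed$variant == "b"], "clumped")
})

test_that("clumping keeps correlated pairs below the r2 threshold", {
  snp <- c("a", "b")
  eqtl <- mkEqtl(snp, beta = c(0.5, 0.4), se = c(0.05, 0.05),
                 pos = c(100L, 200L))
  gwas <- toyGwas(snp, z = c(1, 1), pos = c(100L, 200L))
  C03 <- matrix(c(1, 0.3, 0.3, 1), 2, dimnames = list(snp, snp))
  iv <- buildIvSet(eqtl, gwas, C03)      # r2 = 0.09 < 0.1: both kept
  expect_equal(nrow(ivTable(iv)), 2L)
  expect_equal(ivTable(iv)$ldScore, rowSums(C03), ignore_attr = TRUE)

  C04 <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(snp, snp))
  iv2 <- buildIvSet(eqtl, gwas, C04)     # r2 = 0.16 >= 0.1: weaker dropped
  expect_equal(ivTable(iv2)$variant, "a")

  # exposure p-values above the clump threshold are excluded
  weak <- mkEqtl(snp, beta = c(0.5, 0.01), se = c(0.05, 0.05),
                 pos = c(100L, 200L))
  iv3 <- buildIvSet(weak, gwas, C03)
  expect_equal(ivTable(iv3)$variant, "a")
  expect_true("p_threshold" %in% iv3@removed$reason)
})

test_that("IVW reduces to the ratio for one IV and is exact when proportional", {
  iv1 <- ivSet(0.5, 0.2, seOutcome = 0.1)
  expect_equal(ivw(iv1)$alpha, 0.4)

  set.seed(4)
  b <- rnorm(12)
  ivp <- ivSet(b, 0.7 * b, seOutcome = runif(12, 0.05, 0.2))
  expect_equal(ivw(ivp)$alpha, 0.7)
  expect_error(ivw(ivSet(numeric(0), numeric(0))), "at least 1")
  expect_error(ivw(ivSet(c(0, 0), c(1, 1))), "zero")
})

test_that("MR-JTI returns the null fit for zero outcome effects", {
  set.seed(7)
  iv <- ivSet(rnorm(10), rep(0, 10))
  f <- mrJti(iv, nBoot = 0, seed = 1)
  expect_equal(alphaHat(f), 0)
  expect_equal(unname(f@vHat), rep(0, 10))
  expect_equal(f@wHat, 0)
})

test_that("MR-JTI recovers an exactly proportional effect", {
  set.seed(9)
  b <- rnorm(30)
  iv <- ivSet(b, 0.3 * b)
  f <- mrJti(iv, nBoot = 0, seed = 2)
  expect_equal(alphaHat(f), 0.3, tolerance = 0.02)
  expect_lt(sum(abs(f@vHat)), 0.01)
})

test_that("MR-JTI with nuisance blocks off and tiny penalty equals OLS", {
  set.seed(10)
  b <- rnorm(8)
  th <- 0.4 * b + rnorm(8, sd = 0.05)
  iv <- ivSet(b, th)
  f <- mrJti(iv, lambdaGrid = c(1e-6, 1e-7, 1e-8), nBoot = 0, seed = 3,
             relaxed = FALSE, useHeterogeneity = FALSE,
             useLdScore = FALSE)
  ols <- sum(b * th) / sum(b^2)
  expect_equal(alphaHat(f), ols, tolerance = 1e-4)
})

test_that("causal effect is equivariant to exposure rescaling", {
  set.seed(13)
  b <- rnorm(20)
  th <- 0.25 * b + rnorm(20, sd = 0.01)
  f1 <- mrJti(ivSet(b, th, seOutcome = rep(0.01, 20)), nBoot = 0,
              seed = 5)
  f2 <- mrJti(ivSet(2 * b, th, seOutcome = rep(0.01, 20)), nBoot = 0,
              seed = 5)
  expect_equal(alphaHat(f2), alphaHat(f1) / 2, tolerance = 1e-3)
})

test_that("bootstrap interval brackets the point estimate and errors early", {
  set.seed(15)
  b <- rnorm(15)
  th <- 0.3 * b + rnorm(15, sd = 0.02)
  f <- mrJti(ivSet(b, th, seOutcome = rep(0.02, 15)), nBoot = 200,
             seed = 6)
  expect_lte(f@ciLow, f@ciHigh)
  expect_lte(f@ciLow, alphaHat(f) + 1e-8)
  expect_gte(f@ciHigh, alphaHat(f) - 1e-8)
  expect_error(mrJti(ivSet(rnorm(2), rnorm(2))), "at least 3")
})

test_that("MR-JTI resists directional pleiotropy that misleads IVW", {
  set.seed(18)
  J <- 30
  diffs <- vapply(1:10, function(r) {
    b <- rnorm(J, sd = 0.18)
    invalid <- sample.int(J, 6)
    v <- rep(0, J); v[invalid] <- 2 * 0.3 * b[invalid]
    th <- 0.3 * b + v + rnorm(J, sd = 0.005)
    iv <- ivSet(b, th, seOutcome = rep(0.005, J))
    c(abs(ivw(iv)$alpha - 0.3),
      abs(alphaHat(mrJti(iv, nBoot = 0, seed = r)) - 0.3))
  }, numeric(2))
  expect_gt(mean(diffs[1, ]), mean(diffs[2, ]))
})
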