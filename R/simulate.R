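# ---- bivariate-normal machinery for the dosage copula -------------------
#
# Dosages are generated by thresholding a latent Gaussian at the
# Hardy-Weinberg genotype-probability quantiles. Thresholding attenuates
# pairwise correlation, so the latent correlation is pre-compensated by the
# first-order attenuation factor, and the exact dosage-scale correlation
# implied by the copula is available in closed form via 1-D quadrature of
# the bivariate normal density (Phi2(h,k,rho) = Phi(h)Phi(k) +
# int_0^rho phi2(h,k,r) dr).

gaussLegendre32 <- function() {
  # nodes/weights on [0, 1] from the symmetric 32-point rule on [-1, 1]
  if (!is.null(.glCache$gl)) return(.glCache$gl)
  # Newton iteration on Legendre polynomials
  n <- 32L
  x <- cos(pi * (seq_len(n) - 0.25) / (n + 0.5))
  for (it in 1:100) {
    p0 <- rep(1, n); p1 <- x
    for (k in 2:n) {
      p2 <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k
      p0 <- p1; p1 <- p2
    }
    dp <- n * (x * p1 - p0) / (x^2 - 1)
    x1 <- x - p1 / dp
    if (max(abs(x1 - x)) < 1e-15) { x <- x1; break }
    x <- x1
  }
  p0 <- rep(1, n); p1 <- x
  for (k in 2:n) {
    p2 <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k
    p0 <- p1; p1 <- p2
  }
  dp <- n * (x * p1 - p0) / (x^2 - 1)
  w <- 2 / ((1 - x^2) * dp^2)
  gl <- list(nodes = (x + 1) / 2, weights = w / 2)
  .glCache$gl <- gl
  gl
}
.glCache <- new.env(parent = emptyenv())

# vectorized P(Z1 <= h, Z2 <= k) for correlation rho
bvnCdf <- function(h, k, rho) {
  gl <- gaussLegendre32()
  out <- pnorm(h) * pnorm(k)
  for (i in seq_along(gl$nodes)) {
    r <- rho * gl$nodes[i]
    phi2 <- exp(-(h^2 - 2 * r * h * k + k^2) / (2 * (1 - r^2))) /
      (2 * pi * sqrt(1 - r^2))
    out <- out + gl$weights[i] * rho * phi2
  }
  out
}

# vectorized P(Z1 > h, Z2 > k)
bvnUpper <- function(h, k, rho) {
  1 - pnorm(h) - pnorm(k) + bvnCdf(h, k, rho)
}

hweThresholds <- function(maf) {
  list(q1 = qnorm((1 - maf)^2), q2 = qnorm(1 - maf^2))
}

# first-order attenuation factor of thresholded-dosage correlation
attenuationFactor <- function(maf) {
  th <- hweThresholds(maf)
  (dnorm(th$q1) + dnorm(th$q2)) / sqrt(2 * maf * (1 - maf))
}

# latent Gaussian correlation used by the generator for a dosage target
latentFromTarget <- function(targetLd, maf) {
  cf <- attenuationFactor(maf)
  R <- targetLd / tcrossprod(cf)
  R[R > 0.999] <- 0.999
  R[R < -0.999] <- -0.999
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {      # restore PSD after the compensation
    vals <- pmax(ev$values, 1e-8)
    R <- ev$vectors %*% (vals * t(ev$vectors))
    s <- sqrt(diag(R))
    R <- R / tcrossprod(s)
  }
  (R + t(R)) / 2
}

# exact dosage covariance of two thresholded variants at latent rho
dosageCovFromLatent <- function(rho, maf1, maf2) {
  t1 <- hweThresholds(maf1)
  t2 <- hweThresholds(maf2)
  e12 <- bvnUpper(t1$q1, t2$q1, rho) + bvnUpper(t1$q1, t2$q2, rho) +
    bvnUpper(t1$q2, t2$q1, rho) + bvnUpper(t1$q2, t2$q2, rho)
  e12 - 4 * maf1 * maf2
}

#' Exact dosage-scale LD implied by the genotype generator
#'
#' \code{\link{simulateGenotypes}} draws a latent Gaussian copula and
#' thresholds it to \{0, 1, 2\} dosages under Hardy-Weinberg proportions.
#' This function returns the exact population correlation matrix of those
#' dosages — the "true LD" of the generated population — computed by
#' quadrature of the bivariate normal, for use as the ground-truth matrix
#' in simulation studies.
#'
#' @param targetLd the dosage-scale target correlation handed to the
#'   generator.
#' @param maf the minor allele frequencies handed to the generator.
#' @return exact dosage correlation matrix (same dimension as
#'   \code{targetLd}).
#' @export
impliedDosageLD <- function(targetLd, maf) {
  p <- length(maf)
  stopifnot(nrow(targetLd) == p)
  R <- latentFromTarget(targetLd, maf)
  iu <- which(upper.tri(R), arr.ind = TRUE)
  cv <- dosageCovFromLatent(R[iu], maf[iu[, 1]], maf[iu[, 2]])
  s <- sqrt(2 * maf * (1 - maf))
  out <- diag(p)
  out[iu] <- cv / (s[iu[, 1]] * s[iu[, 2]])
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  dimnames(out) <- dimnames(targetLd)
  out
}

# fast path used by the studies: draw a raw dosage matrix from a
# precomputed latent Cholesky factor (or independent variants)
drawDosageMatrix <- function(n, maf, cholR = NULL) {
  p <- length(maf)
  Z <- matrix(rnorm(n * p), n, p)
  if (!is.null(cholR)) Z <- Z %*% cholR
  th <- hweThresholds(maf)
  D <- (Z > rep(th$q1, each = n)) + (Z > rep(th$q2, each = n))
  storage.mode(D) <- "double"
  colnames(D) <- paste0("v", seq_len(p))
  D
}

#' Block AR(1) correlation template
#'
#' Default LD template for the generators: contiguous blocks with AR(1)
#' decay, block-wise correlation drawn from \code{rhoRange}.
#'
#' @param p number of variants.
#' @param blockSize variants per block (default 25).
#' @param rhoRange range of the per-block AR(1) parameter
#'   (default \code{c(0.2, 0.9)}).
#' @param seed RNG seed.
#' @return p x p correlation matrix.
#' @export
arBlockCorrelation <- function(p, blockSize = 25L, rhoRange = c(0.2, 0.9),
                               seed = NULL) {
  withSeed(seed, {
    C <- diag(p)
    starts <- seq(1L, p, by = blockSize)
    for (s in starts) {
      e <- min(s + blockSize - 1L, p)
      idx <- s:e
      rho <- runif(1, rhoRange[1], rhoRange[2])
      C[idx, idx] <- rho^abs(outer(idx, idx, "-"))
    }
    C
  })
}

#' Simulate genotype dosages with target LD and allele frequencies
#'
#' Gaussian-copula generator: a latent multivariate normal (with pairwise
#' correlations pre-compensated for threshold attenuation) is thresholded
#' at Hardy-Weinberg genotype-probability quantiles to \{0, 1, 2\}
#' dosages. At large n the empirical dosage correlation tracks
#' \code{targetLd}; the exact population value is available from
#' \code{\link{impliedDosageLD}}.
#'
#' @param n number of samples (> 0).
#' @param maf allele-frequency vector in \eqn{(0, 0.5]}; if \code{NULL},
#'   drawn uniformly from \eqn{[0.05, 0.5]} (seeded).
#' @param targetLd dosage-scale target correlation (PSD); \code{NULL}
#'   means independent variants.
#' @param seed RNG seed.
#' @param chrom,segment chromosome name and optional \linkS4class{Segment}
#'   over which variant positions are evenly spaced (default a 50 kb
#'   window starting at 1).
#' @param idPrefix variant id prefix.
#' @return a \linkS4class{GenotypeMatrix}.
#' @examples
#' gt <- simulateGenotypes(100, maf = c(0.3, 0.1), seed = 7)
#' dim(dosages(gt))
#' @export
simulateGenotypes <- function(n, maf = NULL, targetLd = NULL, seed = NULL,
                              chrom = "chr1", segment = NULL,
                              idPrefix = "v") {
  if (n <= 0) stop("n must be positive")
  if (is.null(maf) && is.null(targetLd))
    stop("supply 'maf' and/or 'targetLd'")
  p <- if (!is.null(maf)) length(maf) else nrow(targetLd)
  withSeed(seed, {
    if (is.null(maf)) maf <- runif(p, 0.05, 0.5)
    checkFraction(maf * 2, "maf * 2")
    if (any(maf <= 0)) stop("maf must be positive")
    if (!is.null(targetLd)) {
      stopifnot(nrow(targetLd) == p)
      ev <- min(eigen(targetLd, symmetric = TRUE,
                      only.values = TRUE)$values)
      if (ev < -1e-8) stop("targetLd must be positive semi-definite")
      R <- latentFromTarget(targetLd, maf)
      Z <- matrix(rnorm(n * p), n, p) %*% chol(R)
    } else {
      Z <- matrix(rnorm(n * p), n, p)
    }
    th <- hweThresholds(maf)
    D <- (Z > rep(th$q1, each = n)) + (Z > rep(th$q2, each = n))
    storage.mode(D) <- "double"
  })
  if (is.null(segment))
    segment <- new("Segment", chrom = chrom, start = 0, end = 50000)
  pos <- floor(seq(segment@start + 1, segment@end, length.out = p))
  ids <- paste0(idPrefix, seq_len(p))
  colnames(D) <- ids
  rownames(D) <- paste0("s", seq_len(n))
  GenotypeMatrix(D, data.frame(id = ids, chrom = segment@chrom, pos = pos,
                               ref = "A", alt = "G",
                               stringsAsFactors = FALSE))
}

#' Local-heritability simulation study
#'
#' Reproduces the reference simulation design for the summary-statistics
#' local heritability estimator. Per replicate: genotypes for a ~50 kb
#' segment are drawn (block-AR(1) LD template, MAF uniform on
#' \eqn{[0.05, 0.5]}) for a GWAS cohort of \code{nGwas} samples; one causal
#' variant is picked uniformly; the trait is
#' \eqn{Y = \beta G + \varepsilon} with \eqn{G} the standardized causal
#' dosage, \eqn{\beta = \sqrt{h^2_{local}}} (so \eqn{var(Y) = 1}) and
#' \eqn{\varepsilon \sim N(0, 1 - h^2)}; standardized marginal effects are
#' computed per variant; and local heritability is estimated three ways —
#' with the generator's exact ("true") LD matrix, with the raw LD matrix of
#' an independent \code{nPanel}-subject reference panel, and with the
#' Ledoit-Wolf projection of that panel matrix. Genotypes are shared
#' across heritability levels within a replicate; phenotypes are redrawn
#' per level.
#'
#' @param h2Levels true local heritability levels
#'   (default \code{c(0.01, 0.02, 0.03)}).
#' @param nReps replicates (default 500; the validation runs use 100).
#' @param nGwas GWAS cohort size (default 50,000).
#' @param nPanel external reference panel size (default 500).
#' @param nVariants variants per segment (default 150).
#' @param seed RNG seed.
#' @return data.frame (rep, h2_true, ld_mode, h2_hat, variance).
#' @export
simulateLocalH2Study <- function(h2Levels = c(0.01, 0.02, 0.03),
                                 nReps = 500L, nGwas = 50000L,
                                 nPanel = 500L, nVariants = 150L,
                                 seed = NULL) {
  rows <- vector("list", nReps * length(h2Levels) * 3L)
  k <- 0L
  for (rep in seq_len(nReps)) {
    repSeed <- childSeed(seed, "localh2", rep)
    target <- arBlockCorrelation(nVariants,
                                 seed = childSeed(repSeed, "ld"))
    maf <- withSeed(childSeed(repSeed, "maf"),
                    runif(nVariants, 0.05, 0.5))
    trueLd <- impliedDosageLD(target, maf)
    cholR <- chol(latentFromTarget(target, maf))
    Dg <- withSeed(childSeed(repSeed, "gwas"),
                   drawDosageMatrix(nGwas, maf, cholR))
    Dp <- withSeed(childSeed(repSeed, "panel"),
                   drawDosageMatrix(nPanel, maf, cholR))
    Xs <- standardizeDosages(Dg)
    panelObs <- empiricalLD(Dp)
    panelProj <- ledoitWolfProject(Dp)
    causal <- withSeed(childSeed(repSeed, "causal"),
                       sample.int(nVariants, 1L))
    for (h2 in h2Levels) {
      y <- withSeed(childSeed(repSeed, paste0("y", h2 * 1000)), {
        sqrt(h2) * Xs[, causal] + rnorm(nGwas, sd = sqrt(1 - h2))
      })
      ys <- (y - mean(y)) / sd(y)
      betaStd <- drop(crossprod(Xs, ys)) / nGwas
      for (mode in c("true", "observed", "projected")) {
        ld <- switch(mode, true = trueLd, observed = panelObs,
                     projected = panelProj)
        est <- estimateLocalH2(betaStd, ld, n = nGwas, ldMode = mode)
        k <- k + 1L
        rows[[k]] <- data.frame(rep = rep, h2_true = h2, ld_mode = mode,
                                h2_hat = est@r2Local,
                                variance = est@variance)
      }
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Mendelian-randomization simulation study
#'
#' Reproduces the reference simulation comparing IVW with the penalized
#' estimator under horizontal pleiotropy. Per gene: \code{nIv} independent
#' eQTL instruments with effects \eqn{\beta_j \sim N(0, \sigma_\beta^2)}
#' (calibrated so the median top-eQTL expression variance explained is
#' about 0.1); expression \eqn{X = \beta G + \varepsilon_X} with
#' \eqn{\sigma_X^2 = 1 - \sum\beta_j^2}; trait
#' \eqn{Y = \alpha X + Z + \varepsilon_Y}, \eqn{\varepsilon_Y \sim N(0,1)},
#' where a fraction \code{invalidFrac} of the instruments carry a direct
#' (horizontal-pleiotropy) effect \code{pleiotropyRatio} times their
#' mediated effect \eqn{\alpha\beta_j}. Outcome-side marginal effects are
#' estimated from an \code{nGwas}-sample cohort; the generating eQTL
#' effects serve as the exposure-side input (the design treats them as
#' known, mirroring the use of reference eQTL effect sizes). Both
#' estimators are fit per gene.
#'
#' @param alphaGrid true causal effects (default \code{seq(0, 0.5, 0.1)}).
#' @param nGenes genes per grid point (default 100).
#' @param nIv instruments per gene (default 30, a typical
#'   post-clumping cis instrument count).
#' @param invalidFrac fraction of invalid instruments (default 0.2).
#' @param pleiotropyRatio pleiotropy / mediated-effect ratio (default 2).
#' @param nGwas outcome cohort size (default 50,000).
#' @param topEqtlH2 median expression variance explained by a gene's top
#'   eQTL (default 0.1), calibrating \eqn{\sigma_\beta}.
#' @param seed RNG seed.
#' @return data.frame (gene, alpha_true, alpha_ivw, alpha_mrjti).
#' @export
simulateMrStudy <- function(alphaGrid = seq(0, 0.5, 0.1), nGenes = 100L,
                            nIv = 30L, invalidFrac = 0.2,
                            pleiotropyRatio = 2, nGwas = 50000L,
                            topEqtlH2 = 0.1, seed = NULL) {
  checkFraction(invalidFrac, "invalidFrac")
  # median of the max of nIv iid chi-square(1) draws
  sigmaB2 <- topEqtlH2 / qchisq(0.5^(1 / nIv), df = 1)
  rows <- list()
  for (alpha in alphaGrid) {
    for (g in seq_len(nGenes)) {
      gSeed <- childSeed(seed, sprintf("mr-a%03d", round(alpha * 100)), g)
      res <- withSeed(gSeed, {
        beta <- rnorm(nIv, sd = sqrt(sigmaB2))
        if (sum(beta^2) >= 0.9) beta <- beta * sqrt(0.9 / sum(beta^2))
        maf <- runif(nIv, 0.05, 0.5)
        Gs <- standardizeDosages(drawDosageMatrix(nGwas, maf))
        X <- drop(Gs %*% beta) + rnorm(nGwas, sd = sqrt(1 - sum(beta^2)))
        nInvalid <- round(invalidFrac * nIv)
        invalid <- if (nInvalid > 0) sample.int(nIv, nInvalid)
                   else integer(0)
        Z <- if (length(invalid)) {
          drop(Gs[, invalid, drop = FALSE] %*%
                 (pleiotropyRatio * alpha * beta[invalid]))
        } else 0
        Y <- alpha * X + Z + rnorm(nGwas)
        thetaHat <- drop(crossprod(Gs, Y)) / nGwas
        seTheta <- sqrt(pmax(var(Y) - thetaHat^2, 1e-12) / nGwas)
        ivLd <- crossprod(Gs) / nGwas
        dimnames(ivLd) <- list(colnames(Gs), colnames(Gs))
        iv <- ivSet(betaExposure = beta, betaOutcome = thetaHat,
                    seOutcome = seTheta, ld = ivLd,
                    variant = colnames(Gs))
        fitIvw <- ivw(iv)
        fitJti <- mrJti(iv, nBoot = 0L, seed = childSeed(gSeed, "fit"),
                        relaxed = TRUE)
        c(fitIvw$alpha, alphaHat(fitJti))
      })
      rows[[length(rows) + 1L]] <-
        data.frame(gene = g, alpha_true = alpha, alpha_ivw = res[1],
                   alpha_mrjti = res[2])
    }
  }
  do.call(rbind, rows)
}

#' Simulate multi-tissue expression with shared eQTL architecture
#'
#' Fixture generator for cross-tissue model training: causal effects are
#' correlated across tissues at the given similarity, each tissue's
#' genetic component explains \code{h2Expr} of its expression variance,
#' and tissues have disjoint donor sets.
#'
#' @param nTissues number of tissues.
#' @param nPerTissue samples per tissue (recycled).
#' @param similarity cross-tissue correlation of causal effects in
#'   \eqn{[0, 1]}.
#' @param h2Expr expression heritability per tissue.
#' @param nCausal causal variants.
#' @param nVariants total variants.
#' @param maf optional MAF vector.
#' @param seed RNG seed.
#' @return list: \code{genotypes} (\linkS4class{GenotypeMatrix} over all
#'   donors), \code{expression} (named list tissue -> named vector),
#'   \code{truth} (causal ids, per-tissue effects and genetic components).
#' @export
simulateMultitissueExpression <- function(nTissues = 2L, nPerTissue = 100L,
                                          similarity = 0.9, h2Expr = 0.3,
                                          nCausal = 2L, nVariants = 20L,
                                          maf = NULL, seed = NULL) {
  checkFraction(similarity, "similarity")
  checkFraction(h2Expr, "h2Expr")
  nPerTissue <- rep_len(nPerTissue, nTissues)
  nTotal <- sum(nPerTissue)
  gt <- simulateGenotypes(nTotal, maf = maf,
                          targetLd = if (is.null(maf))
                            arBlockCorrelation(nVariants,
                              seed = childSeed(seed, "ld")) else NULL,
                          seed = childSeed(seed, "geno"))
  Xs <- standardizeDosages(dosages(gt))
  tissues <- paste0("tissue", seq_len(nTissues))
  withSeed(childSeed(seed, "effects"), {
    causal <- sort(sample.int(ncol(Xs), nCausal))
    base <- rnorm(nCausal)
    donorSplit <- split(rownames(Xs),
                        rep(seq_len(nTissues), times = nPerTissue))
    expression <- list()
    betas <- list()
    genetic <- list()
    for (t in seq_len(nTissues)) {
      bt <- sqrt(similarity) * base +
        sqrt(1 - similarity) * rnorm(nCausal)
      g <- drop(Xs[, causal, drop = FALSE] %*% bt)
      sg <- sd(g)
      if (sg > 0) {
        scaleF <- sqrt(h2Expr) / sg
        bt <- bt * scaleF
        g <- g * scaleF
      }
      donors <- donorSplit[[t]]
      e <- g[match(donors, rownames(Xs))] +
        rnorm(length(donors), sd = sqrt(1 - h2Expr))
      expression[[tissues[t]]] <- setNames(e, donors)
      betas[[tissues[t]]] <- setNames(bt, colnames(Xs)[causal])
      genetic[[tissues[t]]] <- setNames(g, rownames(Xs))
    }
  })
  list(genotypes = gt, expression = expression,
       truth = list(causal = colnames(Xs)[causal], effects = betas,
                    genetic = genetic))
}
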