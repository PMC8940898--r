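#' Build a harmonized, clumped instrument set
#'
#' Starting from eQTL (exposure) and GWAS (outcome) summary statistics:
#' palindromic (A/T, C/G) instruments are removed; effect alleles are
#' harmonized (swapped alleles flip the outcome effect); instruments are
#' then greedily clumped on the exposure p-value — sorted ascending, a
#' variant is kept iff its \eqn{r^2} with every already-kept variant is
#' below \code{clumpR2} and its exposure p-value is below \code{clumpP}
#' (ties in p break by ascending genomic position). Residual correlation
#' among surviving instruments is retained in the returned LD submatrix,
#' and each instrument's LD score (row sum over the surviving set) is
#' recorded.
#'
#' @param eqtl exposure-side \linkS4class{GwasSummary} (per-variant eQTL
#'   effect, se, n); a \code{p} column is used if present, otherwise the
#'   p-value is derived from z.
#' @param gwas outcome-side \linkS4class{GwasSummary}.
#' @param ld LD matrix covering the candidate instruments (variant-id
#'   dimnames).
#' @param clumpP exposure p-value threshold (default 0.05).
#' @param clumpR2 pairwise \eqn{r^2} threshold (default 0.1).
#' @return an \linkS4class{IVSet}.
#' @export
buildIvSet <- function(eqtl, gwas, ld, clumpP = 0.05, clumpR2 = 0.1) {
  et <- gwasTable(eqtl)
  gt <- gwasTable(gwas)
  idx <- match(et$snp, gt$snp)
  present <- !is.na(idx)
  et <- et[present, , drop = FALSE]
  gt <- gt[idx[present], , drop = FALSE]
  harm <- harmonizeAlleles(et$ea, et$oa, gt$ea, gt$oa, gt$beta)
  removed <- data.frame(variant = character(), reason = character(),
                        stringsAsFactors = FALSE)
  drop <- !harm$action %in% c("keep", "flip")
  if (any(drop))
    removed <- rbind(removed, data.frame(
      variant = et$snp[drop],
      reason = ifelse(harm$action[drop] == "palindromic", "palindromic",
                      "mismatch")))
  et <- et[!drop, , drop = FALSE]
  gt <- gt[!drop, , drop = FALSE]
  gt$beta <- harm$beta[!drop]

  pExp <- if ("p" %in% colnames(et)) et$p else 2 * pnorm(-abs(et$z))
  C <- ldMatrix(ld)
  ci <- match(et$snp, rownames(C))
  if (anyNA(ci)) stop("LD matrix does not cover all candidate instruments")

  aboveP <- pExp >= clumpP
  if (any(aboveP))
    removed <- rbind(removed, data.frame(variant = et$snp[aboveP],
                                         reason = "p_threshold"))
  cand <- which(!aboveP)
  ord <- cand[order(pExp[cand], et$pos[cand])]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(C[ci[i], ci[kept]]^2 < clumpR2)) {
      kept <- c(kept, i)
    } else {
      removed <- rbind(removed, data.frame(variant = et$snp[i],
                                           reason = "clumped"))
    }
  }
  if (!length(kept)) stop("empty instrument set after filters")
  kept <- kept[order(et$pos[kept])]
  Ck <- C[ci[kept], ci[kept], drop = FALSE]
  tab <- data.frame(variant = et$snp[kept],
                    betaExposure = et$beta[kept],
                    seExposure = et$se[kept],
                    pExposure = pExp[kept],
                    betaOutcome = gt$beta[kept],
                    seOutcome = gt$se[kept],
                    ldScore = rowSums(Ck),
                    stringsAsFactors = FALSE)
  new("IVSet", table = tab, ld = Ck, removed = removed)
}

#' Construct an IVSet directly from effect vectors
#'
#' Convenience constructor for already-harmonized instruments (e.g. from
#' the simulation studies), bypassing allele harmonization and clumping.
#'
#' @param betaExposure,betaOutcome instrument effects on exposure/outcome.
#' @param seExposure,seOutcome standard errors.
#' @param ld correlation matrix among the instruments (default identity).
#' @param variant instrument ids.
#' @return an \linkS4class{IVSet}.
#' @export
ivSet <- function(betaExposure, betaOutcome, seExposure = NULL,
                  seOutcome = NULL,
                  ld = diag(length(betaExposure)),
                  variant = paste0("iv", seq_along(betaExposure))) {
  J <- length(betaExposure)
  if (J < 1L) stop("at least 1 instrument is required")
  if (is.null(seExposure)) seExposure <- rep(NA_real_, J)
  if (is.null(seOutcome)) seOutcome <- rep(1, J)
  ld <- ldMatrix(ld)
  tab <- data.frame(variant = variant, betaExposure = betaExposure,
                    seExposure = seExposure, pExposure = NA_real_,
                    betaOutcome = betaOutcome, seOutcome = seOutcome,
                    ldScore = rowSums(ld), stringsAsFactors = FALSE)
  new("IVSet", table = tab, ld = ld,
      removed = data.frame(variant = character(), reason = character()))
}

#' Inverse-variance-weighted Mendelian randomization
#'
#' The conventional fixed-effect estimator
#' \deqn{\hat\alpha_{IVW} = \frac{\sum_j \hat\theta_j \hat\beta_j /
#'   se_j^2}{\sum_j \hat\beta_j^2 / se_j^2}}
#' with standard error \eqn{1 / \sqrt{\sum_j \hat\beta_j^2 / se_j^2}}
#' (\eqn{se_j} the outcome-side standard errors). Not robust to horizontal
#' pleiotropy; serves as the baseline against \code{\link{mrJti}}.
#'
#' @param iv an \linkS4class{IVSet}.
#' @return list with \code{alpha}, \code{se}, \code{p}, \code{nIv}.
#' @export
ivw <- function(iv) {
  tab <- ivTable(iv)
  if (!nrow(tab)) stop("at least 1 instrument is required")
  if (all(tab$betaExposure == 0)) stop("all exposure effects are zero")
  wt <- 1 / tab$seOutcome^2
  denom <- sum(tab$betaExposure^2 * wt)
  alpha <- sum(tab$betaOutcome * tab$betaExposure * wt) / denom
  se <- sqrt(1 / denom)
  list(alpha = alpha, se = se, p = 2 * pnorm(-abs(alpha / se)),
       nIv = nrow(tab))
}

# design matrix [betaExposure | I_J | ldScore]; optional blocks for the
# constrained variants used in the OLS-limit diagnostics
mrJtiDesign <- function(tab, useHeterogeneity = TRUE, useLdScore = TRUE) {
  J <- nrow(tab)
  x <- matrix(tab$betaExposure, J, 1)
  if (useHeterogeneity) x <- cbind(x, diag(J))
  if (useLdScore) x <- cbind(x, tab$ldScore)
  x
}

# lasso path on the MR design; returns coefficients (rows) x lambda (cols)
mrJtiPath <- function(tab, lambdaGrid, useHeterogeneity, useLdScore) {
  x <- mrJtiDesign(tab, useHeterogeneity, useLdScore)
  y <- tab$betaOutcome
  J <- nrow(x)
  if (all(y == 0))
    return(matrix(0, ncol(x), length(lambdaGrid)))
  if (ncol(x) == 1L) {
    # soft-threshold closed form of the single-coefficient lasso
    xy <- sum(x[, 1] * y) / J
    xx <- sum(x[, 1]^2) / J
    u <- sign(xy) * pmax(abs(xy) - lambdaGrid, 0) / xx
    return(matrix(u, 1L))
  }
  fit <- glmnet(x, y, lambda = lambdaGrid,
                standardize = FALSE, intercept = FALSE)
  cf <- as.matrix(coef(fit))[-1, , drop = FALSE]
  # glmnet may truncate the path; pad with the last fitted column
  if (ncol(cf) < length(lambdaGrid))
    cf <- cf[, c(seq_len(ncol(cf)),
                 rep(ncol(cf), length(lambdaGrid) - ncol(cf))),
             drop = FALSE]
  cf
}

# OLS refit on the nonzero penalized support. The causal-effect column is
# always retained (the lasso support decides which nuisance terms v_j, w
# stay), and the heterogeneity support is capped at floor(J/2) — the
# majority-valid-instruments assumption — keeping the largest |v_j|, so
# the refit never degenerates when the penalty path saturates.
mrJtiRelaxed <- function(tab, cfPen, useHeterogeneity, useLdScore) {
  x <- mrJtiDesign(tab, useHeterogeneity, useLdScore)
  J <- nrow(tab)
  support <- cfPen != 0
  support[1L] <- TRUE
  if (useHeterogeneity) {
    vIdx <- seq_len(J) + 1L
    inV <- vIdx[support[vIdx]]
    maxV <- max(0L, floor(J / 2))
    if (length(inV) > maxV) {
      keepV <- inV[order(abs(cfPen[inV]), decreasing = TRUE)][
        seq_len(maxV)]
      support[setdiff(inV, keepV)] <- FALSE
    }
  }
  cf <- rep(0, ncol(x))
  fit <- lm.fit(x[, support, drop = FALSE], tab$betaOutcome)
  b <- fit$coefficients
  b[is.na(b)] <- 0
  cf[support] <- b
  cf
}

#' Penalized Mendelian randomization (MR-JTI)
#'
#' Jointly estimates the gene causal effect \eqn{u}, per-instrument
#' heterogeneity \eqn{v_j} (horizontal pleiotropy and unobserved
#' confounding) and an LD-score coefficient \eqn{w} by solving
#' \deqn{\min_{u, v, w} \sum_{j=1}^J
#'   (\hat\theta_j - u\hat\beta_j - v_j - w l_j)^2
#'   + \lambda(\|v\|_1 + |u| + |w|)}
#' over a penalty grid. The penalty \eqn{\lambda} is selected, by
#' default, by a BIC-type criterion evaluated on the relaxed fit:
#' \eqn{RSS/\sigma^2 + \log(J)\,df}, with the noise scale
#' \eqn{\sigma^2} taken from the outcome-side standard errors. (The
#' per-instrument heterogeneity terms apply to single observations, so
#' instrument-level cross-validation cannot validate them — held-out
#' instruments are predicted with their heterogeneity at zero — which
#' makes CV drift toward vanishing penalties and over-flagging;
#' CV selection remains available via \code{selectionRule}.)
#'
#' Because \eqn{|u|} is itself penalized the raw point estimate is
#' shrunken toward zero; by default the reported estimate is the relaxed
#' refit — unpenalized least squares on the selected support, with the
#' causal-effect column always retained and the heterogeneity support
#' capped at half the instruments (majority-valid assumption) — while the
#' penalized value is kept in \code{alphaPenalized}. Inference is by
#' percentile bootstrap over instruments (resampled with replacement,
#' reselected and refit per draw).
#'
#' @param iv an \linkS4class{IVSet} with at least 3 instruments.
#' @param lambdaGrid decreasing penalty grid; \code{NULL} builds a
#'   log-spaced 50-point grid from the data.
#' @param nBoot bootstrap draws (default 1000).
#' @param seed RNG seed for fold assignment and the bootstrap.
#' @param nFolds CV folds over instruments (default 5; only used by the
#'   CV selection rules).
#' @param nCvRepeats random fold splits averaged for the CV curve
#'   (default 5; only used by the CV selection rules).
#' @param selectionRule \code{"bic"} (default), \code{"cv-min"}
#'   (CV-error minimum) or \code{"cv-1se"} (largest lambda within one
#'   standard error of the CV minimum).
#' @param relaxed report the relaxed refit as the point estimate
#'   (default TRUE).
#' @param level confidence level for the percentile interval.
#' @param useHeterogeneity,useLdScore include the \eqn{v} / \eqn{w}
#'   blocks (both TRUE for the full model; turning them off gives the
#'   penalized regression of \eqn{\hat\theta} on \eqn{\hat\beta}
#'   alone, whose \eqn{\lambda \to 0} limit is ordinary least squares).
#' @return an \linkS4class{MRFit}.
#' @examples
#' b <- rnorm(30); iv <- ivSet(b, 0.3 * b)
#' alphaHat(mrJti(iv, nBoot = 50, seed = 1))
#' @export
mrJti <- function(iv, lambdaGrid = NULL, nBoot = 1000L, seed = NULL,
                  nFolds = 5L, nCvRepeats = 5L,
                  selectionRule = c("bic", "cv-min", "cv-1se"),
                  relaxed = TRUE, level = 0.95,
                  useHeterogeneity = TRUE, useLdScore = TRUE) {
  selectionRule <- match.arg(selectionRule)
  tab <- ivTable(iv)
  J <- nrow(tab)
  if (J < 3L) stop("at least 3 instruments are required")
  if (all(tab$betaExposure == 0)) stop("all exposure effects are zero")
  if (is.null(lambdaGrid)) {
    lmax <- max(abs(crossprod(
      mrJtiDesign(tab, useHeterogeneity, useLdScore),
      tab$betaOutcome))) / J + 1e-12
    lambdaGrid <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 50))
  }

  selectIndex <- function(t2) {
    path <- mrJtiPath(t2, lambdaGrid, useHeterogeneity, useLdScore)
    if (selectionRule == "bic") {
      s2 <- stats::median(t2$seOutcome^2)
      if (!is.finite(s2) || s2 <= 0) {
        r0 <- t2$betaOutcome -
          mrJtiDesign(t2, FALSE, useLdScore) %*%
            lm.fit(mrJtiDesign(t2, FALSE, useLdScore),
                   t2$betaOutcome)$coefficients
        s2 <- stats::mad(r0)^2 + 1e-12
      }
      x <- mrJtiDesign(t2, useHeterogeneity, useLdScore)
      Jt <- nrow(t2)
      P <- ncol(x)
      # consecutive path points often share a support; refit each once
      sig <- apply(path != 0, 2L, paste, collapse = "")
      firstOf <- match(sig, sig)
      bicBy <- setNames(rep(NA_real_, length(unique(firstOf))),
                        unique(firstOf))
      for (k in unique(firstOf)) {
        cf <- mrJtiRelaxed(t2, path[, k], useHeterogeneity, useLdScore)
        rss <- sum((t2$betaOutcome - x %*% cf)^2)
        df <- sum(cf != 0)
        # extended BIC (gamma = 1): the heterogeneity support is chosen
        # among all instruments, so the selection space must be priced in
        bicBy[as.character(k)] <- rss / s2 + df * log(Jt) +
          2 * lchoose(P, df)
      }
      which.min(bicBy[as.character(firstOf)])
    } else {
      nf <- min(nFolds, nrow(t2))
      cvErr <- matrix(0, nCvRepeats * nf, length(lambdaGrid))
      row <- 0L
      for (r in seq_len(nCvRepeats)) {
        folds <- withSeed(childSeed(seed, "mrjti-folds", r),
                          sample(rep_len(seq_len(nf), nrow(t2))))
        for (k in seq_len(nf)) {
          tr <- t2[folds != k, , drop = FALSE]
          te <- t2[folds == k, , drop = FALSE]
          cf <- mrJtiPath(tr, lambdaGrid, useHeterogeneity, useLdScore)
          u <- cf[1L, ]
          w <- if (useLdScore) cf[nrow(cf), ] else rep(0, ncol(cf))
          pred <- outer(te$betaExposure, u) + outer(te$ldScore, w)
          row <- row + 1L
          cvErr[row, ] <- colMeans((te$betaOutcome - pred)^2)
        }
      }
      mErr <- colMeans(cvErr)
      if (selectionRule == "cv-1se") {
        seErr <- apply(cvErr, 2L, sd) / sqrt(nrow(cvErr))
        min(which(mErr <= mErr[which.min(mErr)] +
                    seErr[which.min(mErr)]))
      } else which.min(mErr)
    }
  }

  li <- selectIndex(tab)
  lambda <- lambdaGrid[li]
  fitAt <- function(t2) {
    k <- selectIndex(t2)
    cf <- mrJtiPath(t2, lambdaGrid, useHeterogeneity, useLdScore)[, k]
    if (relaxed) mrJtiRelaxed(t2, cf, useHeterogeneity, useLdScore)
    else cf
  }
  cfPen <- mrJtiPath(tab, lambdaGrid, useHeterogeneity, useLdScore)[, li]
  est <- if (relaxed)
    mrJtiRelaxed(tab, cfPen, useHeterogeneity, useLdScore)
  else cfPen
  vHat <- if (useHeterogeneity) est[seq_len(J) + 1L] else rep(0, J)
  wHat <- if (useLdScore) est[length(est)] else 0

  boot <- withSeed(childSeed(seed, "mrjti-boot"), {
    vapply(seq_len(nBoot), function(b) {
      idx <- sample.int(J, J, replace = TRUE)
      t2 <- tab[idx, , drop = FALSE]
      if (all(t2$betaExposure == 0)) return(NA_real_)
      tryCatch(fitAt(t2)[1L], error = function(e) NA_real_)
    }, numeric(1))
  })
  qs <- if (nBoot > 0 && any(is.finite(boot))) {
    quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2),
             na.rm = TRUE, names = FALSE)
  } else c(NA_real_, NA_real_)
  new("MRFit", alphaHat = est[1L], alphaPenalized = cfPen[1L],
      vHat = setNames(vHat, tab$variant), wHat = wHat, lambda = lambda,
      ciLow = qs[1], ciHigh = qs[2], nBoot = as.integer(nBoot),
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed),
      relaxed = relaxed, bootEstimates = boot)
}
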