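#' Genetically determined expression (GDE) score of one subject
#'
#' Dot product of the model's variant weights with the subject's dosages
#' over the predictors available in the profile. Missing predictors
#' contribute 0 (no imputation): for an archaic genotype profile the
#' missingness is structural, so a score is only reported when at least
#' \code{minPredictors} of the model's predictor variants are genotyped
#' (default 2 for archaic profiles).
#'
#' @param model an \linkS4class{ExpressionModel}.
#' @param profile named dosage vector (names are variant ids); predictors
#'   absent from the profile, or \code{NA}, count as missing.
#' @param minPredictors minimum genotyped predictors required to report a
#'   score (default 1; use 2 for archaic profiles).
#' @param subject,population labels stored on the result.
#' @return data.frame row: subject, gene, tissue, score,
#'   n_predictors_used, population, suppressed, reason. A suppressed score
#'   is \code{NA}.
#' @export
gdeScore <- function(model, profile, minPredictors = 1L,
                     subject = "subject", population = NA_character_) {
  w <- model@weights
  d <- profile[names(w)]
  used <- !is.na(d)
  nUsed <- sum(used)
  if (nUsed < minPredictors) {
    return(data.frame(subject = subject, gene = model@gene,
                      tissue = model@tissue, score = NA_real_,
                      n_predictors_used = nUsed, population = population,
                      suppressed = TRUE,
                      reason = sprintf(
                        "only %d of %d predictors genotyped (min %d)",
                        nUsed, length(w), minPredictors),
                      stringsAsFactors = FALSE))
  }
  data.frame(subject = subject, gene = model@gene, tissue = model@tissue,
             score = sum(w[used] * d[used]), n_predictors_used = nUsed,
             population = population, suppressed = FALSE, reason = "",
             stringsAsFactors = FALSE)
}

#' GDE-score distributions per population, with archaic placement
#'
#' Scores every subject of a genotype panel with each model, summarizes the
#' score distribution per population (n, mean, sd, quartiles), and — when
#' an archaic genotype profile is supplied — locates the archaic score as
#' an empirical quantile within each population's distribution. The
#' archaic score is subject to the at-least-2-genotyped-predictors rule and
#' propagates as absent when suppressed.
#'
#' @param models list of \linkS4class{ExpressionModel} (scores are summed
#'   over models per subject, giving a per-subject aggregate when several
#'   genes/tissues are passed; pass a single model for a per-gene view).
#' @param panel a \linkS4class{GenotypeMatrix}.
#' @param populations named character vector: sample id -> population
#'   label (e.g. AFR, AMR, EAS, EUR, SAS).
#' @param archaicProfile optional named dosage vector for the archaic
#'   genotype (missing predictors = absent).
#' @param minArchaicPredictors the archaic reporting rule (default 2).
#' @return list with \code{scores} (per subject), \code{summary} (per
#'   population) and \code{archaic} (score + per-population empirical
#'   quantile, or \code{NULL} when suppressed/absent).
#' @export
populationGdeDistributions <- function(models, panel, populations,
                                       archaicProfile = NULL,
                                       minArchaicPredictors = 2L) {
  if (is(models, "ExpressionModel")) models <- list(models)
  X <- dosages(panel)
  miss <- setdiff(rownames(X), names(populations))
  if (length(miss))
    stop("population labels missing for: ",
         paste(head(miss, 3), collapse = ", "))
  if (length(unique(populations[rownames(X)])) < 2L &&
      is.null(archaicProfile))
    stop("need >= 2 populations, or 1 population plus an archaic profile")
  total <- rep(0, nrow(X))
  for (m in models) {
    w <- m@weights
    hit <- intersect(names(w), colnames(X))
    if (length(hit))
      total <- total + drop(X[, hit, drop = FALSE] %*% w[hit])
  }
  scores <- data.frame(subject = rownames(X), score = total,
                       population = unname(populations[rownames(X)]),
                       stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(scores$score, scores$population),
    function(s) data.frame(n = length(s), mean = mean(s), sd = sd(s),
                           q25 = quantile(s, 0.25, names = FALSE),
                           median = median(s),
                           q75 = quantile(s, 0.75, names = FALSE))))
  summ <- cbind(population = rownames(summ), summ)
  rownames(summ) <- NULL

  archaic <- NULL
  if (!is.null(archaicProfile)) {
    parts <- lapply(models, gdeScore, profile = archaicProfile,
                    minPredictors = minArchaicPredictors,
                    subject = "archaic")
    if (all(!vapply(parts, `[[`, logical(1), "suppressed"))) {
      aScore <- sum(vapply(parts, `[[`, numeric(1), "score"))
      qtl <- vapply(split(scores$score, scores$population),
                    function(s) ecdf(s)(aScore), numeric(1))
      archaic <- list(score = aScore, quantile = qtl)
    }
  }
  list(scores = scores, summary = summ, archaic = archaic)
}
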