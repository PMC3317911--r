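# -2 ln L of a Gaussian fit with per-genotype-class means (MLE variance,
# 1/n normalisation). Residual variance floored at double.xmin so that
# noiseless data yield a finite, overwhelmingly dominant score.
negTwoLogLikClass <- function(y, g) {
  n <- length(y)
  mu <- ifelse(g == 1, mean(y[g == 1]), mean(y[g == 0]))
  s2 <- max(mean((y - mu)^2), .Machine$double.xmin)
  n * log(2 * pi * s2) + n
}

# -2 ln L of y ~ alpha + rho * x (plain OLS, MLE variance)
negTwoLogLikOLS <- function(y, x) {
  n <- length(y)
  xc <- x - mean(x)
  rho <- if (sum(xc^2) > 0) sum(xc * (y - mean(y))) / sum(xc^2) else 0
  res <- y - mean(y) - rho * xc
  s2 <- max(mean(res^2), .Machine$double.xmin)
  n * log(2 * pi * s2) + n
}

# -2 ln L of y ~ mu_g(y) + rho * (x - mu_g(x)) : class means for both
# traits plus a pooled slope on the class-centred anchor trait. The
# class-mean/pooled-OLS estimator satisfies all first-order conditions of
# the joint likelihood, so it is the exact MLE.
negTwoLogLikClassResid <- function(y, x, g) {
  n <- length(y)
  mux <- ifelse(g == 1, mean(x[g == 1]), mean(x[g == 0]))
  muy <- ifelse(g == 1, mean(y[g == 1]), mean(y[g == 0]))
  xc <- x - mux
  rho <- if (sum(xc^2) > 0) sum(xc * (y - muy)) / sum(xc^2) else 0
  res <- y - muy - rho * xc
  s2 <- max(mean(res^2), .Machine$double.xmin)
  n * log(2 * pi * s2) + n
}

#' Penalized scores of the three anchored causal models
#'
#' For two traits T1, T2 linked to the same biallelic locus L, three
#' models are compared: causal M1 (L -> T1 -> T2), reactive M2
#' (L -> T2 -> T1) and independent M3 (L -> T1, L -> T2 with a residual
#' correlation term absorbing other shared influences). Each likelihood
#' is Gaussian: the anchored trait is normal about its genotype-class
#' means; the downstream trait in M1/M2 is a linear regression on the
#' upstream trait; in M3 the second trait is normal about its own class
#' means plus a pooled slope on the class-centred first trait. The
#' genotype distribution P(L) is identical across the three models (the
#' anchor is observed) and cancels from score differences, so it is
#' dropped. Scores are BIC-penalized:
#' S_i = -2 ln Lhat_i + p_i ln n, with p1 = p2 = 6 and p3 = 7.
#' The model with the smallest S wins.
#'
#' @param t1,t2 numeric trait vectors.
#' @param g 0/1 genotype vector at the shared locus.
#' @return named numeric: \code{causal}, \code{reactive},
#'   \code{independent}.
#' @examples
#' sc <- makeScenario("chain", seed = 1)
#' v <- traitValues(sc$traits)
#' g <- genoValues(sc$geno)[, "m_chr01_0120"]
#' modelScores(v[, "T1"], v[, "T2"], g)
#' @export
modelScores <- function(t1, t2, g) {
  if (length(t1) != length(t2) || length(t1) != length(g))
    stopf("t1, t2 and g must have equal length")
  ok <- complete.cases(t1, t2, g)
  t1 <- t1[ok]; t2 <- t2[ok]; g <- g[ok]
  n <- length(t1)
  if (n < 10L) stopf("need at least 10 complete observations")
  if (length(unique(g)) < 2L)
    stopf("causality test inapplicable: locus is monomorphic")
  if (var(t1) == 0 || var(t2) == 0)
    stopf("degenerate data: a trait has zero variance")
  ln <- log(n)
  s1 <- negTwoLogLikClass(t1, g) + negTwoLogLikOLS(t2, t1) + 6 * ln
  s2 <- negTwoLogLikClass(t2, g) + negTwoLogLikOLS(t1, t2) + 6 * ln
  s3 <- negTwoLogLikClass(t1, g) + negTwoLogLikClassResid(t2, t1, g) +
    7 * ln
  c(causal = s1, reactive = s2, independent = s3)
}

#' Genotype-anchored causality call for one trait pair
#'
#' Selects the model minimising the penalized statistic of
#' \code{\link{modelScores}}. An exact tie between the two best scores
#' (|difference| < 1e-9) is resolved conservatively to "independent" with
#' \code{tieFlag} set.
#'
#' @param t1,t2 numeric trait vectors.
#' @param g 0/1 genotype vector at the shared locus.
#' @param trait1,trait2,locus optional labels carried into the result.
#' @return a \linkS4class{CausalCall}.
#' @export
causalCall <- function(t1, t2, g, trait1 = "T1", trait2 = "T2",
                       locus = "L") {
  s <- modelScores(t1, t2, g)
  o <- order(s)
  tie <- abs(s[o[1L]] - s[o[2L]]) < 1e-9
  model <- if (tie) "independent" else names(s)[o[1L]]
  new("CausalCall", trait1 = trait1, trait2 = trait2, locus = locus,
      model = model, scores = s, tieFlag = tie)
}

#' Bootstrap reliabilities of the three causal models
#'
#' Resamples segregants with replacement and records the fraction of
#' resamples in which each model wins; the three reliabilities sum to 1.
#' Resamples in which the locus comes out monomorphic are redrawn (up to
#' 100 attempts each, then skipped, with the fractions renormalised over
#' the resamples actually scored).
#'
#' @param t1,t2 numeric trait vectors.
#' @param g 0/1 genotype vector.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed integer seed.
#' @return named numeric (\code{causal}, \code{reactive},
#'   \code{independent}) summing to 1.
#' @export
bootstrapReliability <- function(t1, t2, g, n_boot = 200, seed = 1) {
  if (n_boot < 100) stopf("n_boot must be >= 100")
  n <- length(g)
  withSeed(seed, {
    wins <- c(causal = 0, reactive = 0, independent = 0)
    scored <- 0L
    for (b in seq_len(n_boot)) {
      idx <- NULL
      for (try in seq_len(100L)) {
        cand <- sample.int(n, n, replace = TRUE)
        if (length(unique(g[cand])) == 2L) { idx <- cand; break }
      }
      if (is.null(idx)) next
      cl <- causalCall(t1[idx], t2[idx], g[idx])
      wins[[callModel(cl)]] <- wins[[callModel(cl)]] + 1
      scored <- scored + 1L
    }
    if (scored == 0L) stopf("no bootstrap resample kept both alleles")
    wins / scored
  })
}

#' Batch causality tests over a pair list
#'
#' Runs \code{\link{causalCall}} (and optionally
#' \code{\link{bootstrapReliability}}) for each (trait1, trait2, marker)
#' row, as used when building genetic structure priors.
#'
#' @param traits a \linkS4class{TraitMatrix}.
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param pairs data.frame with columns \code{trait1}, \code{trait2},
#'   \code{marker}.
#' @param n_boot bootstrap resamples per pair; 0 skips reliabilities.
#' @param seed integer seed.
#' @return data.frame with one row per pair: labels, selected model, the
#'   three scores, the tie flag and (when bootstrapped) the three
#'   reliabilities.
#' @export
causalBatch <- function(traits, geno, pairs, n_boot = 200, seed = 1) {
  al <- alignSegregants(traits, geno)
  bad <- setdiff(c(pairs$trait1, pairs$trait2), colnames(al$Y))
  if (length(bad)) stopf("unknown trait(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(pairs$marker, colnames(al$G))
  if (length(bad)) stopf("unknown marker(s): %s", paste(bad, collapse = ", "))
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    t1 <- al$Y[, pairs$trait1[i]]; t2 <- al$Y[, pairs$trait2[i]]
    g <- al$G[, pairs$marker[i]]
    cl <- causalCall(t1, t2, g, pairs$trait1[i], pairs$trait2[i],
                     pairs$marker[i])
    row <- data.frame(trait1 = pairs$trait1[i], trait2 = pairs$trait2[i],
                      marker = pairs$marker[i], model = callModel(cl),
                      s_causal = cl@scores[["causal"]],
                      s_reactive = cl@scores[["reactive"]],
                      s_independent = cl@scores[["independent"]],
                      tie = cl@tieFlag, stringsAsFactors = FALSE)
    if (n_boot > 0) {
      r <- bootstrapReliability(t1, t2, g, n_boot, childSeed(seed, i))
      row$r_causal <- r[["causal"]]
      row$r_reactive <- r[["reactive"]]
      row$r_independent <- r[["independent"]]
    }
    out[[i]] <- row
  }
  do.call(rbind, out)
}
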