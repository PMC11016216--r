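#' Wald ratio estimate from a single instrument
#'
#' \code{beta = by / bx}, \code{se = byse / |bx|} (first-order, exposure
#' uncertainty ignored), two-sided normal p-value.
#'
#' @param bx,bxse exposure effect and standard error.
#' @param by,byse outcome effect and standard error.
#' @return an \code{\linkS4class{MRResult}} with method \code{"wald"}.
#' @examples
#' waldRatio(bx = 0.2, bxse = 0.02, by = 0.06, byse = 0.05)
#' @export
waldRatio <- function(bx, bxse, by, byse) {
  if (bx == 0) stop("undefined-ratio: bx = 0")
  .mrResult("wald", by / bx, byse / abs(bx), 1L)
}

.asHarmonized <- function(data) {
  if (is(data, "HarmonizedData")) return(data)
  stop("data must be a HarmonizedData object")
}

#' Inverse-variance weighted estimate
#'
#' Zero-intercept weighted regression of outcome on exposure effects with
#' weights \code{1/byse^2}:
#' \code{beta = sum(bx by / byse^2) / sum(bx^2 / byse^2)}. In
#' \code{"fixed"} mode \code{se = 1 / sqrt(sum(bx^2 / byse^2))}; in
#' \code{"multiplicative_random"} mode (the package default throughout the
#' screen) the fixed-effect se is scaled by the residual standard deviation
#' of the weighted fit, floored at 1.
#'
#' @param data \code{\linkS4class{HarmonizedData}} with >= 2 variants.
#' @param mode \code{"multiplicative_random"} (default) or \code{"fixed"}.
#' @return an \code{\linkS4class{MRResult}} with method \code{"ivw"}.
#' @export
ivw <- function(data, mode = c("multiplicative_random", "fixed")) {
  data <- .asHarmonized(data)
  mode <- match.arg(mode)
  k <- nsnp(data)
  if (k < 2) stop("insufficient-instruments: IVW requires >= 2 (use waldRatio)")
  w <- 1 / data@byse^2
  denom <- sum(data@bx^2 * w)
  beta <- sum(data@bx * data@by * w) / denom
  se <- 1 / sqrt(denom)
  scale <- 1
  if (mode == "multiplicative_random") {
    rss <- sum(w * (data@by - beta * data@bx)^2)
    scale <- max(1, sqrt(rss / (k - 1)))
  }
  .mrResult("ivw", beta, se * scale, k,
            extra = list(mode = mode, residScale = scale))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure effects with intercept and
#' weights \code{1/byse^2}, after orienting every pair so \code{bx >= 0}
#' (negating both effects where needed). Slope and intercept standard errors
#' are inflated by the residual standard deviation floored at 1. The
#' intercept and its p-value are the directional-pleiotropy test.
#'
#' @param data \code{\linkS4class{HarmonizedData}} with >= 3 variants.
#' @return an \code{\linkS4class{MRResult}} with method \code{"egger"} and
#'   \code{extra$intercept}, \code{extra$interceptSE},
#'   \code{extra$interceptP}.
#' @export
mrEgger <- function(data) {
  data <- .asHarmonized(data)
  k <- nsnp(data)
  if (k < 3) stop("insufficient-instruments: MR-Egger requires >= 3")
  s <- ifelse(data@bx < 0, -1, 1)
  bx <- s * data@bx
  by <- s * data@by
  w <- 1 / data@byse^2
  fit <- stats::lm.wfit(cbind(intercept = 1, bx = bx), by, w)
  rss <- sum(w * fit$residuals^2)
  sigma <- sqrt(rss / (k - 2))
  XtWX <- crossprod(cbind(1, bx) * sqrt(w))
  covUnit <- solve(XtWX)                    # fixed-effect (sigma = 1) cov
  infl <- max(1, sigma)
  seInt <- sqrt(covUnit[1, 1]) * infl
  seSlope <- sqrt(covUnit[2, 2]) * infl
  .mrResult("egger", unname(fit$coefficients["bx"]), seSlope, k,
            extra = list(intercept = unname(fit$coefficients["intercept"]),
                         interceptSE = seInt,
                         interceptP = .pTwoSidedNormal(
                           fit$coefficients["intercept"], seInt),
                         residScale = infl))
}

## Per-variant Wald ratios and the spec's inverse-variance weights
## w_j = (bx_j / byse_j)^2 (exposure uncertainty ignored).
.ratioWeights <- function(bx, byse) (bx / byse)^2

.weightedMedianPoint <- function(ratios, w) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  n <- length(r)
  if (s[n] <= 0.5) return(r[n])
  j <- max(which(s < 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

## Parametric bootstrap over per-variant effect uncertainty, shared by the
## weighted median and mode: redraw (bx, by), recompute the point estimate.
.bootstrapSE <- function(data, pointFun, nBoot, seed) {
  set.seed(.subSeed(seed, "bootstrap"))
  k <- nsnp(data)
  bxM <- matrix(stats::rnorm(nBoot * k, data@bx, data@bxse), nBoot,
                byrow = TRUE)
  byM <- matrix(stats::rnorm(nBoot * k, data@by, data@byse), nBoot,
                byrow = TRUE)
  est <- vapply(seq_len(nBoot), function(b) {
    bx <- bxM[b, ]
    bx[bx == 0] <- .Machine$double.eps
    pointFun(byM[b, ] / bx, .ratioWeights(bx, data@byse))
  }, numeric(1))
  stats::sd(est)
}

#' Weighted median estimate
#'
#' Per-variant Wald ratios with inverse-variance weights
#' \code{(bx/byse)^2}; the estimate interpolates the weighted empirical
#' distribution of the ratios at probability 0.5 and is consistent as long
#' as more than half of the weight comes from valid instruments. The
#' standard error is a seeded parametric bootstrap (per-variant effects
#' redrawn from their normal distributions).
#'
#' @param data \code{\linkS4class{HarmonizedData}} with >= 3 variants.
#' @param nBoot bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @return an \code{\linkS4class{MRResult}} with method
#'   \code{"weighted_median"}.
#' @export
weightedMedian <- function(data, nBoot = 1000, seed = 1) {
  data <- .asHarmonized(data)
  k <- nsnp(data)
  if (k < 3) stop("insufficient-instruments: weighted median requires >= 3")
  ratios <- data@by / data@bx
  w <- .ratioWeights(data@bx, data@byse)
  beta <- .weightedMedianPoint(ratios, w)
  se <- .bootstrapSE(data, .weightedMedianPoint, nBoot, seed)
  if (!is.finite(se) || se <= 0) se <- .Machine$double.eps
  .mrResult("weighted_median", beta, se, k,
            extra = list(nBoot = nBoot, seed = seed))
}

.weightedModePoint <- function(ratios, w, bandwidthFactor = 1) {
  w <- w / sum(w)
  ## robust spread; the MAD degenerates when a majority of ratios tie
  s <- stats::mad(ratios)
  if (s == 0) s <- stats::sd(ratios)
  if (!is.finite(s) || s <= 1e-10 * max(1, abs(stats::median(ratios))))
    return(ratios[which.max(w)])
  h <- bandwidthFactor * 0.9 * s * length(ratios)^(-1/5)
  dens <- function(x)
    vapply(x, function(xi) sum(w * stats::dnorm((xi - ratios) / h)),
           numeric(1))
  lo <- min(ratios) - h
  hi <- max(ratios) + h
  grid <- seq(lo, hi, length.out = 512)
  fx <- dens(grid)
  g0 <- grid[which.max(fx)]
  step <- grid[2] - grid[1]
  stats::optimize(dens, lower = max(lo, g0 - step),
                  upper = min(hi, g0 + step), maximum = TRUE)$maximum
}

#' Weighted mode estimate
#'
#' Per-variant Wald ratios with inverse-variance weights; the estimate is
#' the argmax of a weighted normal-kernel density over the ratios, with a
#' robust (median-absolute-deviation based) default bandwidth scaled by
#' \code{bandwidthFactor}. Consistent when the largest weight cluster comes
#' from valid instruments. Bootstrap se as in
#' \code{\link{weightedMedian}}.
#'
#' @param data \code{\linkS4class{HarmonizedData}} with >= 3 variants.
#' @param bandwidthFactor multiplier on the default bandwidth.
#' @param nBoot bootstrap replicates.
#' @param seed integer seed.
#' @return an \code{\linkS4class{MRResult}} with method
#'   \code{"weighted_mode"}.
#' @export
weightedMode <- function(data, bandwidthFactor = 1, nBoot = 1000, seed = 1) {
  data <- .asHarmonized(data)
  k <- nsnp(data)
  if (k < 3) stop("insufficient-instruments: weighted mode requires >= 3")
  ratios <- data@by / data@bx
  w <- .ratioWeights(data@bx, data@byse)
  beta <- .weightedModePoint(ratios, w, bandwidthFactor)
  se <- .bootstrapSE(data,
                     function(r, w) .weightedModePoint(r, w, bandwidthFactor),
                     nBoot, seed)
  if (!is.finite(se) || se <= 0) se <- .Machine$double.eps
  .mrResult("weighted_mode", beta, se, k,
            extra = list(bandwidthFactor = bandwidthFactor,
                         nBoot = nBoot, seed = seed))
}

#' Cochran's Q heterogeneity test across instruments
#'
#' With per-variant ratios \code{r_j = by_j / bx_j}, weights
#' \code{w_j = (bx_j / byse_j)^2} and the fixed-effect IVW estimate
#' \code{b}: \code{Q = sum w_j (r_j - b)^2}, compared to a chi-square with
#' \code{nsnp - 1} degrees of freedom (upper tail).
#'
#' @param data \code{\linkS4class{HarmonizedData}} with >= 2 variants.
#' @return a \code{\linkS4class{QTest}}.
#' @export
cochranQ <- function(data) {
  data <- .asHarmonized(data)
  k <- nsnp(data)
  if (k < 2) stop("insufficient-instruments: Q requires >= 2")
  ratios <- data@by / data@bx
  w <- .ratioWeights(data@bx, data@byse)
  b <- sum(w * ratios) / sum(w)
  q <- sum(w * (ratios - b)^2)
  new("QTest", q = q, df = k - 1L,
      pval = max(qPvalue(q, k - 1L), .Machine$double.xmin))
}

#' Upper-tail chi-square probability for a heterogeneity statistic
#'
#' @param q Cochran's Q statistic (>= 0).
#' @param df degrees of freedom (instrument count minus 1).
#' @return upper-tail probability.
#' @examples
#' qPvalue(0.671, 2)
#' @export
qPvalue <- function(q, df) stats::pchisq(q, df, lower.tail = FALSE)

#' Full MR analysis with method dispatch on instrument count
#'
#' One instrument: Wald ratio only. Two instruments: IVW plus Cochran's Q
#' (MR-Egger, weighted median and weighted mode require at least three
#' instruments). Three or more: IVW, MR-Egger, weighted median, weighted
#' mode and Cochran's Q. The primary estimate is the Wald ratio (single
#' instrument) or IVW.
#'
#' @param data \code{\linkS4class{HarmonizedData}} with >= 1 variant.
#' @param ivwMode IVW variance mode, see \code{\link{ivw}}.
#' @param nBoot,seed bootstrap settings for median/mode.
#' @return an \code{\linkS4class{MRAnalysis}}.
#' @export
mrAuto <- function(data, ivwMode = "multiplicative_random",
                   nBoot = 1000, seed = 1) {
  data <- .asHarmonized(data)
  k <- nsnp(data)
  if (k < 1) stop("insufficient-instruments: empty dataset")
  est <- list()
  qt <- list()
  if (k == 1) {
    est$wald <- waldRatio(data@bx, data@bxse, data@by, data@byse)
  } else {
    est$ivw <- ivw(data, mode = ivwMode)
    qt$q <- cochranQ(data)
    if (k >= 3) {
      est$egger <- mrEgger(data)
      est$weighted_median <- weightedMedian(data, nBoot = nBoot, seed = seed)
      est$weighted_mode <- weightedMode(data, nBoot = nBoot, seed = seed)
    }
  }
  new("MRAnalysis", exposureId = data@exposureId,
      outcomeId = data@outcomeId, estimates = est, qtest = qt)
}

#' Primary estimate of an MRAnalysis
#'
#' @param x an \code{\linkS4class{MRAnalysis}}.
#' @return the Wald (single instrument) or IVW \code{MRResult}.
#' @export
primaryEstimate <- function(x) {
  stopifnot(is(x, "MRAnalysis"))
  if (!is.null(x@estimates$wald)) x@estimates$wald else x@estimates$ivw
}
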