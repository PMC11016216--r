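#' Default colocalization priors
#'
#' Per-variant prior probabilities: \code{p1} (associated with trait 1
#' only), \code{p2} (trait 2 only), \code{p12} (associated with both).
#'
#' @param p1,p2 per-variant single-trait priors.
#' @param p12 per-variant shared-causal-variant prior.
#' @return validated list of priors.
#' @export
colocPriors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(p1 > 0, p2 > 0, p12 > 0, p12 <= min(p1, p2),
            p1 + p2 + p12 < 1)
  list(p1 = p1, p2 = p2, p12 = p12)
}

#' Wakefield log approximate Bayes factor for a quantitative trait
#'
#' With observed variance \code{V = se^2}, prior effect variance
#' \code{W = priorSd^2}, \code{z = beta/se} and shrinkage
#' \code{r = W / (V + W)}:
#' \code{log ABF = 0.5 (log(1 - r) + r z^2)}.
#'
#' @param beta,se per-variant association and standard error (se > 0).
#' @param priorSd prior standard deviation of true effects; the default
#'   0.15 corresponds to a standardized (sd 1) trait.
#' @return log Bayes factor(s) favouring association over the null.
#' @export
logABF <- function(beta, se, priorSd = 0.15) {
  if (any(se <= 0)) stop("se must be > 0")
  if (any(priorSd <= 0)) stop("priorSd must be > 0")
  V <- se^2
  W <- priorSd^2
  r <- W / (V + W)
  0.5 * (log1p(-r) + r * (beta / se)^2)
}

#' Construct a RegionalSummary
#'
#' @param traitId trait label.
#' @param variants variant ids.
#' @param beta,se per-variant association and standard error.
#' @param maf per-variant minor-allele frequency in (0, 0.5].
#' @param n sample size.
#' @param sdTrait trait standard deviation (1 = standardized).
#' @return a \code{\linkS4class{RegionalSummary}}.
#' @export
regionalSummary <- function(traitId, variants, beta, se, maf, n,
                            sdTrait = 1) {
  new("RegionalSummary", traitId = traitId,
      variants = as.character(variants), beta = as.numeric(beta),
      se = as.numeric(se), maf = as.numeric(maf), n = n, sdTrait = sdTrait)
}

#' Extract a paired colocalization region around a pQTL
#'
#' Intersects the variants present in both studies within \code{window} bp
#' of the pQTL position (inclusive), requiring minor-allele frequency
#' strictly above \code{mafMin} in both studies; position order is
#' preserved.
#'
#' @param pqtl variant id of the sentinel pQTL (must be present in
#'   \code{table1}).
#' @param table1,table2 summary-statistics data.frames (canonical columns)
#'   for the protein and the outcome.
#' @param window half-width of the region in bp (default 1 Mb).
#' @param mafMin minor-allele frequency floor (strict).
#' @param trait1,trait2 labels for the returned summaries.
#' @return list with \code{region1} and \code{region2}
#'   (\code{\linkS4class{RegionalSummary}} over identical variant lists).
#' @export
extractRegion <- function(pqtl, table1, table2, window = 1e6,
                          mafMin = 0.01, trait1 = "trait1",
                          trait2 = "trait2") {
  validateSumstats(table1)
  validateSumstats(table2)
  i0 <- match(pqtl, table1$snp)
  if (is.na(i0)) stop("pqtl '", pqtl, "' absent from table1")
  centre <- table1$pos[i0]
  chr <- table1$chr[i0]
  maf1 <- pmin(table1$eaf, 1 - table1$eaf)
  sel1 <- table1$chr == chr & abs(table1$pos - centre) <= window &
    maf1 > mafMin
  shared <- intersect(table1$snp[sel1], table2$snp)
  j2 <- match(shared, table2$snp)
  maf2 <- pmin(table2$eaf[j2], 1 - table2$eaf[j2])
  shared <- shared[maf2 > mafMin]
  if (!length(shared)) stop("empty-region: no shared variants pass filters")
  i1 <- match(shared, table1$snp)
  i1 <- i1[order(table1$pos[i1])]
  ids <- table1$snp[i1]
  i2 <- match(ids, table2$snp)
  list(region1 = regionalSummary(trait1, ids, table1$beta[i1],
                                 table1$se[i1],
                                 pmin(table1$eaf[i1], 1 - table1$eaf[i1]),
                                 stats::median(table1$n[i1])),
       region2 = regionalSummary(trait2, ids, table2$beta[i2],
                                 table2$se[i2],
                                 pmin(table2$eaf[i2], 1 - table2$eaf[i2]),
                                 stats::median(table2$n[i2])))
}

#' Colocalization posterior probabilities (PPH0-PPH4)
#'
#' Computes per-variant log approximate Bayes factors for both traits and
#' combines them under the five single-causal-variant hypotheses in log
#' space (log-sum-exp). The distinct-variants sum (H3) uses the stable
#' complement \code{exp(L1 + L2) - sum_j exp(l1j + l2j)}, falling back to
#' direct pairwise summation for small regions when cancellation threatens;
#' a single-variant region cannot support H3 and gets PPH3 = 0 with a note.
#'
#' @param region1,region2 \code{\linkS4class{RegionalSummary}} objects with
#'   identical variant lists.
#' @param priors \code{\link{colocPriors}}.
#' @param priorSdFactor effect-size prior sd as a multiple of the trait sd.
#' @param strong,suggestive PPH4 thresholds for the evidence call.
#' @return a \code{\linkS4class{ColocResult}}.
#' @export
colocPosteriors <- function(region1, region2, priors = colocPriors(),
                            priorSdFactor = 0.15, strong = 0.8,
                            suggestive = 0.6) {
  stopifnot(is(region1, "RegionalSummary"), is(region2, "RegionalSummary"))
  if (!identical(region1@variants, region2@variants))
    stop("invalid-argument: regions must share an identical variant list")
  nv <- length(region1@variants)
  if (!nv) stop("empty-region")
  l1 <- logABF(region1@beta, region1@se, priorSdFactor * region1@sdTrait)
  l2 <- logABF(region2@beta, region2@se, priorSdFactor * region2@sdTrait)
  L1 <- .logSumExp(l1)
  L2 <- .logSumExp(l2)
  L12 <- .logSumExp(l1 + l2)
  notes <- character(0)
  s0 <- 0
  s1 <- log(priors$p1) + L1
  s2 <- log(priors$p2) + L2
  if (nv == 1) {
    s3 <- -Inf
    notes <- "single-variant region: PPH3 undefined, set to 0"
  } else if (nv <= 64) {
    ## direct double sum over ordered pairs j != k, in log space
    cross <- outer(l1, l2, "+")
    diag(cross) <- -Inf
    s3 <- log(priors$p1) + log(priors$p2) + .logSumExp(as.numeric(cross))
  } else {
    a <- L1 + L2
    d <- L12 - a            # <= 0 by construction
    s3 <- log(priors$p1) + log(priors$p2) +
      if (d > -1e-12) -Inf else a + log1p(-exp(d))
  }
  s4 <- log(priors$p12) + L12
  s <- c(s0, s1, s2, s3, s4)
  m <- max(s)
  pp <- exp(s - m) / sum(exp(s - m))
  names(pp) <- paste0("pph", 0:4)
  res <- new("ColocResult", pp = pp, nVariants = as.integer(nv),
             call = "not_colocalized", notes = notes)
  res@call <- callColocalization(res, strong = strong,
                                 suggestive = suggestive)
  res
}

#' Evidence call from colocalization posteriors
#'
#' PPH4 strictly above \code{strong} is called \code{"colocalized"};
#' between \code{suggestive} (exclusive) and \code{strong} (inclusive),
#' \code{"suggestive"}; otherwise \code{"not_colocalized"}.
#'
#' @param post a \code{\linkS4class{ColocResult}} or a named posterior
#'   vector containing \code{pph4}.
#' @param strong,suggestive PPH4 thresholds.
#' @return the call label.
#' @export
callColocalization <- function(post, strong = 0.8, suggestive = 0.6) {
  pph4 <- if (is(post, "ColocResult")) post@pp[["pph4"]] else post[["pph4"]]
  if (pph4 > strong) "colocalized"
  else if (pph4 > suggestive) "suggestive"
  else "not_colocalized"
}
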