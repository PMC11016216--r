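## Shared fixture builders: everything is generated in code at test time.

## Ten independent instruments on one synthetic chromosome (adjacent r2
## ~ 4.5e-5, far below the clumping cutoff).
independentLD <- function(k = 10, chromosome = "1", prefix = NULL) {
  if (is.null(prefix)) prefix <- paste0("rs", chromosome, "_")
  simulateLDReference(k, decay = 5e-5, chromosome = chromosome,
                      spacing = 1e5, prefix = prefix)
}

## A hand-rolled summary-statistics table.
makeSumstats <- function(snp, beta, se, chr = "1",
                         pos = seq(1e6, by = 1e5,
                                   length.out = length(snp)),
                         ea = "A", oa = "G", eaf = 0.3,
                         n = 10000) {
  data.frame(snp = snp, chr = chr, pos = pos, ea = ea, oa = oa,
             eaf = eaf, beta = beta, se = se,
             pval = 2 * pnorm(-abs(beta / se)), n = n,
             stringsAsFactors = FALSE)
}

## An InstrumentSet wrapping a table verbatim (bypasses selection filters).
makeInstrumentSet <- function(tab, exposureId = "exposure") {
  st <- computeInstrumentStrength(tab$beta, tab$se, tab$eaf, tab$n)
  new("InstrumentSet", exposureId = exposureId, instruments = tab,
      r2Explained = st$r2, fStat = st$f,
      provenance = data.frame(snp = tab$snp, status = "kept",
                              proxy_for = NA_character_,
                              stringsAsFactors = FALSE))
}

## One replicate of the instrument-level calibration experiment: 10
## instruments, outcome generated downstream; returns a HarmonizedData.
## trueBx pairs the outcome draws with the true (noise-free) exposure
## effects, the regime in which IVW's normal theory is exact.
calibrationDraw <- function(theta = 0, seed = 1, alpha = 0,
                            k = 10, nExposure = 10000, nOutcome = 30000,
                            instrumentR2 = 0.02, trueBx = TRUE,
                            mafRange = c(0.05, 0.5)) {
  refs <- list(independentLD(k))
  tr <- truthConfig(nProteins = 1, nVariantsPerProtein = k,
                    nExposure = nExposure, nOutcome = nOutcome,
                    theta = theta, alpha = alpha,
                    instrumentR2 = instrumentR2, mafRange = mafRange,
                    palindromicRate = 0, seed = seed)
  ps <- simulateProteinGwas(tr, refs)[[1]]
  os <- simulateDownstreamGwas(tr, ps, "outcome")
  harmonizedData(bx = if (trueBx) ps@truth$trueBeta else ps@table$beta,
                 bxse = ps@table$se,
                 by = os@table$beta, byse = os@table$se)
}

## Linear-space brute-force colocalization oracle for small regions.
colocOracle <- function(l1, l2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  a1 <- exp(l1); a2 <- exp(l2)
  s0 <- 1
  s1 <- p1 * sum(a1)
  s2 <- p2 * sum(a2)
  s3 <- 0
  for (j in seq_along(a1)) for (k in seq_along(a2))
    if (j != k) s3 <- s3 + a1[j] * a2[k]
  s3 <- p1 * p2 * s3
  s4 <- p12 * sum(a1 * a2)
  s <- c(s0, s1, s2, s3, s4)
  stats::setNames(s / sum(s), paste0("pph", 0:4))
}
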