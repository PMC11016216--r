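test_that("instrument strength arithmetic", {
  s <- computeInstrumentStrength(beta = 0, se = 0.01, eaf = 0.3, n = 1000)
  expect_equal(s$r2, 0)
  expect_equal(s$f, 0)
  s <- computeInstrumentStrength(beta = 0.2, se = 0.01, eaf = 0.5, n = 3000)
  expect_equal(s$r2, 0.02, tolerance = 1e-12)
  expect_equal(s$f, 0.02 * 2998 / 0.98, tolerance = 1e-12)
  ## eaf above 0.5 folds to the minor allele
  s2 <- computeInstrumentStrength(beta = 0.2, se = 0.01, eaf = 0.5, n = 3000)
  expect_equal(computeInstrumentStrength(0.2, 0.01, 0.5, 3000)$r2, s2$r2)
  expect_error(computeInstrumentStrength(0.1, 0.01, 0.3, n = 2),
               "invalid-argument")
})

test_that("selection applies the four rules in order and records provenance", {
  ld <- independentLD(6)
  tab <- makeSumstats(ld@variantIds,
                      beta = rep(0.4, 6), se = rep(0.03, 6),
                      pos = ld@positions, eaf = 0.3, n = 10000)
  tab$pval[2] <- 1e-4                               # fails rule 1
  tab$chr[3] <- "6"; tab$pos[3] <- 30e6             # MHC, rule 2
  tab$beta[4] <- 0.04; tab$se[4] <- 0.004           # significant but F < 10
  counts <- c(5L); names(counts) <- tab$snp[5]      # rule 4
  ## MHC variant needs LD coverage on chr 6 too
  ld6 <- simulateLDReference(1, chromosome = "6", start = 30e6,
                             prefix = "mhc_")
  ld6@variantIds <- tab$snp[3]
  iset <- selectInstruments(tab, counts, list(ld, ld6),
                            exposureId = "p1")
  expect_setequal(instruments(iset)$snp, tab$snp[c(1, 6)])
  prov <- iset@provenance
  expect_equal(prov$status[2], "p_above_threshold")
  expect_equal(prov$status[3], "mhc_region")
  expect_equal(prov$status[4], "weak_instrument")
  expect_equal(prov$status[5], "pleiotropic_snp")
  expect_true(all(iset@fStat >= 10))
})

test_that("greedy clumping keeps the most significant of linked variants", {
  ## two variants in strong LD: only the smaller p survives
  ld <- simulateLDReference(2, decay = 1e-6, spacing = 1e4)  # r2 ~ 0.98
  tab <- makeSumstats(ld@variantIds, beta = c(0.5, 0.45),
                      se = c(0.03, 0.03), pos = ld@positions, n = 10000)
  expect_lt(tab$pval[1], tab$pval[2])
  iset <- selectInstruments(tab, ld = ld)
  expect_identical(instruments(iset)$snp, ld@variantIds[1])
  expect_equal(iset@provenance$status[2], "clumped")
})

test_that("clumping equals the brute-force independence criterion", {
  ## oracle: every kept pair independent; every clumped variant conflicts
  ## with a kept variant of smaller p
  for (s in 1:5) {
    set.seed(s)
    k <- sample(5:12, 1)
    ld <- simulateLDReference(k, decay = 10^runif(1, -6, -4.3),
                              spacing = 1e4)
    tab <- makeSumstats(ld@variantIds, beta = runif(k, 0.3, 0.6),
                        se = rep(0.03, k), pos = ld@positions, n = 10000)
    params <- selectionParams(clumpR2 = runif(1, 0.001, 0.5))
    iset <- selectInstruments(tab, ld = ld, params = params)
    kept <- instruments(iset)$snp
    ki <- match(kept, ld@variantIds)
    if (length(ki) > 1)
      for (a in ki) for (b in ki) if (a != b)
        expect_lt(ld@r2[a, b], params$clumpR2)
    clumped <- iset@provenance$snp[iset@provenance$status == "clumped"]
    for (cs in clumped) {
      ci <- match(cs, ld@variantIds)
      conflicts <- ld@r2[ci, ki] >= params$clumpR2
      better <- tab$pval[ki] <= tab$pval[ci]
      expect_true(any(conflicts & better))
    }
  }
})

test_that("selection is idempotent and monotone in the p threshold", {
  ld <- independentLD(8)
  set.seed(42)
  tab <- makeSumstats(ld@variantIds, beta = runif(8, 0.1, 0.5),
                      se = rep(0.03, 8), pos = ld@positions, n = 10000)
  iset <- selectInstruments(tab, ld = ld)
  again <- selectInstruments(instruments(iset), ld = ld)
  expect_identical(instruments(again), instruments(iset))
  ## candidate set (pre-clumping survivors of rule 1) grows as p relaxes
  nCand <- function(p) {
    pr <- selectInstruments(tab, ld = ld,
                            params = selectionParams(pThreshold = p)
                            )@provenance
    sum(pr$status != "p_above_threshold")
  }
  thresholds <- c(1e-12, 1e-10, 5e-8, 1e-4)
  expect_true(all(diff(vapply(thresholds, nCand, numeric(1))) >= 0))
})

test_that("selection errors on candidates missing from the LD reference", {
  ld <- independentLD(3)
  tab <- makeSumstats(c(ld@variantIds[1:2], "rs_unknown"),
                      beta = rep(0.4, 3), se = rep(0.03, 3), n = 10000)
  expect_error(selectInstruments(tab, ld = ld), "missing-ld")
})

test_that("proxy lookup: threshold, identity and tie-breaks", {
  ## dense block: adjacent r2 = exp(-0.1)^2 ~ 0.82
  ld <- simulateLDReference(7, decay = 1e-5, spacing = 1e4)
  v <- ld@variantIds
  expect_identical(findProxy(v[4], ld, v), v[4])           # itself, r2 = 1
  ## only neighbours above 0.8 qualify; two-step r2 ~ 0.67
  expect_identical(findProxy(v[4], ld, v[c(2, 6, 5)]), v[5])
  ## equidistant tie at equal r2 -> lexicographically smaller id
  expect_identical(findProxy(v[4], ld, v[c(3, 5)]), v[3])
  ## nothing above the threshold -> none
  expect_true(is.na(findProxy(v[4], ld, v[c(1, 7)])))
  ## 0.79 just below the strict cutoff -> none
  params <- selectionParams(proxyR2 = exp(-0.1)^2 + 1e-6)
  expect_true(is.na(findProxy(v[4], ld, v[5], params)))
  expect_error(findProxy("nope", ld, v), "invalid-argument")
})
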