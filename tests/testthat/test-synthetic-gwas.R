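test_that("LD kernel: unit diagonal, symmetry, exponential decay", {
  expect_identical(simulateLDReference(1)@r2, matrix(1, 1, 1))
  flat <- simulateLDReference(4, decay = 0)
  expect_true(all(flat@r2 == 1))
  ld <- simulateLDReference(5, decay = 1e-5, spacing = 1e4)
  expect_equal(ld@r2[1, 2], exp(-0.1)^2, tolerance = 1e-12)
  expect_equal(ld@r2[1, 3], exp(-0.2)^2, tolerance = 1e-12)
  expect_equal(ld@r2, t(ld@r2))
  expect_error(simulateLDReference(0), "invalid-argument")
  expect_error(simulateLDReference(3, decay = -1), "invalid-argument")
})

test_that("protein GWAS matches the configured instrument strength", {
  ## variants far enough apart that LD leakage into the marginal effects
  ## is numerically zero
  refs <- list(simulateLDReference(10, decay = 5e-5, spacing = 2e6))
  tr <- truthConfig(nProteins = 1, nVariantsPerProtein = 10,
                    nExposure = 10000, theta = 0, instrumentR2 = 0.01,
                    mafRange = c(0.5, 0.5), palindromicRate = 0, seed = 3)
  ps <- simulateProteinGwas(tr, refs)[[1]]
  ## maf = 0.5: se = 1/sqrt(5000), true |beta| = sqrt(0.02)
  expect_equal(ps@table$se, rep(1 / sqrt(5000), 10), tolerance = 1e-12)
  expect_equal(ps@truth$trueBeta, rep(sqrt(0.02), 10), tolerance = 1e-10)
  expect_true(mean(abs(ps@table$beta - sqrt(0.02))) < 4 * 1 / sqrt(5000))
})

test_that("generator is deterministic and the null generator is null", {
  refs <- list(independentLD(8))
  tr <- truthConfig(nProteins = 1, nVariantsPerProtein = 8, theta = 0.2,
                    seed = 11)
  a <- simulateProteinGwas(tr, refs)[[1]]
  b <- simulateProteinGwas(tr, refs)[[1]]
  expect_identical(a@table, b@table)
  oa <- simulateDownstreamGwas(tr, a, "outcome")
  ob <- simulateDownstreamGwas(tr, b, "outcome")
  expect_identical(oa@table, ob@table)
  ## exposure and outcome noise are independent (two-sample design)
  zx <- (a@table$beta - a@truth$trueBeta) / a@table$se
  zy <- (oa@table$beta - oa@truth$trueBeta) / oa@table$se
  expect_lt(abs(cor(zx, zy)), 0.9)
  ## null generator: no exposure signal
  trNull <- truthConfig(nProteins = 1, nVariantsPerProtein = 8,
                        theta = 0, instrumentR2 = 0, seed = 4)
  null <- simulateProteinGwas(trNull, refs)[[1]]
  expect_equal(null@truth$trueBeta, rep(0, 8))
  z <- null@table$beta / null@table$se
  expect_lt(abs(mean(abs(z)) - sqrt(2 / pi)), 0.5)
})

test_that("empirical F-statistics track the configured variance explained", {
  refs <- list(independentLD(25))
  fs <- unlist(lapply(1:20, function(s) {
    tr <- truthConfig(nProteins = 1, nVariantsPerProtein = 25,
                      nExposure = 10000, theta = 0, instrumentR2 = 0.02,
                      mafRange = c(0.3, 0.3), palindromicRate = 0,
                      seed = 100 + s)
    ps <- simulateProteinGwas(tr, refs)[[1]]
    computeInstrumentStrength(ps@table$beta, ps@table$se, ps@table$eaf,
                              ps@table$n)$f
  }))
  expect_gte(length(fs), 500)
  expectedF <- 0.02 * 9998 / 0.98
  expect_lt(abs(mean(fs) / expectedF - 1), 0.10)
})

test_that("downstream IVW p-values are uniform under the global null", {
  pv <- vapply(seq_len(2000), function(s) {
    h <- calibrationDraw(theta = 0, seed = 40000 + s, trueBx = FALSE)
    pvalue(ivw(h, mode = "fixed"))
  }, numeric(1))
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("downstream generator validates the trait map", {
  refs <- list(independentLD(5))
  tr <- truthConfig(nProteins = 1, nVariantsPerProtein = 5, theta = 0.1)
  ps <- simulateProteinGwas(tr, refs)[[1]]
  expect_error(simulateDownstreamGwas(tr, ps, "nonexistent"),
               "invalid-argument")
})

test_that("coloc region scenarios honour their hypothesis labels", {
  ld <- simulateLDReference(40, decay = 5e-5, spacing = 1e4)
  expect_error(simulateColocRegion("H3", simulateLDReference(1)),
               "invalid-argument")
  h0 <- simulateColocRegion("H0", ld, seed = 5)
  expect_lt(max(abs(h0$region1@beta) / h0$region1@se), 5)
  h1 <- simulateColocRegion("H1", ld, effectSd = 0.1, seed = 5)
  expect_gt(max(abs(h1$region1@beta) / h1$region1@se), 5)
  expect_lt(max(abs(h1$region2@beta) / h1$region2@se), 5)
  h3 <- simulateColocRegion("H3", ld, effectSd = 0.1, seed = 5)
  expect_false(identical(h3$truth$causal1, h3$truth$causal2))
  ## determinism
  a <- simulateColocRegion("H4", ld, seed = 9)
  b <- simulateColocRegion("H4", ld, seed = 9)
  expect_identical(a$region1@beta, b$region1@beta)
})

test_that("summary statistics and LD references round-trip through text", {
  refs <- list(independentLD(6))
  tr <- truthConfig(nProteins = 1, nVariantsPerProtein = 6, theta = 0,
                    seed = 2)
  ps <- simulateProteinGwas(tr, refs)[[1]]
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSumstats(ps, f)
  back <- readSumstats(f)
  expect_equal(back$beta, ps@table$beta, tolerance = 1e-12)
  expect_identical(back$snp, ps@table$snp)
  g <- withr::local_tempfile(fileext = ".tsv")
  writeLDReference(refs[[1]], g)
  ldBack <- readLDReference(g)
  expect_equal(ldBack@r2, refs[[1]]@r2, tolerance = 1e-10)
  expect_identical(ldBack@variantIds, refs[[1]]@variantIds)
})
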