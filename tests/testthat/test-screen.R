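test_that("Bonferroni threshold arithmetic", {
  expect_equal(bonferroniThreshold(0.05, 1002), 0.05 / 1002)
  expect_equal(signif(bonferroniThreshold(0.05, 1002), 3), 4.99e-5)
  expect_equal(signif(bonferroniThreshold(0.05, 18), 2), 0.0028)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_error(bonferroniThreshold(0.05, 0), "invalid-argument")
})

test_that("empty inputs yield empty, well-formed reports", {
  sc <- simulateScreenScenario(nNull = 1, nCausal = 0, nConfounded = 0,
                               seed = 3)
  rep0 <- runPrimaryScreen(list(), sc$outcomeStudies, sc$ld)
  expect_equal(nrow(rep0), 0)
  ## a null protein is testable but not significant
  rep1 <- runPrimaryScreen(sc$proteinStudies, sc$outcomeStudies, sc$ld)
  expect_equal(nrow(rep1), 1)
  expect_false(rep1$significant)
  expect_false(rep1$untestable)
})

test_that("proteins without surviving instruments are untestable, not errors", {
  sc <- simulateScreenScenario(nNull = 1, nCausal = 1, nConfounded = 0,
                               seed = 5)
  ## weaken every variant of the null protein below genome-wide significance
  weak <- sc$proteinStudies
  tab <- weak$null1@table
  tab$pval <- pmax(tab$pval, 1e-4)
  weak$null1 <- tab
  out <- runPrimaryScreen(weak, sc$outcomeStudies, sc$ld)
  expect_true(out$untestable[out$exposure == "null1"])
  expect_false(out$untestable[out$exposure == "causal1"])
})

test_that("single-instrument exposures are analyzed with the Wald ratio", {
  sc <- simulateScreenScenario(nNull = 0, nCausal = 1, nConfounded = 0,
                               nInstruments = 1, seed = 7)
  out <- runPrimaryScreen(sc$proteinStudies, sc$outcomeStudies, sc$ld)
  expect_equal(out$method, "wald")
  expect_equal(out$nsnp, 1L)
  expect_true(out$significant)
  expect_equal(out$beta, 0.4, tolerance = 0.15)
})

test_that("step-2 is gated on step-1 and thresholds are recorded", {
  ch <- simulateMediationChain(seed = 9)
  cfg <- screenConfig(nBoot = 100)
  two <- runTwoStepScreen(ch$proteinStudies, ch$riskFactorStudies,
                          ch$outcomeStudies, ch$ld, cfg)
  expect_equal(two$step1Threshold, 0.05 / 18)
  expect_equal(two$step2Threshold, 0.05 / 1002)
  expect_true(any(two$step1$significant))
  expect_true(any(two$step2$significant))
  ## no mediator passes step-1 -> step-2 empty
  nullCh <- simulateMediationChain(theta1 = 0, theta2 = 0, direct = 0,
                                   seed = 10)
  twoNull <- runTwoStepScreen(nullCh$proteinStudies,
                              nullCh$riskFactorStudies,
                              nullCh$outcomeStudies, nullCh$ld, cfg)
  expect_false(any(twoNull$step1$significant))
  expect_equal(nrow(twoNull$step2), 0)
})

test_that("mediation candidates are gated on all three screens", {
  ch <- simulateMediationChain(seed = 12)
  cfg <- screenConfig(nBoot = 100)
  rep <- runScreen(ch$proteinStudies, ch$outcomeStudies,
                   ch$riskFactorStudies, ch$ld, cfg)
  med <- rep@mediation
  expect_equal(nrow(med), 1)
  expect_equal(med$exposure, "protein")
  expect_equal(med$mediator, "mediator")
  expect_match(med$notes, "direction-consistent")
  expect_true(med$valid)
  expect_equal(med$proportion_pct, 100 * 0.12 / 0.22, tolerance = 25)
  ## gating soundness: constituent p-values pass their thresholds
  thrP <- rep@config$proteinThreshold
  thr1 <- rep@config$riskFactorThreshold
  pr <- rep@primary
  expect_lt(pr$pval[pr$significant & pr$exposure == "protein"], thrP)
  s1 <- rep@step1
  expect_lt(s1$pval[s1$significant & s1$exposure == "mediator"], thr1)
  s2 <- rep@step2
  expect_lt(s2$pval[s2$significant], thrP)
  ## sign-inconsistent triples are still emitted, with a note
  fake1 <- data.frame(exposure = "p", outcome = "o", beta = -0.2,
                      se = 0.02, pval = 1e-9, significant = TRUE,
                      untestable = FALSE, stringsAsFactors = FALSE)
  fakeS1 <- data.frame(exposure = "m", outcome = "o", beta = 0.3,
                       se = 0.02, pval = 1e-9, significant = TRUE,
                       untestable = FALSE, stringsAsFactors = FALSE)
  fakeS2 <- data.frame(exposure = "p", outcome = "m", beta = 0.4,
                       se = 0.02, pval = 1e-9, significant = TRUE,
                       untestable = FALSE, stringsAsFactors = FALSE)
  cands <- selectMediationCandidates(fake1, fakeS1, fakeS2)
  expect_length(cands, 1)
  expect_equal(attr(cands[[1]], "directionNote"), "direction-inconsistent")
})

test_that("the screen prioritizes colocalized causal proteins only", {
  sc <- simulateScreenScenario(nNull = 6, nCausal = 2, nConfounded = 1,
                               seed = 21)
  rep <- runScreen(sc$proteinStudies, sc$outcomeStudies, ld = sc$ld,
                   config = screenConfig(nBoot = 100))
  pr <- rep@primary
  flagged <- sort(pr$exposure[pr$significant])
  expect_setequal(flagged, c(sc$truth$causal, sc$truth$confounded))
  pri <- rep@coloc$exposure[rep@coloc$prioritized]
  expect_setequal(pri, sc$truth$causal)
  ## confounded proteins show distinct-variant evidence
  conf <- rep@coloc[rep@coloc$exposure %in% sc$truth$confounded, ]
  expect_true(all(conf$pph3 > 0.8))
})

test_that("report writing is deterministic and records the thresholds", {
  sc <- simulateScreenScenario(nNull = 2, nCausal = 1, nConfounded = 0,
                               seed = 33)
  rep <- runScreen(sc$proteinStudies, sc$outcomeStudies, ld = sc$ld,
                   config = screenConfig(nBoot = 100, seed = 33))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeReport(rep, d1)
  writeReport(rep, d2)
  for (f in c("primary.tsv", "step1.tsv", "step2.tsv", "mediation.tsv",
              "coloc.tsv", "manifest.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$proteinThreshold, 0.05 / 1002, tolerance = 1e-12)
  expect_equal(man$alpha, 0.05)
  expect_equal(man$seed, 33)
  ## an empty report writes header-only tables
  repE <- runScreen(list(), sc$outcomeStudies, ld = sc$ld,
                    config = screenConfig())
  dE <- withr::local_tempdir()
  writeReport(repE, dE)
  expect_equal(length(readLines(file.path(dE, "primary.tsv"))), 1)
})
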