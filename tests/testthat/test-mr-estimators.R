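test_that("Wald ratio arithmetic and degenerate input", {
  e <- waldRatio(bx = 0.2, bxse = 0.02, by = 0.06, byse = 0.05)
  expect_equal(mrBeta(e), 0.3)
  expect_equal(mrSE(e), 0.25)
  expect_equal(confint95(e), c(0.3 - 1.96 * 0.25, 0.3 + 1.96 * 0.25))
  null <- waldRatio(bx = -0.2, bxse = 0.02, by = 0, byse = 0.05)
  expect_equal(mrBeta(null), 0)
  expect_equal(pvalue(null), 1)
  expect_error(waldRatio(0, 0.02, 0.1, 0.05), "undefined-ratio")
})

test_that("IVW closed form, variance modes, and ratio-mean identity", {
  h <- harmonizedData(bx = c(0.1, 0.2), bxse = c(0.01, 0.01),
                      by = c(0.05, 0.10), byse = c(0.1, 0.1))
  expect_equal(mrBeta(ivw(h, mode = "fixed")), 0.5, tolerance = 1e-12)
  ## proportional data: residual scale floors at 1, modes agree
  expect_equal(mrSE(ivw(h, mode = "fixed")),
               mrSE(ivw(h, mode = "multiplicative_random")))
  ## algebraic identity: IVW = inverse-variance weighted mean of ratios
  set.seed(1)
  for (r in 1:20) {
    k <- sample(2:15, 1)
    h2 <- harmonizedData(bx = runif(k, 0.05, 0.5), bxse = runif(k, 0.01, 0.05),
                         by = rnorm(k, 0.1, 0.2), byse = runif(k, 0.01, 0.1))
    w <- (h2@bx / h2@byse)^2
    expect_equal(mrBeta(ivw(h2, mode = "fixed")),
                 sum(w * h2@by / h2@bx) / sum(w),
                 tolerance = 1e-12)
  }
  expect_error(ivw(harmonizedData(0.1, 0.01, 0.05, 0.1)),
               "insufficient-instruments")
})

test_that("MR-Egger recovers exact linear data and orients bx >= 0", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- harmonizedData(bx = bx, bxse = rep(0.01, 4),
                      by = 0.1 + 0.5 * bx, byse = rep(0.05, 4))
  e <- mrEgger(h)
  expect_equal(mrBeta(e), 0.5, tolerance = 1e-10)
  expect_equal(e@extra$intercept, 0.1, tolerance = 1e-10)
  ## negating one instrument's bx and by leaves the fit unchanged
  h2 <- harmonizedData(bx = c(-bx[1], bx[-1]), bxse = rep(0.01, 4),
                       by = c(-(0.1 + 0.5 * bx[1]), 0.1 + 0.5 * bx[-1]),
                       byse = rep(0.05, 4))
  expect_equal(mrBeta(mrEgger(h2)), 0.5, tolerance = 1e-10)
  expect_equal(mrEgger(h2)@extra$intercept, 0.1, tolerance = 1e-10)
  expect_error(mrEgger(harmonizedData(1:2 / 10, c(.01, .01), c(.1, .2),
                                      c(.1, .1))),
               "insufficient-instruments")
})

test_that("weighted median: constants, symmetric case, breakdown", {
  hc <- harmonizedData(bx = c(1, 2, 4), bxse = rep(0.01, 3),
                       by = c(0.7, 1.4, 2.8), byse = c(0.1, 0.3, 0.2))
  expect_equal(mrBeta(weightedMedian(hc, nBoot = 50)), 0.7,
               tolerance = 1e-10)
  hs <- harmonizedData(bx = rep(1, 3), bxse = rep(0.01, 3),
                       by = c(0.1, 0.5, 0.9), byse = rep(0.1, 3))
  expect_equal(mrBeta(weightedMedian(hs, nBoot = 50)), 0.5,
               tolerance = 1e-10)
  ## >50% of weight valid at ratio 0.3, rest wildly pleiotropic
  hb <- harmonizedData(bx = rep(0.3, 10), bxse = rep(0.005, 10),
                       by = c(rep(0.09, 6), rep(0.6, 4)),
                       byse = rep(0.02, 10))
  wm <- mrBeta(weightedMedian(hb, nBoot = 100, seed = 2))
  expect_lt(abs(wm - 0.3), 0.1)
  expect_gt(mrBeta(ivw(hb, mode = "fixed")), 0.8)   # IVW dragged upward
})

test_that("weighted mode: modal cluster and large-bandwidth limit", {
  hm <- harmonizedData(bx = rep(1, 4), bxse = rep(0.01, 4),
                       by = c(0.3, 0.3, 0.3, 0.9), byse = rep(0.1, 4))
  expect_equal(mrBeta(weightedMode(hm, nBoot = 50)), 0.3, tolerance = 0.02)
  hconst <- harmonizedData(bx = c(1, 2, 3), bxse = rep(0.01, 3),
                           by = c(0.4, 0.8, 1.2), byse = rep(0.1, 3))
  expect_equal(mrBeta(weightedMode(hconst, nBoot = 50)), 0.4,
               tolerance = 1e-9)
  ## bandwidth -> infinity: argmax tends to the weighted mean of ratios
  ratios <- hm@by / hm@bx
  w <- (hm@bx / hm@byse)^2
  big <- mrBeta(weightedMode(hm, bandwidthFactor = 1e5, nBoot = 50))
  expect_equal(big, weighted.mean(ratios, w), tolerance = 1e-3)
})

test_that("Cochran's Q: zero on proportional data, hand-checked otherwise", {
  hp <- harmonizedData(bx = c(0.1, 0.2, 0.4), bxse = rep(0.01, 3),
                       by = c(0.05, 0.10, 0.20), byse = rep(0.1, 3))
  q0 <- cochranQ(hp)
  expect_equal(q0@q, 0, tolerance = 1e-20)
  expect_equal(pvalue(q0), 1)
  h <- harmonizedData(bx = c(0.2, 0.25), bxse = c(0.01, 0.01),
                      by = c(0.05, 0.09), byse = c(0.02, 0.03))
  qt <- cochranQ(h)
  ## independent recomputation from the definition
  r <- h@by / h@bx
  w <- (h@bx / h@byse)^2
  b <- sum(w * r) / sum(w)
  expect_equal(qt@q, sum(w * (r - b)^2), tolerance = 1e-12)
  expect_equal(qt@df, 1L)
  expect_equal(pvalue(qt), pchisq(qt@q, 1, lower.tail = FALSE))
})

test_that("mrAuto dispatches on instrument count", {
  h1 <- harmonizedData(0.2, 0.02, 0.06, 0.05)
  a1 <- mrAuto(h1)
  expect_named(a1@estimates, "wald")
  expect_equal(mrBeta(primaryEstimate(a1)),
               mrBeta(waldRatio(0.2, 0.02, 0.06, 0.05)))
  expect_equal(mrSE(primaryEstimate(a1)), 0.25)
  h2 <- harmonizedData(c(0.1, 0.2), c(0.01, 0.01), c(0.05, 0.1),
                       c(0.1, 0.1))
  a2 <- mrAuto(h2)
  expect_setequal(names(a2@estimates), "ivw")
  expect_length(a2@qtest, 1)
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  h5 <- harmonizedData(bx, rep(0.01, 5), 0.5 * bx, rep(0.1, 5))
  a5 <- mrAuto(h5, nBoot = 50)
  expect_setequal(names(a5@estimates),
                  c("ivw", "egger", "weighted_median", "weighted_mode"))
  betas <- vapply(a5@estimates, mrBeta, numeric(1))
  expect_equal(unname(betas), rep(0.5, 4), tolerance = 0.01)
  expect_equal(a5@qtest$q@q, 0, tolerance = 1e-18)
  expect_error(mrAuto(harmonizedData(numeric(0), numeric(0), numeric(0),
                                     numeric(0))),
               "insufficient-instruments")
})

test_that("sign equivariance: negating outcomes negates betas only", {
  set.seed(5)
  k <- 8
  h <- harmonizedData(bx = runif(k, 0.1, 0.4), bxse = rep(0.02, k),
                      by = rnorm(k, 0.15, 0.05), byse = runif(k, 0.03, 0.08))
  hNeg <- harmonizedData(bx = h@bx, bxse = h@bxse, by = -h@by,
                         byse = h@byse)
  for (fit in list(function(d) ivw(d, mode = "fixed"),
                   function(d) ivw(d, mode = "multiplicative_random"),
                   mrEgger)) {
    a <- fit(h); b <- fit(hNeg)
    expect_equal(mrBeta(b), -mrBeta(a), tolerance = 1e-12)
    expect_equal(mrSE(b), mrSE(a), tolerance = 1e-12)
    expect_equal(pvalue(b), pvalue(a), tolerance = 1e-12)
  }
  ## median/mode point estimates are deterministic: exact negation
  expect_equal(mrBeta(weightedMedian(hNeg, nBoot = 50)),
               -mrBeta(weightedMedian(h, nBoot = 50)), tolerance = 1e-12)
  expect_equal(mrBeta(weightedMode(hNeg, nBoot = 50)),
               -mrBeta(weightedMode(h, nBoot = 50)), tolerance = 1e-9)
  expect_equal(cochranQ(hNeg)@q, cochranQ(h)@q, tolerance = 1e-12)
})

test_that("IVW multiplicative random-effects inflates but never deflates", {
  set.seed(9)
  k <- 12
  h <- harmonizedData(bx = runif(k, 0.1, 0.4), bxse = rep(0.02, k),
                      by = rnorm(k, 0.1, 0.3), byse = rep(0.05, k))
  expect_gte(mrSE(ivw(h, mode = "multiplicative_random")),
             mrSE(ivw(h, mode = "fixed")))
})
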