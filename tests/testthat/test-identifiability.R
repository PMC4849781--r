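test_that("the chi-square threshold is the upper-alpha quantile with 1 df", {
  expect_equal(chi2Threshold(0.05), stats::qchisq(0.95, 1))
  expect_equal(chi2Threshold(0.05), 3.841, tolerance = 1e-3)
  expect_equal(chi2Threshold(0.32), 0.989, tolerance = 1e-2)
  expect_gt(chi2Threshold(0.01), chi2Threshold(0.05))
  expect_error(chi2Threshold(0), "alpha")
  expect_error(chi2Threshold(1.2), "alpha")
})

noiseFreeChainFit <- function(sd = 0.05, maxEval = 300L) {
  toy <- makeToy("chain3")
  ds <- generateSyntheticDataset(toy$network, toy$params, toy$conditions,
                                 toy$observables, noiseSd = 0, seed = 1L)
  ds$sd <- sd
  problem <- fitProblem(toy$network, toy$params, toy$groups, toy$conditions,
                        ds, rtol = 1e-6, atol = 1e-8)
  fit <- structure(list(factors = stats::setNames(c(1, 1, 1), names(toy$groups)),
                        X2 = unname(objective(c(1, 1, 1), problem)),
                        schedule = list(maxEval = maxEval)),
                   class = "klFit")
  list(problem = problem, fit = fit)
}

test_that("profiles are anchored at the best fit and contain the truth on clean data", {
  nf <- noiseFreeChainFit()
  pr <- profileParameter(nf$problem, nf$fit, "k1", alpha = 0.05,
                         control = list(reoptEval = 40L, movesPerTemp = 8L,
                                        stepFactor = 1.4),
                         seed = 11L)
  expect_true(pr$lowerBounded && pr$upperBounded)
  expect_lte(pr$lower, 1)
  expect_gte(pr$upper, 1)
  # X2 at the fixed best-fit value differs by 0 < threshold
  expect_lt(min(abs(pr$points$X2 - nf$fit$X2)), pr$threshold)
  # every accepted boundary set stays inside the confidence region
  for (fb in pr$boundarySets)
    expect_lte(unname(objective(fb, nf$problem)) - nf$fit$X2,
               pr$threshold + 1e-6)
})

test_that("halving the measurement sd narrows the profile interval", {
  wide <- noiseFreeChainFit(sd = 0.1)
  narrow <- noiseFreeChainFit(sd = 0.05)
  ctl <- list(reoptEval = 40L, movesPerTemp = 8L, stepFactor = 1.4)
  pw <- profileParameter(wide$problem, wide$fit, "k1", control = ctl, seed = 11L)
  pn <- profileParameter(narrow$problem, narrow$fit, "k1", control = ctl, seed = 11L)
  expect_lt(pn$upper - pn$lower, pw$upper - pw$lower)
})

test_that("the degenerate pair yields an unbounded upper interval for the fast step", {
  toy <- makeToy("degenerate_pair")
  ds <- generateSyntheticDataset(toy$network, toy$params, toy$conditions,
                                 toy$observables, noiseSd = 0, seed = 1L)
  ds$sd <- 0.5
  problem <- fitProblem(toy$network, toy$params, toy$groups, toy$conditions,
                        ds, rtol = 1e-6, atol = 1e-8)
  fit <- structure(list(factors = stats::setNames(c(1, 1), names(toy$groups)),
                        X2 = unname(objective(c(1, 1), problem)),
                        schedule = list(maxEval = 200L)),
                   class = "klFit")
  ctl <- list(reoptEval = 30L, movesPerTemp = 6L, stepFactor = 1.8)
  p2 <- profileParameter(problem, fit, "k2", control = ctl, seed = 21L)
  expect_false(p2$upperBounded)  # flat profile upward: structurally non-identifiable
  p1 <- profileParameter(problem, fit, "k1", control = ctl, seed = 22L)
  expect_true(p1$upperBounded && p1$lowerBounded)
  # brute-force grid confirms the flat direction
  x2grid <- vapply(c(1, 10, 100, 1000), function(f)
    unname(objective(c(1, f), problem)), 0)
  expect_lt(max(x2grid) - min(x2grid), chi2Threshold(0.05))
})

test_that("envelopes contain the best fit, widen monotonically, and collapse without profiles", {
  nf <- noiseFreeChainFit()
  vars <- data.frame(type = c("conc", "flux", "mid"),
                     id = c("C", "r2", "B"),
                     fragment = c("", "", ""),
                     isotopologue_index = c(NA, NA, 1L))
  noProf <- envelopes(nf$problem, nf$fit, list(), "chain3", vars,
                      times = c(0, 30, 60))
  for (v in noProf) {
    expect_equal(v$lower, v$best, tolerance = 1e-12)
    expect_equal(v$upper, v$best, tolerance = 1e-12)
  }
  pr <- profileParameter(nf$problem, nf$fit, "k1",
                         control = list(reoptEval = 30L, movesPerTemp = 6L,
                                        stepFactor = 1.5),
                         seed = 31L)
  one <- envelopes(nf$problem, nf$fit, list(pr), "chain3", vars,
                   times = c(0, 30, 60))
  for (v in one) {
    expect_true(all(v$lower <= v$best + 1e-12))
    expect_true(all(v$upper >= v$best - 1e-12))
  }
  # adding a fabricated parameter set can only widen the band
  prWide <- pr
  prWide$boundarySets <- c(pr$boundarySets,
                           list(stats::setNames(c(1.3, 1, 1), c("k1", "k2", "k3"))))
  two <- envelopes(nf$problem, nf$fit, list(prWide), "chain3", vars,
                   times = c(0, 30, 60))
  for (k in seq_along(one)) {
    expect_true(all(two[[k]]$lower <= one[[k]]$lower + 1e-12))
    expect_true(all(two[[k]]$upper >= one[[k]]$upper - 1e-12))
  }
})
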