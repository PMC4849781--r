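test_that("isotopomer-to-isotopologue conversion bins by 13C count", {
  # all mass at m0
  iso <- c(1, numeric(7))
  expect_equal(as.numeric(toIsotopologues(iso)), c(1, 0, 0, 0))
  # equal mass at masks 0b001 and 0b100 -> m1 = 1
  iso <- numeric(8); iso[c(1 + 1, 4 + 1)] <- 0.5
  expect_equal(as.numeric(toIsotopologues(iso)), c(0, 1, 0, 0))
  # uniform over all 8 masks of a 3-carbon metabolite: binomial counts
  expect_equal(as.numeric(toIsotopologues(uniformIso(3))),
               c(1, 3, 3, 1) / 8)
})

test_that("fragment ranges restrict the popcount to the fragment's carbons", {
  # glucose labelled at C1 and C2 only (mask 3)
  iso <- numeric(64); iso[3 + 1] <- 2.5
  expect_equal(as.numeric(toIsotopologues(iso, c(3, 6)))[1], 1)  # C3-C6: m0 = 1
  midC14 <- toIsotopologues(iso, c(1, 4))
  expect_equal(as.numeric(midC14)[3], 1)                         # C1-C4: m2 = 1
  expect_length(midC14, 5)
  expect_error(toIsotopologues(iso, c(0, 4)), "fragment")
  expect_error(toIsotopologues(iso, c(3, 7)), "fragment")
})

test_that("fragment fractions always sum to 1 and are scale invariant", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    iso <- stats::runif(2^n)
    a <- sample(n, 1); b <- if (a == n) n else sample(a:n, 1)
    mid <- toIsotopologues(iso, c(a, b))
    expect_equal(sum(mid), 1, tolerance = 1e-12)
    expect_true(all(mid >= 0))
    scaled <- toIsotopologues(iso * 17.3, c(a, b))
    expect_equal(as.numeric(mid), as.numeric(scaled), tolerance = 1e-12)
  }
})

test_that("zero totals flag the MID as undefined with m0 = 1", {
  mid <- toIsotopologues(numeric(8))
  expect_true(attr(mid, "undefined"))
  expect_equal(as.numeric(mid), c(1, 0, 0, 0))
})

test_that("sorbitol pools the two hexoses by concentration weight", {
  glc <- c(10, numeric(63))                 # 10 mM unlabelled
  fru <- numeric(64); fru[63 + 1] <- 10     # 10 mM [U-13C6]
  mid <- pooledHexoseMid(glc, fru)
  expect_equal(as.numeric(mid)[c(1, 7)], c(0.5, 0.5))
  # degenerate weight: zero fructose -> sorbitol MID equals the glucose MID
  expect_equal(as.numeric(pooledHexoseMid(glc, numeric(64))),
               as.numeric(toIsotopologues(glc)))
  # the pooled MID is the weighted average of member MIDs
  set.seed(4)
  g <- stats::runif(64); f <- stats::runif(64) * 0.2
  wG <- sum(g) / (sum(g) + sum(f))
  expect_equal(as.numeric(pooledHexoseMid(g, f)),
               wG * as.numeric(toIsotopologues(g)) +
                 (1 - wG) * as.numeric(toIsotopologues(f)),
               tolerance = 1e-12)
  expect_error(pooledHexoseMid(numeric(8), numeric(64)), "6-carbon")
})

test_that("condition A2 media give sorbitol m6 = 1.5/23 at time zero", {
  demo <- makeDemoModel()
  conds <- demoConditions()
  tr <- simulateLabeling(demo$network, demo$params, conds$A2, times = c(0, 1))
  iso <- isotopomersAt(tr, "eGlc", 1) + isotopomersAt(tr, "eFru", 1)
  mid <- toIsotopologues(iso, c(1, 6))
  expect_equal(mid[["m6"]], 1.5 / 23, tolerance = 1e-9)
  expect_equal(mid[["m0"]], 21.5 / 23, tolerance = 1e-9)
})

test_that("observablesAt returns concentrations and normalized fragment MIDs", {
  toy <- makeToy("chain3")
  tr <- simulateLabeling(toy$network, toy$params, toy$conditions[[1]],
                         times = c(0, 60, 120))
  specs <- data.frame(metabolite = c("B", "C", "C", "C"),
                      fragment = c("", "", "C1-C3", "C1-C3"),
                      isotopologue_index = c(NA, NA, 0L, 1L))
  out <- observablesAt(tr, specs, 120)
  expect_equal(out$value[1], tr$concentrations[3, "B"], ignore_attr = TRUE)
  midC <- toIsotopologues(isotopomersAt(tr, "C", 3), c(1, 3))
  expect_equal(out$value[3:4], as.numeric(midC)[1:2])
  expect_error(observablesAt(tr, specs, 33), "output time")
  badMet <- data.frame(metabolite = "nope", fragment = "",
                       isotopologue_index = NA)
  expect_error(observablesAt(tr, badMet, 120), "nope")
  badMid <- data.frame(metabolite = "waste", fragment = "",
                       isotopologue_index = 0L)
  expect_error(observablesAt(tr, badMid, 120), "not labelable")
})
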