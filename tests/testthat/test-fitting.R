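chainProblem <- function(noiseSd = 0, factors = c(1, 1, 1), seed = 5L,
                         rtol = 1e-8, atol = 1e-10) {
  toy <- makeToy("chain3")
  truth <- applyParameterGroups(toy$params, toy$groups,
                                stats::setNames(factors, names(toy$groups)))
  ds <- generateSyntheticDataset(toy$network, truth, toy$conditions,
                                 toy$observables, noiseSd = noiseSd, seed = seed)
  problem <- fitProblem(toy$network, toy$params, toy$groups, toy$conditions,
                        ds, rtol = rtol, atol = atol)
  list(toy = toy, problem = problem, truth = truth, dataset = ds)
}

test_that("objective is zero at the generating parameters for noise-free data", {
  cp <- chainProblem(noiseSd = 0)
  x2 <- objective(c(1, 1, 1), cp$problem)
  expect_lt(x2, 1e-6)
})

test_that("the sigma floor turns sd 0.005 residuals of 0.1 into X2 = 100", {
  cp <- chainProblem(noiseSd = 0)
  ds <- cp$dataset[1, ]
  ds$value <- 1.0; ds$sd <- 0.005
  toy <- cp$toy
  p2 <- fitProblem(toy$network, toy$params, toy$groups, toy$conditions, ds)
  # force the prediction to 0.9 by checking the arithmetic directly:
  sim <- predictedObservables(p2, c(1, 1, 1))
  x2 <- objective(c(1, 1, 1), p2)
  expect_equal(x2, ((1.0 - sim$predicted[1]) / 0.01)^2)
  # and the forced example: Y = 1, Z = 0.9, floored sigma 0.01 -> 100
  expect_equal(((1 - 0.9) / max(0.005, 0.01))^2, 100)
})

test_that("the concentration ceiling rejects runaway parameter sets with +Inf", {
  cp <- chainProblem(noiseSd = 0)
  # k1 x 50, k3 -> tiny: C accumulates past 50 mM within the horizon
  x2 <- objective(c(50, 1, 0.001), cp$problem)
  expect_identical(unname(as.numeric(x2)), Inf)
  expect_match(attr(x2, "cause"), "50")
})

test_that("objective is invariant to measurement order and to Y = Z rows", {
  cp <- chainProblem(noiseSd = 0.01)
  x2 <- objective(c(1.2, 0.9, 1), cp$problem)
  perm <- sample(nrow(cp$dataset))
  pPerm <- fitProblem(cp$toy$network, cp$toy$params, cp$toy$groups,
                      cp$toy$conditions, cp$dataset[perm, ])
  expect_equal(unname(objective(c(1.2, 0.9, 1), pPerm)), unname(x2),
               tolerance = 1e-10)
  # append a measurement that exactly matches the prediction
  pred <- predictedObservables(cp$problem, c(1.2, 0.9, 1))
  extra <- pred[3, ]
  extra$value <- extra$predicted
  extra$predicted <- NULL
  pPlus <- fitProblem(cp$toy$network, cp$toy$params, cp$toy$groups,
                      cp$toy$conditions, rbind(cp$dataset, extra))
  expect_equal(unname(objective(c(1.2, 0.9, 1), pPlus)), unname(x2),
               tolerance = 1e-8)
})

test_that("a zero-iteration anneal returns the initial point", {
  cp <- chainProblem(noiseSd = 0.01)
  fit <- fitAnneal(cp$problem, schedule = list(maxEval = 0L), seed = 1L)
  expect_equal(unname(fit$factors), c(1, 1, 1))
  expect_equal(fit$X2, unname(objective(c(1, 1, 1), cp$problem)))
  expect_equal(fit$evaluations, 1L)
})

test_that("annealing runs are bit-identical under the same seed", {
  cp <- chainProblem(noiseSd = 0.01, rtol = 1e-6, atol = 1e-8)
  f1 <- fitAnneal(cp$problem, schedule = list(maxEval = 60L, movesPerTemp = 10L),
                  seed = 7L)
  f2 <- fitAnneal(cp$problem, schedule = list(maxEval = 60L, movesPerTemp = 10L),
                  seed = 7L)
  expect_identical(f1, f2)
  f3 <- fitAnneal(cp$problem, schedule = list(maxEval = 60L, movesPerTemp = 10L),
                  seed = 8L)
  expect_false(identical(f1$factors, f3$factors))
})

test_that("annealing recovers parameters on a noisy chain and never ends worse than truth", {
  cp <- chainProblem(noiseSd = 0.01, factors = c(1.4, 0.7, 1.1),
                     rtol = 1e-6, atol = 1e-8)
  fit <- fitAnneal(cp$problem, schedule = list(maxEval = 2500L, movesPerTemp = 20L,
                                               moveScale = 0.35, cooling = 0.85,
                                               TminFrac = 1e-12),
                   seed = 2L)
  trueFactors <- c(1.4, 0.7, 1.1)
  x2AtTruth <- objective(trueFactors, cp$problem)
  expect_lte(fit$X2, unname(x2AtTruth) + 1e-6)
  expect_equal(unname(fit$factors), trueFactors, tolerance = 0.25)
})

test_that("noise-free recovery drives X2 to near zero from a wrong start", {
  cp <- chainProblem(noiseSd = 0, factors = c(1.3, 0.8, 1.0),
                     rtol = 1e-8, atol = 1e-10)
  fit <- fitAnneal(cp$problem, schedule = list(maxEval = 4000L, movesPerTemp = 20L,
                                               moveScale = 0.3, cooling = 0.85,
                                               TminFrac = 1e-14),
                   seed = 3L)
  expect_lt(fit$X2, 1e-3)
})
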