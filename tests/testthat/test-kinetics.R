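test_that("irreversible Michaelis-Menten is half-maximal at Km", {
  comp <- list(Compartment("c", volume = 1))
  mets <- list(Metabolite("S", compartment = "c", initialConcentration = 1),
               Metabolite("P", compartment = "c"))
  net <- Network(comp, mets, list(
    Reaction("r", substrates = c(S = 1), products = c(P = 1),
             law = rateLaw("michaelis", params = c(Vmax = "V", Km.S = "K")))),
    ncell = 1)
  fl <- evaluateFluxes(net, c(S = 2, P = 0), params = c(V = 10, K = 2))
  expect_equal(fl$forward, 5)
  expect_equal(fl$reverse, 0)
  # zero substrate -> zero rate; mass-action-like behaviour at the origin
  expect_equal(evaluateFluxes(net, c(S = 0, P = 0), c(V = 10, K = 2))$forward, 0)
})

test_that("Haldane relationship fixes the reverse capacity", {
  expect_equal(haldaneReverseCapacity(1, 1, 1, 1), 1)
  expect_equal(haldaneReverseCapacity(2, 4, 1, 2), 1)
  expect_error(haldaneReverseCapacity(1, 0, 1, 1), "Keq")
  expect_error(haldaneReverseCapacity(1, -2, 1, 1), "Keq")
})

test_that("Haldane-constrained reversible law has zero net flux exactly at equilibrium", {
  tm <- twoMetNet()
  net <- tm$net
  net$reactions$r1$law <- rateLaw("michaelisRev",
                                  params = c(Vmax = "V", Ks.A = "KA", Kp.B = "KB", Keq = "Keq"))
  net$reactions$r1$reversible <- TRUE
  params <- c(V = 3, KA = 0.7, KB = 1.3, Keq = 2.5)
  set.seed(1)
  for (i in 1:25) {
    A <- stats::runif(1, 0.01, 20)
    fl <- evaluateFluxes(net, c(A = A, B = params[["Keq"]] * A), params)
    expect_equal(fl$net, 0, tolerance = 1e-12)
    # off equilibrium the net flux points downhill
    flLow <- evaluateFluxes(net, c(A = A, B = 0.5 * params[["Keq"]] * A), params)
    expect_gt(flLow$net, 0)
  }
})

test_that("rate laws are homogeneous in capacity", {
  demo <- makeDemoModel()
  conc <- kinlabel:::defaultInitialState(demo$network)
  caps <- grep("\\.(Vmax|k|kr)$", names(demo$params), value = TRUE)
  p2 <- demo$params
  p2[caps] <- 2 * p2[caps]
  f1 <- evaluateFluxes(demo$network, conc, demo$params)
  f2 <- evaluateFluxes(demo$network, conc, p2)
  expect_equal(f2$forward, 2 * f1$forward, tolerance = 1e-12)
  expect_equal(f2$reverse, 2 * f1$reverse, tolerance = 1e-12)
})

test_that("flux evaluation is deterministic and rejects unknown symbols", {
  tm <- twoMetNet()
  f1 <- evaluateFluxes(tm$net, c(A = 1.5, B = 0.5), tm$params)
  f2 <- evaluateFluxes(tm$net, c(A = 1.5, B = 0.5), tm$params)
  expect_identical(f1, f2)
  expect_error(evaluateFluxes(tm$net, c(A = 1, B = 1), c(wrong = 1)),
               "r1.k")
  net <- tm$net
  net$reactions$r1$law <- rateLaw("expression", forward = "k * A / B")
  expect_error(evaluateFluxes(net, c(A = 1, B = 0), c(k = 1)), "r1")
})

test_that("parameter groups apply factors times relative weights", {
  groups <- parameterGroups(list(lower = c(gapdh = 1, pgk = 2)))
  params <- c(gapdh = 9, pgk = 9, other = 7)
  out <- applyParameterGroups(params, groups, c(lower = 3))
  expect_equal(out[["gapdh"]], 3)
  expect_equal(out[["pgk"]], 6)
  expect_equal(out[["other"]], 7)
  # factor 0 silences the chain
  expect_equal(unname(applyParameterGroups(params, groups, 0)[c("gapdh", "pgk")]),
               c(0, 0))
})

test_that("group application order is irrelevant and membership is exclusive", {
  g <- parameterGroups(list(a = c(p1 = 1), b = c(p2 = 2)))
  params <- c(p1 = 0, p2 = 0)
  out1 <- applyParameterGroups(params, g, c(a = 2, b = 3))
  out2 <- applyParameterGroups(params, g[2:1], c(b = 3, a = 2))
  expect_equal(out1[sort(names(out1))], out2[sort(names(out2))])
  expect_error(parameterGroups(list(a = c(p1 = 1), b = c(p1 = 2))),
               "more than one group")
  expect_error(applyParameterGroups(params, g, 1), "factors")
})
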