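test_that("the demo model builds validated with the expected content", {
  demo <- makeDemoModel()
  net <- demo$network
  expect_equal(length(net$compartments), 3L)
  expect_equal(nrow(validateAtomMaps(net)), 0L)
  for (id in c("glctr", "gka", "gkb", "g6pasea", "g6paseb", "gpia", "gpib",
               "pfka", "pfkb", "fbasea", "fbaseb", "aldo1", "aldo2", "aldo3",
               "tim", "frutr", "fruhk", "trik", "gapdh", "pgk", "pgm", "eno",
               "pk", "ldh", "lactr", "pglm", "gs", "gp", "atpase", "adk",
               "ppase", "pitr", "antr", "oxphos"))
    expect_true(id %in% names(net$reactions), info = id)
  for (id in c("eGlc", "eFru", "Glyc", "eLac"))
    expect_true(net$metabolites[[id]]$labelable, info = id)
  # group factors at 1 reproduce the default parameters
  p1 <- applyParameterGroups(demo$params, demo$groups,
                             rep(1, length(demo$groups)))
  expect_equal(p1, demo$params)
  expect_error(makeDemoModel(c(nonsense = 1)), "unknown parameter")
})

test_that("conditions A1 and A2 differ only in the labelling pattern", {
  conds <- demoConditions()
  expect_equal(conds$A1$initial, conds$A2$initial)
  expect_equal(conds$A1$tEnd, conds$A2$tEnd)
  expect_false(identical(conds$A1$tracer, conds$A2$tracer))
  # A1: 20 mM glucose, half [1,2-13C2] -> 10 mM at mask 3, 10 mM at mask 0
  demo <- makeDemoModel()
  mA1 <- buildJointOdes(demo$network, demo$params, conds$A1)
  isoG <- mA1$y0[mA1$isoOffset$eGlc + 1:64]
  expect_equal(unname(isoG[3 + 1]), 10)
  expect_equal(unname(isoG[0 + 1]), 10)
  expect_equal(sum(isoG), 20)
  # A2: 3 mM fructose, half [U-13C6] -> 1.5 mM at mask 63, 1.5 at mask 0
  mA2 <- buildJointOdes(demo$network, demo$params, conds$A2)
  isoF <- mA2$y0[mA2$isoOffset$eFru + 1:64]
  expect_equal(unname(isoF[63 + 1]), 1.5)
  expect_equal(unname(isoF[0 + 1]), 1.5)
  expect_equal(sum(isoF), 3)
})

test_that("cytosolic adenine and total phosphate moieties are conserved", {
  demo <- makeDemoModel()
  tr <- simulateConcentrations(demo$network, demo$params, demoConditions()$B,
                               times = seq(0, 120, 10))
  conc <- tr$concentrations
  aden <- rowSums(conc[, c("cATP", "cADP", "cAMP")])
  expect_lt(diff(range(aden)) / aden[1], 1e-7)
  # phosphate: weight each pool by its phosphate count, in moles (conc * vol)
  pCount <- c(cATP = 3, cADP = 2, cAMP = 1, cPi = 1, cPPi = 2,
              G6Pa = 1, G6Pb = 1, F6Pa = 1, F6Pb = 1, FBPa = 2, FBPb = 2,
              F1P = 1, G1P = 1, DHAP = 1, GAP = 1, BPG = 2, PG3 = 1,
              PG2 = 1, PEP = 1, mATP = 3, mADP = 2, mPi = 1)
  vols <- vapply(names(pCount),
                 function(id) kinlabel:::compartmentVolume(demo$network, id), 0)
  phos <- as.vector(conc[, names(pCount)] %*% (pCount * vols))
  expect_lt(diff(range(phos)) / phos[1], 1e-7)
})

test_that("high fructose depletes ATP and phosphate, suppresses glycogen and label flow", {
  demo <- makeDemoModel()
  conds <- demoConditions()
  trA <- simulateLabeling(demo$network, demo$params, conds$A1,
                          times = c(0, 60, 120), rtol = 1e-6, atol = 1e-8)
  trB <- simulateLabeling(demo$network, demo$params, conds$B,
                          times = c(0, 60, 120), rtol = 1e-6, atol = 1e-8)
  a <- trA$concentrations[3, ]; b <- trB$concentrations[3, ]
  expect_lt(b[["cATP"]], a[["cATP"]])
  expect_lt(b[["cATP"]], trB$concentrations[1, "cATP"])  # drop below t = 0
  expect_lt(b[["cPi"]], a[["cPi"]])
  expect_gt(b[["F1P"]], a[["F1P"]])
  expect_gt(b[["F1P"]], trA$concentrations[1, "F1P"])
  expect_lt(b[["Glyc"]], a[["Glyc"]])
  m2A <- toIsotopologues(isotopomersAt(trA, "eLac"))[["m2"]]
  m2B <- toIsotopologues(isotopomersAt(trB, "eLac"))[["m2"]]
  expect_lt(m2B, m2A)
})

test_that("toy networks have their designed structure", {
  ch <- makeToy("chain3")
  expect_length(ch$network$reactions, 3L)
  expect_equal(names(ch$groups), c("k1", "k2", "k3"))
  lo <- makeToy("loop_exchange")
  expect_true(any(vapply(lo$network$reactions, `[[`, TRUE, "invisible")))
  sy <- makeToy("symmetric_krebs_stub")
  expect_equal(sy$network$symmetricMetabolites, "S")
  dg <- makeToy("degenerate_pair")
  expect_length(dg$groups, 2L)
  expect_error(makeToy("nope"))
})

test_that("synthetic datasets are reproducible, noise-free at sd 0, and honestly noisy", {
  toy <- makeToy("chain3")
  d1 <- generateSyntheticDataset(toy$network, toy$params, toy$conditions,
                                 toy$observables, noiseSd = 0.01, seed = 9L)
  d2 <- generateSyntheticDataset(toy$network, toy$params, toy$conditions,
                                 toy$observables, noiseSd = 0.01, seed = 9L)
  expect_identical(d1, d2)
  mid <- !is.na(d1$isotopologue_index)
  expect_true(all(d1$sd[mid] == 0.01))
  expect_equal(d1$sd[!mid], pmax(0.01 * abs(d1$value[!mid]), 0.01),
               tolerance = 0.05)
  expect_true(all(d1$value[mid] >= 0 & d1$value[mid] <= 1))
  # replicate noise has roughly the requested scale
  reps <- vapply(1:12, function(s)
    generateSyntheticDataset(toy$network, toy$params, toy$conditions,
                             toy$observables, noiseSd = 0.01, seed = s)$value[1],
    0)
  emp <- stats::sd(reps)
  expect_gt(emp, 0.01 / 3)
  expect_lt(emp, 0.01 * 3)
})

test_that("the shipped native config files match the in-code constructors", {
  demo <- makeDemoModel()
  dir <- system.file("extdata", "demo", package = "kinlabel")
  net <- readNetwork(file.path(dir, "network.yaml"),
                     atomMapFile = file.path(dir, "atom_maps.tsv"))
  N1 <- stoichiometricMatrix(demo$network)
  expect_equal(stoichiometricMatrix(net)[rownames(N1), colnames(N1)], N1)
  expect_equal(readParameters(file.path(dir, "parameters.tsv")), demo$params)
  conds <- readConditions(file.path(dir, "conditions.yaml"))
  expect_equal(names(conds), c("A1", "A2", "B"))
  expect_equal(conds$B$initial[["eFru"]], 20)
  ds <- readMeasurements(file.path(dir, "synthetic_measurements.tsv"))
  expect_true(all(c("A1", "A2", "B") %in% ds$condition_id))
  toyDir <- system.file("extdata", "toys", "chain3", package = "kinlabel")
  toy <- makeToy("chain3")
  netT <- readNetwork(file.path(toyDir, "network.yaml"),
                      atomMapFile = file.path(toyDir, "atom_maps.tsv"))
  expect_equal(stoichiometricMatrix(netT)[c("A", "B", "C", "waste"), ],
               stoichiometricMatrix(toy$network))
})
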