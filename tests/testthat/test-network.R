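test_that("a two-metabolite network builds and yields the expected stoichiometry", {
  tm <- twoMetNet(n = 3L)
  expect_s3_class(tm$net, "klNetwork")
  expect_length(tm$net$reactions, 1L)
  expect_length(tm$net$metabolites, 2L)
  N <- stoichiometricMatrix(tm$net)
  expect_equal(unname(N[, "r1"]), c(-1, 1))
  expect_equal(dimnames(N), list(c("A", "B"), "r1"))
})

test_that("validation rejects unresolved references, duplicates and bad stoichiometry", {
  comp <- list(Compartment("c", volume = 1))
  metA <- Metabolite("A", compartment = "c", nCarbons = 3L)
  law <- rateLaw("massAction", params = c(k = "k"))
  expect_error(
    Network(comp, list(metA),
            list(Reaction("r1", substrates = c(A = 1), products = c(X = 1), law = law)),
            ncell = 1),
    "X")
  expect_error(
    Network(comp, list(metA, Metabolite("A", compartment = "c")),
            list(), ncell = 1),
    "duplicate metabolite")
  expect_error(Reaction("r1", substrates = c(A = 0.5), products = c(B = 1)),
               "fractional")
  expect_error(Compartment("c", volume = -1), "volume")
  expect_error(Metabolite("A", compartment = "c", nCarbons = 0L, labelable = TRUE),
               "at least one carbon")
  expect_error(
    Network(comp, list(Metabolite("A", compartment = "c", constant = TRUE,
                                  initialConcentration = 1)),
            list(), ncell = 1),
    "non-constant")
})

test_that("constant metabolites and invisible reactions zero out the stoichiometric matrix", {
  comp <- list(Compartment("c", volume = 1))
  mets <- list(Metabolite("A", compartment = "c", nCarbons = 3L, constant = TRUE,
                          initialConcentration = 1),
               Metabolite("B", compartment = "c", nCarbons = 3L, initialConcentration = 1),
               Metabolite("C", compartment = "c", nCarbons = 3L, initialConcentration = 1))
  rxns <- list(
    Reaction("r1", substrates = c(A = 1), products = c(B = 1),
             atomMap = atomMap(rep(1, 3), 1:3, rep(1, 3), 1:3),
             law = rateLaw("massAction", params = c(k = "k"))),
    Reaction("x1", substrates = c(B = 1), products = c(C = 1), invisible = TRUE,
             atomMap = atomMap(rep(1, 3), 1:3, rep(1, 3), 1:3),
             law = rateLaw("exchange", params = c(k = "kx"))))
  net <- Network(comp, mets, rxns, ncell = 1)
  N <- stoichiometricMatrix(net)
  expect_equal(unname(N["A", ]), c(0, 0))      # constant row zeroed
  expect_equal(unname(N[, "x1"]), c(0, 0, 0))  # invisible column zeroed
  expect_gt(nrow(net$reactions$x1$atomMap), 0) # while its atom map is non-empty
})

test_that("atom map validation accepts the aldolase cleavage and flags gaps", {
  comp <- list(Compartment("c", volume = 1))
  mets <- list(Metabolite("F16BP", compartment = "c", nCarbons = 6L, initialConcentration = 1),
               Metabolite("DHAP", compartment = "c", nCarbons = 3L),
               Metabolite("GAP", compartment = "c", nCarbons = 3L))
  fullMap <- atomMap(rep(1, 6), 1:6, c(1, 1, 1, 2, 2, 2), c(3, 2, 1, 1, 2, 3))
  mkNet <- function(map) Network(comp, mets, list(
    Reaction("aldo", substrates = c(F16BP = 1), products = c(DHAP = 1, GAP = 1),
             atomMap = map, law = rateLaw("massAction", params = c(k = "k")))),
    ncell = 1)
  expect_equal(nrow(validateAtomMaps(mkNet(fullMap))), 0L)
  # omit F16BP C6 -> unmapped substrate carbon and unfilled product carbon
  rep6 <- validateAtomMaps(mkNet(fullMap[-6, ]))
  expect_true(any(grepl("unmapped substrate carbon: F16BP C6", rep6$problem)))
})

test_that("decarboxylation bookkeeping allows carbons routed to a non-labelable sink", {
  comp <- list(Compartment("c", volume = 1))
  mets <- list(Metabolite("Pyr", compartment = "c", nCarbons = 3L, initialConcentration = 1),
               Metabolite("CO2", compartment = "c", nCarbons = 1L, labelable = FALSE),
               Metabolite("ACoA", compartment = "c", nCarbons = 2L))
  pdhMap <- atomMap(c(1, 1, 1), c(1, 2, 3), c(1, 2, 2), c(1, 1, 2))
  net <- Network(comp, mets, list(
    Reaction("pdh", substrates = c(Pyr = 1), products = c(CO2 = 1, ACoA = 1),
             atomMap = pdhMap, law = rateLaw("massAction", params = c(k = "k")))),
    ncell = 1)
  expect_equal(nrow(validateAtomMaps(net)), 0L)
  # dropping the C1 -> CO2 route leaves an unmapped substrate carbon
  net$reactions$pdh$atomMap <- pdhMap[-1, ]
  rep1 <- validateAtomMaps(net)
  expect_true(any(grepl("unmapped substrate carbon: Pyr C1", rep1$problem)))
})

test_that("carbon balance holds for every shipped network's atom maps", {
  nets <- c(list(makeDemoModel()$network),
            lapply(c("chain3", "loop_exchange", "symmetric_krebs_stub",
                     "degenerate_pair"), function(nm) makeToy(nm)$network))
  for (net in nets) {
    expect_equal(nrow(validateAtomMaps(net)), 0L, info = net$name)
    for (r in net$reactions) {
      if (is.null(r$atomMap)) next
      st <- kinlabel:::slotTable(net, r, "substrates")
      nSubCarbons <- sum(st$nCarbons[st$labelable])
      expect_equal(nrow(r$atomMap), nSubCarbons,
                   info = paste(net$name, r$id))
    }
  }
})
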