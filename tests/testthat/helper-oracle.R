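# Molecule-level Monte Carlo oracle for label propagation, independent of the
# isotopomer ODE machinery: every labelable pool is an explicit bag of
# molecules carrying 13C bitmasks; at each time step the deterministic
# reaction rates convert a Poisson-drawn number of randomly sampled
# molecules, routing their carbons through the atom map. Only the rate
# evaluation (which depends on totals, not labels) is shared with the
# package.

mcLabelOracle <- function(net, params, condition, tEnd, dt = 0.05,
                          molPerMM = 4e4, seed = 42L) {
  set.seed(seed)
  mids <- names(net$metabolites)
  lab <- vapply(net$metabolites, `[[`, TRUE, "labelable")
  constant <- vapply(net$metabolites, `[[`, TRUE, "constant")
  init <- stats::setNames(vapply(net$metabolites, `[[`, 0, "initialConcentration"), mids)
  if (length(condition$initial)) init[names(condition$initial)] <- condition$initial
  vol <- vapply(mids, function(i) kinlabel:::compartmentVolume(net, i), 0)

  drawTracer <- function(id, k) {
    tr <- condition$tracer[[id]]
    if (is.null(tr)) return(integer(k))
    tr$mask[sample.int(nrow(tr), k, replace = TRUE, prob = tr$fraction)]
  }
  symmetrize <- function(id, masks) {
    if (!(id %in% net$symmetricMetabolites)) return(masks)
    n <- net$metabolites[[id]]$nCarbons
    flip <- stats::runif(length(masks)) < 0.5
    masks[flip] <- kinlabel:::reverseBits(masks[flip], n)
    masks
  }
  # molecule pools (labelable only); counts in molecules = conc * vol-free
  # scaling (toys are single unit-volume compartments)
  pools <- list()
  for (id in mids[lab]) {
    k <- round(init[[id]] * molPerMM)
    pools[[id]] <- symmetrize(id, drawTracer(id, k))
  }
  conc <- init

  N <- stoichiometricMatrix(net)
  scale <- net$ncell / vol
  nStep <- ceiling(tEnd / dt)
  for (step in seq_len(nStep)) {
    rates <- evaluateFluxes(net, conc, params)
    for (ri in seq_len(nrow(rates))) {
      rxn <- net$reactions[[ri]]
      if (is.null(rxn$atomMap)) next
      dirs <- if (rxn$reversible || rxn$invisible) 1:2 else 1L
      for (d in dirs) {
        J <- if (d == 1L) rates$forward[ri] else rates$reverse[ri]
        if (J <= 0) next
        if (d == 1L) {
          st <- kinlabel:::slotTable(net, rxn, "substrates")
          pt <- kinlabel:::slotTable(net, rxn, "products")
          map <- rxn$atomMap
        } else {
          st <- kinlabel:::slotTable(net, rxn, "products")
          pt <- kinlabel:::slotTable(net, rxn, "substrates")
          map <- data.frame(subSlot = rxn$atomMap$prodSlot,
                            subCarbon = rxn$atomMap$prodCarbon,
                            prodSlot = rxn$atomMap$subSlot,
                            prodCarbon = rxn$atomMap$subCarbon)
        }
        nConv <- stats::rpois(1L, J * net$ncell * molPerMM * dt)
        # cap events at the scarcest participating pool before sampling
        for (s in seq_len(nrow(st)))
          if (st$labelable[s] && !constant[[st$metabolite[s]]])
            nConv <- min(nConv, length(pools[[st$metabolite[s]]]))
        if (nConv == 0L) next
        # sample one molecule per labelable substrate slot, per event
        subMasks <- vector("list", nrow(st))
        for (s in seq_len(nrow(st))) {
          id <- st$metabolite[s]
          if (!st$labelable[s]) next
          if (constant[[id]]) {
            subMasks[[s]] <- drawTracer(id, nConv)
          } else {
            idx <- sample.int(length(pools[[id]]), nConv)
            subMasks[[s]] <- pools[[id]][idx]
            pools[[id]] <- pools[[id]][-idx]
          }
        }
        prodMasks <- matrix(0L, nConv, nrow(pt))
        for (e in seq_len(nrow(map))) {
          s <- map$subSlot[e]; p <- map$prodSlot[e]
          if (!st$labelable[s] || !pt$labelable[p]) next
          bit <- bitwAnd(bitwShiftR(subMasks[[s]], map$subCarbon[e] - 1L), 1L)
          prodMasks[, p] <- bitwOr(prodMasks[, p], bitwShiftL(bit, map$prodCarbon[e] - 1L))
        }
        for (p in seq_len(nrow(pt))) {
          id <- pt$metabolite[p]
          if (!pt$labelable[p] || constant[[id]]) next
          pools[[id]] <- c(pools[[id]], symmetrize(id, prodMasks[, p]))
        }
      }
    }
    # advance totals deterministically (Euler on the same rates)
    conc <- pmax(conc + as.vector(N %*% rates$net) * scale * dt, 0)
    # keep pool-derived totals in sync for labelable non-constant species
    for (id in mids[lab & !constant]) conc[[id]] <- length(pools[[id]]) / molPerMM
  }
  list(pools = pools, conc = conc,
       mid = function(id, fragment = NULL) {
         n <- net$metabolites[[id]]$nCarbons
         counts <- tabulate(pools[[id]] + 1L, nbins = 2^n)
         toIsotopologues(counts, fragment)
       },
       nMolecules = vapply(pools, length, 0L))
}
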