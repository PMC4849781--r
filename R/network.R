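#' Define a compartment
#'
#' A compartment is a well-mixed volume (extracellular medium, cytosol,
#' mitochondrial matrix, ...). Volumes enter the ODE right-hand side as the
#' `ncell/vol` scaling that converts per-cell fluxes (mmol cell^-1 min^-1)
#' into concentration derivatives (mM min^-1).
#'
#' @param id Short unique identifier.
#' @param name Human-readable name.
#' @param volume Compartment volume in litres (must be positive).
#' @return An object of class `klCompartment`.
#' @export
Compartment <- function(id, name = id, volume) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(volume) || length(volume) != 1L || !is.finite(volume) || volume <= 0)
    stop("compartment '", id, "': volume must be a positive finite number (litres)")
  structure(list(id = id, name = name, volume = as.numeric(volume)),
            class = "klCompartment")
}

#' Define a metabolite
#'
#' @param id Short unique identifier.
#' @param name Human-readable name.
#' @param compartment Id of the compartment the metabolite lives in.
#' @param nCarbons Number of carbon atoms tracked for labelling (0 for
#'   species whose carbons are never labelled, e.g. cofactors).
#' @param labelable Whether 13C isotopomers are simulated for this species.
#'   Defaults to `nCarbons > 0`.
#' @param constant If `TRUE` the concentration is held fixed during
#'   integration (boundary/medium species declared constant).
#' @param initialConcentration Default initial concentration in mM.
#' @return An object of class `klMetabolite`.
#' @export
Metabolite <- function(id, name = id, compartment, nCarbons = 0L,
                       labelable = nCarbons > 0L, constant = FALSE,
                       initialConcentration = 0) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  nCarbons <- as.integer(nCarbons)
  if (is.na(nCarbons) || nCarbons < 0L)
    stop("metabolite '", id, "': nCarbons must be a non-negative integer")
  if (labelable && nCarbons < 1L)
    stop("metabolite '", id, "': labelable species need at least one carbon")
  if (!is.numeric(initialConcentration) || initialConcentration < 0)
    stop("metabolite '", id, "': initial concentration must be >= 0 mM")
  structure(list(id = id, name = name, compartment = compartment,
                 nCarbons = nCarbons, labelable = isTRUE(labelable),
                 constant = isTRUE(constant),
                 initialConcentration = as.numeric(initialConcentration)),
            class = "klMetabolite")
}

#' Define a reaction
#'
#' Substrates and products are named integer vectors mapping metabolite ids to
#' stoichiometric coefficients (small positive integers; atom maps require
#' integer molecule counts). Reversible reactions carry kinetic laws with both
#' a forward and a reverse rate. Invisible reactions exchange label between
#' pools without changing any total concentration: they contribute an all-zero
#' stoichiometric column but still carry an atom map and an exchange rate law.
#'
#' @param id Short unique identifier.
#' @param name Human-readable name.
#' @param substrates,products Named integer vectors (metabolite id -> coefficient).
#' @param reversible Logical.
#' @param invisible Logical; label-only exchange reaction.
#' @param atomMap A data frame from [atomMap()], or `NULL` when no labelable
#'   species participates.
#' @param law A rate law from [rateLaw()].
#' @return An object of class `klReaction`.
#' @export
Reaction <- function(id, name = id, substrates, products = numeric(0),
                     reversible = FALSE, invisible = FALSE,
                     atomMap = NULL, law = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  checkStoich <- function(v, side) {
    if (length(v) == 0L) return(numeric(0))
    if (is.null(names(v)) || any(!nzchar(names(v))))
      stop("reaction '", id, "': ", side, " must be a named vector")
    if (any(v <= 0) || any(v != round(v)))
      stop("reaction '", id, "': fractional or non-positive stoichiometry in ",
           side, " is not supported (atom maps require integer molecule counts)")
    stats::setNames(as.numeric(v), names(v))
  }
  structure(list(id = id, name = name,
                 substrates = checkStoich(substrates, "substrates"),
                 products = checkStoich(products, "products"),
                 reversible = isTRUE(reversible), invisible = isTRUE(invisible),
                 atomMap = atomMap, law = law),
            class = "klReaction")
}

#' Build a carbon atom-transition map
#'
#' Entries map 1-based carbon positions of substrate molecule slots to carbon
#' positions of product molecule slots. Slot `k` denotes the k-th molecule in
#' the expanded substrate (or product) list, counting stoichiometric copies,
#' in the order the reaction declares them. Carbon positions follow
#' biochemical numbering (C1 is the carbonyl end of sugars). Carbons that
#' leave to a non-labelable species (e.g. the CO2 of a decarboxylation) are
#' mapped to that species' slot; bijectivity is enforced only over labelable
#' species.
#'
#' @param subSlot,subCarbon,prodSlot,prodCarbon Equal-length integer vectors.
#' @return A data frame of class `klAtomMap`.
#' @export
atomMap <- function(subSlot, subCarbon, prodSlot, prodCarbon) {
  m <- data.frame(subSlot = as.integer(subSlot), subCarbon = as.integer(subCarbon),
                  prodSlot = as.integer(prodSlot), prodCarbon = as.integer(prodCarbon))
  if (any(m < 1L)) stop("atom map slots and carbon positions are 1-based")
  class(m) <- c("klAtomMap", "data.frame")
  m
}

#' Assemble a metabolic network
#'
#' @param compartments List of [Compartment()] objects.
#' @param metabolites List of [Metabolite()] objects.
#' @param reactions List of [Reaction()] objects.
#' @param ncell Cell number (positive; scales per-cell fluxes to
#'   concentration changes together with compartment volumes).
#' @param symmetricMetabolites Character vector of metabolite ids whose carbon
#'   skeleton is rotationally symmetric (e.g. succinate, fumarate); label
#'   produced into these pools is split 50/50 between the two orientations.
#' @param name Optional model name.
#' @return A validated object of class `klNetwork`.
#' @export
Network <- function(compartments, metabolites, reactions, ncell,
                    symmetricMetabolites = character(0), name = "model") {
  net <- structure(list(name = name,
                        compartments = stats::setNames(compartments, vapply(compartments, `[[`, "", "id")),
                        metabolites = stats::setNames(metabolites, vapply(metabolites, `[[`, "", "id")),
                        reactions = stats::setNames(reactions, vapply(reactions, `[[`, "", "id")),
                        ncell = as.numeric(ncell),
                        symmetricMetabolites = symmetricMetabolites),
                   class = "klNetwork")
  validateNetwork(net)
  net
}

#' @export
print.klNetwork <- function(x, ...) {
  cat(sprintf("klNetwork '%s': %d reactions, %d metabolites, %d compartments, ncell = %g\n",
              x$name, length(x$reactions), length(x$metabolites),
              length(x$compartments), x$ncell))
  nlab <- sum(vapply(x$metabolites, `[[`, TRUE, "labelable"))
  ninv <- sum(vapply(x$reactions, `[[`, TRUE, "invisible"))
  cat(sprintf("  labelable metabolites: %d; invisible reactions: %d\n", nlab, ninv))
  invisible(x)
}

#' Validate a network
#'
#' Checks that all references resolve, ids are unique, volumes are positive,
#' ncell is positive and there is at least one non-constant metabolite.
#' Called by [Network()]; exported for use after programmatic edits.
#'
#' @param net A `klNetwork`.
#' @return Invisibly `TRUE`; stops with the offending element named otherwise.
#' @export
validateNetwork <- function(net) {
  cids <- vapply(net$compartments, `[[`, "", "id")
  mids <- vapply(net$metabolites, `[[`, "", "id")
  rids <- vapply(net$reactions, `[[`, "", "id")
  for (nm in list(c("compartment", cids), c("metabolite", mids), c("reaction", rids))) {
    dup <- unique(nm[-1][duplicated(nm[-1])])
    if (length(dup)) stop("duplicate ", nm[1], " id(s): ", paste(dup, collapse = ", "))
  }
  if (!is.finite(net$ncell) || net$ncell <= 0) stop("ncell must be positive")
  for (m in net$metabolites)
    if (!m$compartment %in% cids)
      stop("metabolite '", m$id, "' references unknown compartment '", m$compartment, "'")
  for (r in net$reactions) {
    for (id in names(c(r$substrates, r$products)))
      if (!id %in% mids)
        stop("reaction '", r$id, "' references unknown metabolite '", id, "'")
    if (r$reversible && !r$invisible && !is.null(r$law) && !lawHasReverse(r$law))
      stop("reaction '", r$id, "' is reversible but its rate law defines no reverse rate")
  }
  bad <- setdiff(net$symmetricMetabolites, mids)
  if (length(bad)) stop("symmetric metabolite(s) not in network: ", paste(bad, collapse = ", "))
  if (!any(!vapply(net$metabolites, `[[`, TRUE, "constant")))
    stop("network needs at least one non-constant metabolite")
  invisible(TRUE)
}

#' Stoichiometric matrix
#'
#' Entry (i, r) is the product minus substrate coefficient of metabolite i in
#' reaction r. Rows of constant (boundary) metabolites are zeroed and
#' invisible (label-only exchange) reactions contribute an all-zero column,
#' so `N %*% j` gives total-concentration changes directly.
#'
#' @param net A `klNetwork`.
#' @return A dense numeric matrix (metabolites x reactions) with dimnames.
#' @export
stoichiometricMatrix <- function(net) {
  mids <- names(net$metabolites)
  rids <- names(net$reactions)
  N <- matrix(0, length(mids), length(rids), dimnames = list(mids, rids))
  for (r in net$reactions) {
    if (r$invisible) next
    for (id in names(r$substrates)) N[id, r$id] <- N[id, r$id] - r$substrates[[id]]
    for (id in names(r$products))  N[id, r$id] <- N[id, r$id] + r$products[[id]]
  }
  const <- vapply(net$metabolites, `[[`, TRUE, "constant")
  N[const, ] <- 0
  N
}

# Expanded molecule slots of one side of a reaction: one row per molecule copy.
# Slot numbering counts stoichiometric copies in declaration order.
slotTable <- function(net, rxn, side = c("substrates", "products")) {
  side <- match.arg(side)
  v <- rxn[[side]]
  if (length(v) == 0L)
    return(data.frame(slot = integer(0), metabolite = character(0),
                      nCarbons = integer(0), labelable = logical(0)))
  ids <- rep(names(v), times = v)
  data.frame(slot = seq_along(ids), metabolite = ids,
             nCarbons = vapply(ids, function(i) net$metabolites[[i]]$nCarbons, 0L),
             labelable = vapply(ids, function(i) net$metabolites[[i]]$labelable, TRUE),
             row.names = NULL)
}

#' Validate the carbon atom-transition maps of a network
#'
#' For every reaction carrying an atom map, checks that each carbon of each
#' labelable substrate molecule is mapped exactly once, that each carbon of
#' each labelable product molecule receives exactly one mapping from a
#' declared source, and that slot/carbon indices are within range. Carbons
#' routed to non-labelable species (decarboxylation sinks) are allowed and
#' excluded from the bijection. Report-only: an empty report means all maps
#' are valid.
#'
#' @param net A `klNetwork`.
#' @return A data frame (reaction, problem) of violations; zero rows iff valid.
#' @export
validateAtomMaps <- function(net) {
  out <- list()
  note <- function(rid, msg) out[[length(out) + 1L]] <<- data.frame(reaction = rid, problem = msg)
  for (r in net$reactions) {
    if (is.null(r$atomMap)) next
    st <- slotTable(net, r, "substrates")
    pt <- slotTable(net, r, "products")
    m <- r$atomMap
    if (any(m$subSlot > nrow(st)) || any(m$prodSlot > nrow(pt))) {
      note(r$id, "atom map references a molecule slot beyond the stoichiometry")
      next
    }
    if (any(m$subCarbon > st$nCarbons[m$subSlot]))
      note(r$id, "atom map references a substrate carbon beyond the molecule's carbon count")
    if (any(m$prodCarbon > pt$nCarbons[m$prodSlot]))
      note(r$id, "atom map references a product carbon beyond the molecule's carbon count")
    # every labelable substrate carbon mapped exactly once
    for (s in seq_len(nrow(st))) {
      if (!st$labelable[s]) next
      hits <- m$subCarbon[m$subSlot == s]
      miss <- setdiff(seq_len(st$nCarbons[s]), hits)
      if (length(miss))
        note(r$id, sprintf("unmapped substrate carbon: %s C%s (slot %d)",
                           st$metabolite[s], paste(miss, collapse = ","), s))
      if (anyDuplicated(hits))
        note(r$id, sprintf("substrate carbon mapped twice: %s slot %d", st$metabolite[s], s))
    }
    # every labelable product carbon receives exactly one carbon
    for (p in seq_len(nrow(pt))) {
      if (!pt$labelable[p]) next
      hits <- m$prodCarbon[m$prodSlot == p]
      miss <- setdiff(seq_len(pt$nCarbons[p]), hits)
      if (length(miss))
        note(r$id, sprintf("unfilled product carbon: %s C%s (slot %d)",
                           pt$metabolite[p], paste(miss, collapse = ","), p))
      if (anyDuplicated(hits))
        note(r$id, sprintf("product carbon filled twice: %s slot %d", pt$metabolite[p], p))
    }
    # balance over labelable-to-labelable mappings
    lab2lab <- st$labelable[m$subSlot] & pt$labelable[m$prodSlot]
    nsub <- sum(st$nCarbons[st$labelable])
    lost <- sum(st$labelable[m$subSlot] & !pt$labelable[m$prodSlot])
    if (sum(lab2lab) + lost != nsub)
      note(r$id, "mapped substrate carbons do not balance mapped product carbons")
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(reaction = character(0), problem = character(0))
}

# Helpers shared across modules ------------------------------------------

metaboliteIds <- function(net) names(net$metabolites)

compartmentVolume <- function(net, metaboliteId) {
  net$compartments[[net$metabolites[[metaboliteId]]$compartment]]$volume
}

# ncell/vol scale converting a per-cell flux into mM/min for a metabolite
concScale <- function(net, metaboliteId) net$ncell / compartmentVolume(net, metaboliteId)

defaultInitialState <- function(net) {
  stats::setNames(vapply(net$metabolites, `[[`, 0, "initialConcentration"),
                  names(net$metabolites))
}
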