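#' Decompose a directional flux into isotopomer fluxes
#'
#' Reference implementation of the label-routing step: a net-direction flux
#' `J` through a reaction is split over all combinations of substrate
#' isotopomers, each combination weighted by the product of the substrates'
#' fractional abundances (well-mixed assumption), and each combination's
#' carbons are routed through the atom-transition map to one product
#' isotopomer per product molecule. The compiled ODE core evaluates exactly
#' this decomposition from precomputed tables; this R version is the readable
#' specification and is used for cross-checks.
#'
#' @param net A `klNetwork`.
#' @param reactionId Reaction id.
#' @param J Non-negative directional flux (mmol cell^-1 min^-1). Forward and
#'   reverse rates of a reversible reaction are decomposed by two calls with
#'   `direction` swapped.
#' @param isoVectors Named list of isotopomer concentration vectors (length
#'   `2^nCarbons`) for the labelable substrates of the chosen direction.
#'   Substrates with total 0 are treated as unlabelled (with a warning) when
#'   `J > 0`.
#' @param direction `"forward"` or `"reverse"`.
#' @return Named list of per-metabolite derivative contributions in mM/min:
#'   negative entries for consumed substrate isotopomers, positive for
#'   produced product isotopomers (already scaled by `ncell/vol`).
#' @export
decomposeFlux <- function(net, reactionId, J, isoVectors,
                          direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  if (J < 0) stop("J must be >= 0; decompose reverse rates with direction = 'reverse'")
  rxn <- net$reactions[[reactionId]]
  if (is.null(rxn)) stop("unknown reaction '", reactionId, "'")
  if (is.null(rxn$atomMap)) stop("reaction '", reactionId, "' has no atom map")
  if (direction == "forward") {
    st <- slotTable(net, rxn, "substrates"); pt <- slotTable(net, rxn, "products")
    m <- rxn$atomMap
  } else {
    st <- slotTable(net, rxn, "products"); pt <- slotTable(net, rxn, "substrates")
    m <- data.frame(subSlot = rxn$atomMap$prodSlot, subCarbon = rxn$atomMap$prodCarbon,
                    prodSlot = rxn$atomMap$subSlot, prodCarbon = rxn$atomMap$subCarbon)
  }
  out <- list()
  addTo <- function(id, v) {
    if (is.null(out[[id]])) out[[id]] <<- numeric(length(v))
    out[[id]] <<- out[[id]] + v
  }
  subLab <- which(st$labelable)
  fracs <- lapply(subLab, function(s) {
    id <- st$metabolite[s]
    v <- isoVectors[[id]]
    if (is.null(v)) stop("isotopomer vector for substrate '", id, "' not supplied")
    tot <- sum(pmax(v, 0))
    if (tot < 1e-12) {
      if (J > 0) warning("substrate '", id, "' has zero total with J > 0; ",
                         "treating as unlabelled")
      c(1, numeric(length(v) - 1L))
    } else pmax(v, 0) / tot
  })
  # substrate depletion
  for (k in seq_along(subLab)) {
    id <- st$metabolite[subLab[k]]
    if (!net$metabolites[[id]]$constant)
      addTo(id, -J * concScale(net, id) * fracs[[k]])
  }
  nStates <- vapply(subLab, function(s) 2^st$nCarbons[s], 0)
  grid <- if (length(subLab))
    as.matrix(expand.grid(lapply(nStates, function(n) 0:(n - 1L)),
                          KEEP.OUT.ATTRS = FALSE))
  else matrix(0L, 1L, 0L)
  w <- rep(J, nrow(grid))
  for (k in seq_along(subLab)) w <- w * fracs[[k]][grid[, k] + 1L]
  for (p in seq_len(nrow(pt))) {
    if (!pt$labelable[p]) next
    id <- pt$metabolite[p]
    if (net$metabolites[[id]]$constant) next
    nC <- pt$nCarbons[p]
    mask <- integer(nrow(grid))
    ent <- m[m$prodSlot == p, , drop = FALSE]
    for (e in seq_len(nrow(ent))) {
      ks <- match(ent$subSlot[e], subLab)
      if (is.na(ks)) next
      bits <- bitwAnd(bitwShiftR(grid[, ks], ent$subCarbon[e] - 1L), 1L)
      mask <- bitwOr(mask, bitwShiftL(bits, ent$prodCarbon[e] - 1L))
    }
    v <- numeric(2^nC)
    if (id %in% net$symmetricMetabolites) {
      alt <- reverseBits(mask, nC)
      for (i in seq_along(w)) {
        v[mask[i] + 1L] <- v[mask[i] + 1L] + 0.5 * w[i]
        v[alt[i] + 1L] <- v[alt[i] + 1L] + 0.5 * w[i]
      }
    } else {
      for (i in seq_along(w)) v[mask[i] + 1L] <- v[mask[i] + 1L] + w[i]
    }
    addTo(id, concScale(net, id) * v)
  }
  out
}

#' Build the joint concentration + isotopomer ODE system
#'
#' Total-concentration derivatives are identical to
#' [buildConcentrationOdes()]; isotopomer derivatives are obtained by
#' decomposing each reaction's forward and reverse rate separately through
#' its atom-transition map, with invisible reactions contributing equal and
#' opposite label-exchange terms and no total-concentration change. The joint
#' state is integrated as one stiff system.
#'
#' @inheritParams buildConcentrationOdes
#' @param condition A [Condition()] defining initial totals and tracer
#'   enrichments.
#' @return A `klModel` with isotopomer blocks in its state vector.
#' @export
buildJointOdes <- function(net, params, condition = NULL) {
  compileModel(net, params, condition, withLabels = TRUE)
}

#' Simulate a condition with 13C label propagation
#'
#' Compiles the joint concentration/isotopomer system for the condition's
#' tracer composition and integrates it from 0 to the condition's end time.
#'
#' @inheritParams buildConcentrationOdes
#' @param condition A [Condition()].
#' @param times Output times (minutes); default 61 points over `[0, tEnd]`.
#' @param ... Passed to [integrateOdes()] (tolerances, method).
#' @return A `klTrajectory` including isotopomer time courses.
#' @export
simulateLabeling <- function(net, params, condition, times = NULL, ...) {
  if (is.null(times)) times <- seq(0, condition$tEnd, length.out = 61L)
  model <- compileModel(net, params, condition, withLabels = TRUE)
  integrateOdes(model, times, ...)
}

#' Isotopomer vector of a metabolite at one output time
#'
#' For labelled (tracer-reachable) pools the simulated isotopomer block is
#' returned; labelable pools the tracer cannot reach are reported as fully
#' unlabelled at their simulated total concentration; constant labelled pools
#' return their fixed composition.
#'
#' @param traj A `klTrajectory` from [simulateLabeling()].
#' @param metabolite Metabolite id.
#' @param timeIndex Row index into `traj$times` (default: last time point).
#' @return Numeric vector of isotopomer concentrations (mM), length
#'   `2^nCarbons`.
#' @export
isotopomersAt <- function(traj, metabolite, timeIndex = length(traj$times)) {
  met <- traj$model$net$metabolites[[metabolite]]
  if (is.null(met)) stop("unknown metabolite '", metabolite, "'")
  if (!met$labelable) stop("metabolite '", metabolite, "' is not labelable")
  n <- 2^met$nCarbons
  tot <- traj$concentrations[timeIndex, metabolite]
  if (!is.null(traj$iso[[metabolite]]))
    return(traj$iso[[metabolite]][timeIndex, ])
  frac <- traj$model$constIsoFrac[[metabolite]]
  if (!is.null(frac)) return(frac * tot)
  c(tot, numeric(n - 1L))  # unreachable pool: pure 12C
}

#' Tidy isotopomer trajectory table
#'
#' @param traj A `klTrajectory` with isotopomer time courses.
#' @return Data frame (time, metabolite, mask as binary string with C1 as the
#'   rightmost bit, concentration).
#' @export
isotopomerTable <- function(traj) {
  rows <- list()
  for (id in names(traj$iso)) {
    n <- traj$model$net$metabolites[[id]]$nCarbons
    masks <- 0:(2^n - 1L)
    bin <- vapply(masks, function(m)
      paste(rev(as.integer(intToBits(m))[seq_len(n)]), collapse = ""), "")
    rows[[id]] <- data.frame(
      time = rep(traj$times, length(masks)),
      metabolite = id,
      mask = rep(bin, each = length(traj$times)),
      concentration = as.vector(traj$iso[[id]]))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Total 13C content of a trajectory
#'
#' Sums `popcount(mask) * concentration * volume` over all simulated
#' isotopomer pools: the number of mmol of 13C atoms in the system. Constant
#' in any closed labelable subnetwork.
#'
#' @param traj A `klTrajectory` with isotopomer time courses.
#' @return Numeric vector along `traj$times` (mmol of 13C).
#' @export
total13C <- function(traj) {
  out <- numeric(length(traj$times))
  for (id in names(traj$iso)) {
    n <- traj$model$net$metabolites[[id]]$nCarbons
    pc <- vapply(0:(2^n - 1L), function(m) sum(as.integer(intToBits(m))[seq_len(n)]), 0)
    vol <- compartmentVolume(traj$model$net, id)
    out <- out + as.vector(traj$iso[[id]] %*% pc) * vol
  }
  out
}
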