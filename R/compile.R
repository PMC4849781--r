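# Lowering of a network + condition into the flat index tables evaluated by
# the compiled right-hand side (src/rhs.cpp). Structure (index tables, atom
# routing combos) is built once per network/condition; numeric rate-law
# parameters can be swapped cheaply with setModelParams() during fitting.

templateIdOf <- c(massAction = 1L, michaelis = 2L, michaelisRev = 3L,
                  hill = 4L, glucokinase = 5L, exchange = 6L, expression = 7L)

# Pack a law's numeric parameters per the C++ contract.
packLawParams <- function(rxn, params) {
  law <- rxn$law
  rid <- rxn$id
  pget <- function(slot, default = NULL) resolveParam(law, slot, params, rid, default)
  ki <- vapply(law$inhibitors, function(p) {
    if (!p %in% names(params))
      stop("reaction '", rid, "': inhibition constant '", p, "' missing")
    params[[p]]
  }, 0, USE.NAMES = FALSE)
  switch(law$template,
    massAction = c(pget("k"),
                   if ("kr" %in% names(law$params)) pget("kr") else 0),
    michaelis = c(pget("Vmax"),
                  vapply(names(rxn$substrates),
                         function(id) pget(paste0("Km.", id)), 0),
                  ki),
    michaelisRev = {
      Ks <- vapply(names(rxn$substrates), function(id) pget(paste0("Ks.", id)), 0)
      Kp <- vapply(names(rxn$products), function(id) pget(paste0("Kp.", id)), 0)
      useHaldane <- !("Vr" %in% names(law$params))
      c(pget("Vmax"), Ks, Kp,
        if (useHaldane) pget("Keq") else pget("Vr"),
        as.numeric(useHaldane), ki)
    },
    hill = c(pget("Vmax"), pget("K"), pget("h"),
             if (length(rxn$substrates) > 1L)
               vapply(names(rxn$substrates)[-1L],
                      function(id) pget(paste0("Km.", id)), 0) else numeric(0)),
    glucokinase = c(pget("Vmax"), pget("Km"), pget("KmATP"),
                    pget("Ki"), pget("Kir")),
    exchange = pget("k"),
    expression = numeric(0))
}

reverseBits <- function(mask, n) {
  out <- integer(length(mask))
  for (b in seq_len(n))
    out <- bitwOr(out, bitwShiftL(bitwAnd(bitwShiftR(mask, b - 1L), 1L), n - b))
  out
}

symmetrizeIso <- function(v, n) {
  idx <- reverseBits(0:(2^n - 1L), n)
  (v + v[idx + 1L]) / 2
}

# Which labelable metabolites can receive 13C from the tracer-labelled pools.
labelReachable <- function(net, seeds) {
  lab <- names(net$metabolites)[vapply(net$metabolites, `[[`, TRUE, "labelable")]
  reach <- intersect(seeds, lab)
  repeat {
    added <- FALSE
    for (r in net$reactions) {
      if (is.null(r$atomMap)) next
      st <- slotTable(net, r, "substrates")
      pt <- slotTable(net, r, "products")
      m <- r$atomMap
      fromMet <- st$metabolite[m$subSlot]
      toMet <- pt$metabolite[m$prodSlot]
      pairs <- unique(data.frame(from = fromMet, to = toMet))
      if (r$reversible || r$invisible)
        pairs <- unique(rbind(pairs, data.frame(from = pairs$to, to = pairs$from)))
      hit <- pairs$from %in% reach & !(pairs$to %in% reach) & pairs$to %in% lab
      if (any(hit)) {
        reach <- union(reach, pairs$to[hit])
        added <- TRUE
      }
    }
    if (!added) break
  }
  reach
}

resolveTracerIso <- function(met, tracer, total) {
  n <- met$nCarbons
  v <- numeric(2^n)
  tr <- tracer[[met$id]]
  if (is.null(tr)) {
    v[1L] <- total
  } else {
    if (any(tr$mask < 0) || any(tr$mask >= 2^n))
      stop("tracer for '", met$id, "': isotopomer mask out of range")
    if (abs(sum(tr$fraction) - 1) > 1e-9)
      stop("tracer fractions for '", met$id, "' must sum to 1")
    for (k in seq_len(nrow(tr)))
      v[tr$mask[k] + 1L] <- v[tr$mask[k] + 1L] + tr$fraction[k] * total
  }
  v
}

buildLabelOp <- function(net, rxn, dir, reachable, isoOffset, constIsoFrac, rxnIndex) {
  if (dir == 0L) {
    st <- slotTable(net, rxn, "substrates"); pt <- slotTable(net, rxn, "products")
    m <- rxn$atomMap
  } else {
    st <- slotTable(net, rxn, "products"); pt <- slotTable(net, rxn, "substrates")
    m <- data.frame(subSlot = rxn$atomMap$prodSlot, subCarbon = rxn$atomMap$prodCarbon,
                    prodSlot = rxn$atomMap$subSlot, prodCarbon = rxn$atomMap$subCarbon)
  }
  subLab <- which(st$labelable & st$metabolite %in% reachable)
  prodLab <- which(pt$labelable & pt$metabolite %in% reachable)
  if (!length(subLab) && !length(prodLab)) return(NULL)

  subs <- lapply(subLab, function(s) {
    id <- st$metabolite[s]
    met <- net$metabolites[[id]]
    n <- 2^met$nCarbons
    if (met$constant)
      list(isoOff = -1L, nStates = as.integer(n), fixed = TRUE,
           fixedFrac = constIsoFrac[[id]], scale = 0)
    else
      list(isoOff = isoOffset[[id]], nStates = as.integer(n), fixed = FALSE,
           fixedFrac = numeric(0), scale = concScale(net, id))
  })
  nSubs <- length(subLab)
  if (nSubs > 8L)
    stop("reaction '", rxn$id, "': more than 8 labelable substrate molecules ",
         "per reaction direction is not supported")

  nStatesPer <- vapply(subs, `[[`, 0L, "nStates")
  grid <- if (nSubs) {
    g <- expand.grid(lapply(nStatesPer, function(n) 0:(n - 1L)), KEEP.OUT.ATTRS = FALSE)
    as.matrix(g)
  } else matrix(0L, 1L, 0L)
  nCombos <- nrow(grid)

  prodOff <- integer(0); prodScale <- numeric(0)
  comboProd <- matrix(0L, nCombos, length(prodLab))
  comboAlt <- matrix(-1L, nCombos, length(prodLab))
  for (j in seq_along(prodLab)) {
    p <- prodLab[j]
    id <- pt$metabolite[p]
    met <- net$metabolites[[id]]
    prodOff[j] <- if (met$constant) -1L else isoOffset[[id]]
    prodScale[j] <- if (met$constant) 0 else concScale(net, id)
    mask <- integer(nCombos)
    ent <- m[m$prodSlot == p, , drop = FALSE]
    for (k in seq_len(nrow(ent))) {
      ks <- match(ent$subSlot[k], subLab)
      if (is.na(ks)) next  # carbon arrives from a non-labelable/unreached source: 12C
      bits <- bitwAnd(bitwShiftR(grid[, ks], ent$subCarbon[k] - 1L), 1L)
      mask <- bitwOr(mask, bitwShiftL(bits, ent$prodCarbon[k] - 1L))
    }
    comboProd[, j] <- mask
    if (id %in% net$symmetricMetabolites)
      comboAlt[, j] <- reverseBits(mask, met$nCarbons)
  }

  list(rxn = rxnIndex - 1L, dir = dir, subs = subs,
       prodOff = prodOff, prodScale = prodScale,
       comboSub = as.integer(t(grid)),
       comboProd = as.integer(t(comboProd)),
       comboProdAlt = as.integer(t(comboAlt)))
}

applyConditionToNetwork <- function(net, condition) {
  if (is.null(condition)) return(net)
  if (!is.null(condition$ncell)) net$ncell <- condition$ncell
  if (!is.null(condition$volumes))
    for (cid in names(condition$volumes))
      net$compartments[[cid]]$volume <- condition$volumes[[cid]]
  net
}

#' Compile a model for integration
#'
#' Lowers a network, a parameter vector and (optionally) an experimental
#' condition into the table-driven form evaluated by the compiled ODE
#' right-hand side. When `withLabels = TRUE` the state vector is extended
#' with isotopomer blocks for every labelable metabolite reachable by carbon
#' flow from the condition's tracer-labelled pools; metabolites the tracer
#' cannot reach are simulated as totals only and reported as unlabelled.
#'
#' @param net A `klNetwork`.
#' @param params Named numeric parameter vector.
#' @param condition A [Condition()] or `NULL` (network defaults, no tracer).
#' @param withLabels Simulate isotopomers (`TRUE`) or totals only.
#' @return An object of class `klModel` holding the compiled tables, the
#'   initial state `y0` and state-name metadata.
#' @export
compileModel <- function(net, params, condition = NULL, withLabels = TRUE) {
  net <- applyConditionToNetwork(net, condition)
  mids <- names(net$metabolites)
  isConst <- vapply(net$metabolites, `[[`, TRUE, "constant")

  init <- defaultInitialState(net)
  if (!is.null(condition) && length(condition$initial)) {
    unknown <- setdiff(names(condition$initial), mids)
    if (length(unknown))
      stop("condition '", condition$id, "' sets unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    init[names(condition$initial)] <- condition$initial
  }

  stateIdx <- rep(-1L, length(mids))
  stateIdx[!isConst] <- seq_len(sum(!isConst)) - 1L
  nTot <- sum(!isConst)
  constVals <- ifelse(isConst, init, 0)

  tracer <- if (is.null(condition)) list() else condition$tracer

  reachable <- character(0)
  isoOffset <- list(); constIsoFrac <- list()
  y0 <- unname(init[!isConst])
  stateNames <- mids[!isConst]
  if (withLabels) {
    seeds <- names(tracer)[vapply(tracer, function(tr)
      any(tr$fraction > 0 & tr$mask > 0), TRUE)]
    unknown <- setdiff(names(tracer), mids)
    if (length(unknown))
      stop("tracer references unknown metabolite(s): ", paste(unknown, collapse = ", "))
    reachable <- labelReachable(net, seeds)
    # every reaction that touches a reachable labelable pool must carry a map
    for (r in net$reactions) {
      if (!is.null(r$atomMap)) next
      touched <- intersect(names(c(r$substrates, r$products)), reachable)
      if (length(touched))
        stop("reaction '", r$id, "' touches labelled pool(s) ",
             paste(touched, collapse = ", "), " but has no atom map")
    }
    off <- nTot
    for (id in mids) {
      met <- net$metabolites[[id]]
      if (!met$labelable || !(id %in% reachable)) next
      n <- 2^met$nCarbons
      iso <- resolveTracerIso(met, tracer, init[[id]])
      if (id %in% net$symmetricMetabolites) iso <- symmetrizeIso(iso, met$nCarbons)
      if (met$constant) {
        tot <- sum(iso)
        constIsoFrac[[id]] <- if (tot > 0) iso / tot else c(1, numeric(n - 1L))
      } else {
        isoOffset[[id]] <- off
        y0 <- c(y0, iso)
        stateNames <- c(stateNames, sprintf("%s.iso%d", id, 0:(n - 1L)))
        off <- off + n
      }
    }
  }
  yLen <- length(y0)

  lawSpecs <- vector("list", length(net$reactions))
  parsEnv <- new.env(parent = emptyenv())
  parsEnv$params <- params
  metIndex <- stats::setNames(seq_along(mids) - 1L, mids)
  for (k in seq_along(net$reactions)) {
    r <- net$reactions[[k]]
    if (is.null(r$law)) stop("reaction '", r$id, "' has no rate law")
    law <- r$law
    gkIdx <- if (law$template == "glucokinase") {
      slots <- c("S", "ATP", "I", "R")
      miss <- setdiff(slots, names(law$conc))
      if (length(miss))
        stop("reaction '", r$id, "': glucokinase law needs conc slots ",
             paste(miss, collapse = ", "))
      unname(metIndex[law$conc[slots]])
    } else integer(0)
    exprFun <- if (law$template == "expression") {
      local({
        rxn <- r
        function(concFull) {
          names(concFull) <- mids
          evalRateLaw(rxn, concFull, parsEnv$params)
        }
      })
    } else NULL
    lawSpecs[[k]] <- list(
      tmpl = templateIdOf[[law$template]], id = r$id,
      subIdx = unname(metIndex[names(r$substrates)]),
      subCoef = as.integer(r$substrates),
      prodIdx = unname(metIndex[names(r$products)]),
      prodCoef = as.integer(r$products),
      inhIdx = unname(metIndex[names(law$inhibitors)]),
      gkIdx = gkIdx,
      pars = packLawParams(r, params),
      exprFun = exprFun)
  }

  stoichSpecs <- lapply(net$reactions, function(r) {
    if (r$invisible) return(list(idx = integer(0), val = numeric(0)))
    ids <- c(names(r$substrates), names(r$products))
    coef <- c(-unname(r$substrates), unname(r$products))
    keep <- !isConst[match(ids, mids)]
    ids <- ids[keep]; coef <- coef[keep]
    list(idx = unname(stateIdx[match(ids, mids)]),
         val = coef * vapply(ids, function(i) concScale(net, i), 0, USE.NAMES = FALSE))
  })

  labelOps <- list()
  if (withLabels) {
    for (k in seq_along(net$reactions)) {
      r <- net$reactions[[k]]
      if (is.null(r$atomMap)) next
      dirs <- if (r$reversible || r$invisible) c(0L, 1L) else 0L
      for (d in dirs) {
        op <- buildLabelOp(net, r, d, reachable, isoOffset, constIsoFrac, k)
        if (!is.null(op)) labelOps[[length(labelOps) + 1L]] <- op
      }
    }
  }

  spec <- list(nMet = length(mids), nTot = nTot, yLen = as.integer(yLen),
               stateIdx = stateIdx, constVals = unname(constVals),
               stateNames = stateNames, metIds = mids,
               laws = unname(lawSpecs), stoich = unname(stoichSpecs),
               labelOps = labelOps)
  ptr <- kl_model_build(spec)

  structure(list(ptr = ptr, net = net, condition = condition,
                 params = params, withLabels = withLabels,
                 y0 = stats::setNames(y0, stateNames), stateNames = stateNames,
                 nTot = nTot, stateIdx = stats::setNames(stateIdx, mids),
                 isoOffset = isoOffset, constIsoFrac = constIsoFrac,
                 reachable = reachable, parsEnv = parsEnv),
            class = "klModel")
}

#' Swap the numeric parameters of a compiled model
#'
#' Replaces the rate-law parameter values without rebuilding the structural
#' tables (index maps, atom-routing combinations). Used heavily by the
#' fitting and profiling loops.
#'
#' @param model A `klModel` from [compileModel()].
#' @param params Named numeric parameter vector.
#' @return The model, invisibly (parameters are swapped in place).
#' @export
setModelParams <- function(model, params) {
  model$parsEnv$params <- params
  parsList <- lapply(model$net$reactions, packLawParams, params = params)
  kl_model_set_pars(model$ptr, unname(parsList))
  invisible(model)
}

#' @export
print.klModel <- function(x, ...) {
  cat(sprintf("klModel: %d states (%d totals + %d isotopomer), %d reactions%s\n",
              length(x$y0), x$nTot, length(x$y0) - x$nTot,
              length(x$net$reactions),
              if (x$withLabels) sprintf(", %d labelled pools", length(x$reachable)) else ""))
  invisible(x)
}
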