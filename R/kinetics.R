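#' Rate-law templates
#'
#' Kinetic laws are instances of named templates. Forward and reverse rates
#' are always computed separately; a reversible law's reverse capacity is
#' derived from the forward capacity and the equilibrium constant through the
#' Haldane relationship unless an explicit reverse capacity is supplied.
#' Parameters are referenced by name into a single flat parameter vector so
#' that enzyme-activity grouping and fitting can rescale them.
#'
#' Available templates:
#' \describe{
#'   \item{massAction}{`k` (and `kr` when reversible): `f = k * prod(S^m)`,
#'     `r = kr * prod(P^m)`.}
#'   \item{michaelis}{Irreversible Michaelis-Menten over all substrates:
#'     `Vmax * prod(S/(Km.S + S))`, optionally damped by competitive
#'     inhibitors `1/(1 + sum(I/Ki))`.}
#'   \item{michaelisRev}{Generalized reversible Michaelis-Menten.
#'     `f = Vmax * prod((S/Ks)^m) / D`, `r = Vr * prod((P/Kp)^m) / D` with
#'     `D = prod((1+S/Ks)^m) + prod((1+P/Kp)^m) - 1 + sum(I/Ki)`. `Vr` is
#'     derived from `Keq` by the Haldane relationship
#'     (`Vr = Vmax * prod(Kp^m) / (Keq * prod(Ks^m))`), or given explicitly
#'     as parameter `Vr`. Net flux is exactly zero when `prod(P^m)/prod(S^m)
#'     = Keq`.}
#'   \item{hill}{`Vmax * S^h / (K^h + S^h)` on the first substrate,
#'     multiplied by `S/(Km.S+S)` saturation terms for any further
#'     substrates.}
#'   \item{glucokinase}{Michaelis-Menten in glucose and ATP with competitive
#'     inhibition by fructose 6-phosphate that is relieved by fructose
#'     1-phosphate: the inhibition term `I/Ki` is scaled by
#'     `1/(1 + R/Kir)`. Concentration slots `S`, `ATP`, `I`, `R` must be
#'     bound explicitly via `conc`.}
#'   \item{exchange}{Label-only exchange rate for invisible reactions:
#'     `v = k * prod(S) * prod(P)`; applied symmetrically in both directions
#'     so totals never change.}
#'   \item{expression}{Arbitrary arithmetic expression(s) over metabolite ids
#'     and parameter names (used by the SBML importer). Either separate
#'     `forward`/`reverse` strings, or a single net expression with
#'     `net = TRUE`, in which case `f = max(e, 0)`, `r = max(-e, 0)`.}
#' }
#'
#' @param template Template name (see Details).
#' @param params Named character vector mapping template parameter slots
#'   (e.g. `Vmax`, `Km.glc`, `Keq`) to names in the parameter vector.
#' @param conc Named character vector binding template concentration slots to
#'   metabolite ids (only needed by templates with explicit slots such as
#'   `glucokinase`; substrate/product slots default to the reaction's own
#'   lists).
#' @param inhibitors Named character vector: metabolite id -> name of its
#'   competitive inhibition constant parameter.
#' @param forward,reverse Expression strings (template `expression` only).
#' @param net Logical; `expression` only, single net-rate expression.
#' @return An object of class `klRateLaw`.
#' @export
rateLaw <- function(template, params = character(0), conc = character(0),
                    inhibitors = character(0), forward = NULL, reverse = NULL,
                    net = FALSE) {
  known <- c("massAction", "michaelis", "michaelisRev", "hill",
             "glucokinase", "exchange", "expression")
  if (!template %in% known)
    stop("unknown rate-law template '", template, "'")
  structure(list(template = template, params = params, conc = conc,
                 inhibitors = inhibitors, forward = forward, reverse = reverse,
                 net = isTRUE(net)),
            class = "klRateLaw")
}

lawHasReverse <- function(law) {
  switch(law$template,
         massAction = "kr" %in% names(law$params),
         michaelisRev = TRUE,
         exchange = TRUE,
         expression = !is.null(law$reverse) || law$net,
         FALSE)
}

resolveParam <- function(law, slot, params, rid, default = NULL) {
  pname <- law$params[[slot]]
  if (is.null(pname) || is.na(pname)) {
    if (!is.null(default)) return(default)
    stop("reaction '", rid, "': rate law needs parameter slot '", slot, "'")
  }
  if (!pname %in% names(params))
    stop("reaction '", rid, "': parameter '", pname, "' missing from the parameter set")
  params[[pname]]
}

#' Haldane-constrained reverse capacity
#'
#' For a reversible Michaelis-Menten law the thermodynamic equilibrium
#' constant ties the reverse maximal rate to the forward one:
#' `Keq = Vmax_f * prod(Km_P) / (Vmax_r * prod(Km_S))`, so
#' `Vmax_r = Vmax_f * prod(Km_P) / (Keq * prod(Km_S))`. With this capacity
#' the net rate vanishes exactly when `prod(P)/prod(S) = Keq`. Stoichiometric
#' coefficients enter as powers of the corresponding Michaelis constants.
#'
#' @param VmaxF Forward maximal rate (mmol cell^-1 min^-1).
#' @param Keq Equilibrium constant (> 0).
#' @param KmS,KmP Michaelis constants of substrates and products (mM),
#'   repeated per stoichiometric copy.
#' @return Reverse maximal rate, same units as `VmaxF`.
#' @export
haldaneReverseCapacity <- function(VmaxF, Keq, KmS, KmP) {
  if (!is.finite(Keq) || Keq <= 0) stop("Keq must be a positive number")
  if (any(c(KmS, KmP) <= 0)) stop("affinity constants must be positive")
  VmaxF * prod(KmP) / (Keq * prod(KmS))
}

# Evaluate one rate law in R. conc is the full named concentration vector
# (negative trial values clamped to zero by the caller). Returns c(forward,
# reverse) in mmol cell^-1 min^-1.
evalRateLaw <- function(rxn, conc, params) {
  law <- rxn$law
  rid <- rxn$id
  if (is.null(law)) stop("reaction '", rid, "' has no rate law")
  getConc <- function(id) {
    if (!id %in% names(conc))
      stop("reaction '", rid, "': rate law references unknown metabolite '", id, "'")
    max(conc[[id]], 0)
  }
  S <- rxn$substrates; P <- rxn$products
  inhTerm <- function() {
    if (length(law$inhibitors) == 0L) return(0)
    sum(vapply(names(law$inhibitors), function(id) {
      ki <- law$inhibitors[[id]]
      if (!ki %in% names(params))
        stop("reaction '", rid, "': inhibition constant '", ki,
             "' missing from the parameter set")
      getConc(id) / params[[ki]]
    }, 0))
  }
  pget <- function(slot, default = NULL) resolveParam(law, slot, params, rid, default)
  res <- switch(law$template,
    massAction = {
      f <- pget("k") * prod(vapply(names(S), getConc, 0)^S)
      r <- if ("kr" %in% names(law$params))
        pget("kr") * prod(vapply(names(P), getConc, 0)^P) else 0
      c(f, r)
    },
    michaelis = {
      Vmax <- pget("Vmax")
      sat <- prod(vapply(names(S), function(id) {
        Km <- pget(paste0("Km.", id))
        s <- getConc(id); s / (Km + s)
      }, 0))
      c(Vmax * sat / (1 + inhTerm()), 0)
    },
    michaelisRev = {
      Vmax <- pget("Vmax")
      Ks <- vapply(names(S), function(id) pget(paste0("Ks.", id)), 0)
      Kp <- vapply(names(P), function(id) pget(paste0("Kp.", id)), 0)
      sv <- vapply(names(S), getConc, 0) / Ks
      pv <- vapply(names(P), getConc, 0) / Kp
      D <- prod((1 + sv)^S) + prod((1 + pv)^P) - 1 + inhTerm()
      Vr <- if ("Vr" %in% names(law$params)) pget("Vr")
            else haldaneReverseCapacity(Vmax, pget("Keq"), rep(Ks, S), rep(Kp, P))
      c(Vmax * prod(sv^S) / D, Vr * prod(pv^P) / D)
    },
    hill = {
      ids <- names(S)
      s1 <- getConc(ids[1L]); h <- pget("h"); K <- pget("K")
      sat <- s1^h / (K^h + s1^h)
      if (length(ids) > 1L)
        sat <- sat * prod(vapply(ids[-1L], function(id) {
          Km <- pget(paste0("Km.", id)); s <- getConc(id); s / (Km + s)
        }, 0))
      c(pget("Vmax") * sat, 0)
    },
    glucokinase = {
      s <- getConc(law$conc[["S"]]); atp <- getConc(law$conc[["ATP"]])
      i <- getConc(law$conc[["I"]]); rl <- getConc(law$conc[["R"]])
      inh <- (i / pget("Ki")) / (1 + rl / pget("Kir"))
      f <- pget("Vmax") * s / (pget("Km") * (1 + inh) + s) *
        atp / (pget("KmATP") + atp)
      c(f, 0)
    },
    exchange = {
      v <- pget("k") * prod(vapply(names(S), getConc, 0)^S) *
        prod(vapply(names(P), getConc, 0)^P)
      c(v, v)
    },
    expression = {
      env <- list2env(as.list(c(conc, params)), parent = baseenv())
      ev <- function(txt) {
        val <- tryCatch(eval(parse(text = txt), envir = env), error = function(e)
          stop("reaction '", rid, "': rate expression failed: ",
               conditionMessage(e), call. = FALSE))
        if (!is.finite(val))
          stop("reaction '", rid, "': rate expression is not finite ",
               "(division by zero?)")
        val
      }
      if (law$net) {
        e <- ev(law$forward); c(max(e, 0), max(-e, 0))
      } else {
        c(ev(law$forward), if (is.null(law$reverse)) 0 else ev(law$reverse))
      }
    },
    stop("unknown template '", law$template, "'"))
  if (any(!is.finite(res)))
    stop("reaction '", rid, "': non-finite rate (division by zero in the law?)")
  res
}

#' Evaluate all reaction rates
#'
#' Computes the separate forward and reverse rate of every reaction at the
#' given concentrations. Negative concentrations (possible during trial
#' integrator steps) are clamped to zero inside the evaluation only.
#' Deterministic and side-effect free.
#'
#' @param net A `klNetwork`.
#' @param concentrations Named numeric vector of concentrations (mM) covering
#'   every metabolite the rate laws reference.
#' @param params Named numeric parameter vector.
#' @return A data frame with columns `reaction`, `forward`, `reverse`, `net`
#'   (rates in mmol cell^-1 min^-1).
#' @export
evaluateFluxes <- function(net, concentrations, params) {
  rates <- vapply(net$reactions, evalRateLaw, c(0, 0),
                  conc = concentrations, params = params)
  data.frame(reaction = names(net$reactions),
             forward = rates[1L, ], reverse = rates[2L, ],
             net = rates[1L, ] - rates[2L, ], row.names = NULL)
}

#' Define enzyme-activity parameter groups
#'
#' Enzyme activities catalysing sequential reactions with no branch points
#' (reaction chains) cannot be separated by the data: the chain flux is set
#' by whichever activity limits it. Such activities are therefore fitted as
#' one group: a single free factor `E_z` scales all member capacities, each
#' multiplied by its fixed relative weight.
#'
#' @param groups Named list; each element is a named numeric vector mapping
#'   parameter names to relative weights.
#' @return An object of class `klParameterGroups`.
#' @export
parameterGroups <- function(groups) {
  stopifnot(is.list(groups), !is.null(names(groups)), all(nzchar(names(groups))))
  members <- unlist(lapply(groups, names))
  dup <- unique(members[duplicated(members)])
  if (length(dup))
    stop("parameter(s) in more than one group: ", paste(dup, collapse = ", "))
  structure(groups, class = "klParameterGroups")
}

#' Apply group factors to a parameter vector
#'
#' Sets every member parameter of group z to `factors[z] * weight`; parameters
#' outside any group are untouched. Groups are disjoint so the order of
#' application is irrelevant.
#'
#' @param params Named numeric parameter vector.
#' @param groups A [parameterGroups()] object.
#' @param factors Numeric vector of scaling factors, one per group (named or
#'   in group order), all >= 0.
#' @return The updated parameter vector.
#' @export
applyParameterGroups <- function(params, groups, factors) {
  if (length(factors) != length(groups))
    stop("expected ", length(groups), " group factors, got ", length(factors))
  if (is.null(names(factors))) names(factors) <- names(groups)
  if (any(factors < 0)) stop("group factors must be >= 0")
  for (g in names(groups)) {
    w <- groups[[g]]
    missing <- setdiff(names(w), names(params))
    if (length(missing))
      stop("group '", g, "' references unknown parameter(s): ",
           paste(missing, collapse = ", "))
    params[names(w)] <- factors[[g]] * w
  }
  params
}
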