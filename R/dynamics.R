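#' Define an experimental condition
#'
#' A condition bundles the experimental design of one incubation: initial
#' concentrations, the tracer composition of the medium substrates, the cell
#' number, optional compartment-volume overrides and the incubation horizon.
#'
#' @param id Condition identifier (e.g. `"A1"`).
#' @param initial Named numeric vector of initial concentrations (mM)
#'   overriding the network defaults.
#' @param tracer Named list: metabolite id -> data frame with columns `mask`
#'   (isotopomer bitmask, bit k-1 set means 13C at carbon k) and `fraction`.
#'   Fractions per substrate must sum to 1. Use [tracerSpec()].
#' @param ncell Cell-number override (positive), or `NULL`.
#' @param volumes Named numeric vector of compartment-volume overrides
#'   (litres), or `NULL`.
#' @param tEnd Incubation end time in minutes (default 120, a 2 h incubation).
#' @return An object of class `klCondition`.
#' @export
Condition <- function(id, initial = numeric(0), tracer = list(),
                      ncell = NULL, volumes = NULL, tEnd = 120) {
  for (nm in names(tracer)) {
    tr <- tracer[[nm]]
    if (!is.data.frame(tr) || !all(c("mask", "fraction") %in% names(tr)))
      stop("tracer entry '", nm, "' must be a data frame with mask and fraction")
    if (abs(sum(tr$fraction) - 1) > 1e-9)
      stop("tracer fractions for '", nm, "' must sum to 1")
  }
  if (!is.null(ncell) && (!is.numeric(ncell) || ncell <= 0))
    stop("ncell must be positive")
  structure(list(id = id, initial = initial, tracer = tracer,
                 ncell = ncell, volumes = volumes, tEnd = as.numeric(tEnd)),
            class = "klCondition")
}

#' Tracer composition helper
#'
#' @param mask Integer isotopomer bitmasks (bit k-1 set means 13C at carbon k;
#'   e.g. `[1,2-13C2]` hexose is mask 3, `[U-13C6]` hexose is mask 63).
#' @param fraction Molar fractions, summing to 1.
#' @return Data frame usable in the `tracer` list of [Condition()].
#' @export
tracerSpec <- function(mask, fraction) {
  stopifnot(length(mask) == length(fraction))
  data.frame(mask = as.integer(mask), fraction = as.numeric(fraction))
}

#' Build the concentration-only derivative function
#'
#' Assembles `dc/dt = N j(c, p) ncell/vol` over the non-constant metabolites:
#' for metabolite i in compartment k, `dc_i/dt = sum_r N_ir j_r ncell/vol_k`
#' in mM/min. Constant metabolites are excluded from the state vector (not
#' carried as zero-derivative entries).
#'
#' @param net A `klNetwork`.
#' @param params Named numeric parameter vector.
#' @param condition Optional [Condition()] (initial-value/cell-number overrides).
#' @return A `klModel` whose `deriv(t, y)` evaluates the derivatives and whose
#'   `y0` is the initial state.
#' @export
buildConcentrationOdes <- function(net, params, condition = NULL) {
  compileModel(net, params, condition, withLabels = FALSE)
}

#' Derivative function of a compiled model
#'
#' @param model A `klModel`.
#' @return `function(t, y)` returning the derivative vector (mM/min).
#' @export
derivFunction <- function(model) {
  ptr <- model$ptr
  function(t, y) kl_rhs(ptr, t, y)
}

#' Integrate a compiled model
#'
#' Stiff implicit integration of the (joint) ODE system via \pkg{deSolve}.
#' The default `lsodes` uses an internally generated sparse Jacobian, which
#' the block-structured isotopomer system rewards; `lsoda` is available as a
#' dense fallback. Integration failures are turned into structured errors
#' carrying the last valid time.
#'
#' @param model A `klModel` from [compileModel()] or [buildJointOdes()].
#' @param times Output times in minutes (strictly increasing, starting at the
#'   initial time).
#' @param y0 Initial state; defaults to the model's assembled `y0`.
#' @param method \pkg{deSolve} method (default `"lsodes"`).
#' @param rtol,atol Relative / absolute (mM) integrator tolerances.
#' @param computeFluxes Evaluate per-reaction rates at every output time
#'   (default `TRUE`; the fitting loop turns this off).
#' @param ... Passed to [deSolve::ode()].
#' @return A `klTrajectory`: output times, total concentrations (constant
#'   metabolites included as fixed columns), per-reaction forward/reverse/net
#'   fluxes, and per-metabolite isotopomer matrices when labels are simulated.
#' @export
integrateOdes <- function(model, times, y0 = model$y0, method = "lsodes",
                          rtol = 1e-8, atol = 1e-10, computeFluxes = TRUE,
                          ...) {
  stopifnot(inherits(model, "klModel"))
  if (any(diff(times) <= 0)) stop("output times must be strictly increasing")
  if (any(y0[seq_len(model$nTot)] < 0)) stop("initial concentrations must be >= 0")
  ptr <- model$ptr
  fn <- function(t, y, p) list(kl_rhs(ptr, t, y))
  out <- tryCatch(
    deSolve::ode(y = unname(y0), times = times, func = fn, parms = NULL,
                 method = method, rtol = rtol, atol = atol, ...),
    warning = function(w) {
      res <- suppressWarnings(
        deSolve::ode(y = unname(y0), times = times, func = fn, parms = NULL,
                     method = method, rtol = rtol, atol = atol, ...))
      attr(res, "integrationWarning") <- conditionMessage(w)
      res
    })
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1L] < 0) {
    lastT <- out[nrow(out), 1L]
    cond <- structure(class = c("klIntegrationError", "error", "condition"),
                      list(message = sprintf(
                        "integration failed (istate %d) at t = %.6g min: %s",
                        istate[1L], lastT,
                        attr(out, "integrationWarning") %||% "step-size collapse"),
                        call = sys.call(-1L), lastTime = lastT))
    stop(cond)
  }
  makeTrajectory(model, out, computeFluxes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

makeTrajectory <- function(model, out, computeFluxes = TRUE) {
  times <- out[, 1L]
  ymat <- out[, -1L, drop = FALSE]
  mids <- names(model$net$metabolites)
  conc <- matrix(0, length(times), length(mids), dimnames = list(NULL, mids))
  for (i in seq_along(mids)) {
    s <- model$stateIdx[[mids[i]]]
    conc[, i] <- if (s < 0) {
      # constant metabolites: fixed at their (condition-resolved) value
      rep(kl_const_val(model, i), length(times))
    } else ymat[, s + 1L]
  }
  rids <- names(model$net$reactions)
  fwd <- rev <- matrix(0, length(times), length(rids), dimnames = list(NULL, rids))
  if (computeFluxes) {
    for (k in seq_along(times)) {
      rr <- kl_rates(model$ptr, ymat[k, ])
      fwd[k, ] <- rr[, 1L]; rev[k, ] <- rr[, 2L]
    }
  }
  iso <- list()
  for (id in names(model$isoOffset)) {
    n <- 2^model$net$metabolites[[id]]$nCarbons
    off <- model$isoOffset[[id]]
    iso[[id]] <- ymat[, off + seq_len(n), drop = FALSE]
    colnames(iso[[id]]) <- sprintf("iso%d", 0:(n - 1L))
  }
  structure(list(times = times, concentrations = conc,
                 forward = fwd, reverse = rev, net = fwd - rev,
                 iso = iso, model = model),
            class = "klTrajectory")
}

# constant value of metabolite i (1-based) as compiled
kl_const_val <- function(model, i) {
  mids <- names(model$net$metabolites)
  init <- defaultInitialState(model$net)
  if (!is.null(model$condition) && length(model$condition$initial)) {
    ov <- model$condition$initial
    init[names(ov)] <- ov
  }
  unname(init[[mids[i]]])
}

#' @export
print.klTrajectory <- function(x, ...) {
  cat(sprintf("klTrajectory: %d time points over [%g, %g] min, %d metabolites%s\n",
              length(x$times), min(x$times), max(x$times),
              ncol(x$concentrations),
              if (length(x$iso)) sprintf(", %d labelled pools", length(x$iso)) else ""))
  invisible(x)
}

#' Simulate total concentrations for a condition
#'
#' Convenience wrapper: compile without labels, integrate to the condition's
#' end time.
#'
#' @inheritParams buildConcentrationOdes
#' @param times Output times (minutes); default 61 points over `[0, tEnd]`.
#' @param ... Passed to [integrateOdes()].
#' @return A `klTrajectory`.
#' @export
simulateConcentrations <- function(net, params, condition = NULL,
                                   times = NULL, ...) {
  tEnd <- if (!is.null(condition)) condition$tEnd else 120
  if (is.null(times)) times <- seq(0, tEnd, length.out = 61L)
  model <- compileModel(net, params, condition, withLabels = FALSE)
  integrateOdes(model, times, ...)
}

#' Extract a tidy concentration table
#'
#' @param traj A `klTrajectory`.
#' @return Data frame (time, metabolite, concentration) in mM.
#' @export
concentrationTable <- function(traj) {
  data.frame(time = rep(traj$times, ncol(traj$concentrations)),
             metabolite = rep(colnames(traj$concentrations), each = length(traj$times)),
             concentration = as.vector(traj$concentrations))
}

#' Extract a tidy flux table
#'
#' @param traj A `klTrajectory`.
#' @return Data frame (time, reaction, forward, reverse, net) in
#'   mmol cell^-1 min^-1.
#' @export
fluxTable <- function(traj) {
  data.frame(time = rep(traj$times, ncol(traj$forward)),
             reaction = rep(colnames(traj$forward), each = length(traj$times)),
             forward = as.vector(traj$forward),
             reverse = as.vector(traj$reverse),
             net = as.vector(traj$net))
}
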