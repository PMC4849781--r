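#' Assemble a fitting problem
#'
#' Bundles a network, its baseline parameters, the enzyme-activity groups
#' whose factors are fitted, the experimental conditions and the measurement
#' table. Models are compiled once per condition (with isotopomer blocks only
#' where the condition's measurements include isotopologue fractions) and
#' reused across objective evaluations with swapped parameters.
#'
#' @param net A `klNetwork`.
#' @param params Baseline named parameter vector (group members are
#'   overwritten by `factor * weight` at each evaluation).
#' @param groups A [parameterGroups()] object; its factors `E_1..E_m` are the
#'   free parameters of the fit.
#' @param conditions List of [Condition()] objects (shared parameter set
#'   across all of them).
#' @param dataset Measurement data frame with columns `condition_id`,
#'   `observable_id`, `metabolite`, `fragment`, `isotopologue_index` (integer
#'   m-index or `NA`/`"conc"`), `time_min`, `value`, `sd`.
#' @param rtol,atol,method Integrator settings used inside the objective.
#' @param nDense Number of dense output samples per condition used (in
#'   addition to measurement times) for the concentration-ceiling rejection.
#' @param rejectAbove Concentration ceiling in mM: parameter sets driving any
#'   metabolite above it anywhere along the trajectory are discarded
#'   (objective `+Inf`). Default 50 mM.
#' @param sigmaFloor Lower bound applied to measurement standard deviations
#'   before weighting (default 0.01, guarding against near-zero reported sd).
#' @return An object of class `klFitProblem`.
#' @export
fitProblem <- function(net, params, groups, conditions, dataset,
                       rtol = 1e-8, atol = 1e-10, method = "lsodes",
                       nDense = 41L, rejectAbove = 50, sigmaFloor = 0.01) {
  need <- c("condition_id", "metabolite", "fragment", "isotopologue_index",
            "time_min", "value", "sd")
  missing <- setdiff(need, names(dataset))
  if (length(missing))
    stop("dataset lacks column(s): ", paste(missing, collapse = ", "))
  condIds <- vapply(conditions, `[[`, "", "id")
  names(conditions) <- condIds
  bad <- setdiff(unique(dataset$condition_id), condIds)
  if (length(bad))
    stop("dataset references unknown condition(s): ", paste(bad, collapse = ", "))
  midRow <- !(is.na(dataset$isotopologue_index) |
                as.character(dataset$isotopologue_index) == "conc")
  models <- lapply(conditions, function(cond) {
    rows <- dataset$condition_id == cond$id
    compileModel(net, params, cond, withLabels = any(midRow[rows]))
  })
  times <- lapply(conditions, function(cond) {
    mt <- dataset$time_min[dataset$condition_id == cond$id]
    sort(unique(c(seq(0, cond$tEnd, length.out = nDense), mt, cond$tEnd)))
  })
  problem <- structure(list(net = net, params = params, groups = groups,
                            conditions = conditions, dataset = dataset,
                            models = models, times = times,
                            rtol = rtol, atol = atol, method = method,
                            rejectAbove = rejectAbove, sigmaFloor = sigmaFloor),
                       class = "klFitProblem")
  problem$plan <- buildObsPlan(problem)
  problem$nonConst <- names(net$metabolites)[
    !vapply(net$metabolites, `[[`, TRUE, "constant")]
  problem
}

# Precompiled evaluation plan for the dataset rows: direct indices into the
# trajectory instead of repeated data-frame dispatch inside the hot loop.
buildObsPlan <- function(problem) {
  ds <- problem$dataset
  net <- problem$net
  plan <- vector("list", nrow(ds))
  for (k in seq_len(nrow(ds))) {
    cid <- ds$condition_id[k]
    ti <- which(abs(problem$times[[cid]] - ds$time_min[k]) < 1e-9)
    if (length(ti) != 1L)
      stop("measurement time ", ds$time_min[k], " not on the output grid")
    idx <- ds$isotopologue_index[k]
    isConc <- is.na(idx) || identical(as.character(idx), "conc")
    met <- ds$metabolite[k]
    entry <- list(cid = cid, ti = ti, met = met, isConc = isConc)
    if (!isConc) {
      n <- if (identical(met, "sorbitol")) 6L else {
        if (is.null(net$metabolites[[met]]))
          stop("unknown observable metabolite '", met, "'")
        if (!net$metabolites[[met]]$labelable)
          stop("metabolite '", met, "' is not labelable; no MID observable")
        net$metabolites[[met]]$nCarbons
      }
      frag <- parseFragment(ds$fragment[k])
      if (is.null(frag)) frag <- c(1L, n)
      masks <- 0:(2^n - 1L)
      fb <- bitwAnd(bitwShiftR(masks, frag[1L] - 1L), 2^(frag[2L] - frag[1L] + 1L) - 1L)
      w <- vapply(fb, function(mm) sum(as.integer(intToBits(mm))), 0L)
      entry$sel <- which(w == as.integer(idx))
      if (!length(entry$sel))
        stop("isotopologue index m", idx, " out of range for '", met, "'")
    }
    plan[[k]] <- entry
  }
  plan
}

predictRow <- function(entry, trajs) {
  traj <- trajs[[entry$cid]]
  if (entry$isConc) return(traj$concentrations[entry$ti, entry$met])
  iso <- if (identical(entry$met, "sorbitol"))
    isotopomersAt(traj, "eGlc", entry$ti) + isotopomersAt(traj, "eFru", entry$ti)
  else isotopomersAt(traj, entry$met, entry$ti)
  tot <- sum(iso)
  if (tot <= 0) return(if (1L %in% entry$sel) 1 else 0)
  sum(iso[entry$sel]) / tot
}

# Simulate every condition at the given group factors; NULL on rejection.
simulateProblem <- function(problem, factors) {
  params <- applyParameterGroups(problem$params, problem$groups, factors)
  trajs <- list()
  for (cid in names(problem$conditions)) {
    model <- problem$models[[cid]]
    setModelParams(model, params)
    traj <- tryCatch(
      integrateOdes(model, problem$times[[cid]], method = problem$method,
                    rtol = problem$rtol, atol = problem$atol,
                    computeFluxes = FALSE),
      error = function(e) e)
    if (inherits(traj, "error"))
      return(structure(list(), rejected = paste0("condition ", cid, ": ",
                                                 conditionMessage(traj))))
    if (max(traj$concentrations[, problem$nonConst]) > problem$rejectAbove)
      return(structure(list(), rejected = sprintf(
        "condition %s: concentration above %g mM", cid, problem$rejectAbove)))
    trajs[[cid]] <- traj
  }
  trajs
}

evalDatasetPredictions <- function(problem, trajs) {
  ds <- problem$dataset
  ds$predicted <- vapply(problem$plan, predictRow, 0, trajs = trajs)
  ds
}

#' Predicted observables at given group factors
#'
#' @param problem A [fitProblem()].
#' @param factors Group factor vector.
#' @return The problem's dataset with a `predicted` column, or `NULL` if the
#'   parameter set is rejected (ceiling exceeded or integration failure).
#' @export
predictedObservables <- function(problem, factors) {
  trajs <- simulateProblem(problem, factors)
  if (!is.null(attr(trajs, "rejected"))) return(NULL)
  evalDatasetPredictions(problem, trajs)
}

#' Multi-condition square-deviation objective
#'
#' `X^2 = sum_i ((Y_i - Z_i(E_1..E_m)) / sigma_i)^2` over all measurements of
#' all conditions, simulated with one shared parameter set. Standard
#' deviations are floored at `sigmaFloor` (default 0.01). Returns an `+Inf`
#' sentinel (with attribute `cause`) if any metabolite exceeds the
#' concentration ceiling anywhere along the dense output, or if integration
#' fails; such parameter sets are rejected rather than crashing the fit.
#'
#' @param factors Group factor vector (one `E_z` per group, >= 0).
#' @param problem A [fitProblem()].
#' @return The scalar objective value.
#' @export
objective <- function(factors, problem) {
  trajs <- simulateProblem(problem, factors)
  rej <- attr(trajs, "rejected")
  if (!is.null(rej)) return(structure(Inf, cause = rej))
  ds <- evalDatasetPredictions(problem, trajs)
  sigma <- pmax(ds$sd, problem$sigmaFloor)
  sum(((ds$value - ds$predicted) / sigma)^2)
}

#' Fit group factors by simulated annealing
#'
#' A Kirkpatrick-style annealer on the objective: proposals perturb one
#' randomly chosen factor multiplicatively (log-normal step), Metropolis
#' acceptance on the X^2 difference, geometric temperature ladder. Reverse
#' capacities tied by the Haldane relationship are recomputed from the
#' scaled forward capacities at every evaluation (they are derived, never
#' free). The best-ever point is returned; runs are reproducible given the
#' seed.
#'
#' @param problem A [fitProblem()].
#' @param schedule List overriding any of: `T0` (initial temperature; default
#'   the initial objective value), `cooling` (default 0.95 per ladder step),
#'   `movesPerTemp` (default 50), `moveScale` (sd of the log-normal step,
#'   default 0.4), `TminFrac` (stop when `T < TminFrac * T0`, default 1e-3),
#'   `maxEval` (objective-evaluation budget, default 20000).
#' @param bounds Length-2 multiplicative bounds on each factor relative to its
#'   initial value (default `c(1e-3, 1e3)`); search is in log space.
#' @param init Initial factor vector (default all 1).
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `klFit`: `factors` (best), `X2`, `evaluations`,
#'   `seed`, `schedule`, `accepted` (move count), and `trace` (best X^2 per
#'   temperature).
#' @export
fitAnneal <- function(problem, schedule = list(), bounds = c(1e-3, 1e3),
                      init = NULL, seed = 1L) {
  sch <- utils::modifyList(list(T0 = NULL, cooling = 0.95, movesPerTemp = 50L,
                                moveScale = 0.4, TminFrac = 1e-3,
                                maxEval = 20000L), schedule)
  if (sch$cooling <= 0 || sch$cooling >= 1) stop("cooling factor must be in (0, 1)")
  if (any(bounds <= 0) || bounds[1L] >= bounds[2L]) stop("bounds must be positive and increasing")
  m <- length(problem$groups)
  if (is.null(init)) init <- stats::setNames(rep(1, m), names(problem$groups))
  if (length(init) != m) stop("init must supply one factor per group")
  set.seed(seed)

  lo <- init * bounds[1L]; hi <- init * bounds[2L]
  evals <- 0L
  f <- function(x) { evals <<- evals + 1L; objective(x, problem) }

  cur <- init; curX <- f(cur)
  tries <- 0L
  while (!is.finite(curX) && tries < 200L && evals < sch$maxEval) {
    cand <- pmin(pmax(init * exp(stats::rnorm(m, 0, 1)), lo), hi)
    x <- f(cand)
    if (is.finite(x)) { cur <- cand; curX <- x }
    tries <- tries + 1L
  }
  if (!is.finite(curX))
    stop("no finite objective found near the initial point; ",
         "widen the bounds or improve the initial factors")

  best <- cur; bestX <- curX
  T0 <- if (is.null(sch$T0)) max(curX, 1e-8) else sch$T0
  Temp <- T0
  accepted <- 0L
  trace <- numeric(0)
  while (Temp >= sch$TminFrac * T0 && evals < sch$maxEval && sch$maxEval > 0L) {
    # proposal width shrinks with the temperature so late moves polish the
    # minimum instead of re-exploring
    scale <- sch$moveScale * max((Temp / T0)^0.5, 0.02)
    for (mv in seq_len(sch$movesPerTemp)) {
      if (evals >= sch$maxEval) break
      cand <- cur
      if (m > 1L && stats::runif(1L) < 0.25) {
        # joint scaling move: enzyme chains leave the objective nearly flat
        # along a common rescaling of sequential activities, which
        # single-factor moves traverse only in slow zigzags
        cand <- cur * exp(stats::rnorm(1L, 0, scale))
      } else {
        i <- sample.int(m, 1L)
        cand[i] <- cur[i] * exp(stats::rnorm(1L, 0, scale))
      }
      if (any(cand < lo | cand > hi)) next
      candX <- f(cand)
      d <- candX - curX
      if (is.finite(candX) && (d <= 0 || stats::runif(1L) < exp(-d / Temp))) {
        cur <- cand; curX <- candX; accepted <- accepted + 1L
        if (curX < bestX) { best <- cur; bestX <- curX }
      }
    }
    trace <- c(trace, bestX)
    Temp <- Temp * sch$cooling
    # elitist restart: begin each temperature from the best-ever point so the
    # high-temperature exploration cannot strand the walk far from the basin
    cur <- best; curX <- bestX
  }
  structure(list(factors = best, X2 = bestX, evaluations = evals,
                 seed = seed, schedule = sch, accepted = accepted,
                 trace = trace),
            class = "klFit")
}

#' @export
print.klFit <- function(x, ...) {
  cat(sprintf("klFit: X2 = %.6g after %d evaluations (seed %d)\n",
              x$X2, x$evaluations, x$seed))
  print(round(x$factors, 4))
  invisible(x)
}
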