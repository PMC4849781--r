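#' Chi-square confidence threshold
#'
#' The profile-likelihood confidence region at significance level `alpha` is
#' `{theta_i : X2(theta_i) - X2_bf < Delta_alpha}` with `Delta_alpha` the
#' upper-`alpha` quantile of the chi-square distribution with one degree of
#' freedom (experimental errors assumed normal).
#'
#' @param alpha Significance level in (0, 1); 0.05 gives 3.841.
#' @return The threshold `Delta_alpha`.
#' @export
chi2Threshold <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  stats::qchisq(1 - alpha, df = 1)
}

# Re-optimize the remaining factors with factor `i` fixed at `theta`,
# warm-started from `warm`. A shortened anneal per the profile design.
reoptimizeFixed <- function(problem, i, theta, warm, sch, seed) {
  m <- length(warm)
  free <- setdiff(seq_len(m), i)
  insert <- function(sub) {
    x <- warm
    x[i] <- theta
    x[free] <- sub
    x
  }
  evals <- 0L
  fsub <- function(sub) { evals <<- evals + 1L; objective(insert(sub), problem) }
  if (length(free) == 0L) {
    x2 <- fsub(numeric(0))
    return(list(X2 = as.numeric(x2), factors = insert(numeric(0)), evaluations = evals))
  }
  set.seed(seed)
  cur <- warm[free]; curX <- fsub(cur)
  best <- cur; bestX <- curX
  T0 <- if (is.finite(curX)) max(curX, 1e-6) else 1
  Temp <- T0
  lo <- warm[free] * 1e-3; hi <- warm[free] * 1e3
  while (evals < sch$maxEval && Temp >= 1e-3 * max(bestX, 1e-6)) {
    scale <- sch$moveScale * max((Temp / T0)^0.5, 0.05)
    for (mv in seq_len(sch$movesPerTemp)) {
      if (evals >= sch$maxEval) break
      j <- sample.int(length(free), 1L)
      cand <- cur
      cand[j] <- cur[j] * exp(stats::rnorm(1L, 0, scale))
      if (cand[j] < lo[j] || cand[j] > hi[j]) next
      candX <- fsub(cand)
      d <- candX - curX
      if (is.finite(candX) && (d <= 0 || stats::runif(1L) < exp(-d / Temp))) {
        cur <- cand; curX <- candX
        if (curX < bestX) { best <- cur; bestX <- curX }
      }
    }
    Temp <- Temp * sch$cooling
  }
  list(X2 = as.numeric(bestX), factors = insert(best), evaluations = evals)
}

#' Profile-likelihood confidence interval for one group factor
#'
#' Fixes the chosen factor on a multiplicative grid walking outward from its
#' best-fit value, re-optimizes the remaining factors at every grid point
#' (shortened warm-started anneal seeded from the neighbouring accepted
#' point), and brackets-then-bisects the crossing of
#' `X2(theta_i) - X2_bf = Delta_alpha`. A side is declared unbounded when the
#' walk passes `boundFactor` times (upper) or `1/boundFactor` times (lower)
#' the best-fit value without crossing the threshold.
#'
#' @param problem A [fitProblem()].
#' @param fit A `klFit` from [fitAnneal()].
#' @param param Name (or index) of the group factor to profile.
#' @param alpha Significance level (default 0.05).
#' @param control List overriding any of: `stepFactor` (grid step, default
#'   1.2), `boundFactor` (unbounded declaration limit, default 1e3),
#'   `reoptEval` (objective budget per re-optimization; default 10% of the
#'   full fit budget), `movesPerTemp`, `moveScale`, `cooling` (re-optimizer
#'   schedule), `bisectIter` (default 4).
#' @param seed Integer seed for the re-optimization anneals.
#' @return An object of class `klProfile`: `parameter`, `best`, `lower`,
#'   `upper`, `lowerBounded`, `upperBounded`, `threshold`, `alpha`, a
#'   `points` data frame (theta, X2) and `boundarySets` (the full factor
#'   vectors at every accepted profile point, used for envelopes).
#' @export
profileParameter <- function(problem, fit, param, alpha = 0.05,
                             control = list(), seed = 1L) {
  ctl <- utils::modifyList(list(stepFactor = 1.2, boundFactor = 1e3,
                                reoptEval = max(20L, round(0.1 * fit$schedule$maxEval)),
                                movesPerTemp = 10L, moveScale = 0.25,
                                cooling = 0.85, bisectIter = 4L), control)
  sch <- list(maxEval = ctl$reoptEval, movesPerTemp = ctl$movesPerTemp,
              moveScale = ctl$moveScale, cooling = ctl$cooling)
  m <- length(fit$factors)
  i <- if (is.character(param)) match(param, names(fit$factors)) else as.integer(param)
  if (is.na(i) || i < 1L || i > m) stop("unknown parameter '", param, "'")
  thr <- chi2Threshold(alpha)
  # anchor of Eq-style differences; lowered on the fly if a re-optimization
  # finds a better point than the fit itself (the threshold is defined
  # relative to the global minimum, not to wherever the annealer stopped)
  X2bf <- fit$X2
  best <- fit$factors[i]

  pts <- data.frame(theta = best, X2 = X2bf)
  sets <- list(fit$factors)
  seedCounter <- 0L
  evalAt <- function(theta, warm) {
    seedCounter <<- seedCounter + 1L
    reoptimizeFixed(problem, i, theta, warm, sch, seed + seedCounter)
  }

  walk <- function(direction) {
    theta <- best
    warm <- fit$factors
    lastIn <- best; lastInX2 <- X2bf
    repeat {
      theta <- if (direction > 0) theta * ctl$stepFactor else theta / ctl$stepFactor
      if (theta > best * ctl$boundFactor || theta < best / ctl$boundFactor)
        return(list(bound = NA_real_, bounded = FALSE))
      res <- evalAt(theta, warm)
      pts <<- rbind(pts, data.frame(theta = theta, X2 = res$X2))
      if (is.finite(res$X2) && res$X2 < X2bf) X2bf <<- res$X2
      if (is.finite(res$X2) && res$X2 - X2bf <= thr) {
        sets[[length(sets) + 1L]] <<- res$factors
        warm <- res$factors
        lastIn <- theta; lastInX2 <- res$X2
      } else {
        # bracket [lastIn, theta]; bisect in log space
        loT <- min(lastIn, theta); hiT <- max(lastIn, theta)
        for (b in seq_len(ctl$bisectIter)) {
          midT <- exp((log(loT) + log(hiT)) / 2)
          rmid <- evalAt(midT, warm)
          pts <<- rbind(pts, data.frame(theta = midT, X2 = rmid$X2))
          if (is.finite(rmid$X2) && rmid$X2 < X2bf) X2bf <<- rmid$X2
          inside <- is.finite(rmid$X2) && rmid$X2 - X2bf <= thr
          if (inside) {
            sets[[length(sets) + 1L]] <<- rmid$factors
            warm <- rmid$factors
          }
          if (direction > 0) {
            if (inside) loT <- midT else hiT <- midT
          } else {
            if (inside) hiT <- midT else loT <- midT
          }
        }
        return(list(bound = if (direction > 0) loT else hiT, bounded = TRUE))
      }
    }
  }
  up <- walk(+1); dn <- walk(-1)
  structure(list(parameter = names(fit$factors)[i] %||% paste0("E", i),
                 best = unname(best),
                 lower = if (dn$bounded) dn$bound else NA_real_,
                 upper = if (up$bounded) up$bound else NA_real_,
                 lowerBounded = dn$bounded, upperBounded = up$bounded,
                 threshold = thr, alpha = alpha,
                 points = pts[order(pts$theta), ],
                 boundarySets = sets),
            class = "klProfile")
}

#' @export
print.klProfile <- function(x, ...) {
  cat(sprintf("klProfile '%s': best %.4g, %g%% CI [%s, %s]\n",
              x$parameter, x$best, 100 * (1 - x$alpha),
              if (x$lowerBounded) sprintf("%.4g", x$lower) else "unbounded",
              if (x$upperBounded) sprintf("%.4g", x$upper) else "unbounded"))
  invisible(x)
}

#' Profile table
#'
#' @param profiles List of `klProfile` objects.
#' @return Data frame (parameter, best, lower, upper, lowerBounded,
#'   upperBounded, threshold, alpha).
#' @export
profileTable <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p)
    data.frame(parameter = p$parameter, best = p$best,
               lower = p$lower, upper = p$upper,
               lowerBounded = p$lowerBounded, upperBounded = p$upperBounded,
               threshold = p$threshold, alpha = p$alpha)))
}

#' Min/max envelopes of dependent variables over the confidence region
#'
#' Simulates the best-fit factors plus every parameter set accepted during
#' profiling (all profile points inside the threshold, not only the two
#' extremes per parameter: the extreme-parameter heuristic can miss
#' non-monotone responses, so the superset is used) and takes pointwise
#' minima and maxima of the requested variables. Parameter sets that no
#' longer integrate are skipped with a warning.
#'
#' @param problem A [fitProblem()].
#' @param fit A `klFit`.
#' @param profiles List of `klProfile` objects carrying boundary sets (may be
#'   empty: the band then collapses onto the best-fit trajectory).
#' @param conditionId Which condition to simulate.
#' @param variables Data frame with columns `type` (`"conc"`, `"flux"` or
#'   `"mid"`), `id` (metabolite or reaction id), and for `"mid"` rows
#'   `fragment` and `isotopologue_index`.
#' @param times Output times (minutes); default the problem's grid.
#' @return Named list of data frames (variable label -> time, lower, best,
#'   upper), class `klEnvelopes`.
#' @export
envelopes <- function(problem, fit, profiles, conditionId, variables,
                      times = NULL) {
  if (is.null(times)) times <- problem$times[[conditionId]]
  sets <- c(list(fit$factors), unlist(lapply(profiles, `[[`, "boundarySets"),
                                      recursive = FALSE))
  cond <- problem$conditions[[conditionId]]
  if (is.null(cond)) stop("unknown condition '", conditionId, "'")
  model <- problem$models[[conditionId]]
  label <- function(v) {
    if (v["type"] == "mid")
      sprintf("%s %s m%s", v["id"],
              if (nzchar(v["fragment"]) && !is.na(v["fragment"])) v["fragment"] else "C*",
              v["isotopologue_index"])
    else sprintf("%s %s", v["id"], v["type"])
  }
  curves <- list()
  for (k in seq_along(sets)) {
    params <- applyParameterGroups(problem$params, problem$groups, sets[[k]])
    setModelParams(model, params)
    traj <- tryCatch(integrateOdes(model, times, method = problem$method,
                                   rtol = problem$rtol, atol = problem$atol),
                     error = function(e) e)
    if (inherits(traj, "error")) {
      warning("parameter set ", k, " no longer integrates; skipped")
      next
    }
    vals <- matrix(NA_real_, length(times), nrow(variables))
    for (v in seq_len(nrow(variables))) {
      row <- variables[v, ]
      vals[, v] <- switch(as.character(row$type),
        conc = traj$concentrations[, row$id],
        flux = traj$net[, row$id],
        mid = vapply(seq_along(times), function(ti) {
          mid <- toIsotopologues(isotopomersAt(traj, row$id, ti),
                                 parseFragment(row$fragment))
          unclass(mid)[[as.integer(row$isotopologue_index) + 1L]]
        }, 0),
        stop("unknown variable type '", row$type, "'"))
    }
    curves[[length(curves) + 1L]] <- list(best = (k == 1L), vals = vals)
  }
  if (!length(curves) || !curves[[1L]]$best)
    stop("best-fit parameter set failed to integrate")
  out <- list()
  for (v in seq_len(nrow(variables))) {
    allv <- vapply(curves, function(cv) cv$vals[, v], numeric(length(times)))
    out[[label(vapply(variables[v, ], as.character, ""))]] <- data.frame(
      time = times,
      lower = apply(allv, 1L, min),
      best = curves[[1L]]$vals[, v],
      upper = apply(allv, 1L, max))
  }
  structure(out, class = "klEnvelopes")
}
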