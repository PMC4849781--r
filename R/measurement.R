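#' Convert an isotopomer vector to isotopologue (MID) fractions
#'
#' GC/MS measures isotopologues (mass isotopomers): classes of isotopomers
#' sharing the same number of 13C atoms, reported as fractions m0, m1, m2, ...
#' For a fragment spanning carbons `a..b`, isotopomers are binned by the
#' popcount of their mask restricted to the fragment's bits and the bin sums
#' are divided by the total concentration. Invariant to scaling of the
#' isotopomer vector by any positive constant.
#'
#' @param iso Isotopomer concentration vector, length `2^nCarbons` (bit k-1 of
#'   the index-1 mask set means 13C at carbon k).
#' @param fragment Integer pair `c(a, b)` (1-based, inclusive carbon range) or
#'   `NULL` for the whole molecule.
#' @return Object of class `klMid`: numeric vector `m0..m(b-a+1)` of
#'   fractions. If the total is zero the fractions are undefined; `m0 = 1` is
#'   returned with attribute `undefined = TRUE`.
#' @export
toIsotopologues <- function(iso, fragment = NULL) {
  nStates <- length(iso)
  n <- as.integer(round(log2(nStates)))
  if (2^n != nStates) stop("isotopomer vector length must be a power of two")
  if (is.null(fragment)) fragment <- c(1L, n)
  a <- fragment[1L]; b <- fragment[2L]
  if (a < 1L || b > n || a > b)
    stop("fragment range [", a, ",", b, "] outside carbons 1..", n)
  masks <- 0:(nStates - 1L)
  fragBits <- bitwAnd(bitwShiftR(masks, a - 1L), 2^(b - a + 1L) - 1L)
  weight <- vapply(fragBits, function(m) sum(as.integer(intToBits(m))), 0L)
  tot <- sum(iso)
  k <- b - a + 1L
  if (tot <= 0) {
    out <- c(1, numeric(k))
    names(out) <- paste0("m", 0:k)
    attr(out, "undefined") <- TRUE
    class(out) <- "klMid"
    return(out)
  }
  out <- as.vector(tapply(iso, factor(weight, levels = 0:k), sum))
  out[is.na(out)] <- 0
  out <- out / tot
  names(out) <- paste0("m", 0:k)
  attr(out, "undefined") <- FALSE
  class(out) <- "klMid"
  out
}

#' @export
print.klMid <- function(x, ...) {
  v <- unclass(x); attributes(v) <- list(names = names(x))
  print(round(v, 6))
  if (isTRUE(attr(x, "undefined"))) cat("  (total concentration 0: fractions undefined)\n")
  invisible(x)
}

#' MID of the pooled hexoses measured as sorbitol
#'
#' Borohydride treatment of the incubation medium reduces both glucose and
#' fructose to sorbitol, so the measured sorbitol MID is the
#' concentration-weighted mixture of the two hexose pools: the isotopomer
#' vectors are summed and converted over C1-C6.
#'
#' @param glucoseIso,fructoseIso Isotopomer vectors of the two 6-carbon
#'   hexoses (length 64), in the same concentration units.
#' @return `klMid` fractions m0..m6 for sorbitol (undefined flag if both
#'   totals are zero).
#' @export
pooledHexoseMid <- function(glucoseIso, fructoseIso) {
  if (length(glucoseIso) != 64L || length(fructoseIso) != 64L)
    stop("both hexoses must be 6-carbon (isotopomer vectors of length 64)")
  toIsotopologues(glucoseIso + fructoseIso, c(1L, 6L))
}

parseFragment <- function(fragment) {
  if (is.null(fragment) || is.na(fragment) || fragment %in% c("", "whole"))
    return(NULL)
  m <- regmatches(fragment, regexec("^C([0-9]+)-C([0-9]+)$", fragment))[[1L]]
  if (length(m) != 3L)
    stop("cannot parse fragment '", fragment, "' (expected e.g. 'C1-C4')")
  c(as.integer(m[2L]), as.integer(m[3L]))
}

#' Evaluate observables on a trajectory
#'
#' Computes the predicted values `Z_i` that are compared against measurements:
#' total concentrations or (fragment) isotopologue fractions at a given time.
#' The special metabolite name `"sorbitol"` denotes the pooled
#' glucose+fructose hexose measurement and requires `pool` to name the two
#' hexoses.
#'
#' @param traj A `klTrajectory`.
#' @param specs Data frame with columns `metabolite`, `fragment` (`"C1-C4"`
#'   style, `""`/`NA` for the whole molecule, ignored for concentrations),
#'   `isotopologue_index` (integer m-index, or `NA`/`"conc"` for a total
#'   concentration), and optionally `observable_id`.
#' @param time Time (minutes) at which to evaluate; must match an output time
#'   of the trajectory (nearest within 1e-6 min).
#' @param pool Character vector of two metabolite ids pooled for `"sorbitol"`
#'   rows (default `c("eGlc", "eFru")`).
#' @return The `specs` data frame with a `value` column of predictions.
#' @export
observablesAt <- function(traj, specs, time, pool = c("eGlc", "eFru")) {
  ti <- which(abs(traj$times - time) < 1e-6)
  if (length(ti) != 1L)
    stop("time ", time, " min is not an output time of the trajectory")
  net <- traj$model$net
  vals <- numeric(nrow(specs))
  for (i in seq_len(nrow(specs))) {
    met <- specs$metabolite[i]
    idx <- specs$isotopologue_index[i]
    isConc <- is.na(idx) || identical(as.character(idx), "conc")
    if (isConc) {
      if (!met %in% colnames(traj$concentrations))
        stop("unknown observable metabolite '", met, "'")
      vals[i] <- traj$concentrations[ti, met]
      next
    }
    idx <- as.integer(idx)
    frag <- parseFragment(specs$fragment[i])
    if (identical(met, "sorbitol")) {
      iso <- isotopomersAt(traj, pool[1L], ti) + isotopomersAt(traj, pool[2L], ti)
      mid <- toIsotopologues(iso, c(1L, 6L))
    } else {
      if (is.null(net$metabolites[[met]]))
        stop("unknown observable metabolite '", met, "'")
      if (!net$metabolites[[met]]$labelable)
        stop("metabolite '", met, "' is not labelable; no MID observable")
      mid <- toIsotopologues(isotopomersAt(traj, met, ti), frag)
    }
    if (idx < 0L || idx >= length(mid))
      stop("isotopologue index m", idx, " out of range for '", met, "'")
    vals[i] <- unclass(mid)[[idx + 1L]]
  }
  specs$value <- vals
  specs
}

#' Standard hexose/triose fragment catalogue
#'
#' The fragment ranges quantified by the GC/MS protocol: whole-molecule
#' C1-C6 hexoses (medium glucose, glycogen glucose, sorbitol), the C1-C4 and
#' C3-C6 glycogen glucose fragments, whole-molecule C1-C3 lactate, and the
#' C2-C4/C2-C5 glutamate fragments. Arbitrary ranges remain allowed in
#' [toIsotopologues()]; this catalogue is a convenience for building
#' measurement schemas.
#'
#' @return Data frame (molecule, fragment).
#' @export
fragmentCatalogue <- function() {
  data.frame(
    molecule = c("glucose", "glycogen", "glycogen", "glycogen",
                 "lactate", "glutamate", "glutamate", "sorbitol"),
    fragment = c("C1-C6", "C1-C6", "C1-C4", "C3-C6",
                 "C1-C3", "C2-C4", "C2-C5", "C1-C6"))
}
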