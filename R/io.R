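# Native structured-config I/O (YAML network + TSV atom maps), measurement
# schema TSV, and SBML level 2/3 import.

fmtNum <- function(x) {
  # fixed float formatting so the writer is bit-reproducible
  if (is.numeric(x)) sprintf("%.12g", x) else x
}

lawToList <- function(law) {
  if (is.null(law)) return(NULL)
  out <- list(template = law$template)
  if (length(law$params)) out$params <- as.list(law$params)
  if (length(law$conc)) out$conc <- as.list(law$conc)
  if (length(law$inhibitors)) out$inhibitors <- as.list(law$inhibitors)
  if (!is.null(law$forward)) out$forward <- law$forward
  if (!is.null(law$reverse)) out$reverse <- law$reverse
  if (isTRUE(law$net)) out$net <- TRUE
  out
}

lawFromList <- function(l) {
  if (is.null(l)) return(NULL)
  rateLaw(l$template,
          params = unlist(l$params) %||% character(0),
          conc = unlist(l$conc) %||% character(0),
          inhibitors = unlist(l$inhibitors) %||% character(0),
          forward = l$forward, reverse = l$reverse, net = isTRUE(l$net))
}

#' Write a network in the native format
#'
#' One YAML document for the structure (compartments, metabolites, reactions
#' with their rate laws, ncell) plus one TSV table for the atom-transition
#' maps (`reaction`, `substrate` as `slot.carbon`, `product` as
#' `slot.carbon`). Keys are emitted in a fixed sorted order and floats with
#' fixed formatting, so writing the same network twice is byte-identical.
#'
#' @param net A `klNetwork`.
#' @param file Path of the YAML network file.
#' @param atomMapFile Path of the atom-map TSV (default: `file` with
#'   `.atoms.tsv` appended).
#' @return Invisibly, the two paths.
#' @export
writeNetwork <- function(net, file, atomMapFile = paste0(file, ".atoms.tsv")) {
  doc <- list(
    compartments = lapply(net$compartments[order(names(net$compartments))],
                          function(x) list(id = x$id, name = x$name,
                                           volume = fmtNum(x$volume))),
    metabolites = lapply(net$metabolites[order(names(net$metabolites))],
                         function(m) list(compartment = m$compartment,
                                          constant = m$constant,
                                          id = m$id,
                                          initial_concentration = fmtNum(m$initialConcentration),
                                          labelable = m$labelable,
                                          n_carbons = m$nCarbons,
                                          name = m$name)),
    name = net$name,
    ncell = fmtNum(net$ncell),
    reactions = lapply(net$reactions[order(names(net$reactions))],
                       function(r) list(id = r$id,
                                        invisible = r$invisible,
                                        law = lawToList(r$law),
                                        name = r$name,
                                        products = as.list(r$products),
                                        reversible = r$reversible,
                                        substrates = as.list(r$substrates))),
    symmetric_metabolites = as.list(sort(net$symmetricMetabolites)))
  doc$compartments <- unname(doc$compartments)
  doc$metabolites <- unname(doc$metabolites)
  doc$reactions <- unname(doc$reactions)
  writeLines(yaml::as.yaml(doc), file)

  rows <- list()
  for (r in net$reactions[order(names(net$reactions))]) {
    if (is.null(r$atomMap)) next
    m <- r$atomMap[order(r$atomMap$subSlot, r$atomMap$subCarbon), ]
    rows[[r$id]] <- data.frame(
      reaction = r$id,
      substrate = sprintf("%d.%d", m$subSlot, m$subCarbon),
      product = sprintf("%d.%d", m$prodSlot, m$prodCarbon))
  }
  tbl <- if (length(rows)) do.call(rbind, rows)
  else data.frame(reaction = character(0), substrate = character(0),
                  product = character(0))
  utils::write.table(tbl, atomMapFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(file, atomMapFile))
}

#' Read a network from the native format
#'
#' @param file YAML network file written by [writeNetwork()] (or by hand).
#' @param atomMapFile Atom-map TSV; default as in [writeNetwork()]. `NULL` to
#'   skip atom maps.
#' @return A validated `klNetwork`.
#' @export
readNetwork <- function(file, atomMapFile = paste0(file, ".atoms.tsv")) {
  doc <- yaml::read_yaml(file)
  comps <- lapply(doc$compartments, function(x)
    Compartment(x$id, x$name %||% x$id, as.numeric(x$volume)))
  mets <- lapply(doc$metabolites, function(m)
    Metabolite(m$id, m$name %||% m$id, m$compartment,
               nCarbons = m$n_carbons %||% 0L,
               labelable = m$labelable %||% ((m$n_carbons %||% 0L) > 0L),
               constant = m$constant %||% FALSE,
               initialConcentration = as.numeric(m$initial_concentration %||% 0)))
  maps <- list()
  if (!is.null(atomMapFile) && file.exists(atomMapFile)) {
    tbl <- utils::read.table(atomMapFile, sep = "\t", header = TRUE,
                             colClasses = "character")
    splitSC <- function(s) {
      parts <- strsplit(s, ".", fixed = TRUE)
      list(slot = vapply(parts, function(p) as.integer(p[1L]), 0L),
           carbon = vapply(parts, function(p) as.integer(p[2L]), 0L))
    }
    for (rid in unique(tbl$reaction)) {
      rt <- tbl[tbl$reaction == rid, ]
      s <- splitSC(rt$substrate); p <- splitSC(rt$product)
      maps[[rid]] <- atomMap(s$slot, s$carbon, p$slot, p$carbon)
    }
  }
  rxns <- lapply(doc$reactions, function(r)
    Reaction(r$id, r$name %||% r$id,
             substrates = unlist(r$substrates) %||% numeric(0),
             products = unlist(r$products) %||% numeric(0),
             reversible = r$reversible %||% FALSE,
             invisible = r$invisible %||% FALSE,
             atomMap = maps[[r$id]],
             law = lawFromList(r$law)))
  Network(comps, mets, rxns, ncell = as.numeric(doc$ncell),
          symmetricMetabolites = unlist(doc$symmetric_metabolites) %||% character(0),
          name = doc$name %||% "model")
}

#' Read/write a parameter vector (TSV: parameter, value)
#'
#' @param params Named numeric vector.
#' @param file Path.
#' @return `readParameters`: named numeric vector.
#' @export
writeParameters <- function(params, file) {
  utils::write.table(
    data.frame(parameter = names(params), value = fmtNum(unname(params))),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeParameters
#' @export
readParameters <- function(file) {
  tbl <- utils::read.table(file, sep = "\t", header = TRUE,
                           colClasses = c("character", "numeric"))
  stats::setNames(tbl$value, tbl$parameter)
}

#' Read/write conditions (YAML)
#'
#' @param conditions Named list of [Condition()] objects.
#' @param file Path.
#' @return `readConditions`: named list of conditions.
#' @export
writeConditions <- function(conditions, file) {
  doc <- lapply(conditions, function(cd) {
    out <- list(id = cd$id, t_end = cd$tEnd)
    if (length(cd$initial)) out$initial <- as.list(cd$initial)
    if (length(cd$tracer))
      out$tracer <- lapply(cd$tracer, function(tr)
        list(mask = as.list(tr$mask), fraction = as.list(tr$fraction)))
    if (!is.null(cd$ncell)) out$ncell <- cd$ncell
    if (!is.null(cd$volumes)) out$volumes <- as.list(cd$volumes)
    out
  })
  writeLines(yaml::as.yaml(unname(doc)), file)
  invisible(file)
}

#' @rdname writeConditions
#' @export
readConditions <- function(file) {
  doc <- yaml::read_yaml(file)
  conds <- lapply(doc, function(cd)
    Condition(cd$id,
              initial = unlist(cd$initial) %||% numeric(0),
              tracer = lapply(cd$tracer %||% list(), function(tr)
                tracerSpec(unlist(tr$mask), unlist(tr$fraction))),
              ncell = cd$ncell, volumes = unlist(cd$volumes),
              tEnd = cd$t_end %||% 120))
  stats::setNames(conds, vapply(conds, `[[`, "", "id"))
}

#' Read/write measurement tables (schema TSV)
#'
#' Columns: `condition_id`, `observable_id`, `metabolite`, `fragment`,
#' `isotopologue_index` (integer or `conc`), `time_min`, `value`, `sd`.
#'
#' @param dataset Measurement data frame.
#' @param file Path.
#' @return `readMeasurements`: the data frame (with integer
#'   `isotopologue_index`, `NA` for concentration rows).
#' @export
writeMeasurements <- function(dataset, file) {
  out <- dataset
  out$isotopologue_index <- ifelse(is.na(out$isotopologue_index), "conc",
                                   as.character(out$isotopologue_index))
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeMeasurements
#' @export
readMeasurements <- function(file) {
  tbl <- utils::read.table(file, sep = "\t", header = TRUE,
                           colClasses = "character")
  need <- c("condition_id", "metabolite", "fragment", "isotopologue_index",
            "time_min", "value", "sd")
  missing <- setdiff(need, names(tbl))
  if (length(missing))
    stop("measurement file lacks column(s): ", paste(missing, collapse = ", "),
         " (rows are 1..", nrow(tbl), ")")
  tbl$isotopologue_index <- suppressWarnings(
    ifelse(tbl$isotopologue_index == "conc", NA_integer_,
           as.integer(tbl$isotopologue_index)))
  for (col in c("time_min", "value", "sd")) {
    v <- suppressWarnings(as.numeric(tbl[[col]]))
    if (anyNA(v))
      stop("measurement file: non-numeric '", col, "' in row(s) ",
           paste(which(is.na(v)), collapse = ", "))
    tbl[[col]] <- v
  }
  tbl
}

# ---- SBML import ---------------------------------------------------------

mathmlToExpr <- function(node) {
  nm <- xml2::xml_name(node)
  kids <- xml2::xml_children(node)
  switch(nm,
    math = {
      if (length(kids) != 1L) stop("SBML MathML: expected one root expression")
      mathmlToExpr(kids[[1L]])
    },
    ci = trimws(xml2::xml_text(node)),
    cn = {
      type <- xml2::xml_attr(node, "type")
      if (!is.na(type) && type == "e-notation") {
        parts <- trimws(strsplit(xml2::xml_text(node), "\n")[[1L]])
        parts <- parts[nzchar(parts)]
        paste0("(", parts[1L], "e", parts[2L], ")")
      } else paste0("(", trimws(xml2::xml_text(node)), ")")
    },
    apply = {
      op <- xml2::xml_name(kids[[1L]])
      args <- vapply(kids[-1L], mathmlToExpr, "")
      switch(op,
        plus = paste0("(", paste(args, collapse = " + "), ")"),
        minus = if (length(args) == 1L) paste0("(-", args, ")")
                else paste0("(", paste(args, collapse = " - "), ")"),
        times = paste0("(", paste(args, collapse = " * "), ")"),
        divide = paste0("(", args[1L], " / ", args[2L], ")"),
        power = paste0("(", args[1L], " ^ ", args[2L], ")"),
        exp = paste0("exp(", args[1L], ")"),
        ln = paste0("log(", args[1L], ")"),
        abs = paste0("abs(", args[1L], ")"),
        root = paste0("sqrt(", args[length(args)], ")"),
        stop("SBML MathML operator '", op, "' is not supported"))
    },
    stop("SBML MathML node '", nm, "' is not supported"))
}

#' Import a kinetic model from SBML (level 2/3)
#'
#' Species become metabolites, SBML reactions become reactions, compartment
#' sizes become compartment volumes and each kinetic law's MathML is lowered
#' into a generic expression rate law (a reversible SBML law is treated as a
#' net rate: its positive part is the forward and its negative part the
#' reverse rate). Global and local parameters are collected into one flat
#' parameter vector (local parameters prefixed `reactionId.`); compartment
#' ids are added as parameters holding their sizes so kinetic expressions
#' referencing them evaluate. Carbon counts and atom-transition maps are not
#' expressible in plain SBML and come from an auxiliary annotation table.
#'
#' @param file SBML file path.
#' @param carbonFile Optional TSV (`species`, `n_carbons`, `labelable`)
#'   annotating carbon skeletons; species absent from it get 0 carbons.
#' @param atomMapFile Optional atom-map TSV in the native format (see
#'   [writeNetwork()]).
#' @param ncell Cell number for the imported model (SBML has no such
#'   concept; default 1 makes fluxes per-litre quantities).
#' @return List with `network` and `params`.
#' @export
importSBML <- function(file, carbonFile = NULL, atomMapFile = NULL, ncell = 1) {
  doc <- xml2::read_xml(file)
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) stop("no <model> element in '", file, "'")

  att <- function(node, name, default = NA_character_) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) default else v
  }
  carbons <- list()
  if (!is.null(carbonFile)) {
    tbl <- utils::read.table(carbonFile, sep = "\t", header = TRUE,
                             colClasses = "character")
    for (i in seq_len(nrow(tbl)))
      carbons[[tbl$species[i]]] <- list(
        n = as.integer(tbl$n_carbons[i]),
        lab = tolower(tbl$labelable[i]) %in% c("true", "1", "yes"))
  }

  comps <- lapply(xml2::xml_find_all(model, ".//listOfCompartments/compartment"),
                  function(x) {
                    size <- as.numeric(att(x, "size", att(x, "volume", "1")))
                    Compartment(att(x, "id"), att(x, "name", att(x, "id")), size)
                  })
  if (!length(comps)) stop("SBML model declares no compartments")
  compSizes <- stats::setNames(vapply(comps, `[[`, 0, "volume"),
                               vapply(comps, `[[`, "", "id"))

  mets <- lapply(xml2::xml_find_all(model, ".//listOfSpecies/species"),
                 function(x) {
                   id <- att(x, "id")
                   if (is.na(id)) stop("SBML species without id")
                   cb <- carbons[[id]]
                   conc <- as.numeric(att(x, "initialConcentration", NA))
                   if (is.na(conc)) {
                     amt <- as.numeric(att(x, "initialAmount", "0"))
                     conc <- amt / compSizes[[att(x, "compartment")]]
                   }
                   Metabolite(id, att(x, "name", id), att(x, "compartment"),
                              nCarbons = if (is.null(cb)) 0L else cb$n,
                              labelable = if (is.null(cb)) FALSE else cb$lab,
                              constant = att(x, "constant", "false") == "true" ||
                                att(x, "boundaryCondition", "false") == "true",
                              initialConcentration = max(conc, 0))
                 })

  params <- numeric(0)
  for (p in xml2::xml_find_all(model, ".//listOfParameters/parameter")) {
    # global parameters only: local ones live under kineticLaw
    if (xml2::xml_name(xml2::xml_parent(xml2::xml_parent(p))) != "model") next
    params[[att(p, "id")]] <- as.numeric(att(p, "value", "0"))
  }
  params <- c(params, compSizes[setdiff(names(compSizes), names(params))])

  maps <- list()
  if (!is.null(atomMapFile) && file.exists(atomMapFile)) {
    tbl <- utils::read.table(atomMapFile, sep = "\t", header = TRUE,
                             colClasses = "character")
    for (rid in unique(tbl$reaction)) {
      rt <- tbl[tbl$reaction == rid, ]
      sp <- strsplit(rt$substrate, ".", fixed = TRUE)
      pp <- strsplit(rt$product, ".", fixed = TRUE)
      maps[[rid]] <- atomMap(vapply(sp, function(x) as.integer(x[1L]), 0L),
                             vapply(sp, function(x) as.integer(x[2L]), 0L),
                             vapply(pp, function(x) as.integer(x[1L]), 0L),
                             vapply(pp, function(x) as.integer(x[2L]), 0L))
    }
  }

  rxns <- list()
  for (x in xml2::xml_find_all(model, ".//listOfReactions/reaction")) {
    rid <- att(x, "id")
    if (is.na(rid)) stop("SBML reaction without id")
    refs <- function(path) {
      nodes <- xml2::xml_find_all(x, path)
      if (!length(nodes)) return(numeric(0))
      sp <- vapply(nodes, att, "", "species")
      st <- vapply(nodes, function(n) as.numeric(att(n, "stoichiometry", "1")), 0)
      stats::setNames(st, sp)
    }
    subs <- refs(".//listOfReactants/speciesReference")
    prods <- refs(".//listOfProducts/speciesReference")
    reversible <- att(x, "reversible", "true") == "true"
    lawNode <- xml2::xml_find_first(x, ".//kineticLaw")
    law <- NULL
    if (!inherits(lawNode, "xml_missing")) {
      for (p in xml2::xml_find_all(lawNode,
                                   ".//listOfParameters/parameter|.//listOfLocalParameters/localParameter")) {
        pid <- att(p, "id")
        params[[paste0(rid, ".", pid)]] <- as.numeric(att(p, "value", "0"))
      }
      mathNode <- xml2::xml_find_first(lawNode, ".//math")
      if (!inherits(mathNode, "xml_missing")) {
        expr <- mathmlToExpr(mathNode)
        # rename local parameters to their prefixed form
        for (p in xml2::xml_find_all(lawNode,
                                     ".//listOfParameters/parameter|.//listOfLocalParameters/localParameter")) {
          pid <- att(p, "id")
          expr <- gsub(paste0("\\b", pid, "\\b"), paste0(rid, ".", pid), expr)
        }
        law <- rateLaw("expression", forward = expr, net = reversible)
      }
    }
    rxns[[rid]] <- Reaction(rid, att(x, "name", rid), substrates = subs,
                            products = prods, reversible = reversible,
                            atomMap = maps[[rid]], law = law)
  }

  net <- Network(comps, mets, rxns, ncell = ncell,
                 name = att(model, "id", att(model, "name", "sbml-model")))
  list(network = net, params = params)
}

#' Structural summary of a network
#'
#' @param net A `klNetwork`.
#' @param params Optional parameter vector (adds its length).
#' @param groups Optional [parameterGroups()] (adds fitted-activity counts).
#' @return Named list: `reactions`, `metabolites`, `compartments`,
#'   `invisible_reactions`, and if supplied `parameters`,
#'   `fitted_activities`, `independent_factors`.
#' @export
networkSummary <- function(net, params = NULL, groups = NULL) {
  out <- list(reactions = length(net$reactions),
              metabolites = length(net$metabolites),
              compartments = length(net$compartments),
              invisible_reactions = sum(vapply(net$reactions, `[[`, TRUE, "invisible")))
  if (!is.null(params)) out$parameters <- length(params)
  if (!is.null(groups)) {
    out$fitted_activities <- length(unlist(unname(groups)))
    out$independent_factors <- length(groups)
  }
  out
}
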