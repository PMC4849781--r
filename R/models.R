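# Shipped models: the reduced hepatocyte glucose/fructose demonstration
# network, four toy networks with analytic or brute-force-checkable
# behaviour, and the synthetic tracer-dataset generator.

idMap <- function(n) atomMap(rep(1L, n), 1:n, rep(1L, n), 1:n)

# rate-law constructors that wire the "<reaction>.<slot>" naming convention
lawMM <- function(rid, subs, inhibitors = character(0)) {
  p <- c(Vmax = paste0(rid, ".Vmax"),
         stats::setNames(paste0(rid, ".Km.", subs), paste0("Km.", subs)))
  rateLaw("michaelis", params = p, inhibitors = inhibitors)
}
lawMMRev <- function(rid, subs, prods, inhibitors = character(0)) {
  p <- c(Vmax = paste0(rid, ".Vmax"),
         stats::setNames(paste0(rid, ".Ks.", subs), paste0("Ks.", subs)),
         stats::setNames(paste0(rid, ".Kp.", prods), paste0("Kp.", prods)),
         Keq = paste0(rid, ".Keq"))
  rateLaw("michaelisRev", params = p, inhibitors = inhibitors)
}
lawMA <- function(rid, reversible = FALSE) {
  p <- c(k = paste0(rid, ".k"))
  if (reversible) p <- c(p, kr = paste0(rid, ".kr"))
  rateLaw("massAction", params = p)
}
lawGK <- function(rid, S, ATP, I, R) {
  rateLaw("glucokinase",
          params = c(Vmax = paste0(rid, ".Vmax"), Km = paste0(rid, ".Km"),
                     KmATP = paste0(rid, ".KmATP"), Ki = paste0(rid, ".Ki"),
                     Kir = paste0(rid, ".Kir")),
          conc = c(S = S, ATP = ATP, I = I, R = R))
}

# Aldolase-type cleavage map: hexose C1-C3 -> 3C product 1 reversed
# (C1->C3, C2->C2, C3->C1), hexose C4-C6 -> 3C product 2 in order.
cleavageMap <- function() {
  atomMap(rep(1L, 6L), 1:6,
          c(1L, 1L, 1L, 2L, 2L, 2L), c(3L, 2L, 1L, 1L, 2L, 3L))
}

#' Build the reduced hepatocyte glucose/fructose demonstration model
#'
#' A three-compartment (medium, cytosol, mitochondria) network of 35
#' reactions covering glucose transport and phosphorylation into two hexose
#' phosphate pools (a: glycolysis-oriented, b: glycogen-oriented), the three
#' aldolase reactions, the fructose pathway (transport, fructokinase,
#' triokinase), lower glycolysis, lactate exchange, the glycogen branch, and
#' a closed energy subsystem (ATP/ADP/AMP, pyrophosphate, phosphate transport
#' and a lumped saturable mitochondrial ATP regeneration standing in for the
#' respiratory chain plus adenine translocator). Cytosolic adenine and total
#' phosphate moieties are conserved. Default parameters reproduce the
#' high-fructose phenotype: with 20 mM medium fructose, fructose 1-phosphate
#' accumulates and cytosolic ATP and phosphate are depleted, suppressing
#' glycogen accumulation and the propagation of glucose label to lactate.
#'
#' @param overrides Named numeric vector of parameter overrides; unknown
#'   names are an error.
#' @return A list with elements `network` (validated `klNetwork`), `params`
#'   (named vector) and `groups` ([parameterGroups()] of fitted enzyme
#'   activities, reaction chains grouped).
#' @export
makeDemoModel <- function(overrides = NULL) {
  comps <- list(Compartment("ext", "incubation medium", 2e-3),
                Compartment("cyt", "cytosol", 8e-5),
                Compartment("mit", "mitochondria", 2e-5))
  hex <- function(id, comp, init, name = id)
    Metabolite(id, name, comp, nCarbons = 6L, initialConcentration = init)
  tri <- function(id, comp, init, name = id)
    Metabolite(id, name, comp, nCarbons = 3L, initialConcentration = init)
  cof <- function(id, comp, init, name = id)
    Metabolite(id, name, comp, nCarbons = 0L, initialConcentration = init)
  mets <- list(
    hex("eGlc", "ext", 20, "medium glucose"),
    hex("eFru", "ext", 3, "medium fructose"),
    tri("eLac", "ext", 0.5, "medium lactate"),
    hex("Glc", "cyt", 1, "cytosolic glucose"),
    hex("G6Pa", "cyt", 0.1), hex("G6Pb", "cyt", 0.1),
    hex("F6Pa", "cyt", 0.03), hex("F6Pb", "cyt", 0.03),
    hex("FBPa", "cyt", 0.01), hex("FBPb", "cyt", 0.01),
    hex("Fru", "cyt", 0.1, "cytosolic fructose"),
    hex("F1P", "cyt", 0.1, "fructose 1-phosphate"),
    hex("G1P", "cyt", 0.02), hex("Glyc", "cyt", 2, "glycogen (glucosyl units)"),
    tri("DHAP", "cyt", 0.04), tri("GAP", "cyt", 0.01),
    tri("GA", "cyt", 0.01, "glyceraldehyde"),
    tri("BPG", "cyt", 0.005, "1,3-bisphosphoglycerate"),
    tri("PG3", "cyt", 0.4), tri("PG2", "cyt", 0.05),
    tri("PEP", "cyt", 0.2), tri("Pyr", "cyt", 0.1), tri("Lac", "cyt", 1),
    cof("cATP", "cyt", 2.8), cof("cADP", "cyt", 0.8), cof("cAMP", "cyt", 0.2),
    cof("cPi", "cyt", 8), cof("cPPi", "cyt", 0.01),
    cof("cNAD", "cyt", 0.45), cof("cNADH", "cyt", 0.05),
    cof("mATP", "mit", 2), cof("mADP", "mit", 1), cof("mPi", "mit", 16))

  rxns <- list(
    Reaction("glctr", "glucose transport (GLUT2)", c(eGlc = 1), c(Glc = 1),
             reversible = TRUE, atomMap = idMap(6), law = lawMMRev("glctr", "eGlc", "Glc")),
    Reaction("gka", "glucokinase (pool a)", c(Glc = 1, cATP = 1), c(G6Pa = 1, cADP = 1),
             atomMap = idMap(6), law = lawGK("gka", "Glc", "cATP", "F6Pa", "F1P")),
    Reaction("gkb", "glucokinase (pool b)", c(Glc = 1, cATP = 1), c(G6Pb = 1, cADP = 1),
             atomMap = idMap(6), law = lawGK("gkb", "Glc", "cATP", "F6Pb", "F1P")),
    Reaction("g6pasea", "glucose 6-phosphatase (a)", c(G6Pa = 1), c(Glc = 1, cPi = 1),
             atomMap = idMap(6), law = lawMM("g6pasea", "G6Pa")),
    Reaction("g6paseb", "glucose 6-phosphatase (b)", c(G6Pb = 1), c(Glc = 1, cPi = 1),
             atomMap = idMap(6), law = lawMM("g6paseb", "G6Pb")),
    Reaction("gpia", "glucose 6-phosphate isomerase (a)", c(G6Pa = 1), c(F6Pa = 1),
             reversible = TRUE, atomMap = idMap(6), law = lawMMRev("gpia", "G6Pa", "F6Pa")),
    Reaction("gpib", "glucose 6-phosphate isomerase (b)", c(G6Pb = 1), c(F6Pb = 1),
             reversible = TRUE, atomMap = idMap(6), law = lawMMRev("gpib", "G6Pb", "F6Pb")),
    Reaction("pfka", "phosphofructokinase (a)", c(F6Pa = 1, cATP = 1), c(FBPa = 1, cADP = 1),
             atomMap = idMap(6), law = lawMM("pfka", c("F6Pa", "cATP"))),
    Reaction("pfkb", "phosphofructokinase (b)", c(F6Pb = 1, cATP = 1), c(FBPb = 1, cADP = 1),
             atomMap = idMap(6), law = lawMM("pfkb", c("F6Pb", "cATP"))),
    Reaction("fbasea", "fructose 1,6-bisphosphatase (a)", c(FBPa = 1), c(F6Pa = 1, cPi = 1),
             atomMap = idMap(6), law = lawMM("fbasea", "FBPa")),
    Reaction("fbaseb", "fructose 1,6-bisphosphatase (b)", c(FBPb = 1), c(F6Pb = 1, cPi = 1),
             atomMap = idMap(6), law = lawMM("fbaseb", "FBPb")),
    Reaction("aldo1", "aldolase: FBP cleavage", c(FBPa = 1), c(DHAP = 1, GAP = 1),
             reversible = TRUE, atomMap = cleavageMap(),
             law = lawMMRev("aldo1", "FBPa", c("DHAP", "GAP"),
                            inhibitors = c(F1P = "aldo1.Ki.F1P"))),
    Reaction("aldo2", "aldolase: F1P cleavage", c(F1P = 1), c(DHAP = 1, GA = 1),
             reversible = TRUE, atomMap = cleavageMap(),
             law = lawMMRev("aldo2", "F1P", c("DHAP", "GA"),
                            inhibitors = c(FBPa = "aldo2.Ki.FBPa"))),
    Reaction("aldo3", "aldolase: triose transfer", c(FBPa = 1, GA = 1), c(F1P = 1, GAP = 1),
             reversible = TRUE,
             atomMap = atomMap(c(1, 1, 1, 1, 1, 1, 2, 2, 2),
                               c(1, 2, 3, 4, 5, 6, 1, 2, 3),
                               c(1, 1, 1, 2, 2, 2, 1, 1, 1),
                               c(1, 2, 3, 1, 2, 3, 4, 5, 6)),
             law = lawMMRev("aldo3", c("FBPa", "GA"), c("F1P", "GAP"))),
    Reaction("tim", "triose phosphate isomerase", c(DHAP = 1), c(GAP = 1),
             reversible = TRUE, atomMap = atomMap(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1), c(3, 2, 1)),
             law = lawMMRev("tim", "DHAP", "GAP")),
    Reaction("frutr", "fructose transport", c(eFru = 1), c(Fru = 1),
             reversible = TRUE, atomMap = idMap(6), law = lawMMRev("frutr", "eFru", "Fru")),
    Reaction("fruhk", "fructokinase", c(Fru = 1, cATP = 1), c(F1P = 1, cADP = 1),
             atomMap = idMap(6), law = lawMM("fruhk", c("Fru", "cATP"))),
    Reaction("trik", "triokinase", c(GA = 1, cATP = 1), c(GAP = 1, cADP = 1),
             atomMap = idMap(3), law = lawMM("trik", c("GA", "cATP"))),
    Reaction("gapdh", "glyceraldehyde 3-phosphate dehydrogenase",
             c(GAP = 1, cNAD = 1, cPi = 1), c(BPG = 1, cNADH = 1),
             reversible = TRUE, atomMap = idMap(3),
             law = lawMMRev("gapdh", c("GAP", "cNAD", "cPi"), c("BPG", "cNADH"))),
    Reaction("pgk", "phosphoglycerate kinase", c(BPG = 1, cADP = 1), c(PG3 = 1, cATP = 1),
             reversible = TRUE, atomMap = idMap(3),
             law = lawMMRev("pgk", c("BPG", "cADP"), c("PG3", "cATP"))),
    Reaction("pgm", "phosphoglycerate mutase", c(PG3 = 1), c(PG2 = 1),
             reversible = TRUE, atomMap = idMap(3), law = lawMMRev("pgm", "PG3", "PG2")),
    Reaction("eno", "enolase", c(PG2 = 1), c(PEP = 1),
             reversible = TRUE, atomMap = idMap(3), law = lawMMRev("eno", "PG2", "PEP")),
    Reaction("pk", "pyruvate kinase", c(PEP = 1, cADP = 1), c(Pyr = 1, cATP = 1),
             atomMap = idMap(3), law = lawMM("pk", c("PEP", "cADP"))),
    Reaction("ldh", "lactate dehydrogenase", c(Pyr = 1, cNADH = 1), c(Lac = 1, cNAD = 1),
             reversible = TRUE, atomMap = idMap(3),
             law = lawMMRev("ldh", c("Pyr", "cNADH"), c("Lac", "cNAD"))),
    Reaction("lactr", "lactate transport (MCT)", c(Lac = 1), c(eLac = 1),
             reversible = TRUE, atomMap = idMap(3), law = lawMMRev("lactr", "Lac", "eLac")),
    Reaction("pglm", "phosphoglucomutase", c(G6Pb = 1), c(G1P = 1),
             reversible = TRUE, atomMap = idMap(6), law = lawMMRev("pglm", "G6Pb", "G1P")),
    Reaction("gs", "glycogen synthesis (UGT+GS lumped)", c(G1P = 1, cATP = 1),
             c(Glyc = 1, cADP = 1, cPPi = 1),
             atomMap = idMap(6), law = lawMM("gs", c("G1P", "cATP"))),
    Reaction("gp", "glycogen phosphorylase", c(Glyc = 1, cPi = 1), c(G1P = 1),
             atomMap = idMap(6), law = lawMM("gp", c("Glyc", "cPi"))),
    Reaction("ppase", "inorganic pyrophosphatase", c(cPPi = 1), c(cPi = 2),
             law = lawMM("ppase", "cPPi")),
    Reaction("atpase", "cytosolic ATP demand", c(cATP = 1), c(cADP = 1, cPi = 1),
             law = lawMM("atpase", "cATP")),
    Reaction("adk", "adenylate kinase", c(cADP = 2), c(cATP = 1, cAMP = 1),
             reversible = TRUE, law = lawMA("adk", reversible = TRUE)),
    Reaction("nadhox", "cytosolic NADH oxidation (shuttles lumped)",
             c(cNADH = 1), c(cNAD = 1), law = lawMM("nadhox", "cNADH")),
    Reaction("pitr", "mitochondrial phosphate transport", c(cPi = 1), c(mPi = 1),
             reversible = TRUE, law = lawMMRev("pitr", "cPi", "mPi")),
    Reaction("antr", "adenine nucleotide translocator", c(mATP = 1, cADP = 1),
             c(cATP = 1, mADP = 1),
             reversible = TRUE, law = lawMMRev("antr", c("mATP", "cADP"), c("cATP", "mADP"))),
    Reaction("oxphos", "mitochondrial ATP regeneration (lumped)",
             c(mADP = 1, mPi = 1), c(mATP = 1), law = lawMM("oxphos", c("mADP", "mPi"))))

  params <- c(
    glctr.Vmax = 4e-11, glctr.Ks.eGlc = 17, glctr.Kp.Glc = 17, glctr.Keq = 1,
    gka.Vmax = 1.2e-12, gka.Km = 7.5, gka.KmATP = 0.4, gka.Ki = 0.03, gka.Kir = 0.01,
    gkb.Vmax = 1.2e-12, gkb.Km = 7.5, gkb.KmATP = 0.4, gkb.Ki = 0.03, gkb.Kir = 0.01,
    g6pasea.Vmax = 8e-13, g6pasea.Km.G6Pa = 2,
    g6paseb.Vmax = 8e-13, g6paseb.Km.G6Pb = 2,
    gpia.Vmax = 1e-10, gpia.Ks.G6Pa = 0.3, gpia.Kp.F6Pa = 0.15, gpia.Keq = 0.3,
    gpib.Vmax = 1e-10, gpib.Ks.G6Pb = 0.3, gpib.Kp.F6Pb = 0.15, gpib.Keq = 0.3,
    pfka.Vmax = 1e-12, pfka.Km.F6Pa = 0.1, pfka.Km.cATP = 0.15,
    pfkb.Vmax = 1e-12, pfkb.Km.F6Pb = 0.1, pfkb.Km.cATP = 0.15,
    fbasea.Vmax = 4e-13, fbasea.Km.FBPa = 0.01,
    fbaseb.Vmax = 4e-13, fbaseb.Km.FBPb = 0.01,
    aldo1.Vmax = 3e-12, aldo1.Ks.FBPa = 0.01, aldo1.Kp.DHAP = 2, aldo1.Kp.GAP = 1,
    aldo1.Keq = 0.068, aldo1.Ki.F1P = 2,
    aldo2.Vmax = 6e-12, aldo2.Ks.F1P = 1, aldo2.Kp.DHAP = 2, aldo2.Kp.GA = 1,
    aldo2.Keq = 0.1, aldo2.Ki.FBPa = 0.3,
    aldo3.Vmax = 8e-13, aldo3.Ks.FBPa = 0.01, aldo3.Ks.GA = 1,
    aldo3.Kp.F1P = 1, aldo3.Kp.GAP = 1, aldo3.Keq = 1,
    tim.Vmax = 1e-10, tim.Ks.DHAP = 0.6, tim.Kp.GAP = 0.4, tim.Keq = 0.045,
    frutr.Vmax = 2.5e-11, frutr.Ks.eFru = 67, frutr.Kp.Fru = 67, frutr.Keq = 1,
    fruhk.Vmax = 8e-12, fruhk.Km.Fru = 0.5, fruhk.Km.cATP = 0.4,
    trik.Vmax = 2.5e-12, trik.Km.GA = 0.05, trik.Km.cATP = 0.1,
    gapdh.Vmax = 4e-11, gapdh.Ks.GAP = 0.05, gapdh.Ks.cNAD = 0.05, gapdh.Ks.cPi = 1.5,
    gapdh.Kp.BPG = 0.01, gapdh.Kp.cNADH = 0.01, gapdh.Keq = 0.01,
    pgk.Vmax = 1.2e-11, pgk.Ks.BPG = 0.005, pgk.Ks.cADP = 0.05,
    pgk.Kp.PG3 = 0.5, pgk.Kp.cATP = 0.3, pgk.Keq = 1600,
    pgm.Vmax = 2e-11, pgm.Ks.PG3 = 0.2, pgm.Kp.PG2 = 0.05, pgm.Keq = 0.12,
    eno.Vmax = 2e-11, eno.Ks.PG2 = 0.05, eno.Kp.PEP = 0.15, eno.Keq = 4.6,
    pk.Vmax = 6e-12, pk.Km.PEP = 0.8, pk.Km.cADP = 0.05,
    ldh.Vmax = 1e-11, ldh.Ks.Pyr = 0.3, ldh.Ks.cNADH = 0.002,
    ldh.Kp.Lac = 10, ldh.Kp.cNAD = 0.2, ldh.Keq = 3600,
    lactr.Vmax = 8e-12, lactr.Ks.Lac = 3, lactr.Kp.eLac = 3, lactr.Keq = 1,
    pglm.Vmax = 1e-11, pglm.Ks.G6Pb = 0.1, pglm.Kp.G1P = 0.05, pglm.Keq = 0.06,
    gs.Vmax = 3e-12, gs.Km.G1P = 0.1, gs.Km.cATP = 0.5,
    gp.Vmax = 3e-13, gp.Km.Glyc = 2, gp.Km.cPi = 4,
    ppase.Vmax = 2e-11, ppase.Km.cPPi = 0.05,
    atpase.Vmax = 3e-12, atpase.Km.cATP = 1,
    adk.k = 5e-11, adk.kr = 5e-11,
    nadhox.Vmax = 5e-13, nadhox.Km.cNADH = 0.01,
    pitr.Vmax = 4e-11, pitr.Ks.cPi = 1, pitr.Kp.mPi = 1, pitr.Keq = 1,
    antr.Vmax = 1.2e-11, antr.Ks.mATP = 0.1, antr.Ks.cADP = 0.25,
    antr.Kp.cATP = 0.5, antr.Kp.mADP = 0.5, antr.Keq = 1,
    oxphos.Vmax = 1.2e-11, oxphos.Km.mADP = 0.3, oxphos.Km.mPi = 1.5)

  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), names(params))
    if (length(unknown))
      stop("unknown parameter override(s): ", paste(unknown, collapse = ", "))
    params[names(overrides)] <- overrides
  }

  groups <- parameterGroups(list(
    glctr = c(glctr.Vmax = 4e-11),
    gk = c(gka.Vmax = 1.2e-12, gkb.Vmax = 1.2e-12),
    g6pase = c(g6pasea.Vmax = 8e-13, g6paseb.Vmax = 8e-13),
    pfk = c(pfka.Vmax = 1e-12, pfkb.Vmax = 1e-12),
    fbase = c(fbasea.Vmax = 4e-13, fbaseb.Vmax = 4e-13),
    aldo = c(aldo1.Vmax = 3e-12, aldo2.Vmax = 6e-12, aldo3.Vmax = 8e-13),
    fru_uptake = c(frutr.Vmax = 2.5e-11, fruhk.Vmax = 8e-12),
    trik = c(trik.Vmax = 2.5e-12),
    glycolysis_lower = c(gapdh.Vmax = 4e-11, pgk.Vmax = 1.2e-11),
    pk = c(pk.Vmax = 6e-12),
    lactate_out = c(ldh.Vmax = 1e-11, lactr.Vmax = 8e-12),
    gs = c(gs.Vmax = 3e-12),
    gp = c(gp.Vmax = 3e-13),
    atp_demand = c(atpase.Vmax = 3e-12),
    oxphos = c(oxphos.Vmax = 1.2e-11, antr.Vmax = 1.2e-11, pitr.Vmax = 4e-11)))

  net <- Network(comps, mets, rxns, ncell = 2e7, name = "hepatocyte-demo")
  rep <- validateAtomMaps(net)
  if (nrow(rep)) stop("demo model atom maps invalid: ", rep$problem[1L])
  list(network = net, params = params, groups = groups)
}

#' Experimental condition library of the demonstration model
#'
#' Three 2-hour incubations of hepatocytes in 20 mM glucose media:
#' \describe{
#'   \item{A1}{20 mM glucose, 50\% enriched in \[1,2-13C2\]-glucose
#'     (isotopomer mask 3), plus 3 mM unlabelled fructose.}
#'   \item{A2}{20 mM unlabelled glucose plus 3 mM fructose, 50\% enriched in
#'     \[U-13C6\]-fructose (mask 63). A1 and A2 differ only in the labelling
#'     pattern of the substrates.}
#'   \item{B}{20 mM glucose, 50\% \[1,2-13C2\]-enriched, plus 20 mM
#'     unlabelled fructose (the high-fructose condition).}
#' }
#'
#' @return Named list of [Condition()] objects.
#' @export
demoConditions <- function() {
  glc12 <- tracerSpec(c(3L, 0L), c(0.5, 0.5))
  fruU <- tracerSpec(c(63L, 0L), c(0.5, 0.5))
  list(
    A1 = Condition("A1", initial = c(eGlc = 20, eFru = 3),
                   tracer = list(eGlc = glc12), tEnd = 120),
    A2 = Condition("A2", initial = c(eGlc = 20, eFru = 3),
                   tracer = list(eFru = fruU), tEnd = 120),
    B = Condition("B", initial = c(eGlc = 20, eFru = 20),
                  tracer = list(eGlc = glc12), tEnd = 120))
}

#' Standard observables of the demonstration experiment
#'
#' The endpoint (120 min) observables the tracer experiment quantifies:
#' medium glucose and lactate concentrations, cellular glycogen (glucosyl
#' units), and the MIDs of medium glucose (C1-C6), glycogen glucose (C1-C4
#' and C3-C6), medium lactate (C1-C3) and sorbitol (the pooled
#' glucose+fructose hexoses, C1-C6). Glutamate fragments are not observable:
#' the demo network omits the Krebs segment, so those observables are
#' disabled rather than faked.
#'
#' @param time Sampling time in minutes (default 120).
#' @return Observable-spec data frame for [generateSyntheticDataset()] /
#'   [observablesAt()].
#' @export
demoObservables <- function(time = 120) {
  conc <- data.frame(metabolite = c("eGlc", "eLac", "Glyc"), fragment = "",
                     isotopologue_index = NA_integer_)
  midBlock <- function(met, frag, k)
    data.frame(metabolite = met, fragment = frag, isotopologue_index = 0:k)
  specs <- rbind(conc,
                 midBlock("eGlc", "C1-C6", 6L),
                 midBlock("Glyc", "C1-C4", 4L),
                 midBlock("Glyc", "C3-C6", 4L),
                 midBlock("eLac", "C1-C3", 3L),
                 midBlock("sorbitol", "C1-C6", 6L))
  specs$time_min <- time
  specs$observable_id <- ifelse(
    is.na(specs$isotopologue_index),
    paste0(specs$metabolite, ".conc"),
    paste0(specs$metabolite, ".",
           ifelse(specs$fragment == "", "C", specs$fragment),
           ".m", specs$isotopologue_index))
  specs
}

#' Toy test networks
#'
#' Small networks with analytic or brute-force-checkable behaviour:
#' \describe{
#'   \item{chain3}{`A -> B -> C -> waste` (mass action, identity atom maps,
#'     3 carbons). `A` is a constant 10 mM pool, 50\% labelled at C1, and the
#'     default initial concentrations put B and C at their metabolic steady
#'     state, so label wash-in follows `1 - exp(-k t)` exactly (k = 0.1/min
#'     for B, 0.05/min for C).}
#'   \item{loop_exchange}{Reversible `A <-> B` at equilibrium plus one
#'     invisible exchange reaction between the pools: totals stay constant
#'     while label mixes.}
#'   \item{symmetric_krebs_stub}{`X -> S -> M -> waste` with S rotationally
#'     symmetric (succinate-like): C1 label entering S leaves M 50/50
#'     labelled at C1/C4.}
#'   \item{degenerate_pair}{Two sequential capacities where the observable
#'     (downstream accumulation at the endpoint) fixes only the first: the
#'     second factor's profile is flat upward (structural
#'     non-identifiability).}
#' }
#'
#' @param name One of `"chain3"`, `"loop_exchange"`, `"symmetric_krebs_stub"`,
#'   `"degenerate_pair"`.
#' @return List with `network`, `params` (true values), `groups`,
#'   `conditions` (length-1 list) and `observables` (spec data frame).
#' @export
makeToy <- function(name = c("chain3", "loop_exchange",
                             "symmetric_krebs_stub", "degenerate_pair")) {
  name <- match.arg(name)
  comp <- list(Compartment("c", "cell", 1))
  if (name == "chain3") {
    mets <- list(
      Metabolite("A", compartment = "c", nCarbons = 3L, constant = TRUE,
                 initialConcentration = 10),
      Metabolite("B", compartment = "c", nCarbons = 3L, initialConcentration = 2),
      Metabolite("C", compartment = "c", nCarbons = 3L, initialConcentration = 4),
      Metabolite("waste", compartment = "c", nCarbons = 3L, labelable = FALSE))
    rxns <- list(
      Reaction("r1", substrates = c(A = 1), products = c(B = 1),
               atomMap = idMap(3), law = lawMA("r1")),
      Reaction("r2", substrates = c(B = 1), products = c(C = 1),
               atomMap = idMap(3), law = lawMA("r2")),
      Reaction("r3", substrates = c(C = 1), products = c(waste = 1),
               atomMap = idMap(3), law = lawMA("r3")))
    params <- c(r1.k = 0.02, r2.k = 0.1, r3.k = 0.05)
    groups <- parameterGroups(list(k1 = c(r1.k = 0.02), k2 = c(r2.k = 0.1),
                                   k3 = c(r3.k = 0.05)))
    cond <- Condition("chain3", tracer = list(A = tracerSpec(c(1L, 0L), c(0.5, 0.5))),
                      tEnd = 120)
    obs <- rbind(
      data.frame(metabolite = c("B", "C"), fragment = "",
                 isotopologue_index = NA_integer_, time_min = rep(c(20, 60, 120), each = 2)),
      expand.grid(metabolite = c("B", "C"), fragment = "",
                  isotopologue_index = 0:1, time_min = c(20, 60, 120),
                  stringsAsFactors = FALSE))
  } else if (name == "loop_exchange") {
    mets <- list(
      Metabolite("A", compartment = "c", nCarbons = 3L, initialConcentration = 1.5),
      Metabolite("B", compartment = "c", nCarbons = 3L, initialConcentration = 1.5))
    rxns <- list(
      Reaction("r1", substrates = c(A = 1), products = c(B = 1), reversible = TRUE,
               atomMap = idMap(3), law = lawMA("r1", reversible = TRUE)),
      Reaction("x1", substrates = c(A = 1), products = c(B = 1), invisible = TRUE,
               atomMap = idMap(3),
               law = rateLaw("exchange", params = c(k = "x1.k"))))
    params <- c(r1.k = 0.05, r1.kr = 0.05, x1.k = 0.04)
    groups <- parameterGroups(list(kx = c(x1.k = 0.04)))
    cond <- Condition("loop_exchange",
                      tracer = list(A = tracerSpec(7L, 1)), tEnd = 60)
    obs <- data.frame(metabolite = "B", fragment = "",
                      isotopologue_index = c(0L, 3L), time_min = 30)
  } else if (name == "symmetric_krebs_stub") {
    mets <- list(
      Metabolite("X", compartment = "c", nCarbons = 4L, constant = TRUE,
                 initialConcentration = 10),
      Metabolite("S", compartment = "c", nCarbons = 4L, initialConcentration = 2),
      Metabolite("M", compartment = "c", nCarbons = 4L, initialConcentration = 2),
      Metabolite("waste", compartment = "c", nCarbons = 4L, labelable = FALSE))
    rxns <- list(
      Reaction("r1", substrates = c(X = 1), products = c(S = 1),
               atomMap = idMap(4), law = lawMA("r1")),
      Reaction("r2", substrates = c(S = 1), products = c(M = 1),
               atomMap = idMap(4), law = lawMA("r2")),
      Reaction("r3", substrates = c(M = 1), products = c(waste = 1),
               atomMap = idMap(4), law = lawMA("r3")))
    params <- c(r1.k = 0.02, r2.k = 0.1, r3.k = 0.1)
    groups <- parameterGroups(list(k1 = c(r1.k = 0.02)))
    cond <- Condition("symmetric_krebs_stub",
                      tracer = list(X = tracerSpec(1L, 1)), tEnd = 120)
    obs <- data.frame(metabolite = "M", fragment = "",
                      isotopologue_index = 0:1, time_min = 60)
    net <- Network(comp, mets, rxns, ncell = 1,
                   symmetricMetabolites = "S", name = name)
    return(list(network = net, params = params, groups = groups,
                conditions = list(cond), observables = finishObs(obs, name)))
  } else { # degenerate_pair
    mets <- list(
      Metabolite("A", compartment = "c", nCarbons = 3L, constant = TRUE,
                 initialConcentration = 1),
      Metabolite("B", compartment = "c", nCarbons = 3L, initialConcentration = 0.2),
      Metabolite("C", compartment = "c", nCarbons = 3L, initialConcentration = 0))
    rxns <- list(
      Reaction("r1", substrates = c(A = 1), products = c(B = 1),
               atomMap = idMap(3), law = lawMA("r1")),
      Reaction("r2", substrates = c(B = 1), products = c(C = 1),
               atomMap = idMap(3), law = lawMA("r2")))
    params <- c(r1.k = 0.2, r2.k = 1)
    groups <- parameterGroups(list(k1 = c(r1.k = 0.2), k2 = c(r2.k = 1)))
    cond <- Condition("degenerate_pair", tEnd = 60)
    obs <- data.frame(metabolite = "C", fragment = "",
                      isotopologue_index = NA_integer_, time_min = c(30, 60))
  }
  net <- Network(comp, mets, rxns, ncell = 1, name = name)
  list(network = net, params = params, groups = groups,
       conditions = list(cond), observables = finishObs(obs, name))
}

finishObs <- function(obs, condId) {
  obs$observable_id <- ifelse(
    is.na(obs$isotopologue_index),
    paste0(obs$metabolite, ".conc.t", obs$time_min),
    paste0(obs$metabolite, ".m", obs$isotopologue_index, ".t", obs$time_min))
  obs$condition_id <- condId
  obs
}

#' Generate a synthetic tracer dataset
#'
#' Simulates every condition with label propagation, samples the requested
#' observables, adds Gaussian noise and records the noise level as the
#' measurement standard deviation (floored at 0.01, matching the weighting
#' floor of the objective). `noiseSd` is applied on the scale each
#' measurement type actually has: as an absolute sd for isotopologue
#' fractions (GC/MS MIDs carry absolute uncertainties of roughly 0.005-0.02)
#' and as a relative sd for concentrations (biochemical assays scale with
#' the measured value). Isotopologue fractions are clipped to [0, 1] after
#' noising. Emulates an endpoint-sampled 2-hour incubation; it does not
#' emulate GC/MS natural-abundance effects (values are already-corrected
#' MIDs) nor replicate-level biological variability.
#'
#' @param net A `klNetwork`.
#' @param params Named parameter vector used as ground truth.
#' @param conditions List of [Condition()] objects.
#' @param observables Observable spec data frame (see [demoObservables()]);
#'   must carry `condition_id`, `observable_id`, `metabolite`, `fragment`,
#'   `isotopologue_index`, `time_min`.
#' @param noiseSd Gaussian noise standard deviation (0 for noise-free data).
#' @param seed Integer seed (datasets are reproducible given the seed).
#' @param ... Integrator options passed to [simulateLabeling()].
#' @return Measurement data frame in the schema used by [fitProblem()].
#' @export
generateSyntheticDataset <- function(net, params, conditions, observables,
                                     noiseSd = 0.01, seed = 1L, ...) {
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  set.seed(seed)
  rows <- list()
  for (cond in conditions) {
    specs <- observables[observables$condition_id == cond$id, , drop = FALSE]
    if (!nrow(specs)) next
    times <- sort(unique(c(0, specs$time_min, cond$tEnd)))
    traj <- simulateLabeling(net, params, cond, times = times, ...)
    for (tm in unique(specs$time_min)) {
      sel <- specs[specs$time_min == tm, , drop = FALSE]
      sel <- observablesAt(traj, sel, tm)
      isMid <- !(is.na(sel$isotopologue_index) |
                   as.character(sel$isotopologue_index) == "conc")
      sdRow <- ifelse(isMid, noiseSd, noiseSd * abs(sel$value))
      noisy <- sel$value + stats::rnorm(nrow(sel), 0, sdRow)
      noisy[isMid] <- pmin(pmax(noisy[isMid], 0), 1)
      noisy[!isMid] <- pmax(noisy[!isMid], 0)
      sel$value <- noisy
      sel$sd <- pmax(sdRow, 0.01)
      rows[[length(rows) + 1L]] <- sel
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[c("condition_id", "observable_id", "metabolite", "fragment",
        "isotopologue_index", "time_min", "value", "sd")]
}
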