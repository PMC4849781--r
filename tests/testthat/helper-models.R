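# Small networks built in code for unit tests.

# one-compartment A -> B, n carbons, identity map, mass action
twoMetNet <- function(n = 3L, k = 0.1, reversible = FALSE, kr = k,
                      initA = 2, initB = 0, constantA = FALSE) {
  law <- if (reversible)
    rateLaw("massAction", params = c(k = "r1.k", kr = "r1.kr"))
  else rateLaw("massAction", params = c(k = "r1.k"))
  net <- Network(
    list(Compartment("c", volume = 1)),
    list(Metabolite("A", compartment = "c", nCarbons = n,
                    constant = constantA, initialConcentration = initA),
         Metabolite("B", compartment = "c", nCarbons = n,
                    initialConcentration = initB)),
    list(Reaction("r1", substrates = c(A = 1), products = c(B = 1),
                  reversible = reversible,
                  atomMap = atomMap(rep(1L, n), 1:n, rep(1L, n), 1:n),
                  law = law)),
    ncell = 1)
  params <- c(r1.k = k)
  if (reversible) params <- c(params, r1.kr = kr)
  list(net = net, params = params)
}

# bimolecular condensation X + Y -> Z (3+3 -> 6 carbons), mass action
condensationNet <- function(kf = 0.05, initX = 1, initY = 1) {
  net <- Network(
    list(Compartment("c", volume = 1)),
    list(Metabolite("X", compartment = "c", nCarbons = 3L, initialConcentration = initX),
         Metabolite("Y", compartment = "c", nCarbons = 3L, initialConcentration = initY),
         Metabolite("Z", compartment = "c", nCarbons = 6L)),
    list(Reaction("cond", substrates = c(X = 1, Y = 1), products = c(Z = 1),
                  atomMap = atomMap(c(1, 1, 1, 2, 2, 2), c(1, 2, 3, 1, 2, 3),
                                    rep(1L, 6), 1:6),
                  law = rateLaw("massAction", params = c(k = "cond.k")))),
    ncell = 1)
  list(net = net, params = c(cond.k = kf))
}

uniformIso <- function(n) rep(1 / 2^n, 2^n)
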