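---
title: "Dynamic kinetic models with nonstationary 13C label propagation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic kinetic models with nonstationary 13C label propagation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinlabel)
```

## The model

`kinlabel` simulates compartmentalized kinetic models of cellular metabolism
together with the propagation of ¹³C label from isotopically enriched
substrates, without assuming either metabolic or isotopic steady state. The
deterministic backbone is the concentration ODE system

$$\frac{dc}{dt} \;=\; N \, j(c, p) \, \frac{n_\mathrm{cell}}{vol},$$

where $c$ is the vector of metabolite concentrations (mM), $N$ the
stoichiometric matrix, $j(c,p)$ the vector of reaction rates in
mmol·cell⁻¹·min⁻¹ given the kinetic parameters $p$, $n_\mathrm{cell}$ the
cell number and $vol$ the volume (litres) of the compartment housing each
metabolite. Constant (boundary) metabolites are removed from the state
vector rather than carried as zero-derivative entries, which keeps the
Jacobian small.

Every reversible reaction carries *separate* forward and reverse rates that
share most parameters. Reverse maximal rates are never free parameters: they
are derived from the forward capacity and the equilibrium constant by the
Haldane relationship,
$V_r = V_f \prod K_P \,/\, (K_{eq} \prod K_S)$ (Michaelis constants raised
to their stoichiometric powers), so that the net rate vanishes exactly where
$\prod [P] / \prod [S] = K_{eq}$. This ties the kinetics to thermodynamics
and halves the number of capacities to estimate. *Invisible* reactions
exchange label between pools at a dedicated exchange rate without any
total-concentration effect: they contribute an all-zero stoichiometric
column and two equal, opposite label-routing operations.

### Isotopomer propagation

A metabolite with $n$ tracked carbons has $2^n$ positional isotopomers,
indexed by a bitmask in which bit $k-1$ set means ¹³C at carbon $C_k$
(carbon numbering follows biochemical convention, C1 at the carbonyl end of
sugars). Each directional flux $J$ is decomposed over the isotopomer
combinations of its labelable substrates: the combination
$(i_1, \dots, i_s)$ carries flux $J \prod_k f_k(i_k)$, where $f_k$ is the
fractional abundance of isotopomer $i_k$ in substrate pool $k$ (well-mixed
assumption: multi-substrate combinations use products of independent
fractional abundances). The combination's carbons are routed through the
reaction's atom-transition map to exactly one isotopomer of each labelable
product. Carbons that leave to species whose isotopomers are not simulated
(CO₂, cofactors) are routed to a declared non-labelable sink slot;
bijectivity of the map is enforced only over labelable species.

The totals and all isotopomer blocks form one joint stiff ODE system — there
is no operator splitting — so label propagation remains correct through fast
transients. Isotopomers are only allocated for metabolites actually
reachable by carbon flow from the condition's enriched substrates
(reachability is computed per condition from the atom maps); unreachable
labelable pools are simulated as totals and reported as unlabelled. Direct
$2^n$ enumeration is used rather than a cumomer or EMU reduction: at this
model scale (≤ 6–7 carbons, ≤ 128 states per pool) the flat representation
is simpler and fast in compiled code.

Three conventions deserve explicit statement because they are easy to get
silently wrong:

* **Rotational symmetry** (succinate/fumarate-like molecules): label
  produced into a symmetric pool is split 50/50 between the two molecular
  orientations. Because *all* production (including initial conditions) is
  symmetrized, the pool remains orientation-symmetric and consumption may
  read it directly.
* **Zero-pool guard**: when a labelable pool's total falls below
  10⁻¹² mM, its fractional abundances are defined as $m_0 = 1$ for flux
  decomposition, avoiding 0/0 at startup.
* **Negative trial concentrations** proposed by the implicit integrator are
  clamped to zero inside rate evaluation only; the state itself is not
  modified. There is no event handling for substrate exhaustion —
  concentrations approach zero smoothly through the clamped rates.

### From isotopomers to observables

GC/MS measures isotopologues (mass isotopomers): the fractions
$m_0, m_1, \dots$ of molecules carrying $0, 1, \dots$ ¹³C atoms, either for
the whole molecule or for a fragment covering carbons $a..b$. Predicted
isotopomer vectors are binned by the popcount of the mask restricted to the
fragment's bits and normalized by the total. The catalogue used by the
hepatocyte demonstration matches the protocol's fragments (glucose C1–C6,
glycogen glucose C1–C4 and C3–C6, lactate C1–C3, sorbitol C1–C6); arbitrary
ranges are supported. The sorbitol observable reflects the chemistry of the
assay — borohydride reduces both medium hexoses to sorbitol — and is
computed as the concentration-weighted mixture of the glucose and fructose
isotopomer pools. **Natural-abundance correction is *not* applied to
simulated MIDs**: the pipeline assumes experimental spectra have already
been corrected, so measured and simulated fractions are directly
comparable.

## Parameter estimation

Enzyme activities in unbranched reaction chains are not separately
identifiable (the chain flux can be set by any member), so activities are
fitted as *groups*: one free factor $E_z$ scales all member capacities, each
with a fixed relative weight. The multi-condition objective is

$$X^2 = \sum_i \left( \frac{Y_i - Z_i(E_1,\dots,E_m)}{\sigma_i} \right)^2,$$

summing over all measurements (isotopologue fractions and concentrations)
of all conditions simulated with the one shared parameter set. Reported
standard deviations are floored at 0.01 to prevent near-zero $\sigma$ from
dominating, and any parameter set that drives any metabolite above 50 mM
*anywhere along the dense output grid* — not only at measurement times — is
rejected with an infinite objective, as are integration failures.

The optimizer is a simulated-annealing variant: multiplicative log-normal
perturbations of one randomly chosen factor, Metropolis acceptance on
$\Delta X^2$, geometric temperature ladder ($T_0$ = initial objective,
cooling 0.95 per rung, 50 moves per rung, stop at $T < 10^{-3} T_0$ or
20 000 evaluations by default; all exposed). Three implementation choices
matter for convergence and are deliberate deviations from the textbook
algorithm:

* the proposal width shrinks with $\sqrt{T/T_0}$ (floored), so late moves
  polish the minimum instead of re-exploring;
* each temperature rung restarts from the best-ever point (elitist
  restart), so high-temperature exploration cannot strand the walk;
* with probability 0.25 a proposal rescales *all* factors jointly — chains
  of sequential activities leave the objective nearly flat along a common
  rescaling, a valley that single-factor moves traverse only in slow
  zigzags.

Haldane-constrained reverse capacities are recomputed from the scaled
forward capacities at every evaluation; they are derived quantities, never
free. Factor search runs in log space within multiplicative bounds
(default $[10^{-3}, 10^{3}]$ around the initial guess) because enzyme
activities span orders of magnitude. Runs are bit-reproducible given the
seed.

## Identifiability

A parameter is identifiable if its profile-likelihood confidence interval is
finite: fixing factor $i$ at $\theta_i$ and re-optimizing the rest gives
$X^2(\theta_i)$, and the $(1-\alpha)$ region is
$\{\theta_i : X^2(\theta_i) - X^2_{bf} < \Delta_\alpha\}$ with
$\Delta_\alpha$ the upper-$\alpha$ quantile of $\chi^2$ with one degree of
freedom (3.841 at $\alpha = 0.05$). The implementation walks a
multiplicative grid (default ×1.2 per step) outward from the best fit,
re-optimizes the remaining factors at each point with a shortened
warm-started anneal (default 10% of the full budget, seeded from the
neighbouring accepted point), then brackets and bisects the threshold
crossing in log space. A side is declared unbounded past 10³× (upper) or
10⁻³× (lower) the best-fit value. If any re-optimization finds a point
better than the fit itself, the anchor $X^2_{bf}$ is lowered on the fly —
the threshold is defined relative to the global minimum, not to wherever
the annealer stopped.

Envelopes for dependent variables (fluxes, concentrations, MID fractions
over time) are the pointwise minima/maxima over simulations of the best fit
plus *every* parameter set accepted during profiling. Using all accepted
sets rather than only the two extreme parameter vectors per interval is a
deliberate deviation: the extreme-parameter heuristic can miss non-monotone
responses, and the superset can only widen the band.

## The hepatocyte demonstration model

`makeDemoModel()` ships a reduced, re-parameterized hepatocyte network — 35
reactions, 33 metabolites, three compartments (2 ml incubation medium,
8·10⁻⁵ l total cytosol and 2·10⁻⁵ l mitochondria for 2·10⁷ cells) — not a
port of any published parameterization. It covers glucose transport and the
two hexose-phosphate pools *a* (glycolysis-oriented) and *b*
(glycogen-oriented), the three aldolase reactions (FBP cleavage, F1P
cleavage, and the triose-transfer reaction FBP + glyceraldehyde ⇌ F1P +
GAP, modelled as net reversible Michaelis–Menten laws with a shared grouped
capacity and competitive cross-inhibition, not as an elementary mechanism),
the fructose pathway (low-affinity transport, Km 67 mM; fructokinase;
triokinase), lower glycolysis, lactate exchange, a glycogen branch
(glycogen as a pool of glucosyl units in cytosolic volume; the
UDP-glucose step lumped into one ATP-consuming, pyrophosphate-releasing
reaction), and a closed energy subsystem: ATP/ADP/AMP with adenylate
kinase, pyrophosphatase, a background ATPase load, mitochondrial phosphate
transport, and one saturable lumped mitochondrial ATP regeneration standing
in for the respiratory chain plus adenine translocator block. The
glucokinase law includes competitive inhibition by fructose 6-phosphate
that fructose 1-phosphate relieves (the inhibition term is scaled by
$1/(1+[\mathrm{F1P}]/K_{ir})$). Glucose-phosphate isomerase, triose-phosphate
isomerase, enolase, phosphoglycerate mutase and phosphoglucomutase are
treated as near-equilibrium with large fixed capacities and are not fitted.
The pentose phosphate pathway, Krebs cycle, fatty-acid and glutamate
branches are excluded, and glutamate observables are disabled rather than
approximated.

Two exact conservation laws hold by construction and are tested: the
cytosolic adenine pool (cATP + cADP + cAMP) and total phosphate (free Pi
plus all phosphorylated intermediates weighted by phosphate count, in
moles across cytosol and mitochondria).

Parameter values are hand-assigned from literature-typical ranges
(glucokinase S₀.₅ 7.5 mM; GLUT2-like glucose transport Km 17 mM; fructose
transport Km 67 mM; aldolase-B Km for F1P 1 mM; GAPDH Km for phosphate
1.5 mM; equilibrium constants of the near-equilibrium steps from standard
tables) and then balanced so that the three incubation conditions integrate
stably for 2 h. Initial intracellular concentrations are assumptions in
physiological ranges (ATP 2.8 mM, free cytosolic phosphate 8 mM,
mitochondrial phosphate 16 mM, NAD/NADH 0.45/0.05 mM); they are not
measured values. The emergent phenotype is the point of the model: with
20 mM medium fructose, fructokinase outruns the shared aldolase capacity,
fructose 1-phosphate accumulates and sequesters phosphate, the
phosphate-starved ATP regeneration can no longer hold the adenylate pool,
and cytosolic ATP and Pi are persistently depleted — suppressing glycogen
accumulation and the transfer of glucose label to lactate. With 3 mM
fructose the F1P transient clears and no persistent depletion occurs. A
sweep perturbing every single parameter by ±20% leaves all of these
directional contrasts intact.

## The synthetic-data generator

`generateSyntheticDataset()` emulates the endpoint sampling of a 2 h
incubation: it simulates each condition with label propagation, evaluates
the requested observables (by default, at 120 min: medium glucose and
lactate concentrations, glycogen content, and the MIDs of medium glucose,
the two glycogen fragments, lactate and sorbitol), and adds Gaussian noise.
The noise scale is applied the way the two measurement classes actually
err: absolutely for isotopologue fractions (corrected GC/MS MIDs carry
absolute uncertainties of roughly 0.005–0.02) and relatively for
concentrations (biochemical assays scale with the measured value); the
recorded standard deviation is floored at 0.01 to match the objective's
weighting floor. It does **not** emulate natural-abundance effects,
derivatization chemistry, replicate-level biological variability, or
drift between conditions — so passing recovery tests demonstrate the
estimator's correctness under the stated error model, not robustness to
real-world systematic error.

## Numerical choices

* Integrator: implicit stiff methods from \pkg{deSolve}; the default is
  `lsodes`, whose internally generated sparse Jacobian suits the
  block-structured isotopomer system (the hepatocyte demonstration has 817
  states and simulates 2 h in about a second; dense-Jacobian `lsoda` is
  several times slower and available as a fallback). Default tolerances
  rtol 10⁻⁸, atol 10⁻¹⁰ mM; the fitting loops use rtol 10⁻⁶ where noted.
  Halving tolerances moves demo endpoints by far less than the coarser
  tolerance.
* The ODE right-hand side is compiled (Rcpp): rate-law templates and the
  precomputed atom-routing tables are evaluated in C++; a readable R
  reference implementation of the flux decomposition (`decomposeFlux()`) is
  tested for exact agreement against the compiled path, and a
  molecule-level Monte Carlo simulation provides an independent oracle for
  the label bookkeeping.
* Time is measured in minutes; the default horizon is 120 min (a 2 h
  incubation).
* Stoichiometric coefficients must be small positive integers (atom maps
  require whole molecules); fractional stoichiometry is rejected at
  construction.
* Atom maps are not expressible in plain SBML, so the SBML importer reads
  structure and kinetics from the SBML document and takes carbon counts and
  atom maps from sidecar annotation tables keyed by species and reaction
  id. Reversible SBML kinetic laws are net rates; their positive part is
  taken as the forward and their negative part as the reverse rate, which
  loses pure exchange fluxes a net law cannot express (models built in the
  native format keep separate rates).
* The native writer emits sorted keys and fixed float formatting, so
  writing the same network twice is byte-identical.

## Problem sizes used by the test suite

The recovery and coverage experiments run on the three-reaction chain toy
(`chain3`: constant 10 mM substrate pool 50% labelled at C1, two
intermediate pools at metabolic steady state, ~20 ODE states), chosen so a
full annealing fit costs a few seconds: noise-free recovery uses a 4 000
evaluation budget, the 20-replicate coverage study at α = 0.05 uses 3 000
evaluations per fit and 150 per profile re-optimization. The Monte Carlo
oracle uses 4·10⁴ molecules per mM (≥ 10⁵ molecules per network) with a
0.05 min step. These sizes are the package's validation design; larger
budgets only sharpen the same comparisons.

## Known limitations

* Direct isotopomer enumeration grows as $2^n$; molecules beyond ~10
  tracked carbons would need a cumomer/EMU reduction, which is out of
  scope.
* Only ¹³C single-element tracers are supported (no ²H or ¹⁵N, no
  multi-element designs).
* The annealer is the only optimizer (no gradient-based or hybrid global
  methods), so very flat multi-dimensional objectives profile slowly.
* The demonstration model makes no claim of quantitative agreement with any
  measured hepatocyte fluxes; it is validated for directional behaviour
  and for the conservation and labelling invariants described above.
* Measurement models assume already-corrected MIDs; no mass-spectrum or
  natural-abundance simulation is provided.
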