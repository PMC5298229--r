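---
title: "vegferk: modeling and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vegferk: modeling and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents how `vegferk` is put together: the rule-based
network engine, the three biological modules, the numerics, and the
inference and analysis layers.  All code chunks are illustrative
(`eval = FALSE`); the package's test suite exercises every claim made here.

## 1. Rule-based network expansion

Species are site graphs: each molecule has named sites that can carry an
internal state (`Y~P`) and/or a bond (`!1`).  A species lives in a
compartment (`@solution`, `@surface`, `@endosome`).  The text dialect is
BNGL-like:

```{r}
sp <- parseSpecies("V(r1!1,r2).VEGFR2(L!1,Y~P)@surface", vegfMoleculeTypes())
canonicalLabel(sp, vegfMoleculeTypes())
```

Canonical labels are computed by exhaustive ordering over molecule
permutations with pruning, so two site graphs are the same species iff their
labels are equal — the network never stores duplicates.

Patterns are partial site graphs: unmentioned sites are unconstrained,
`!+` means "bound to anything".  `countEmbeddings(pattern, species, types)`
counts embeddings *modulo pattern automorphism*, which is what mass-action
rate laws need.  A rule's rate for a concrete reactant set is

rate = k × (number of distinct embeddings) × Π reactant concentrations,

with the conventional factor 1/2 when a binding rule pairs a species with
itself through symmetric ends.

`expandNetwork(rules, seeds, types)` applies every rule to every new species
until closure (no new species), with a hard cap on complex size (`maxAgg`,
default 6 molecules); species rejected by the cap are counted and closure is
re-checked against that count.  `checkClosure(net)` verifies the fixed point
and `emitODEs(net, params)` compiles the stoichiometry into a mass-action
right-hand side.  The result is exact: on small hand-enumerable networks the
emitted ODEs agree with hand-coded ones to machine precision (see
`test-engine.R`).

## 2. Receptor module

Molecule types `V` (VEGF, two receptor arms + an NRP1 arm), `VEGFR2`,
`VEGFR1`, `NRP1`.  Rules cover: ligand capture, dimerization (R2–R2 via the
ligand bridge, R1–R2 coupling), NRP1 bridging of ligated VEGFR2,
phosphorylation of ligand-bridged VEGFR2 homodimers, dephosphorylation
(fast at the surface, ~150× slower in endosomes), and NRP1-dependent
trafficking: complexes carrying NRP1 internalize and recycle quickly,
NRP1-free receptors internalize slowly and mostly degrade.  Degradation
routes every VEGFR2 into an `R2deg` counter species so the moiety
`VEGFR2 + R2deg` is exactly conserved when synthesis is off
(`moietyCounts()` builds such conservation vectors for any molecule type).

Expansion from the standard seeds closes at 167 species and 763 reactions.
Synthesis (`sR2`) is balanced against constitutive turnover so the
ligand-free model sits at a steady state (`restingState()`).

## 3. Cascade and calcium modules

The 20 cascade/calcium states are deliberately *not* expanded by the rule
engine; they use lumped Michaelis–Menten and mass-action forms appended to
the network RHS:

* pVEGFR2 (surface and endosomal pools, weighted per complex) activates
  PLCγ; PLCγ makes IP₃ and DAG-activates PKC with calcium dependence.
* pERK phosphorylates cytosolic SphK1; Ca²⁺-loaded CIB1 translocates SphK1
  to the membrane, where it converts sphingosine to S1P
  (kcat/Km form).  S1P activates Ras catalytically; RasGTP and PKC jointly
  activate Raf, then MEK, then ERK.
* Calcium: IP₃R-gated ER release, SERCA reuptake, PMCA extrusion, and a
  store-operated CRAC current with a steep (Hill n = 4) dependence on ER
  depletion; rapid buffering is folded into an effective fraction `fbuf`.
  Leak rates are balanced algebraically at the resting point
  (`Ca = 100 nM`, `CaER = 400 µM`), so the unstimulated calcium system is
  an exact fixed point.

Because SphK1 membrane recruitment needs calcium (via CIB1) and sustained
calcium entry needs S1P-driven signaling, the loop ignites only above a
sharp VEGF threshold; below it, pERK stays near zero.

## 4. Numerics

The full state is `[167 network species, 20 cascade states]` in nM.  The
RHS is implemented in C++ (via Rcpp) with a pure-R reference implementation
(`vegferk:::.fullRhsR`) that agrees to machine precision; integration uses
`deSolve::lsoda` with `rtol = atol = 1e-8` by default.  Observables are
linear combinations over species (molecule-count semantics: a dimer carrying
two phosphotyrosines contributes twice to `pR2tot`).

`peakStats()` reports peak, peak time, and duration above the
half-excursion level referenced to the pre-stimulus baseline.

## 5. Analysis layer

* `doseResponse()` / `estimateEC50()` — log-interpolated half-maximum.
* `findVegfThreshold()` — log-scale bisection on the all-or-none ERK
  ignition criterion (peak pERK > 5% of total ERK).
* `findPvegfr2Threshold()` — bisects the receptor kinase activity to the
  ignition boundary and reports the corresponding fraction of phosphorylated
  receptors.
* `therapyThreshold()` — scales one or more targets (ligand, kinase
  activity, receptor abundance, Raf, SphK1) by a common blockade fraction
  and bisects for the minimal fraction that keeps ERK off.  Upstream
  single-target blockades are switch-like (ERK stays at full amplitude until
  just below the critical fraction); Raf-containing blockades grade the
  amplitude down smoothly, which is why combinations reach the off state at
  much lower per-target blockade.

## 6. Inference and synthetic data

* `sampleParameters()` — Latin hypercube, log-uniform per parameter.
* `prcc()` — partial rank correlation: rank-transform, residualize each
  parameter and the output against all other parameters, correlate
  residuals.
* `fitParameters()` — derivative-free compass (pattern) search in log10
  space with box constraints; objective failures count as `+Inf`; warns if
  the evaluation budget is exhausted before mesh convergence.
* `makeTimecourseDataset()` — simulates ground truth, applies mean-one
  multiplicative lognormal noise, max-normalizes each trace (mirroring
  western-blot reporting), and keeps the noise-free truth alongside.
  `timecourseObjective()` rebuilds the model per candidate and scores
  max-normalized squared residuals, so pure gain parameters are
  intentionally *not* identifiable from these data — fitting studies should
  target shape parameters (decay, trafficking, turnover rates).

## 7. Reproducing the headline numbers

```{r}
p <- defaultParameters()
summaryStatistics(p)          # network size, trafficking, peaks, thresholds
```

or, from the command line,

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```
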