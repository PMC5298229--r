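# vegferk

Rule-based modeling of VEGFR2 → SphK1/S1P/calcium → ERK1/2 signaling in
endothelial cells.

`vegferk` couples three layers into one stiff ODE system (units: nM, s):

1. **Receptor layer** — a minimal rule-based (BNGL-style) network expansion
   engine generates all VEGF/VEGFR1/VEGFR2/NRP1 complexes (binding, dimer
   phosphorylation, internalization, recycling, degradation, synthesis) from
   a handful of reaction rules.
2. **Cascade layer** — PLCγ/PKC activate SphK1, whose product S1P drives
   Ras/Raf/MEK/ERK.  ERK phosphorylates cytosolic SphK1 and calcium-loaded
   CIB1 translocates it to the membrane, closing a positive feedback loop
   that makes ERK activation switch-like in VEGF dose.
3. **Calcium layer** — IP₃-gated ER release with SERCA/PMCA pumps and CRAC
   entry produces a 200–300 nM transient that gates the feedback loop.

## Worked example

```r
library(vegferk)

## Baseline model at the default (calibrated) parameters
p     <- defaultParameters()
model <- buildModel(p)          # expands the rule network + compiles the RHS
model                           # show(): species/reaction counts, modules

## Stimulate with 50 ng/ml VEGF (= 1200 pM) for 3 h
tc <- runSimulation(p, vegf = 1200, times = seq(0, 10800, 30), model = model)
head(as.data.frame(tc))

## Key observables
peakStats(tc, "Ca")             # calcium transient: peak ~ 200-300 nM
max(observable(tc, "pERKfrac")) # peak fractional ERK activation

## Receptor trafficking: ~80% of VEGFR2 lost after 3 h of VEGF
r2 <- observable(tc, "R2tot")
r2[length(r2)] / r2[1]

## pVEGFR2 dose-response and EC50 (~tens of pM)
dr <- doseResponse(p, doses = 10^seq(0, 3, 0.25), observable = "pR2tot",
                   metric = "final", times = seq(0, 1200, 15), model = model)
estimateEC50(dr)

## The SphK1/S1P/calcium feedback makes ERK ignition all-or-none:
## locate the switching dose (a few pM of VEGF)
findVegfThreshold(p)$threshold

## Anti-angiogenic therapy scans: fraction of the target that must be
## blocked to keep ERK off.  Ligand capture alone must be near-total;
## combinations act at much lower blockade.
therapyThreshold("vegf", p)
therapyThreshold(c("kphos", "raf"), p)
therapyThreshold(c("kphos", "raf", "vegfr2"), p)

## Global sensitivity of pERK(15 min) to pathway totals
totals <- c("Raf_0", "MEK_0", "ERK_0", "Ras_0", "PKC_0", "PLCg_0",
            "SphK1_0", "CIB1_0")
X <- sampleParameters(120, p@values[totals], lowerFac = 0.25, upperFac = 4)
y <- vapply(seq_len(nrow(X)), function(i) {
  pi <- setParams(p, unlist(X[i, ]))
  observable(runSimulation(pi, vegf = 1200, times = c(0, 900),
                           model = buildModel(pi)), "pERK")[2]
}, 1)
prcc(X, y)

## Fit parameters to (synthetic) max-normalized time courses
ds  <- makeTimecourseDataset(p, observables = c("pR2tot", "pERK"),
                             times = seq(300, 3600, 300), sigma = 0.05)
obj <- timecourseObjective(ds, base = p)
fit <- fitParameters(obj, c(kdERK = 2 * p@values[["kdERK"]]),
                     maxEval = 200L)
fit$par
```

## The rule engine on its own

```r
types <- list(A = moleculeType("A", sites = list(b = "0")),
              B = moleculeType("B", sites = list(a = "0", s = c("U", "P"))))
rules <- list(
  bindRule("bindAB", "A(b)", "B(a)", c(1, "b"), c(1, "a"), "kon", types),
  unbindRule("unbindAB", "A(b!1).B(a!1)", c(1, "b"), "koff", types),
  stateRule("phosB", "A(b!1).B(a!1,s~U)", 2, "s", "P", "kp", types))
net <- expandNetwork(rules, c("A(b)@solution", "B(a,s~U)@solution"), types)
speciesTable(net)
exportSBML(net, c(kon = 0.02, koff = 0.05, kp = 0.4), "toy.xml")
```

## Headline numbers

`summaryStatistics(p)` computes the package's principal outputs in one call
(network size, trafficking fractions, calcium/S1P/pERK peaks, EC50,
activation thresholds).  `scripts/acceptance.R` writes them, together with
feedback-sweep thresholds, therapy fractions, the top PRCC sensitivity and a
parameter-recovery score, as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

## Testing

```r
testthat::test_dir("tests/testthat", package = "vegferk",
                   load_package = "installed")
```

See `vignettes/methods.Rmd` for the modeling and numerical methods.
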