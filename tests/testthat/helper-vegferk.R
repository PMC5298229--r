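# Shared fixtures and memoised expensive computations.  testthat sources
# helpers once per run, so the cache is shared across all test files.

.vfCache <- new.env(parent = emptyenv())

vfMemo <- function(key, fn) {
  if (is.null(.vfCache[[key]])) .vfCache[[key]] <- fn()
  .vfCache[[key]]
}

vfParams <- function() vfMemo("params", defaultParameters)

vfModel <- function() vfMemo("model", function() buildModel(vfParams()))

vfRest <- function() vfMemo("rest", function() restingState(vfModel()))

# baseline 50 ng/ml (1200 pM) stimulation, 3 h, 30 s grid
vfBaselineTc <- function() vfMemo("tc1200", function()
  runSimulation(vfParams(), vegf = 1200, times = seq(0, 10800, 30),
                model = vfModel(), rest = vfRest()))

vfNoNrp1Tc <- function() vfMemo("tcNoN1", function() {
  p0 <- setParams(vfParams(), c(NRP1_0 = 0))
  runSimulation(p0, vegf = 1200, times = seq(0, 10800, 60),
                model = buildModel(p0))
})

vfVegfThreshold <- function() vfMemo("thr", function()
  findVegfThreshold(vfParams()))

vfPvegfr2Threshold <- function() vfMemo("pthr", function()
  findPvegfr2Threshold(vfParams()))

vfSphk1LowThreshold <- function() vfMemo("thrSK5", function()
  findVegfThreshold(setParams(vfParams(), c(SphK1_0 = 5)), upper = 1000))

vfKcatLowThreshold <- function() vfMemo("thrKcat", function()
  findVegfThreshold(setParams(vfParams(), c(kcatSK1 = 3.724)), upper = 1000))

vfEC50 <- function() vfMemo("ec50", function() {
  dr <- doseResponse(vfParams(), observable = "pR2tot", metric = "final",
                     times = seq(0, 1200, 15), model = vfModel())
  estimateEC50(dr)
})

# --- toy molecule types for rule-engine tests --------------------------------

toyTypes <- function() {
  list(
    A = moleculeType("A", sites = list(b = "0")),
    B = moleculeType("B", sites = list(a = "0", s = c("U", "P"))),
    Adeg = moleculeType("Adeg"))
}

# A + B <-> A.B with B-site phosphorylation in the bound state
toyRules <- function(types = toyTypes()) {
  list(
    bindRule("bindAB", "A(b)", "B(a)", c(1, "b"), c(1, "a"), "kon", types),
    unbindRule("unbindAB", "A(b!1).B(a!1)", c(1, "b"), "koff", types),
    stateRule("phosB", "A(b!1).B(a!1,s~U)", 2, "s", "P", "kp", types),
    stateRule("dephB", "B(s~P)", 1, "s", "U", "kd", types))
}

toySeeds <- function() c("A(b)@solution", "B(a,s~U)@solution")

toyParams <- function() c(kon = 0.02, koff = 0.05, kp = 0.4, kd = 0.1)
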