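# Simulation layer: determinism, numerical convergence, dose-response tools.

test_that("simulation is deterministic given inputs", {
  tc1 <- runSimulation(vfParams(), vegf = 120, times = seq(0, 600, 60),
                       model = vfModel(), rest = vfRest())
  tc2 <- runSimulation(vfParams(), vegf = 120, times = seq(0, 600, 60),
                       model = vfModel(), rest = vfRest())
  expect_identical(tc1@observables, tc2@observables)
})

test_that("halving integrator tolerances changes observables by < 0.1%", {
  obs <- c("pR2tot", "pERKfrac", "Ca", "S1P", "R2tot")
  tcA <- runSimulation(vfParams(), vegf = 1200, times = seq(0, 3600, 180),
                       model = vfModel(), rest = vfRest(),
                       rtol = 1e-8, atol = 1e-8)
  tcB <- runSimulation(vfParams(), vegf = 1200, times = seq(0, 3600, 180),
                       model = vfModel(), rest = vfRest(),
                       rtol = 5e-9, atol = 5e-9)
  for (ob in obs) {
    a <- observable(tcA, ob); b <- observable(tcB, ob)
    expect_lt(max(abs(a - b)) / max(abs(a)), 1e-3)
  }
})

test_that("doseToPM applies the documented conversion", {
  expect_equal(doseToPM(50, vfParams()), 1200)
  expect_equal(doseToPM(1, vfParams()), 24)
})

test_that("peakStats reports peak, time and baseline-referenced duration", {
  tt <- seq(0, 100, 1)
  y <- 10 + 90 * exp(-((tt - 20)^2) / 50)
  tc <- new("TimeCourse", time = tt, observables = cbind(x = y), dose = 0)
  ps <- peakStats(tc, "x")
  expect_equal(ps[["peak"]], max(y))
  expect_equal(ps[["tPeak"]], 20)
  # half-excursion level ~55; gaussian half-width sqrt(50 log 2) ~ 5.9 snaps
  # to the 1-s grid as t in [15, 25]
  expect_equal(ps[["duration"]], 10)
})

test_that("pVEGFR2 dose-response rises monotonically below saturation", {
  # above ~100 pM ligand-driven internalization bends the 20-min final value
  # back down (bell shape), so monotonicity holds on the rising limb
  dr <- doseResponse(vfParams(), doses = 10^seq(0, 2, 0.25),
                     observable = "pR2tot", metric = "final",
                     times = seq(0, 1200, 60), model = vfModel())
  expect_true(all(diff(dr@response) > 0))
  ec <- estimateEC50(dr)
  expect_gt(ec, min(dr@dose)); expect_lt(ec, max(dr@dose))
})

test_that("estimateEC50 recovers the midpoint of an analytic Hill curve", {
  # the grid must extend well past Kd so the plateau (and thus half-max) is
  # resolved; truncating at 100 biases the estimate a few percent low
  d <- 10^seq(-2, 3, 0.1)
  dr <- new("DoseResponse", dose = d, response = d / (d + 3), observable = "x")
  expect_lt(abs(estimateEC50(dr) / 3 - 1), 0.05)
})

test_that("equilibrium binding curve saturates and matches the bridged affinity scale", {
  bc <- vfMemo("bindingCurve", function()
    bindingCurve(vfParams(), doses = 10^seq(0, 4, 0.5), tEq = 2e4))
  y <- bc@response
  expect_true(all(diff(y) > 0))
  # saturating: last doubling of dose adds little binding
  expect_lt(y[length(y)] / y[length(y) - 1], 1.1)
  # apparent Kd (half-saturation) sits between 1 pM and 10 nM
  ec <- estimateEC50(bc)
  expect_gt(ec, 1); expect_lt(ec, 1e4)
})

test_that("TimeCourse accessors and coercion behave", {
  tc <- vfBaselineTc()
  expect_identical(length(timeGrid(tc)), nrow(tc@observables))
  expect_error(observable(tc, "nonexistent"))
  df <- as.data.frame(tc)
  expect_true(all(c("time", "pERK", "Ca") %in% names(df)))
})
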