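# Calcium module: resting balance, transient window, pump/channel perturbations.

test_that("the resting point is an exact flux balance of the calcium subsystem", {
  model <- vfModel()
  p <- vfParams()@values
  q <- model@cmodel$nNet
  idx <- function(nm) q + match(nm, vegferk:::.cascadeStateNames)
  y <- numeric(length(vfRest())); names(y) <- names(vfRest())
  y[idx("Ca")] <- p[["Ca0"]]; y[idx("CaER")] <- p[["CaER0"]]
  dy <- vegferk:::.fullRhsCpp(0, y, model@cmodel)
  expect_lt(abs(dy[idx("Ca")]), 1e-9)
  expect_lt(abs(dy[idx("CaER")]), 1e-9)
})

test_that("calcium state is stationary for 60 min without stimulation", {
  model <- vfModel()
  out <- deSolve::lsoda(vfRest(), c(0, 3600), vegferk:::.deriv, model@cmodel,
                        rtol = 1e-8, atol = 1e-8)
  y1 <- out[2, -1]; names(y1) <- model@stateNames
  for (nm in c("Ca", "CaER", "IP3"))
    expect_lt(abs(y1[[nm]] - vfRest()[[nm]]) / max(vfRest()[[nm]], 1), 1e-4)
})

test_that("baseline calcium transient stays inside the 200-300 nM window", {
  ca <- peakStats(vfBaselineTc(), "Ca")
  expect_gte(ca[["peak"]], 200)
  expect_lte(ca[["peak"]], 300)
  # transient: returns most of the way to baseline within the 3 h horizon
  y <- observable(vfBaselineTc(), "Ca")
  expect_lt(y[length(y)], y[1] + 0.25 * (ca[["peak"]] - y[1]))
})

test_that("perturbCalcium validates and scales only the targeted rates", {
  p <- vfParams()
  expect_identical(perturbCalcium(p)@values, p@values)
  expect_error(perturbCalcium(p, pmca = -1), "multipliers")
  expect_error(perturbCalcium(p, serca = NA), "multipliers")
  p2 <- perturbCalcium(p, pmca = 0.5, serca = 2, crac = 0, ip3r = 3)
  v <- p@values
  expect_equal(p2@values[["VPMCA"]], 0.5 * v[["VPMCA"]])
  expect_equal(p2@values[["VSERCA"]], 2 * v[["VSERCA"]])
  expect_equal(p2@values[["ACRAC"]], 0)
  expect_equal(p2@values[["kIP3R"]], 3 * v[["kIP3R"]])
  same <- setdiff(names(v), c("VPMCA", "VSERCA", "ACRAC", "kIP3R"))
  expect_identical(p2@values[same], v[same])
})

test_that("PMCA inhibition converts pERK to a plateau with similar peak", {
  pp <- perturbCalcium(vfParams(), pmca = 0.1)
  tc <- runSimulation(pp, vegf = 1200, times = seq(0, 7200, 60),
                      model = buildModel(pp))
  y <- observable(tc, "pERKfrac")
  base <- observable(vfBaselineTc(), "pERKfrac")
  baseline2h <- base[match(7200, timeGrid(vfBaselineTc()))]
  expect_lt(abs(max(y) / max(base) - 1), 0.30)   # peak roughly unchanged
  expect_gt(y[length(y)], 0.9 * max(y))          # sustained plateau at 2 h
  expect_gt(y[length(y)], baseline2h)            # clearly above baseline decay
})

test_that("SERCA inhibition gives a pERK plateau with no decay over time", {
  pp <- perturbCalcium(vfParams(), serca = 0.1)
  tc <- runSimulation(pp, vegf = 1200, times = seq(0, 7200, 60),
                      model = buildModel(pp))
  y <- observable(tc, "pERKfrac")
  expect_gt(y[length(y)], 0.95 * max(y))
})

test_that("CRAC inhibition lowers the late pERK plateau", {
  pp <- perturbCalcium(vfParams(), crac = 0)
  tc <- runSimulation(pp, vegf = 1200, times = seq(0, 7200, 60),
                      model = buildModel(pp))
  y <- observable(tc, "pERKfrac")
  base <- observable(vfBaselineTc(), "pERKfrac")
  baseline2h <- base[match(7200, timeGrid(vfBaselineTc()))]
  expect_lt(y[length(y)], baseline2h)
})

test_that("IP3R inhibition suppresses the calcium transient and blunts ERK", {
  pp <- perturbCalcium(vfParams(), ip3r = 0)
  tc <- runSimulation(pp, vegf = 1200, times = seq(0, 2400, 60),
                      model = buildModel(pp))
  ca <- observable(tc, "Ca")
  expect_lt(max(ca) - ca[1], 25)                  # no release transient
  # resting calcium still loads some CIB1, so ERK is blunted, not abolished
  base <- max(observable(vfBaselineTc(), "pERKfrac"))
  expect_lt(max(observable(tc, "pERKfrac")), base)
})
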