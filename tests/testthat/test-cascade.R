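# Cascade module: rate forms, feedback-loop dependencies, knockouts.

test_that("compiled and R reference right-hand sides agree", {
  model <- vfModel()
  y <- vfRest()
  y[["V(r1,r2,n)@solution"]] <- 1.2
  q <- model@cmodel$nNet
  y[q + seq_len(20)] <- abs(y[q + seq_len(20)]) + seq_len(20) / 10
  dC <- vegferk:::.fullRhsCpp(0, y, model@cmodel)
  dR <- vegferk:::.fullRhsR(0, y, model@cmodel)
  expect_lt(max(abs(dC - dR)), 1e-12 * max(1, max(abs(dC))))
})

test_that("the PLCg rate has the stated Michaelis-Menten form", {
  # rate = kp * pR2 * PLCg / (PLCg + Km), applied per pVEGFR2 pool
  model <- vfModel()
  p <- vfParams()@values
  q <- model@cmodel$nNet
  y <- numeric(length(vfRest())); names(y) <- names(vfRest())
  # any species carrying surface pVEGFR2 drives PLCg through the surface rate
  i <- which(model@cmodel$wSurf > 0)[1]
  y[i] <- 0.5
  pR2s <- model@cmodel$wSurf[i] * 0.5
  y[["PLCg"]] <- p[["KmPLCg"]]         # half-saturation
  dy <- vegferk:::.fullRhsCpp(0, y, model@cmodel)
  dpPLCg <- dy[q + match("pPLCg", vegferk:::.cascadeStateNames)]
  expect_equal(dpPLCg, p[["kpPLCgS"]] * pR2s * 0.5, tolerance = 1e-12)
  # PLCg = 0: no flux
  y[["PLCg"]] <- 0
  dy0 <- vegferk:::.fullRhsCpp(0, y, model@cmodel)
  expect_equal(dy0[q + match("pPLCg", vegferk:::.cascadeStateNames)], 0)
})

test_that("SphK1 phosphorylation flux requires pERK and saturates in SphK1", {
  model <- vfModel()
  p <- vfParams()@values
  q <- model@cmodel$nNet
  idx <- function(nm) q + match(nm, vegferk:::.cascadeStateNames)
  y <- numeric(length(vfRest())); names(y) <- names(vfRest())
  y[idx("SKc")] <- 1e6                  # far above KmSK1
  dy <- vegferk:::.fullRhsCpp(0, y, model@cmodel)
  expect_equal(dy[idx("pSKc")], 0)      # pERK = 0 -> no flux
  y[idx("pERK")] <- 10
  dy <- vegferk:::.fullRhsCpp(0, y, model@cmodel)
  expect_equal(dy[idx("pSKc")], p[["kpSK1"]] * 10, tolerance = 1e-3)
})

test_that("S1P drives Ras catalytically with Michaelis-Menten kinetics", {
  model <- vfModel()
  p <- vfParams()@values
  q <- model@cmodel$nNet
  idx <- function(nm) q + match(nm, vegferk:::.cascadeStateNames)
  y <- numeric(length(vfRest())); names(y) <- names(vfRest())
  y[idx("RasGDP")] <- 100
  dy <- vegferk:::.fullRhsCpp(0, y, model@cmodel)
  expect_equal(dy[idx("RasGTP")], 0)    # S1P = 0 -> no activation
  y[idx("S1P")] <- p[["KmS1PRas"]]      # half-maximal per-RasGDP rate
  dy <- vegferk:::.fullRhsCpp(0, y, model@cmodel)
  expect_equal(dy[idx("RasGTP")], p[["kS1PRas"]] * 100 * 0.5, tolerance = 1e-12)
  expect_equal(dy[idx("S1P")], -p[["kdpS1P"]] * p[["KmS1PRas"]],
               tolerance = 1e-12)       # S1P only turned over, not consumed
})

test_that("blocking SphK1 catalysis abolishes ERK activation", {
  expect_lt(maxPerkFraction(setParams(vfParams(), c(kcatSK1 = 0))), 1e-4)
})

test_that("PKC or PLCg knockout abolishes ERK activation", {
  expect_lt(maxPerkFraction(setParams(vfParams(), c(PKC_0 = 0))), 1e-4)
  expect_lt(maxPerkFraction(setParams(vfParams(), c(PLCg_0 = 0))), 1e-4)
})

test_that("CIB1 starvation (5 nM) prevents ERK activation", {
  expect_lt(maxPerkFraction(setParams(vfParams(), c(CIB1_0 = 5))), 1e-3)
})

test_that("SphK1 translocation has a functional lower bound", {
  # far below the functional bound the loop cannot ignite; baseline can
  expect_lt(maxPerkFraction(setParams(vfParams(), c(ktSK1 = 0.02))), 0.05)
  expect_gt(maxPerkFraction(vfParams(), model = vfModel(), rest = vfRest()),
            0.05)
})

test_that("without ligand the cascade is fully off at rest", {
  rest <- vfRest()
  for (nm in c("pPLCg", "PKCa", "pERK", "pMEK", "pRaf"))
    expect_lt(abs(rest[[nm]]), 1e-6)
})

test_that("baseline pERK transient peaks and then decays over tens of minutes", {
  y <- observable(vfBaselineTc(), "pERKfrac")
  tt <- timeGrid(vfBaselineTc())
  i <- which.max(y)
  expect_gt(y[i], 0.1)                      # clear activation
  expect_lt(tt[i], 3600)                    # peak within the first hour
  expect_lt(y[length(y)], y[i])             # decaying tail at 3 h
})
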