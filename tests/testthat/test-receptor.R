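# Receptor module: rule-set structure, ligand-free steadiness, trafficking.

test_that("receptor network contains the documented complex classes", {
  net <- vfModel()@network
  st <- speciesTable(net)
  types <- vegfMoleculeTypes()
  # VEGFR1/VEGFR2 heterodimers are reachable
  het <- parsePattern("VEGFR1(C!1).VEGFR2(C!1)", types)
  expect_true(any(vapply(net@species,
                         function(sp) countEmbeddings(het, sp, types) > 0, TRUE)))
  # NRP1-bearing VEGFR2 complexes are reachable
  nr <- parsePattern("NRP1(b!1).V(n!1,r2!2).VEGFR2(L!2)", types)
  expect_true(any(vapply(net@species,
                         function(sp) countEmbeddings(nr, sp, types) > 0, TRUE)))
  expect_true(all(st$size <= 6L))
})

test_that("without NRP1 seed the expanded network has no NRP1-bearing species", {
  types <- vegfMoleculeTypes()
  seeds <- c("V(r1,r2,n)@solution", "VEGFR2(L,C,Y~U)@surface",
             "VEGFR1(L,C,N)@surface")
  net <- expandNetwork(buildReceptorRules(types), seeds, types)
  expect_false(any(grepl("NRP1", net@labels)))
  expect_lt(numSpecies(net), numSpecies(vfModel()@network))
})

test_that("surface/endosome dephosphorylation rate ratio is ~150", {
  p <- vfParams()
  ratio <- p@values[["kdephos_surf"]] / p@values[["kdephos_endo"]]
  expect_lt(abs(ratio / 150 - 1), 0.01)
})

test_that("with VEGF = 0 phospho-observables are zero and receptor totals steady", {
  model <- vfModel()
  tc0 <- runSimulation(vfParams(), vegf = 0, times = seq(0, 10800, 120),
                       model = model, rest = vfRest())
  for (ob in c("pR2tot", "pR2surf", "pR2endo", "pERK", "pPLCg"))
    expect_lt(max(abs(observable(tc0, ob))), 1e-6)
  for (ob in c("R2tot", "R1tot", "N1tot")) {
    y <- observable(tc0, ob)
    expect_lt(max(abs(y / y[1] - 1)), 0.01)   # < 1% drift over 180 min
  }
})

test_that("doubling constitutive degradation without synthesis compensation drifts > 1%", {
  p2 <- setParams(vfParams(), c(kdeg0 = 2 * vfParams()@values[["kdeg0"]]))
  m2 <- buildModel(p2)
  # start from the balanced baseline rest so the altered turnover shows up
  tc <- runSimulation(p2, vegf = 0, times = seq(0, 10800, 1080), model = m2,
                      rest = vfRest())
  r2 <- observable(tc, "R2tot")
  expect_gt(max(abs(r2 / r2[1] - 1)), 0.01)
})

test_that("total VEGFR2 including the degradation counter is conserved without synthesis", {
  p0 <- setParams(vfParams(), c(sR2 = 0))
  m0 <- buildModel(p0)
  y0 <- initialState(m0, vegf = 1.2e3)   # pM argument
  out <- deSolve::lsoda(y0, seq(0, 3600, 300), vegferk:::.deriv, m0@cmodel,
                        rtol = 1e-10, atol = 1e-10)
  w <- moietyCounts(m0@network, "VEGFR2", countedAs = "R2deg")
  tot <- out[, 1 + seq_len(m0@cmodel$nNet), drop = FALSE] %*% w
  expect_lt(max(abs(tot / tot[1] - 1)), 1e-6)
})

test_that("NRP1 knockout lowers total VEGFR2 relative to control under VEGF", {
  ctrl <- observable(vfBaselineTc(), "R2tot")
  tt <- timeGrid(vfBaselineTc())
  null <- observable(vfNoNrp1Tc(), "R2tot")
  tt0 <- timeGrid(vfNoNrp1Tc())
  keep <- tt0[tt0 > 300]
  cn <- ctrl[match(keep, tt)] / ctrl[1]
  nn <- null[match(keep, tt0)] / null[1]
  expect_true(all(nn < cn))
})

test_that("surface pVEGFR2 requires ligand-bridged VEGFR2 homodimer context", {
  # VEGFR1 knockout does not abolish phosphorylation, VEGFR2 kinase does
  p <- vfParams()
  pNoPhos <- setParams(p, c(kphos = 0))
  tc <- runSimulation(pNoPhos, vegf = 1200, times = seq(0, 600, 60),
                      model = buildModel(pNoPhos))
  expect_lt(max(observable(tc, "pR2tot")), 1e-8)
  expect_gt(max(observable(tc, "boundV")), 0)
})
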