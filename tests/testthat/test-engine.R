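# Rule engine: expansion, symmetry factors, closure, ODE emission, SBML.

test_that("empty rule list expands to the seeds with no reactions", {
  types <- toyTypes()
  net <- expandNetwork(list(), toySeeds(), types)
  expect_identical(numSpecies(net), 2L)
  expect_identical(numReactions(net), 0L)
})

test_that("single reversible binding rule gives the 3-species 2-reaction network", {
  types <- toyTypes()
  rules <- list(
    bindRule("bind", "A(b)", "B(a)", c(1, "b"), c(1, "a"), "kon", types),
    unbindRule("unbind", "A(b!1).B(a!1)", c(1, "b"), "koff", types))
  net <- expandNetwork(rules, toySeeds(), types)
  expect_identical(numSpecies(net), 3L)
  expect_identical(numReactions(net), 2L)
  rt <- reactionTable(net)
  expect_setequal(rt$rateName, c("kon", "koff"))
  expect_true(all(rt$factor == 1))
})

test_that("symmetric dimerization carries the BioNetGen 1/2 factor", {
  types <- list(M = moleculeType("M", sites = list(d = "0")))
  rules <- list(
    bindRule("dim", "M(d)", "M(d)", c(1, "d"), c(1, "d"), "kon", types),
    unbindRule("undim", "M(d!1).M(d!1)", c(1, "d"), "koff", types))
  net <- expandNetwork(rules, "M(d)@solution", types)
  rt <- reactionTable(net)
  expect_identical(rt$factor[rt$rateName == "kon"], 0.5)
  # the dissociation of the symmetric dimer has one lumped embedding pair
  expect_identical(rt$factor[rt$rateName == "koff"], 1)
})

test_that("non-terminating rule sets raise an explicit closure error", {
  # unbounded chain growth: the expansion cannot close within a small
  # iteration budget
  types <- list(P = moleculeType("P", sites = list(h = "0", t = "0")))
  rules <- list(bindRule("grow", "P(t)", "P(h)", c(1, "t"), c(1, "h"),
                         "kon", types))
  expect_error(
    expandNetwork(rules, "P(h,t)@solution", types, maxIter = 2L, maxAgg = 6L),
    "network not closed")
})

test_that("the aggregate-size cap rejects oversized products and counts them", {
  types <- list(P = moleculeType("P", sites = list(h = "0", t = "0")))
  rules <- list(bindRule("grow", "P(t)", "P(h)", c(1, "t"), c(1, "h"),
                         "kon", types))
  net <- expandNetwork(rules, "P(h,t)@solution", types, maxAgg = 3L)
  expect_identical(max(speciesTable(net)$size), 3L)
  expect_gt(net@rejected, 0L)
  # closure holds under the same cap
  expect_invisible(checkClosure(net, rules, types, maxAgg = 3L))
})

test_that("degradation rules route molecules to declared sink counters", {
  types <- toyTypes()
  rules <- c(toyRules(types), list(
    degradeRule("degA", "A(b)", c(A = "Adeg"), "kdegA", types)))
  net <- expandNetwork(rules, toySeeds(), types)
  expect_true("Adeg()@sink" %in% net@labels)
  ode <- emitODEs(net, c(toyParams(), kdegA = 0.01))
  y0 <- numeric(numSpecies(net))
  y0[match("A(b)@solution", net@labels)] <- 3
  y0[match("B(a,s~U)@solution", net@labels)] <- 5
  out <- deSolve::lsoda(y0, c(0, 400), function(t, y, p) list(ode$rhs(t, y)),
                        NULL, rtol = 1e-10, atol = 1e-10)
  wA <- moietyCounts(net, "A", countedAs = "Adeg")
  totA <- out[, -1] %*% wA
  expect_lt(max(abs(totA / totA[1] - 1)), 1e-6)
  # without the counter the free-A moiety visibly decays
  expect_lt(sum(out[2, -1] * moietyCounts(net, "A")), 3)
})

test_that("synthesis rules create zeroth-order inflows", {
  types <- toyTypes()
  rules <- list(synthRule("mkA", "A(b)@solution", "sA", types))
  net <- expandNetwork(rules, "B(a,s~U)@solution", types)
  expect_true("A(b)@solution" %in% net@labels)
  ode <- emitODEs(net, c(sA = 2))
  dy <- ode$rhs(0, numeric(numSpecies(net)))
  expect_identical(dy[match("A(b)@solution", net@labels)], 2)
})

test_that("transport rules relocate whole complexes", {
  types <- list(M = moleculeType("M", sites = list(d = "0"), isMembrane = TRUE))
  rules <- list(transportRule("int", "M()@surface", "endosome", "kint", types))
  net <- expandNetwork(rules, "M(d)@surface", types)
  expect_setequal(net@labels, c("M(d)@surface", "M(d)@endosome"))
})

test_that("emitODEs resolves rate symbols and reports missing ones by name", {
  types <- toyTypes()
  net <- expandNetwork(toyRules(types), toySeeds(), types)
  expect_error(emitODEs(net, c(kon = 1, koff = 1, kp = 1)), "kd")
  ode <- emitODEs(net, toyParams())
  # zero state: all mass-action derivatives vanish
  expect_identical(max(abs(ode$rhs(0, numeric(numSpecies(net))))), 0)
  # resolved constants carry the statistical factor
  expect_identical(unname(ode$k),
                   unname(toyParams()[net@reactions$rateName] * net@reactions$factor))
})

test_that("observables use molecule-counting (BNGL Molecules) semantics", {
  types <- list(M = moleculeType("M", sites = list(d = "0")))
  rules <- list(bindRule("dim", "M(d)", "M(d)", c(1, "d"), c(1, "d"),
                         "kon", types))
  net <- expandNetwork(rules, "M(d)@solution", types)
  net <- addObservable(net, "Mtot", "M()", types)
  y <- numeric(numSpecies(net))
  y[match("M(d)@solution", net@labels)] <- 1
  y[match("M(d!1).M(d!1)@solution", net@labels)] <- 2  # dimer counts twice
  expect_identical(unname(evalObservables(net, y)[["Mtot"]]), 5)
})

test_that("SBML export round-trips species and reaction counts", {
  types <- toyTypes()
  net <- expandNetwork(toyRules(types), toySeeds(), types)
  f <- tempfile(fileext = ".xml")
  map <- exportSBML(net, toyParams(), f,
                    initial = c("A(b)@solution" = 3, "B(a,s~U)@solution" = 5))
  cnt <- sbmlCounts(f)
  expect_identical(unname(cnt["species"]), numSpecies(net))
  expect_identical(unname(cnt["reactions"]), numReactions(net))
  expect_identical(map$label, net@labels)
  # seeds-only network: valid SBML with zero reactions
  net0 <- expandNetwork(list(), toySeeds(), types)
  f0 <- tempfile(fileext = ".xml")
  exportSBML(net0, c(unused = 1), f0)
  cnt0 <- sbmlCounts(f0)
  expect_identical(unname(cnt0["species"]), 2L)
  expect_identical(unname(cnt0["reactions"]), 0L)
  unlink(c(f, f0))
})

test_that("SBML export of the full receptor network preserves counts and rates", {
  model <- vfModel()
  net <- model@network
  f <- tempfile(fileext = ".xml")
  exportSBML(net, vfParams(), f)
  cnt <- sbmlCounts(f)
  expect_identical(unname(cnt["species"]), numSpecies(net))
  expect_identical(unname(cnt["reactions"]), numReactions(net))
  doc <- xml2::read_xml(f)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  vals <- as.numeric(xml2::xml_attr(
    xml2::xml_find_all(doc, "//s:listOfParameters/s:parameter", ns), "value"))
  k <- unname(vfParams()@values[net@reactions$rateName] * net@reactions$factor)
  expect_equal(vals, k, tolerance = 1e-12)
  unlink(f)
})
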