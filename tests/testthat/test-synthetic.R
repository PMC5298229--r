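# Synthetic data: noise calibration, normalization, plumbing, round trips.

test_that("lognormal noise has mean one and the requested log-scale sd", {
  set.seed(3)
  y <- rep(2, 20000)
  yn <- vegferk:::.noisy(y, 0.05)
  expect_lt(abs(mean(yn) / 2 - 1), 0.005)        # mean-one multiplicative
  expect_lt(abs(sd(log(yn)) / 0.05 - 1), 0.05)   # log-sd == sigma
})

test_that("timecourse dataset is max-normalized with truth attached", {
  ds <- vfMemo("synthTc", function()
    makeTimecourseDataset(vfParams(), observables = c("pR2tot", "pERK"),
                          times = seq(300, 1800, 300), doses = c(24, 1200),
                          sigma = 0.05, seed = 2L))
  expect_identical(sort(names(ds)),
                   sort(c("dose", "observable", "time", "value", "truth")))
  expect_identical(nrow(ds), 2L * 2L * 6L)
  for (d in unique(ds$dose)) for (ob in unique(ds$observable)) {
    sub <- ds[ds$dose == d & ds$observable == ob, ]
    expect_equal(max(abs(sub$value)), 1)
    expect_equal(max(abs(sub$truth)), 1)
  }
  # noise is multiplicative and small at sigma = 0.05: log-ratio stays tight
  r <- ds$value / pmax(ds$truth, 1e-12)
  expect_lt(max(abs(log(r))), 0.4)
})

test_that("dataset generation is reproducible given seed and truth is noise-free", {
  a <- makeDoseResponseDataset(vfParams(), doses = c(3, 30, 100),
                               observable = "pR2tot", metric = "final",
                               sigma = 0.1, seed = 9L)
  b <- makeDoseResponseDataset(vfParams(), doses = c(3, 30, 100),
                               observable = "pR2tot", metric = "final",
                               sigma = 0.1, seed = 9L)
  expect_identical(a, b)
  # doses kept on the rising limb: saturating doses down-regulate receptors
  z <- makeDoseResponseDataset(vfParams(), doses = c(3, 30, 100),
                               observable = "pR2tot", metric = "final",
                               sigma = 0, seed = 9L)
  expect_equal(z$value, z$truth)
  expect_true(all(z$truth > 0))
  expect_gt(z$truth[2], z$truth[1])   # rising limb of the dose-response
})

test_that("EC50 estimation is robust to 5% measurement noise", {
  doses <- 10^seq(0, 2, 0.25)
  z <- vfMemo("synthDr0", function()
    makeDoseResponseDataset(vfParams(), doses = doses, observable = "pR2tot",
                            metric = "final", sigma = 0, seed = 1L))
  ecTrue <- estimateEC50(new("DoseResponse", dose = doses,
                             response = z$truth, observable = "pR2tot"))
  set.seed(17)
  ecs <- replicate(20, {
    yn <- vegferk:::.noisy(z$truth, 0.05)
    estimateEC50(new("DoseResponse", dose = doses,
                     response = yn / max(yn), observable = "pR2tot"))
  })
  # normalizing by a single noisy max point adds scale noise, so individual
  # replicates can stray further than the unbiased ensemble
  expect_lt(abs(mean(ecs) / ecTrue - 1), 0.10)
  expect_lt(max(abs(ecs / ecTrue - 1)), 0.30)
})

test_that("fit datasets round-trip through CSV", {
  ds <- vfMemo("synthTc", function()
    makeTimecourseDataset(vfParams(), observables = c("pR2tot", "pERK"),
                          times = seq(300, 1800, 300), doses = c(24, 1200),
                          sigma = 0.05, seed = 2L))
  path <- tempfile(fileext = ".csv")
  writeFitDataset(ds, path)
  back <- readFitDataset(path)
  expect_identical(names(back), names(ds))
  expect_equal(back$value, ds$value, tolerance = 1e-12)
  expect_identical(back$observable, ds$observable)
  unlink(path)
})
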