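# Inference: pattern search, Latin hypercube sampling, PRCC.

test_that("fitParameters minimizes a smooth bowl with a monotone trace", {
  obj <- function(p) (log10(p[["a"]]) - 0.5)^2 + (log10(p[["b"]]) + 1)^2
  fit <- fitParameters(obj, c(a = 1, b = 1), lower = c(a = 1e-3, b = 1e-3),
                       upper = c(a = 1e3, b = 1e3), maxEval = 400L)
  expect_lt(abs(log10(fit$par[["a"]]) - 0.5), 0.01)
  expect_lt(abs(log10(fit$par[["b"]]) + 1), 0.01)
  expect_true(all(diff(fit$trace$value) <= 0))
})

test_that("fitParameters respects bounds and treats failures as infinitely bad", {
  obj <- function(p) {
    if (p[["a"]] < 0.5) stop("simulated solver failure")
    (p[["a"]] - 1)^2
  }
  fit <- suppressWarnings(
    fitParameters(obj, c(a = 2), lower = c(a = 0.1), upper = c(a = 4),
                  maxEval = 200L))
  expect_gte(fit$par[["a"]], 0.5)
  expect_lt(abs(fit$par[["a"]] - 1), 0.05)
})

test_that("fitParameters warns when the evaluation budget is exhausted", {
  obj <- function(p) sum(log10(unlist(p))^2)
  expect_warning(
    fitParameters(obj, c(a = 10, b = 10, c = 10), maxEval = 5L),
    "budget exhausted")
})

test_that("sampleParameters is a stratified Latin hypercube over log ranges", {
  set.seed(42)
  center <- c(k1 = 1, k2 = 100)
  n <- 50L
  X <- sampleParameters(n, center, lowerFac = 0.01, upperFac = 20)
  expect_identical(dim(X), c(n, 2L))
  for (j in 1:2) {
    x <- X[[j]]
    expect_true(all(x >= 0.01 * center[j] & x <= 20 * center[j]))
    # stratification: exactly one point per quantile bin in log space
    u <- (log10(x) - log10(0.01 * center[j])) /
      (log10(20 * center[j]) - log10(0.01 * center[j]))
    expect_identical(sort(findInterval(u, seq(0, 1, length.out = n + 1),
                                       rightmost.closed = TRUE)),
                     1:n)
  }
  set.seed(42)
  X2 <- sampleParameters(n, center, lowerFac = 0.01, upperFac = 20)
  expect_identical(X, X2)    # reproducible given seed
})

test_that("prcc detects partial monotone dependence under confounding", {
  set.seed(5)
  n <- 400
  x1 <- runif(n); x2 <- runif(n)
  x3 <- x1 + 0.5 * runif(n)              # collinear confounder of x1
  y <- x1^3 + 0.5 * x2
  res <- prcc(data.frame(x1 = x1, x2 = x2, x3 = x3), y)
  r <- setNames(res$prcc, res$parameter)
  expect_gt(r[["x1"]], 0.5)              # real driver survives its confounder
  expect_gt(r[["x2"]], 0.7)
  # x3 correlates strongly with y marginally but carries no partial effect
  expect_gt(cor(x3, y, method = "spearman"), 0.7)
  expect_lt(abs(r[["x3"]]), 0.3)
  expect_lt(abs(r[["x3"]]), 0.5 * cor(x3, y, method = "spearman"))
})

test_that("prcc rejects degenerate designs", {
  expect_error(prcc(data.frame(a = 1:3, b = 3:1), c(1, 2, 3)))
})

test_that("timecourseObjective is zero at truth for noise-free data", {
  p <- vfParams()
  ds <- makeTimecourseDataset(p, observables = c("pR2tot", "pERK"),
                              times = seq(300, 1800, 300), doses = 1200,
                              sigma = 0, seed = 1L)
  expect_equal(ds$value, ds$truth)
  obj <- timecourseObjective(ds, base = p)
  expect_lt(obj(p@values[c("kdERK", "kdpPLCg")]), 1e-10)
  # and strictly worse away from truth
  expect_gt(obj(c(kdERK = 5 * p@values[["kdERK"]])), 1e-4)
})
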