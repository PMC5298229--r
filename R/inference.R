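# Parameter inference: derivative-free fitting, Latin hypercube sampling and
# partial rank correlation (PRCC) sensitivity analysis.

#' Fit parameters by log-scale compass (pattern) search
#'
#' Robust derivative-free minimization tailored to stiff-simulation
#' objectives: coordinate steps in log10 parameter space with mesh expansion
#' on success and contraction on failure.  The objective is only ever accepted
#' when it strictly improves, so the best value is monotone; simulation
#' failures (errors or non-finite values) are treated as infinitely bad.
#'
#' @param objective function(named numeric vector) -> scalar.
#' @param start named numeric start vector (positive).
#' @param lower,upper named bounds (same names as \code{start}).
#' @param step initial log10 step size.
#' @param minStep convergence threshold on the log10 mesh.
#' @param maxEval evaluation budget.
#' @param verbose print progress.
#' @return list with \code{par} (best parameters), \code{value},
#'   \code{evals}, and the improvement \code{trace}.
#' @export
fitParameters <- function(objective, start, lower = start / 100,
                          upper = start * 100, step = 0.25, minStep = 1e-3,
                          maxEval = 500L, verbose = FALSE) {
  nm <- names(start)
  stopifnot(!is.null(nm), all(start > 0), all(lower > 0),
            all(start >= lower), all(start <= upper))
  lo <- log10(lower[nm]); hi <- log10(upper[nm])
  x <- log10(start)
  evals <- 0L
  safeEval <- function(xl) {
    evals <<- evals + 1L
    p <- 10^xl; names(p) <- nm
    v <- tryCatch(objective(p), error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }
  best <- safeEval(x)
  trace <- data.frame(eval = evals, value = best)
  while (step > minStep && evals < maxEval) {
    improved <- FALSE
    for (i in seq_along(x)) {
      for (s in c(step, -step)) {
        if (evals >= maxEval) break
        xt <- x
        xt[i] <- min(max(xt[i] + s, lo[i]), hi[i])
        if (xt[i] == x[i]) next
        v <- safeEval(xt)
        if (v < best) {
          best <- v; x <- xt; improved <- TRUE
          trace <- rbind(trace, data.frame(eval = evals, value = best))
          if (verbose) message(sprintf("eval %d: %s -> %.6g", evals, nm[i], best))
          break
        }
      }
    }
    if (!improved) step <- step / 2
  }
  if (step > minStep)
    warning("evaluation budget exhausted before mesh convergence; ",
            "returning best-so-far")
  par <- 10^x; names(par) <- nm
  list(par = par, value = best, evals = evals, trace = trace)
}

#' Latin hypercube parameter sample
#'
#' Draws a maximin-free (plain random) Latin hypercube over log-uniform
#' parameter ranges given as multiplicative spans around a center.
#'
#' @param n number of samples.
#' @param center named numeric vector of baseline values (positive).
#' @param lowerFac,upperFac multiplicative range bounds (scalar or named).
#' @return data.frame with one column per parameter and \code{n} rows.
#' @export
sampleParameters <- function(n, center, lowerFac = 0.1, upperFac = 10) {
  nm <- names(center)
  stopifnot(!is.null(nm), all(center > 0))
  k <- length(center)
  lf <- rep_len(lowerFac, k); uf <- rep_len(upperFac, k)
  U <- lhs::randomLHS(n, k)
  lo <- log10(center * lf); hi <- log10(center * uf)
  X <- sweep(sweep(U, 2, hi - lo, `*`), 2, lo, `+`)
  X <- as.data.frame(10^X)
  names(X) <- nm
  X
}

#' Partial rank correlation coefficients
#'
#' PRCC of each sampled parameter against a scalar model output: both sides
#' are rank-transformed, then each parameter's ranks and the output ranks are
#' residualized on all remaining parameters by linear regression, and the
#' correlation of the residuals is reported.  This is the standard global
#' sensitivity measure for monotone input-output relations under Latin
#' hypercube sampling.
#'
#' @param X data.frame or matrix of sampled parameters (n x k).
#' @param y numeric output vector of length n.
#' @return data.frame with columns \code{parameter}, \code{prcc}, \code{p}
#'   (two-sided t-test on the residual correlation), sorted by |prcc|.
#' @export
prcc <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  stopifnot(length(y) == n, n > k + 2)
  R <- apply(X, 2, rank)
  ry <- rank(y)
  out <- vapply(seq_len(k), function(j) {
    Z <- cbind(1, R[, -j, drop = FALSE])
    ex <- stats::lsfit(Z, R[, j], intercept = FALSE)$residuals
    ey <- stats::lsfit(Z, ry, intercept = FALSE)$residuals
    r <- sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
    df <- n - k - 1
    tstat <- r * sqrt(df / (1 - r^2))
    c(r, 2 * stats::pt(-abs(tstat), df))
  }, numeric(2))
  res <- data.frame(parameter = colnames(X), prcc = out[1, ], p = out[2, ],
                    row.names = NULL)
  res[order(-abs(res$prcc)), ]
}

#' Sum-of-squares objective against a time-course dataset
#'
#' Builds \code{function(theta)} comparing max-normalized simulated
#' observables to a dataset of measured (noisy, max-normalized) time courses,
#' as produced by \code{\link{makeTimecourseDataset}}.
#'
#' @param dataset data.frame with columns \code{time}, \code{observable},
#'   \code{value}, and optionally \code{dose} (pM; default 1200).
#' @param base ParameterSet supplying all non-fitted parameters.
#' @param weights optional named weights per observable.
#' @return objective closure suitable for \code{\link{fitParameters}}; the
#'   closure's argument is a named vector overriding entries of \code{base}.
#' @export
timecourseObjective <- function(dataset, base = defaultParameters(),
                                weights = NULL) {
  stopifnot(all(c("time", "observable", "value") %in% names(dataset)))
  if (is.null(dataset$dose)) dataset$dose <- 1200
  doses <- sort(unique(dataset$dose))
  function(theta) {
    p <- setParams(base, theta)
    model <- buildModel(p)
    rest <- restingState(model)
    ssr <- 0
    for (d in doses) {
      sub <- dataset[dataset$dose == d, ]
      tt <- sort(unique(c(0, sub$time)))
      tc <- runSimulation(p, vegf = d, times = tt, model = model, rest = rest)
      for (ob in unique(sub$observable)) {
        si <- sub[sub$observable == ob, ]
        y <- observable(tc, ob)[match(si$time, tc@time)]
        top <- max(abs(y))
        yn <- if (top > 0) y / top else y
        w <- if (!is.null(weights) && ob %in% names(weights)) weights[[ob]] else 1
        ssr <- ssr + w * sum((yn - si$value)^2)
      }
    }
    ssr
  }
}
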