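# Synthetic datasets for exercising the inference machinery: noisy,
# max-normalized time courses and dose-response tables of known provenance.

.noisy <- function(y, sigma) {
  # multiplicative lognormal noise, mean-one: exp(sigma Z - sigma^2/2)
  y * exp(stats::rnorm(length(y), 0, sigma) - sigma^2 / 2)
}

#' Generate a synthetic time-course fitting dataset
#'
#' Simulates the model at known ("true") parameters, adds mean-one
#' multiplicative lognormal measurement noise, then max-normalizes each
#' observable trace (mirroring how western-blot time courses are reported).
#'
#' @param params ParameterSet used as ground truth.
#' @param observables observable columns to report.
#' @param times sampling times (s); t = 0 is always simulated but the noisy
#'   report starts at the first requested time.
#' @param doses VEGF doses in pM; each dose yields one set of traces.
#' @param sigma lognormal noise scale.
#' @param seed RNG seed (set for reproducibility).
#' @return data.frame with columns \code{dose}, \code{observable},
#'   \code{time}, \code{value} (noisy, max-normalized) and \code{truth}
#'   (noise-free, max-normalized).
#' @export
makeTimecourseDataset <- function(params = defaultParameters(),
                                  observables = c("pR2tot", "pPLCg", "pERK"),
                                  times = seq(120, 3600, by = 240),
                                  doses = 1200, sigma = 0.1, seed = 1L) {
  set.seed(seed)
  model <- buildModel(params)
  rest <- restingState(model)
  out <- list()
  for (d in doses) {
    tc <- runSimulation(params, vegf = d, times = sort(unique(c(0, times))),
                        model = model, rest = rest)
    keep <- match(times, tc@time)
    for (ob in observables) {
      y <- observable(tc, ob)[keep]
      yn <- .noisy(y, sigma)
      top <- max(abs(yn)); topT <- max(abs(y))
      out[[length(out) + 1L]] <- data.frame(
        dose = d, observable = ob, time = times,
        value = if (top > 0) yn / top else yn,
        truth = if (topT > 0) y / topT else y)
    }
  }
  do.call(rbind, out)
}

#' Generate a synthetic dose-response fitting dataset
#'
#' @param params ground-truth ParameterSet.
#' @param doses VEGF doses in pM.
#' @param observable observable column.
#' @param metric passed to \code{\link{doseResponse}}.
#' @param sigma lognormal noise scale.
#' @param seed RNG seed.
#' @return data.frame with \code{dose}, \code{value} (noisy, max-normalized),
#'   \code{truth}.
#' @export
makeDoseResponseDataset <- function(params = defaultParameters(),
                                    doses = 10^seq(-0.5, 3, by = 0.5),
                                    observable = "pERKfrac", metric = "max",
                                    sigma = 0.1, seed = 1L) {
  set.seed(seed)
  dr <- doseResponse(params, doses = doses, observable = observable,
                     metric = metric)
  y <- dr@response
  yn <- .noisy(y, sigma)
  data.frame(dose = doses,
             value = yn / max(abs(yn)),
             truth = y / max(abs(y)))
}

#' Write / read a fitting dataset as CSV
#' @param dataset data.frame from a generator above.
#' @param path file path.
#' @return \code{readFitDataset} returns the data.frame.
#' @export
writeFitDataset <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFitDataset
#' @export
readFitDataset <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
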