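# Simulation front-end: time courses, dose-response, equilibrium binding.

.vegferkObsNames <- function(model)
  c(names(model@network@observables), .cascadeStateNames,
    "SKmem", "pSK1", "pERKfrac", "pR2frac")

#' Convert a VEGF dose from ng/ml to pM
#' @param ngml dose in ng/ml.
#' @param params ParameterSet (uses \code{pMPerNgMl}).
#' @return dose in pM.
#' @export
doseToPM <- function(ngml, params = defaultParameters())
  ngml * params@values[["pMPerNgMl"]]

#' Simulate a VEGF stimulation time course
#'
#' Relaxes the model to its ligand-free rest, applies free VEGF at \code{vegf}
#' pM at t = 0 and integrates the stiff whole-cell system with
#' \code{deSolve::lsoda}.  Returns network observables, cascade states and a
#' few derived read-outs (membrane SphK1, phosphorylated SphK1, pERK as a
#' fraction of total ERK, surface pVEGFR2 as a fraction of initial surface
#' VEGFR2).
#'
#' @param params \linkS4class{ParameterSet}.
#' @param vegf VEGF dose in pM.
#' @param times output time grid in seconds (default 1 min spacing to 1 h).
#' @param model optional prebuilt \linkS4class{SignalModel} (must match
#'   \code{params}); reuse across calls to amortize network assembly.
#' @param rest optional precomputed resting state (from
#'   \code{\link{restingState}}).
#' @param rtol,atol solver tolerances.
#' @return a \linkS4class{TimeCourse}.
#' @export
runSimulation <- function(params = defaultParameters(), vegf = 1200,
                          times = seq(0, 3600, by = 60), model = NULL,
                          rest = NULL, rtol = 1e-8, atol = 1e-8) {
  if (is.null(model)) model <- buildModel(params)
  if (is.null(rest)) rest <- restingState(model)
  y0 <- rest
  y0[["V(r1,r2,n)@solution"]] <- vegf / 1000
  out <- deSolve::lsoda(y0, times, .deriv, model@cmodel,
                        rtol = rtol, atol = atol)
  .asTimeCourse(out, model, vegf)
}

.asTimeCourse <- function(out, model, vegf) {
  tt <- out[, 1]
  Y <- out[, -1, drop = FALSE]
  nNet <- model@cmodel$nNet
  obs <- vapply(model@network@observables,
                function(o) as.numeric(Y[, seq_len(nNet), drop = FALSE] %*% o$weights),
                numeric(length(tt)))
  if (length(tt) == 1L) obs <- matrix(obs, nrow = 1,
                                      dimnames = list(NULL, names(model@network@observables)))
  casc <- Y[, nNet + seq_along(.cascadeStateNames), drop = FALSE]
  colnames(casc) <- .cascadeStateNames
  pv <- model@params@values
  extra <- cbind(
    SKmem = casc[, "SKm"] + casc[, "pSKm"],
    pSK1 = casc[, "pSKc"] + casc[, "pSKm"],
    pERKfrac = casc[, "pERK"] / pv[["ERK_0"]],
    pR2frac = obs[, "pR2surf"] / pv[["VEGFR2_0"]])
  new("TimeCourse", time = tt, observables = cbind(obs, casc, extra),
      dose = vegf)
}

#' Peak summary of an observable
#'
#' Transient statistics relative to the pre-stimulus baseline (the value at
#' the first time point): peak value, time of peak, and the contiguous time
#' spent above half of the baseline-referenced peak excursion.
#'
#' @param tc TimeCourse.
#' @param name observable column.
#' @return named vector: \code{peak} value, \code{tPeak} (s), and
#'   \code{duration} (s above baseline + half the peak excursion).
#' @export
peakStats <- function(tc, name) {
  y <- observable(tc, name)
  i <- which.max(y)
  half <- y[1] + (y[i] - y[1]) / 2
  above <- y >= half
  # duration: contiguous half-excursion window around the peak
  lo <- i; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- i; while (hi < length(y) && above[hi + 1]) hi <- hi + 1
  c(peak = y[i], tPeak = tc@time[i], duration = tc@time[hi] - tc@time[lo])
}

#' VEGF dose-response of an observable
#'
#' Simulates a dose series (resting state computed once) and reports the
#' response metric per dose.
#'
#' @param params ParameterSet.
#' @param doses VEGF doses in pM (strictly increasing).
#' @param observable observable column name.
#' @param metric "max" (peak over the horizon) or "final".
#' @param times simulation grid.
#' @param model optional prebuilt model.
#' @return a \linkS4class{DoseResponse}.
#' @export
doseResponse <- function(params = defaultParameters(),
                         doses = 10^seq(-1, 3, by = 0.25),
                         observable = "pR2tot", metric = c("max", "final"),
                         times = seq(0, 3600, by = 30), model = NULL) {
  metric <- match.arg(metric)
  if (is.null(model)) model <- buildModel(params)
  rest <- restingState(model)
  resp <- vapply(doses, function(d) {
    tc <- runSimulation(params, vegf = d, times = times, model = model,
                        rest = rest)
    y <- observable(tc, observable)
    if (metric == "max") max(y) else y[length(y)]
  }, 1)
  new("DoseResponse", dose = doses, response = resp, observable = observable)
}

#' Half-maximal effective concentration from a dose-response curve
#'
#' EC50 = dose at half of the top-plateau response, found by log-linear
#' interpolation between bracketing doses.
#'
#' @param dr a \linkS4class{DoseResponse}.
#' @return EC50 in the dose units of \code{dr} (pM).
#' @export
estimateEC50 <- function(dr) {
  y <- dr@response; d <- dr@dose
  half <- max(y) / 2
  i <- which(y >= half)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(d[1])
  f <- (half - y[i - 1]) / (y[i] - y[i - 1])
  10^(log10(d[i - 1]) + f * (log10(d[i]) - log10(d[i - 1])))
}

#' Equilibrium VEGF binding curve
#'
#' Surface binding per dose with trafficking frozen (all internalization rates
#' zero) and free ligand clamped, integrated to equilibrium: the classic 4 degC
#' binding experiment.
#'
#' @param params ParameterSet.
#' @param doses VEGF doses in pM.
#' @param tEq equilibration horizon (s).
#' @return a \linkS4class{DoseResponse} of bound VEGF (nM).
#' @export
bindingCurve <- function(params = defaultParameters(),
                         doses = 10^seq(0, 4, by = 0.25), tEq = 2e4) {
  p2 <- setParams(params, c(kint_nrp1 = 0, kint = 0, kint0 = 0, sR2 = 0))
  model <- buildModel(p2)
  rest <- restingState(model)
  resp <- vapply(doses, function(d) {
    tc <- runSimulation(p2, vegf = d, times = c(0, tEq), model = model,
                        rest = rest)
    observable(tc, "boundV")[2]
  }, 1)
  new("DoseResponse", dose = doses, response = resp, observable = "boundV")
}
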