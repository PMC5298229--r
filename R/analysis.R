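# Systems-level analyses: activation thresholds, parameter sweeps and
# combination-blockade (therapy) scans.

#' Maximum fractional ERK activation for one condition
#'
#' Peak pERK over the simulation horizon, as a fraction of total ERK.
#'
#' @param params ParameterSet.
#' @param vegf dose in pM.
#' @param tEnd horizon (s); ERK ignition resolves well within 40 min.
#' @param model,rest optional prebuilt model and resting state.
#' @return scalar fraction in [0, 1].
#' @export
maxPerkFraction <- function(params = defaultParameters(), vegf = 1200,
                            tEnd = 2400, model = NULL, rest = NULL) {
  if (is.null(model)) model <- buildModel(params)
  tc <- runSimulation(params, vegf = vegf, times = seq(0, tEnd, by = 30),
                      model = model, rest = rest)
  max(observable(tc, "pERKfrac"))
}

#' VEGF threshold for ERK activation
#'
#' The positive feedback through SphK1/S1P/calcium makes ERK activation
#' all-or-none in VEGF dose; this locates the switching dose by bisection on
#' a log scale.  "Activated" means peak pERK exceeds \code{epsFrac} of total
#' ERK.
#'
#' @param params ParameterSet.
#' @param lower,upper bracketing doses in pM (lower must not activate,
#'   upper must).
#' @param epsFrac activation criterion as fraction of total ERK.
#' @param relTol relative bracket width at convergence.
#' @param tEnd per-simulation horizon (s).
#' @return list: \code{threshold} (pM, geometric bracket center),
#'   \code{bracket}, and \code{evaluations}.
#' @export
findVegfThreshold <- function(params = defaultParameters(), lower = 0.25,
                              upper = 250, epsFrac = 0.05, relTol = 0.05,
                              tEnd = 2400) {
  model <- buildModel(params)
  rest <- restingState(model)
  act <- function(d) maxPerkFraction(params, d, tEnd, model, rest) > epsFrac
  nev <- 2L
  if (act(lower)) stop("lower bracket dose already activates ERK")
  if (!act(upper)) stop("upper bracket dose does not activate ERK")
  lo <- log10(lower); hi <- log10(upper)
  while (10^hi / 10^lo - 1 > relTol) {
    mid <- (lo + hi) / 2
    nev <- nev + 1L
    if (act(10^mid)) hi <- mid else lo <- mid
  }
  list(threshold = 10^((lo + hi) / 2), bracket = c(10^lo, 10^hi),
       evaluations = nev)
}

#' One-parameter sweep of a scalar model output
#'
#' @param paramName parameter to vary.
#' @param values values to assign.
#' @param quantity function(ParameterSet) -> scalar; default peak fractional
#'   pERK at 50 ng/ml.
#' @param params baseline ParameterSet.
#' @return data.frame with columns \code{value} and \code{output}.
#' @export
parameterSweep <- function(paramName, values,
                           quantity = function(p) maxPerkFraction(p),
                           params = defaultParameters()) {
  out <- vapply(values, function(v) {
    p <- params
    p[paramName] <- v
    quantity(p)
  }, 1)
  data.frame(value = values, output = out)
}

#' pVEGFR2 threshold for ERK activation
#'
#' Scales the receptor phosphorylation rate \code{kphos} down by bisection to
#' the point where ERK can no longer ignite, and reports both the critical
#' rate (as a fraction of baseline) and the corresponding peak fractional
#' pVEGFR2 (fraction of total VEGFR2) at that critical point.
#'
#' @param params ParameterSet.
#' @param vegf dose in pM.
#' @param epsFrac activation criterion (fraction of total ERK).
#' @param relTol relative bracket width at convergence.
#' @param tEnd horizon (s).
#' @return list: \code{kphosFraction} (critical kphos / baseline kphos),
#'   \code{kphosCritical} (1/s), \code{pR2Fraction} (peak pVEGFR2 as a
#'   fraction of total VEGFR2 at the critical kphos).
#' @export
findPvegfr2Threshold <- function(params = defaultParameters(), vegf = 1200,
                                 epsFrac = 0.05, relTol = 0.05, tEnd = 2400) {
  k0 <- params@values[["kphos"]]
  act <- function(f) {
    p <- setParams(params, c(kphos = k0 * f))
    model <- buildModel(p)
    maxPerkFraction(p, vegf, tEnd, model) > epsFrac
  }
  if (!act(1)) stop("baseline does not activate ERK")
  lo <- -5; hi <- 0                     # log10 fraction bracket
  if (act(10^lo)) stop("ERK still activates at 1e-5 of baseline kphos")
  while (10^hi / 10^lo - 1 > relTol) {
    mid <- (lo + hi) / 2
    if (act(10^mid)) hi <- mid else lo <- mid
  }
  fc <- 10^((lo + hi) / 2)
  pc <- setParams(params, c(kphos = k0 * fc))
  mc <- buildModel(pc)
  tc <- runSimulation(pc, vegf = vegf, times = seq(0, tEnd, 30), model = mc)
  pR2 <- max(observable(tc, "pR2tot")) / pc@values[["VEGFR2_0"]]
  list(kphosFraction = fc, kphosCritical = k0 * fc, pR2Fraction = pR2)
}

.therapyTargets <- list(
  vegf   = "dose",                # free VEGF (ligand capture)
  kphos  = "kphos",               # receptor kinase inhibition
  vegfr2 = c("VEGFR2_0", "sR2"),  # receptor depletion (incl. synthesis)
  raf    = "kaRaf",               # Raf inhibition
  sphk1  = "kcatSK1")             # SphK1 catalytic inhibition

#' Blockade fraction needed to abolish ERK activation
#'
#' Simulates anti-angiogenic blockade: each named target is scaled by
#' \code{(1 - f)} (dose for ligand capture, rate/abundance parameters
#' otherwise), with the same fraction \code{f} applied to every target in a
#' combination.  Bisection finds the minimal \code{f} that prevents ERK
#' ignition.
#'
#' @param targets character vector from
#'   \code{c("vegf","kphos","vegfr2","raf","sphk1")}; more than one means a
#'   combination therapy.
#' @param params ParameterSet.
#' @param vegf unblocked dose in pM.
#' @param epsFrac activation criterion.
#' @param tol absolute tolerance on the blockade fraction.
#' @param tEnd horizon (s).
#' @return critical blockade fraction in (0, 1), or NA if even full blockade
#'   fails to abolish activation.
#' @export
therapyThreshold <- function(targets, params = defaultParameters(),
                             vegf = 1200, epsFrac = 0.05, tol = 0.01,
                             tEnd = 2400) {
  bad <- setdiff(targets, names(.therapyTargets))
  if (length(bad)) stop("unknown therapy target(s): ", paste(bad, collapse = ", "))
  act <- function(f) {
    p <- params; d <- vegf
    for (tg in targets) {
      for (sym in .therapyTargets[[tg]]) {
        if (sym == "dose") d <- vegf * (1 - f)
        else p[sym] <- params@values[[sym]] * (1 - f)
      }
    }
    model <- buildModel(p)
    maxPerkFraction(p, d, tEnd, model) > epsFrac
  }
  if (act(1)) return(NA_real_)
  if (!act(0)) stop("baseline does not activate ERK")
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (act(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Headline model statistics
#'
#' Computes the package's principal quantitative outputs in one call: network
#' size, receptor retention with and without NRP1, signalling peak summaries
#' (calcium, S1P, active SphK1, pERK), the pVEGFR2 EC50, and the VEGF and
#' pVEGFR2 activation thresholds.
#'
#' @param params ParameterSet.
#' @param vegf reference dose in pM (default 50 ng/ml = 1200 pM).
#' @return named list of scalars.
#' @export
summaryStatistics <- function(params = defaultParameters(), vegf = 1200) {
  model <- buildModel(params)
  rest <- restingState(model)
  tc <- runSimulation(params, vegf = vegf, times = seq(0, 10800, 30),
                      model = model, rest = rest)
  r2 <- observable(tc, "R2tot")
  at <- function(min) which(tc@time == min * 60)
  ca <- peakStats(tc, "Ca")
  s1p <- peakStats(tc, "S1P")
  p0 <- setParams(params, c(NRP1_0 = 0))
  tc0 <- runSimulation(p0, vegf = vegf, times = seq(0, 10800, 60),
                       model = buildModel(p0))
  r20 <- observable(tc0, "R2tot")
  dr <- doseResponse(params, observable = "pR2tot", metric = "final",
                     times = seq(0, 1200, 15), model = model)
  thr <- findVegfThreshold(params)
  pthr <- findPvegfr2Threshold(params)
  list(
    nSpecies = numSpecies(model@network),
    nReactions = numReactions(model@network),
    r2FractionAt180min = r2[at(180)] / r2[1],
    r2FractionAt180minNoNrp1 = r20[length(r20)] / r20[1],
    pR2SurfPeakFraction = max(observable(tc, "pR2surf")) / params@values[["VEGFR2_0"]],
    pR2TotPeakFraction = max(observable(tc, "pR2tot")) / params@values[["VEGFR2_0"]],
    caPeak_nM = unname(ca["peak"]), caPeakTime_s = unname(ca["tPeak"]),
    caDuration_s = unname(ca["duration"]),
    s1pPeak_nM = unname(s1p["peak"]), s1pPeakTime_s = unname(s1p["tPeak"]),
    activeSphk1At40min_nM = observable(tc, "pSK1")[at(40)],
    pErkPeakFraction = max(observable(tc, "pERKfrac")),
    pVegfr2EC50_pM = estimateEC50(dr),
    vegfThreshold_pM = thr$threshold,
    pVegfr2ThresholdFraction = pthr$pR2Fraction,
    kphosThresholdFraction = pthr$kphosFraction)
}
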