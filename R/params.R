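# Model parameters: a single named vector with units, shared by the receptor
# network (rate symbols referenced by rules) and the cascade/calcium layer.

#' Default model parameters
#'
#' Returns the calibrated baseline parameter set.  All concentrations are in
#' nM (surface species are expressed as equivalent cytosolic-volume
#' concentrations), times in seconds, bimolecular rate constants in
#' 1/(nM s).  The two passive leak rates (\code{kERleak}, \code{kPMleak}) are
#' computed so that the calcium subsystem is exactly at rest at
#' (\code{Ca0}, \code{CaER0}) with no IP3.
#'
#' @return a \linkS4class{ParameterSet}.
#' @export
defaultParameters <- function() {
  v <- c(
    ## --- geometry / conversions ----------------------------------------
    cellArea   = 1000,     # um^2
    cytosolVol = 1000,     # um^3
    pMPerNgMl  = 24,       # VEGF dose conversion: 1 ng/ml = 24 pM

    ## --- initial amounts -------------------------------------------------
    VEGFR2_0 = 10,         # nM (~6 receptors/um^2)
    VEGFR1_0 = 10,
    NRP1_0   = 33,         # nM (~20/um^2)

    ## --- VEGF binding / receptor coupling --------------------------------
    kon_V_R2  = 3.0e-3,    # 1/(nM s)  (3e6 /M/s)
    koff_V_R2 = 1.0e-3,    # 1/s       (Kd = 100 pM)
    kon_V_R1  = 1.0e-2,
    koff_V_R1 = 1.0e-3,
    kon_V_N1  = 3.1e-3,
    koff_V_N1 = 1.0e-3,
    kc_V_R2   = 1.0e-1,    # 2D bridging, 1/(nM s) in volume-equivalent units
    kc_V_R1   = 5.0e-3,
    kc_V_N1   = 3.0e-2,
    kc_R1_N1  = 1.0e-3,
    koff_R1_N1 = 1.0e-2,
    kc_CC     = 1.0e-4,    # weak ligand-independent dimerization
    koff_CC   = 1.0e-2,

    ## --- Y1175 phosphorylation -------------------------------------------
    kphos        = 42.7,    # 1/s, per liganded homodimer protomer
    kdephos_surf = 0.9,     # 1/s
    kdephos_endo = 0.006,   # 1/s  (surface/endosome ratio 150)

    ## --- trafficking -------------------------------------------------------
    kint_nrp1 = 0.404,     # 1/s, NRP1-containing liganded complexes
    kint      = 6.1e-2,
    krec_nrp1 = 0.756,
    krec      = 1.24e-3,
    kdeg_nrp1 = 1.18e-2,
    kdeg      = 1.41e-3,
    kint0     = 2.0e-4,    # constitutive cycle of unliganded VEGFR2 monomers
    krec0     = 1.5e-3,
    kdeg0     = 3.0e-4,
    sR2       = NA,        # synthesis flux, nM/s; set below for zero drift

    ## --- PLCgamma / PKC ----------------------------------------------------
    PLCg_0   = 100,
    kpPLCgS  = 12,         # 1/s per nM surface pVEGFR2
    kpPLCgE  = 0.02,       # 1/s per nM endosomal pVEGFR2
    KmPLCg   = 50,
    kdpPLCg  = 0.015,
    PKC_0    = 100,
    kaPKC    = 0.05,        # 1/s per nM pPLCg (saturable in PKC)
    KmPKC    = 50,
    kdPKC    = 5.0e-3,
    KaPKCCa  = 300,        # nM calcium half-activation of PKC

    ## --- SphK1 / CIB1 / S1P -------------------------------------------------
    SphK1_0  = 100,
    kpSK1    = 5.0e-3,     # 1/(nM s) per nM pERK
    KmSK1    = 50,
    kdpSK    = 5.0e-4,
    CIB1_0   = 500,
    KdCIB1Ca = 600,        # nM, Hill-2 (two EF hands)
    KdCIB1SK = 200,
    ktSK1    = 1.0,        # 1/s translocation of CIB1-bound pSphK1
    alphaSK  = 0.05,       # relative translocation efficiency, unphos. SphK1
    kretSK   = 0.25,       # 1/s membrane return
    kcatSK1  = 37.24,      # 1/s
    KmSph    = 2500,       # nM
    Sph      = 1000,       # nM membrane sphingosine pool (held constant)
    kdpS1P   = 0.53,       # 1/s S1P turnover

    ## --- Ras / Raf / MEK / ERK ---------------------------------------------
    Ras_0    = 200,
    kS1PRas  = 2.0e-2,     # 1/s
    KmS1PRas = 400,
    kdRas    = 1.0e-2,
    Raf_0    = 100,
    kaRaf    = 6.0,        # nM/s maximal activation rate
    KmRaf    = 50,
    kdRaf    = 3.0e-2,
    KaPKCRaf = 30,
    KaRasRaf = 25,
    MEK_0    = 700,
    kaMEK    = 5.0e-2,     # 1/s per nM pRaf
    KmMEK    = 100,
    kdMEK    = 1.0e-2,
    ERK_0    = 700,
    kaERK    = 3.3e-3,
    KmERK    = 100,
    kdERK    = 5.0e-3,

    ## --- IP3 / calcium -------------------------------------------------------
    kIP3prod = 0.3,        # 1/s per nM pPLCg
    kdIP3    = 0.075,
    kIP3R    = 1.2e-3,     # 1/s channel rate coefficient
    KIP3R    = 100,        # nM IP3 half-activation, Hill 2
    VSERCA   = 400,        # nM/s
    KSERCA   = 200,
    VPMCA    = 300,
    KPMCA    = 250,
    ACRAC    = 1.74e7,     # nM/s (1.74e4 uM/s)
    KCRAC    = 9300,       # nM free ER calcium, Hill 4 store sensing
    nCRAC    = 4,
    fbuf     = 0.04,       # fraction of cytosolic calcium that is free
    gammaER  = 1,          # effective cytosol:ER volume/buffering ratio
    Ca0      = 100,        # nM resting cytosolic calcium
    CaER0    = 4.0e5,      # nM resting free ER calcium
    kERleak  = NA,         # 1/s, balanced below
    kPMleak  = NA)         # nM/s, balanced below

  # synthesis balancing constitutive degradation at the nominal resting
  # endosomal pool (1/10 of total VEGFR2 for the chosen cycle rates)
  e0 <- v[["VEGFR2_0"]] * v[["kint0"]] / (v[["kint0"]] + v[["krec0"]] + v[["kdeg0"]])
  v[["sR2"]] <- v[["kdeg0"]] * e0

  v <- .balanceCalciumLeaks(v)

  units <- rep("1/s", length(v))
  names(units) <- names(v)
  units[c("cellArea")] <- "um^2"; units[c("cytosolVol")] <- "um^3"
  units[c("pMPerNgMl")] <- "pM per ng/ml"
  conc <- c("VEGFR2_0","VEGFR1_0","NRP1_0","PLCg_0","PKC_0","SphK1_0","CIB1_0",
            "Ras_0","Raf_0","MEK_0","ERK_0","KmPLCg","KmPKC","KaPKCCa","KmSK1",
            "KdCIB1Ca","KdCIB1SK","KmSph","Sph","KmS1PRas","KmRaf","KaPKCRaf",
            "KaRasRaf","KmMEK","KmERK","KIP3R","KSERCA","KPMCA","KCRAC",
            "Ca0","CaER0")
  units[conc] <- "nM"
  units[c("kon_V_R2","kon_V_R1","kon_V_N1","kc_V_R2","kc_V_R1","kc_V_N1",
          "kc_R1_N1","kc_CC","kpSK1")] <- "1/(nM s)"
  units[c("sR2","kaRaf","VSERCA","VPMCA","ACRAC","kPMleak")] <- "nM/s"
  units[c("nCRAC","fbuf","gammaER","alphaSK")] <- "dimensionless"
  new("ParameterSet", values = v, units = units)
}

# names of the cascade/calcium parameters in the order expected by the
# compiled right-hand side (see src/rhs.cpp and .cascadeRhsR)
.cascadeParamNames <- c(
  "kpPLCgS", "kpPLCgE", "KmPLCg", "kdpPLCg",
  "kaPKC", "KmPKC", "kdPKC", "KaPKCCa",
  "kpSK1", "KmSK1", "kdpSK",
  "CIB1_0", "KdCIB1Ca", "KdCIB1SK", "ktSK1", "alphaSK", "kretSK",
  "kcatSK1", "KmSph", "Sph", "kdpS1P",
  "kS1PRas", "KmS1PRas", "kdRas",
  "kaRaf", "KmRaf", "kdRaf", "KaPKCRaf", "KaRasRaf",
  "kaMEK", "KmMEK", "kdMEK",
  "kaERK", "KmERK", "kdERK",
  "kIP3prod", "kdIP3", "kIP3R", "KIP3R",
  "VSERCA", "KSERCA", "VPMCA", "KPMCA",
  "ACRAC", "KCRAC", "nCRAC",
  "kERleak", "kPMleak", "fbuf", "gammaER")

# names of the cascade/calcium state variables, appended after the network
.cascadeStateNames <- c(
  "PLCg", "pPLCg", "PKC", "PKCa",
  "SKc", "pSKc", "SKm", "pSKm", "S1P",
  "RasGDP", "RasGTP", "Raf", "pRaf",
  "MEK", "pMEK", "ERK", "pERK",
  "Ca", "CaER", "IP3")

# recompute the two passive calcium leaks so that (Ca0, CaER0) is an exact
# flux-balanced fixed point of the calcium subsystem at zero IP3
.balanceCalciumLeaks <- function(v) {
  hill2 <- function(x, K) x^2 / (x^2 + K^2)
  v[["kERleak"]] <- v[["VSERCA"]] * hill2(v[["Ca0"]], v[["KSERCA"]]) /
    (v[["CaER0"]] - v[["Ca0"]])
  v[["kPMleak"]] <- v[["VPMCA"]] * hill2(v[["Ca0"]], v[["KPMCA"]]) -
    v[["ACRAC"]] / (1 + (v[["CaER0"]] / v[["KCRAC"]])^v[["nCRAC"]])
  v
}

#' Perturb the calcium handling machinery
#'
#' Scales the maximal rates of the PMCA and SERCA pumps, the CRAC channel
#' amplitude and the IP3R channel coefficient by the given multipliers.  The
#' passive leak rates are left at their baseline values, so the perturbed cell
#' settles to a new ligand-free resting point: simulations re-solve the
#' resting state by pre-equilibration before ligand is applied (see
#' \code{\link{restingState}}).
#'
#' @param params ParameterSet.
#' @param pmca,serca,crac,ip3r non-negative multipliers (1 = unchanged).
#' @return a new ParameterSet.
#' @export
perturbCalcium <- function(params = defaultParameters(), pmca = 1, serca = 1,
                           crac = 1, ip3r = 1) {
  mult <- c(pmca = pmca, serca = serca, crac = crac, ip3r = ip3r)
  if (any(!is.finite(mult)) || any(mult < 0))
    stop("calcium pump/channel multipliers must be finite and >= 0")
  v <- params@values
  v[["VPMCA"]] <- v[["VPMCA"]] * pmca
  v[["VSERCA"]] <- v[["VSERCA"]] * serca
  v[["ACRAC"]] <- v[["ACRAC"]] * crac
  v[["kIP3R"]] <- v[["kIP3R"]] * ip3r
  new("ParameterSet", values = v, units = params@units)
}
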