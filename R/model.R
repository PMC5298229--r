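# Whole-cell model assembly: receptor network + cascade/calcium layer.

#' Assemble the whole-cell signalling model
#'
#' Expands (or reuses) the receptor network, resolves all rate symbols against
#' \code{params}, converts the reaction list into stoichiometry triplets for
#' the compiled right-hand side and packs the cascade parameter vector in the
#' exact order the compiled code expects (the order is exported by the
#' compiled code itself, so the two sides cannot drift apart silently).
#'
#' @param params a \linkS4class{ParameterSet} (default
#'   \code{\link{defaultParameters}}).
#' @param clampVegf keep free VEGF constant (default; the experimental medium
#'   is an effectively infinite ligand reservoir). Set \code{FALSE} for
#'   closed-system binding experiments.
#' @param maxAgg aggregate-size cap passed to the network expansion.
#' @return a \linkS4class{SignalModel}.
#' @export
buildModel <- function(params = defaultParameters(), clampVegf = TRUE,
                       maxAgg = 6L) {
  net <- receptorNetwork(maxAgg)
  pv <- params@values
  rx <- net@reactions
  miss <- setdiff(unique(rx$rateName), names(pv))
  if (length(miss))
    stop("missing parameter symbol(s): ", paste(miss, collapse = ", "))
  k <- unname(pv[rx$rateName]) * rx$factor
  m <- nrow(rx)
  r1 <- integer(m); r2 <- integer(m)
  si <- integer(0); sj <- integer(0); sc <- numeric(0)
  for (j in seq_len(m)) {
    re <- rx$reactants[[j]]; pr <- rx$products[[j]]
    r1[j] <- if (length(re) >= 1L) re[1L] else 0L
    r2[j] <- if (length(re) == 2L) re[2L] else 0L
    net_ch <- c(re, pr)
    coef <- c(rep(-1, length(re)), rep(1, length(pr)))
    si <- c(si, net_ch); sj <- c(sj, rep(j, length(net_ch))); sc <- c(sc, coef)
  }
  nNet <- numSpecies(net)
  wS <- net@observables[["pR2surf"]]$weights
  wE <- net@observables[["pR2endo"]]$weights
  clampIdx <- if (clampVegf) match("V(r1,r2,n)@solution", net@labels) else 0L
  if (clampVegf && is.na(clampIdx)) stop("free VEGF species not found")

  expect <- .cascadeParamOrderCpp()
  stopifnot(identical(as.character(expect), .cascadeParamNames))
  missC <- setdiff(.cascadeParamNames, names(pv))
  if (length(missC))
    stop("missing cascade parameter(s): ", paste(missC, collapse = ", "))
  cmodel <- list(nNet = nNet, r1 = r1, r2 = r2, k = k,
                 stoichSp = si, stoichRx = sj, stoichCoef = sc,
                 wSurf = wS, wEndo = wE, clampIdx = as.integer(clampIdx),
                 cascadeParams = unname(pv[.cascadeParamNames]))
  new("SignalModel", network = net, params = params, cmodel = cmodel,
      stateNames = c(net@labels, .cascadeStateNames))
}

#' Initial state of a model
#'
#' Nominal initial condition: receptor seeds at their \code{*_0} amounts on
#' the surface, free VEGF at \code{vegf} (pM, converted to nM), cascade pools
#' fully inactive, calcium at its nominal rest.  Simulations normally relax
#' this state with a ligand-free pre-equilibration (see
#' \code{\link{restingState}}) before applying ligand.
#'
#' @param model a \linkS4class{SignalModel}.
#' @param vegf free-VEGF concentration in pM.
#' @return named numeric state vector.
#' @export
initialState <- function(model, vegf = 0) {
  pv <- model@params@values
  y <- numeric(length(model@stateNames))
  names(y) <- model@stateNames
  y["V(r1,r2,n)@solution"] <- vegf / 1000
  y["VEGFR2(L,C,Y~U)@surface"] <- pv[["VEGFR2_0"]]
  y["VEGFR1(L,C,N)@surface"] <- pv[["VEGFR1_0"]]
  y["NRP1(b)@surface"] <- pv[["NRP1_0"]]
  y["PLCg"] <- pv[["PLCg_0"]]; y["PKC"] <- pv[["PKC_0"]]
  y["SKc"] <- pv[["SphK1_0"]]; y["RasGDP"] <- pv[["Ras_0"]]
  y["Raf"] <- pv[["Raf_0"]]; y["MEK"] <- pv[["MEK_0"]]; y["ERK"] <- pv[["ERK_0"]]
  y["Ca"] <- pv[["Ca0"]]; y["CaER"] <- pv[["CaER0"]]
  y
}

# right-hand side in deSolve's expected signature
.deriv <- function(t, y, parms) list(.fullRhsCpp(t, y, parms))

#' Ligand-free resting state
#'
#' Integrates the model without ligand until the receptor distribution and the
#' calcium/cascade pools are stationary, so that simulated stimulation starts
#' from a self-consistent rest (constitutive receptor cycling redistributes
#' some VEGFR2 to endosomes and dimers; synthesis balances turnover).
#'
#' @param model a \linkS4class{SignalModel}.
#' @param tPre pre-equilibration horizon in seconds.
#' @return named numeric state vector.
#' @export
restingState <- function(model, tPre = 2e5) {
  y0 <- initialState(model, vegf = 0)
  out <- deSolve::lsoda(y0, c(0, tPre), .deriv, model@cmodel,
                        rtol = 1e-8, atol = 1e-8)
  y <- out[nrow(out), -1]
  names(y) <- model@stateNames
  y
}

# R reference implementation of the compiled right-hand side; used by the test
# suite as an independent oracle (must agree with .fullRhsCpp to ~1e-12).
.fullRhsR <- function(t, y, cm) {
  nNet <- cm$nNet
  f <- cm$k
  has1 <- cm$r1 > 0L; f[has1] <- f[has1] * y[cm$r1[has1]]
  has2 <- cm$r2 > 0L; f[has2] <- f[has2] * y[cm$r2[has2]]
  dy <- numeric(length(y))
  inc <- cm$stoichCoef * f[cm$stoichRx]
  for (t3 in seq_along(cm$stoichSp))
    dy[cm$stoichSp[t3]] <- dy[cm$stoichSp[t3]] + inc[t3]
  if (cm$clampIdx > 0L) dy[cm$clampIdx] <- 0
  pR2s <- sum(cm$wSurf * y[seq_len(nNet)])
  pR2e <- sum(cm$wEndo * y[seq_len(nNet)])
  p <- as.list(stats::setNames(cm$cascadeParams, .cascadeParamNames))
  s <- as.list(stats::setNames(y[nNet + seq_along(.cascadeStateNames)],
                               .cascadeStateNames))
  mm <- function(x, km) x / (x + km)
  hill2 <- function(x, k) x^2 / (x^2 + k^2)
  with(c(p, s), {
    d <- numeric(20)
    vPLC <- (kpPLCgS * pR2s + kpPLCgE * pR2e) * mm(PLCg, KmPLCg)
    d[1] <- -vPLC + kdpPLCg * pPLCg; d[2] <- -d[1]
    vPKC <- kaPKC * pPLCg * mm(Ca, KaPKCCa) * mm(PKC, KmPKC)
    d[3] <- -vPKC + kdPKC * PKCa; d[4] <- -d[3]
    CIB1a <- CIB1_0 * hill2(Ca, KdCIB1Ca)
    fB <- CIB1a / (CIB1a + KdCIB1SK)
    vSKp <- kpSK1 * pERK * mm(SKc, KmSK1)
    vTp <- ktSK1 * fB * pSKc; vTu <- ktSK1 * alphaSK * fB * SKc
    d[5] <- -vSKp - vTu + kdpSK * pSKc + kretSK * SKm
    d[6] <-  vSKp - vTp - kdpSK * pSKc + kretSK * pSKm
    d[7] <-  vTu - kretSK * SKm + kdpSK * pSKm
    d[8] <-  vTp - kretSK * pSKm - kdpSK * pSKm
    vS1P <- kcatSK1 * (SKm + pSKm) * mm(Sph, KmSph)
    d[9] <- vS1P - kdpS1P * S1P
    vRas <- kS1PRas * RasGDP * mm(S1P, KmS1PRas)
    d[10] <- -vRas + kdRas * RasGTP; d[11] <- -d[10]
    vRaf <- kaRaf * hill2(PKCa, KaPKCRaf) * hill2(RasGTP, KaRasRaf) * mm(Raf, KmRaf)
    d[12] <- -vRaf + kdRaf * pRaf; d[13] <- -d[12]
    vMEK <- kaMEK * pRaf * mm(MEK, KmMEK)
    d[14] <- -vMEK + kdMEK * pMEK; d[15] <- -d[14]
    vERK <- kaERK * pMEK * mm(ERK, KmERK)
    d[16] <- -vERK + kdERK * pERK; d[17] <- -d[16]
    d[20] <- kIP3prod * pPLCg - kdIP3 * IP3
    J_IP3R <- kIP3R * hill2(IP3, KIP3R) * (CaER - Ca)
    J_ERleak <- kERleak * (CaER - Ca)
    J_SERCA <- VSERCA * hill2(Ca, KSERCA)
    J_PMCA <- VPMCA * hill2(Ca, KPMCA)
    J_CRAC <- ACRAC / (1 + (CaER / KCRAC)^nCRAC)
    d[18] <- fbuf * (J_IP3R + J_ERleak - J_SERCA + J_CRAC + kPMleak - J_PMCA)
    d[19] <- -gammaER * (J_IP3R + J_ERleak - J_SERCA)
    dy[nNet + seq_len(20)] <- d
    dy
  })
}
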