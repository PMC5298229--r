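// Full-model right-hand side: mass-action network + signalling cascade +
// calcium handling.  State layout: [network species (n), cascade states (20)]
// in the order given by the R-side .cascadeStateNames.  Cascade parameters
// arrive as a plain numeric vector in the order reported by
// cascadeParamOrder(); the R wrapper packs it by name so the two sides cannot
// drift silently.

#include <Rcpp.h>
using namespace Rcpp;

static const char* kParamNames[] = {
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
  "kERleak", "kPMleak", "fbuf", "gammaER"};
static const int kNParams = sizeof(kParamNames) / sizeof(kParamNames[0]);

// [[Rcpp::export(name = ".cascadeParamOrderCpp")]]
CharacterVector cascadeParamOrder() {
  return CharacterVector(kParamNames, kParamNames + kNParams);
}

static inline double mm(double s, double km) { return s / (s + km); }
static inline double hill2(double x, double k) {
  double x2 = x * x;
  return x2 / (x2 + k * k);
}

// [[Rcpp::export(name = ".fullRhsCpp")]]
NumericVector fullRhs(double t, NumericVector y, List model) {
  const IntegerVector r1 = model["r1"], r2 = model["r2"];
  const NumericVector k = model["k"];
  const IntegerVector si = model["stoichSp"], sj = model["stoichRx"];
  const NumericVector sc = model["stoichCoef"];
  const NumericVector wS = model["wSurf"], wE = model["wEndo"];
  const int nNet = as<int>(model["nNet"]);
  const int clampIdx = as<int>(model["clampIdx"]);  // 1-based, 0 = off
  const NumericVector p = model["cascadeParams"];
  const int nRx = k.size();

  NumericVector dy(y.size());

  // --- network mass-action fluxes ---------------------------------------
  std::vector<double> flux(nRx);
  for (int j = 0; j < nRx; ++j) {
    double f = k[j];
    if (r1[j] > 0) f *= y[r1[j] - 1];
    if (r2[j] > 0) f *= y[r2[j] - 1];
    flux[j] = f;
  }
  for (int t3 = 0; t3 < si.size(); ++t3)
    dy[si[t3] - 1] += sc[t3] * flux[sj[t3] - 1];
  if (clampIdx > 0) dy[clampIdx - 1] = 0.0;  // free ligand held constant

  // --- receptor-derived drives -------------------------------------------
  double pR2s = 0.0, pR2e = 0.0;
  for (int i = 0; i < nNet; ++i) {
    if (wS[i] != 0.0) pR2s += wS[i] * y[i];
    if (wE[i] != 0.0) pR2e += wE[i] * y[i];
  }

  int q = nNet;
  const double PLCg  = y[q + 0], pPLCg = y[q + 1];
  const double PKC   = y[q + 2], PKCa  = y[q + 3];
  const double SKc   = y[q + 4], pSKc  = y[q + 5];
  const double SKm   = y[q + 6], pSKm  = y[q + 7];
  const double S1P   = y[q + 8];
  const double RasGDP = y[q + 9], RasGTP = y[q + 10];
  const double Raf  = y[q + 11], pRaf = y[q + 12];
  const double MEK  = y[q + 13], pMEK = y[q + 14];
  const double ERK  = y[q + 15], pERK = y[q + 16];
  const double Ca   = y[q + 17], CaER = y[q + 18], IP3 = y[q + 19];

  int i = 0;
  const double kpPLCgS = p[i++], kpPLCgE = p[i++], KmPLCg = p[i++], kdpPLCg = p[i++];
  const double kaPKC = p[i++], KmPKC = p[i++], kdPKC = p[i++], KaPKCCa = p[i++];
  const double kpSK1 = p[i++], KmSK1 = p[i++], kdpSK = p[i++];
  const double CIB1tot = p[i++], KdCIB1Ca = p[i++], KdCIB1SK = p[i++];
  const double ktSK1 = p[i++], alphaSK = p[i++], kretSK = p[i++];
  const double kcatSK1 = p[i++], KmSph = p[i++], Sph = p[i++], kdpS1P = p[i++];
  const double kS1PRas = p[i++], KmS1PRas = p[i++], kdRas = p[i++];
  const double kaRaf = p[i++], KmRaf = p[i++], kdRaf = p[i++];
  const double KaPKCRaf = p[i++], KaRasRaf = p[i++];
  const double kaMEK = p[i++], KmMEK = p[i++], kdMEK = p[i++];
  const double kaERK = p[i++], KmERK = p[i++], kdERK = p[i++];
  const double kIP3prod = p[i++], kdIP3 = p[i++], kIP3R = p[i++], KIP3R = p[i++];
  const double VSERCA = p[i++], KSERCA = p[i++], VPMCA = p[i++], KPMCA = p[i++];
  const double ACRAC = p[i++], KCRAC = p[i++], nCRAC = p[i++];
  const double kERleak = p[i++], kPMleak = p[i++], fbuf = p[i++], gammaER = p[i++];

  // PLCgamma phosphorylation by surface and endosomal pVEGFR2
  const double vPLC = (kpPLCgS * pR2s + kpPLCgE * pR2e) * mm(PLCg, KmPLCg);
  const double rPLC = kdpPLCg * pPLCg;
  dy[q + 0] = -vPLC + rPLC;
  dy[q + 1] =  vPLC - rPLC;

  // PKC activation by pPLCg (DAG proxy) and calcium
  const double vPKC = kaPKC * pPLCg * mm(Ca, KaPKCCa) * mm(PKC, KmPKC);
  const double rPKC = kdPKC * PKCa;
  dy[q + 2] = -vPKC + rPKC;
  dy[q + 3] =  vPKC - rPKC;

  // CIB1 activation by calcium (rapid equilibrium) and SphK1 translocation
  const double CIB1a = CIB1tot * hill2(Ca, KdCIB1Ca);
  const double fB = CIB1a / (CIB1a + KdCIB1SK);
  const double vSKp = kpSK1 * pERK * mm(SKc, KmSK1);
  const double vTp = ktSK1 * fB * pSKc;
  const double vTu = ktSK1 * alphaSK * fB * SKc;
  dy[q + 4] = -vSKp - vTu + kdpSK * pSKc + kretSK * SKm;
  dy[q + 5] =  vSKp - vTp - kdpSK * pSKc + kretSK * pSKm;
  dy[q + 6] =  vTu - kretSK * SKm + kdpSK * pSKm;
  dy[q + 7] =  vTp - kretSK * pSKm - kdpSK * pSKm;

  // S1P production by membrane SphK1 (both forms catalytically active)
  const double vS1P = kcatSK1 * (SKm + pSKm) * mm(Sph, KmSph);
  dy[q + 8] = vS1P - kdpS1P * S1P;

  // Ras activation by S1P (receptor-mediated, saturable in S1P).  The basal
  // S1P leak keeps a modest resting RasGTP pool; ERK stays off at rest
  // because Raf activation also requires the PKC gate (zero without ligand)
  const double vRas = kS1PRas * RasGDP * mm(S1P, KmS1PRas);
  const double rRas = kdRas * RasGTP;
  dy[q + 9]  = -vRas + rRas;
  dy[q + 10] =  vRas - rRas;

  // Raf: PKC gate (multiplicative) x Ras gate, saturable in Raf
  const double vRaf = kaRaf * hill2(PKCa, KaPKCRaf) * hill2(RasGTP, KaRasRaf) * mm(Raf, KmRaf);
  const double rRaf = kdRaf * pRaf;
  dy[q + 11] = -vRaf + rRaf;
  dy[q + 12] =  vRaf - rRaf;

  const double vMEK = kaMEK * pRaf * mm(MEK, KmMEK);
  const double rMEK = kdMEK * pMEK;
  dy[q + 13] = -vMEK + rMEK;
  dy[q + 14] =  vMEK - rMEK;

  const double vERK = kaERK * pMEK * mm(ERK, KmERK);
  const double rERK = kdERK * pERK;
  dy[q + 15] = -vERK + rERK;
  dy[q + 16] =  vERK - rERK;

  // IP3 and calcium
  dy[q + 19] = kIP3prod * pPLCg - kdIP3 * IP3;
  const double hIP3 = hill2(IP3, KIP3R);
  const double J_IP3R = kIP3R * hIP3 * (CaER - Ca);
  const double J_ERleak = kERleak * (CaER - Ca);
  const double J_SERCA = VSERCA * hill2(Ca, KSERCA);
  const double J_PMCA = VPMCA * hill2(Ca, KPMCA);
  const double J_CRAC = ACRAC / (1.0 + std::pow(CaER / KCRAC, nCRAC));
  dy[q + 17] = fbuf * (J_IP3R + J_ERleak - J_SERCA + J_CRAC + kPMleak - J_PMCA);
  dy[q + 18] = -gammaER * (J_IP3R + J_ERleak - J_SERCA);

  return dy;
}
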