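// Direct-method (exact) stochastic simulation of the 22-reaction
// checkpoint network in molecule units. Uses R's RNG so runs are
// reproducible under set.seed(). Copy numbers are ~10^2, so no leaping.

#include <Rcpp.h>
using namespace Rcpp;

// state indices
enum { iC, iA, iAC, iMada, iMadi, iMps1, iMC, iACMC, iPonC, iPonX, iNUK,
       NVAR };
static const int NRX = 22;

// stoichiometry, NRX x NVAR
static const int STOICH[NRX][NVAR] = {
  /* ponC on   */ {0,0,0,0,0,0,0,0, 1,0,0},
  /* ponC off  */ {0,0,0,0,0,0,0,0,-1,0,0},
  /* C synth   */ {1,0,0,0,0,0,0,0, 0,0,0},
  /* ponX on   */ {0,0,0,0,0,0,0,0, 0,1,0},
  /* ponX off  */ {0,0,0,0,0,0,0,0, 0,-1,0},
  /* X synth   */ {0,0,0,0,0,1,0,0, 0,0,0},
  /* C bg deg  */ {-1,0,0,0,0,0,0,0,0,0,0},
  /* X deg     */ {0,0,0,0,0,-1,0,0,0,0,0},
  /* X bg deg  */ {0,0,0,0,0,-1,0,0,0,0,0},
  /* Mad act   */ {0,0,0,1,-1,0,0,0,0,0,0},
  /* Mad inact */ {0,0,0,-1,1,0,0,0,0,0,0},
  /* MCC form  */ {-1,0,0,-1,0,0,1,0,0,0,0},
  /* MCC diss  */ {1,0,0,1,0,0,-1,0,0,0,0},
  /* AC form   */ {-1,-1,1,0,0,0,0,0,0,0,0},
  /* AC diss   */ {1,1,-1,0,0,0,0,0,0,0,0},
  /* ACMC form */ {0,0,-1,0,0,0,-1,1,0,0,0},
  /* ACMC diss */ {0,0,1,0,0,0,1,-1,0,0,0},
  /* ACMC deg  */ {1,1,0,0,1,0,0,-1,0,0,0},  // ACMC -> A + C + Mad(inactive)
  /* MC bg     */ {0,0,0,0,1,0,-1,0,0,0,0},  // MC -> Mad(inactive)
  /* AC bg     */ {0,1,-1,0,0,0,0,0,0,0,0},
  /* ACMC bg   */ {0,1,0,0,1,0,0,-1,0,0,0},  // ACMC -> A + Mad(inactive)
  /* attach    */ {0,0,0,0,0,0,0,0,0,0,-1}
};

struct Pars {
  double kdeg, ksynC, kassMC, kdissMC, kassAC, kdissAC, kassACMC, kdissACMC,
         kdegBG, kact, kinact, ksynX, kdegX, kdegBGX, katt, kprime, Jn, J,
         konC, koffC, konX, koffX;
};

static void propensities(const double *x, const Pars &p, bool attach,
                         double ksynXfac, double *a) {
  double s = p.kprime * x[iNUK] / (p.Jn + x[iNUK]);
  a[0]  = p.konC * (1.0 - x[iPonC]);
  a[1]  = p.koffC * x[iPonC];
  a[2]  = p.ksynC * x[iPonC];
  a[3]  = p.konX * (1.0 - x[iPonX]);
  a[4]  = p.koffX * x[iPonX];
  a[5]  = p.ksynX * ksynXfac * x[iPonX];
  a[6]  = p.kdegBG * x[iC];
  a[7]  = p.kdegX * x[iMps1] * x[iAC];
  a[8]  = p.kdegBGX * x[iMps1];
  a[9]  = p.kact * x[iMps1] * s * x[iMadi] / (p.J + x[iMadi]);
  a[10] = p.kinact * x[iMada] * x[iMada] / (p.J + x[iMada]);
  a[11] = p.kassMC * x[iMada] * x[iC];
  a[12] = p.kdissMC * x[iMC];
  a[13] = p.kassAC * x[iA] * x[iC];
  a[14] = p.kdissAC * x[iAC];
  a[15] = p.kassACMC * x[iMC] * x[iAC];
  a[16] = p.kdissACMC * x[iACMC];
  a[17] = p.kdeg * x[iACMC];
  a[18] = p.kdegBG * x[iMC];
  a[19] = p.kdegBG * x[iAC];
  a[20] = p.kdegBG * x[iACMC];
  a[21] = attach ? p.katt * x[iNUK] : 0.0;
}

// [[Rcpp::export(name = ".ssa_core")]]
List ssa_core(NumericVector x0, NumericVector par, double tmax,
              double threshold, bool attach, bool stopAtCross,
              double recordDt, double ksynXFactor, double pulseFrom,
              double pulseTo) {
  if (x0.size() != NVAR) stop("bad state length");
  Pars p;
  p.kdeg = par["kdeg"]; p.ksynC = par["ksynCDC20"];
  p.kassMC = par["kassMC"]; p.kdissMC = par["kDMC"] * par["kassMC"];
  p.kassAC = par["kassAC"]; p.kdissAC = par["kDAC"] * par["kassAC"];
  p.kassACMC = par["kassACMC"];
  p.kdissACMC = par["kDACMC"] * par["kassACMC"];
  p.kdegBG = par["kdegBG"]; p.kact = par["kact"]; p.kinact = par["kinact"];
  p.ksynX = par["ksynX"]; p.kdegX = par["kdegX"];
  p.kdegBGX = par["kdegBGX"]; p.katt = par["katt"];
  p.kprime = par["kprime"]; p.Jn = par["Jn"]; p.J = par["J"];
  p.konC = par["konCDC20"]; p.koffC = par["koffCDC20"];
  p.konX = par["konX"]; p.koffX = par["koffX"];

  double x[NVAR];
  for (int i = 0; i < NVAR; ++i) {
    x[i] = x0[i];
    if (x[i] < 0 || x[i] != std::floor(x[i]))
      stop("stochastic state must be nonnegative integers");
  }

  std::vector<double> recT;
  std::vector<double> recX;
  bool record = recordDt > 0;
  double nextRec = 0.0;
  double t = 0.0;
  double tCross = NA_REAL, nukAtCross = NA_REAL, tAllAttached = NA_REAL;
  if (x[iNUK] == 0 && attach) tAllAttached = 0.0;
  double a[NRX];

  RNGScope scope;
  bool crossed = x[iAC] >= threshold;
  if (crossed) { tCross = 0.0; nukAtCross = x[iNUK]; }

  while (true) {
    double fac = (t >= pulseFrom && t < pulseTo) ? ksynXFactor : 1.0;
    propensities(x, p, attach, fac, a);
    double a0 = 0.0;
    for (int j = 0; j < NRX; ++j) a0 += a[j];
    if (!R_finite(a0)) stop("propensity overflow");
    double tNext;
    if (a0 <= 0.0) tNext = R_PosInf;
    else tNext = t + exp_rand() / a0;
    // piecewise-constant time dependence: redraw at pulse boundaries
    double boundary = R_PosInf;
    if (t < pulseFrom && pulseFrom < tmax) boundary = pulseFrom;
    else if (t < pulseTo && pulseTo < tmax && fac != 1.0) boundary = pulseTo;
    double tStop = std::min(std::min(tNext, boundary), tmax);
    if (record) {
      while (nextRec <= tStop + 1e-12 && nextRec <= tmax + 1e-12) {
        recT.push_back(nextRec);
        for (int i = 0; i < NVAR; ++i) recX.push_back(x[i]);
        nextRec += recordDt;
      }
    }
    if (tNext > boundary) { t = boundary; continue; }
    if (tNext >= tmax || !R_finite(tNext)) { t = tmax; break; }
    t = tNext;
    double u = unif_rand() * a0, cum = 0.0;
    int j = NRX - 1;
    for (int k = 0; k < NRX; ++k) {
      cum += a[k];
      if (u <= cum) { j = k; break; }
    }
    for (int i = 0; i < NVAR; ++i) x[i] += STOICH[j][i];
    if (j == 21 && x[iNUK] == 0 && !R_finite(tAllAttached))
      tAllAttached = t;
    if (!crossed && x[iAC] >= threshold) {
      crossed = true; tCross = t; nukAtCross = x[iNUK];
      if (stopAtCross) break;
    }
  }

  List out;
  if (record) {
    int nr = recT.size();
    NumericMatrix M(nr, NVAR);
    for (int r = 0; r < nr; ++r)
      for (int i = 0; i < NVAR; ++i) M(r, i) = recX[r * NVAR + i];
    out["time"] = NumericVector(recT.begin(), recT.end());
    out["states"] = M;
  }
  NumericVector fin(NVAR);
  for (int i = 0; i < NVAR; ++i) fin[i] = x[i];
  out["finalState"] = fin;
  out["endTime"] = t;
  out["tCross"] = tCross;
  out["nUKAtCross"] = nukAtCross;
  out["tAllAttached"] = tAllAttached;
  return out;
}
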