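/* Compiled right-hand sides for the DEB and Monod batch-culture models,
 * in the deSolve compiled-model calling convention.
 *
 * The DEB specific growth rate r is implicit: mobilization depends on r
 * and r equals the synthesizing-unit growth flux computed from the
 * mobilized reserves.  g(r) - r is strictly decreasing on [0, kE] with
 * g(kE) = 0, so the fixed point is unique and bracketed; it is solved by
 * bisection at every derivative evaluation.
 */
#include <R.h>
#include <math.h>

/* ---- DEB model ---------------------------------------------------- */

#define N_DEB_PARMS 19

enum {
  P_JECAM, P_JENAM, P_KC, P_KN, P_KE, P_JECM, P_JENM,
  P_YECV, P_YENV, P_YSEC, P_YSEN,
  P_KAPEC, P_KAPEN, P_KAPSC, P_KAPSN,
  P_JPINV, P_V, P_NNV, P_FEED
};

static double parms[N_DEB_PARMS];

void deb_initmod(void (*odeparms)(int *, double *))
{
  int n = N_DEB_PARMS;
  odeparms(&n, parms);
}

typedef struct {
  double jEcA, jEnA;       /* assimilation */
  double jEcC, jEnC;       /* mobilization */
  double jEcG, jEnG;       /* per-reserve growth flux */
  double jG, r;            /* SU growth flux == specific growth rate */
  double jEcR, jEnR;       /* rejected fluxes */
  double jEcMp, jEnMp;     /* maintenance actually paid from reserves */
  double jVMc, jVMn, jVM;  /* switch-model structure maintenance (diagnostic) */
  double JNH3;             /* total metabolite ammonia flux, mol/h */
} fluxset;

static double su_flux(double a, double b, double jPinv)
{
  if (a <= 0.0 || b <= 0.0) return 0.0;
  return 1.0 / (jPinv + 1.0 / a + 1.0 / b - 1.0 / (a + b));
}

/* SU growth flux at trial growth rate r (mobilization floored at 0) */
static double growth_at(double r, double mEc, double mEn)
{
  double jEcC = mEc * (parms[P_KE] - r);
  double jEnC = mEn * (parms[P_KE] - r);
  double a, b;
  if (jEcC < 0.0) jEcC = 0.0;
  if (jEnC < 0.0) jEnC = 0.0;
  a = (jEcC - parms[P_JECM]) / parms[P_YECV];
  b = (jEnC - parms[P_JENM]) / parms[P_YENV];
  if (a < 0.0) a = 0.0;
  if (b < 0.0) b = 0.0;
  return su_flux(a, b, parms[P_JPINV]);
}

static double solve_r(double mEc, double mEn)
{
  double lo = 0.0, hi = parms[P_KE];
  int i;
  if (growth_at(0.0, mEc, mEn) <= 0.0) return 0.0;
  for (i = 0; i < 200; i++) {
    double mid = 0.5 * (lo + hi);
    if (growth_at(mid, mEc, mEn) - mid > 0.0) lo = mid; else hi = mid;
    if (hi - lo < 1e-14 * parms[P_KE]) break;
  }
  return 0.5 * (lo + hi);
}

static void eval_fluxes(const double *y, fluxset *F)
{
  double SC = y[0], SN = y[1], mEc = y[2], mEn = y[3], MV = y[4];
  double r;

  memset(F, 0, sizeof(fluxset));
  if (MV <= 0.0) return;

  F->jEcA = (SC > 0.0) ? parms[P_JECAM] * SC / (parms[P_KC] + SC) : 0.0;
  F->jEnA = (SN > 0.0) ? parms[P_JENAM] * SN / (parms[P_KN] + SN) : 0.0;

  r = solve_r(mEc, mEn);
  F->r = F->jG = r;

  F->jEcC = mEc * (parms[P_KE] - r);
  F->jEnC = mEn * (parms[P_KE] - r);
  if (F->jEcC < 0.0) F->jEcC = 0.0;
  if (F->jEnC < 0.0) F->jEnC = 0.0;

  F->jEcMp = (F->jEcC < parms[P_JECM]) ? F->jEcC : parms[P_JECM];
  F->jEnMp = (F->jEnC < parms[P_JENM]) ? F->jEnC : parms[P_JENM];
  F->jEcG = F->jEcC - F->jEcMp;  /* == max(jEcC - jEcM, 0) */
  F->jEnG = F->jEnC - F->jEnMp;

  F->jEcR = F->jEcG - parms[P_YECV] * r;
  F->jEnR = F->jEnG - parms[P_YENV] * r;
  if (F->jEcR < 0.0) F->jEcR = 0.0;  /* guards roundoff only */
  if (F->jEnR < 0.0) F->jEnR = 0.0;

  /* switch model: maintenance unpaid from reserves charged to structure;
   * reported diagnostically, never fed back into the dynamics (jVM = 0) */
  F->jVMc = (parms[P_JECM] - F->jEcMp) / parms[P_YECV];
  F->jVMn = (parms[P_JENM] - F->jEnMp) / parms[P_YENV];
  F->jVM = F->jVMc + F->jVMn;

  /* nitrogen-closure metabolite flux: assimilation overhead, growth
   * overhead, and maintenance-dissipated N all return to the medium */
  F->JNH3 = MV * ((parms[P_YSEN] - 1.0) * F->jEnA
                  + (parms[P_YENV] - parms[P_NNV]) * r
                  + F->jEnMp);
}

void deb_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
  fluxset F;
  double MV = y[4], V = parms[P_V];

  eval_fluxes(y, &F);

  ydot[0] = (-F.jEcA + parms[P_KAPSC] * (1.0 - parms[P_KAPEC]) * F.jEcR)
            * parms[P_YSEC] * MV / V;
  ydot[1] = (-F.jEnA + parms[P_KAPSN] * (1.0 - parms[P_KAPEN]) * F.jEnR)
            * parms[P_YSEN] * MV / V
            + (F.JNH3 + parms[P_FEED]) / V;
  ydot[2] = F.jEcA - F.jEcC + parms[P_KAPEC] * F.jEcR - F.r * y[2];
  ydot[3] = F.jEnA - F.jEnC + parms[P_KAPEN] * F.jEnR - F.r * y[3];
  ydot[4] = F.r * MV;

  /* dissipation pools close the elemental balances exactly */
  ydot[5] = MV * ((parms[P_YSEC] - 1.0) * F.jEcA
                  + (1.0 - parms[P_KAPEC]) * (1.0 - parms[P_YSEC] * parms[P_KAPSC]) * F.jEcR
                  + (parms[P_YECV] - 1.0) * F.r
                  + F.jEcMp);
  ydot[6] = MV * (1.0 - parms[P_KAPEN])
               * (1.0 - parms[P_YSEN] * parms[P_KAPSN]) * F.jEnR;

  if (ip[0] >= 14) {
    yout[0]  = F.r;
    yout[1]  = F.jEcA;  yout[2]  = F.jEnA;
    yout[3]  = F.jEcC;  yout[4]  = F.jEnC;
    yout[5]  = F.jEcG;  yout[6]  = F.jEnG;
    yout[7]  = F.jG;
    yout[8]  = F.jEcR;  yout[9]  = F.jEnR;
    yout[10] = F.jVMc;  yout[11] = F.jVMn;  yout[12] = F.jVM;
    yout[13] = F.JNH3;
  }
}

/* death condition: mobilization of either reserve falls below its
 * maintenance demand; integration stops at the first crossing */
void deb_root(int *neq, double *t, double *y, int *ng, double *gout,
              double *rpar, int *ipar)
{
  double r = (y[4] > 0.0) ? solve_r(y[2], y[3]) : 0.0;
  double jEcC = y[2] * (parms[P_KE] - r);
  double jEnC = y[3] * (parms[P_KE] - r);
  if (jEcC < 0.0) jEcC = 0.0;
  if (jEnC < 0.0) jEnC = 0.0;
  gout[0] = jEcC - parms[P_JECM];
  gout[1] = jEnC - parms[P_JENM];
}

/* ---- Monod model --------------------------------------------------- */

#define N_MONOD_PARMS 5

static double mparms[N_MONOD_PARMS]; /* mu_max, YXSC, YXSN, KC, KN */

void monod_initmod(void (*odeparms)(int *, double *))
{
  int n = N_MONOD_PARMS;
  odeparms(&n, mparms);
}

void monod_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
  double X = y[0], SC = y[1], SN = y[2];
  double fc = (SC > 0.0) ? SC / (mparms[3] + SC) : 0.0;
  double fn = (SN > 0.0) ? SN / (mparms[4] + SN) : 0.0;
  double mu = mparms[0] * fc * fn;

  ydot[0] = mu * X;
  ydot[1] = -mu * X / mparms[1];
  ydot[2] = -mu * X / mparms[2];

  if (ip[0] >= 1) yout[0] = mu;
}
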