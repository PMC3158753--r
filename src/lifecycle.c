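/* Right-hand sides for the mosquito lifecycle ODEs, in the deSolve
 * compiled-code convention: parameters are filled by the solver via
 * mosq_initmod(), the carrying capacity K(t) arrives as forcing data
 * (daily step function) via mosq_initforc().
 *
 * Parameter slots (always 12, unused slots ignored by the base model):
 *  0 beta   eggs laid per female per day
 *  1 dE     mean duration of early-instar stage (days)
 *  2 dL     mean duration of late-instar stage (days)
 *  3 dP     mean duration of pupal stage (days)
 *  4 muE0   low-density early-instar mortality (1/day)
 *  5 muL0   low-density late-instar mortality (1/day)
 *  6 muP    pupal mortality (1/day)
 *  7 muM    adult mortality (1/day)
 *  8 gamma  relative density-dependence on late instars
 *  9 fem    female fraction of emerging adults
 * 10 xtra   larvicide mortality factor upsilon, or pupacide efficacy F_PPF
 * 11 cov    fraction of breeding sites treated
 */
#include <R.h>

static double parms[12];
static double forc[1];

#define beta_  parms[0]
#define dE_    parms[1]
#define dL_    parms[2]
#define dP_    parms[3]
#define muE0_  parms[4]
#define muL0_  parms[5]
#define muP_   parms[6]
#define muM_   parms[7]
#define gam_   parms[8]
#define fem_   parms[9]
#define xtra_  parms[10]
#define cov_   parms[11]
#define K_     forc[0]

void mosq_initmod(void (*odeparms)(int *, double *))
{
    int n = 12;
    odeparms(&n, parms);
}

void mosq_initforc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forc);
}

/* density factor (E+L)/K, guarded so an empty compartment with a zero
 * share of K contributes nothing rather than 0/0 */
static double dens(double E, double L, double K)
{
    double tot = E + L;
    if (tot <= 0.0) return 0.0;
    if (K < 1e-300) K = 1e-300;
    return tot / K;
}

/* Base model: y = (E, L, P, M) */
void mosq_base(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double x = dens(y[0], y[1], K_);
    double muE = muE0_ * (1.0 + x);
    double muL = muL0_ * (1.0 + gam_ * x);

    ydot[0] = beta_ * y[3] - y[0] / dE_ - muE * y[0];
    ydot[1] = y[0] / dE_ - y[1] / dL_ - muL * y[1];
    ydot[2] = y[1] / dL_ - y[2] / dP_ - muP_ * y[2];
    ydot[3] = fem_ * y[2] / dP_ - muM_ * y[3];
}

/* Larvicide (BTI): y = (E, L, P, E_T, L_T, P_T, M).
 * A fraction cov of breeding sites is treated; oviposition splits
 * cov : (1-cov) and each compartment sees its share of K. Treated
 * background aquatic mortalities are multiplied by upsilon. */
void mosq_bti(int *neq, double *t, double *y, double *ydot,
              double *yout, int *ip)
{
    double Ku = (1.0 - cov_) * K_, Kt = cov_ * K_;
    double ups = xtra_;

    double xu = dens(y[0], y[1], Ku);
    double muEu = muE0_ * (1.0 + xu);
    double muLu = muL0_ * (1.0 + gam_ * xu);

    double xt = dens(y[3], y[4], Kt);
    double muEt = ups * muE0_ * (1.0 + xt);
    double muLt = ups * muL0_ * (1.0 + gam_ * xt);

    ydot[0] = (1.0 - cov_) * beta_ * y[6] - y[0] / dE_ - muEu * y[0];
    ydot[1] = y[0] / dE_ - y[1] / dL_ - muLu * y[1];
    ydot[2] = y[1] / dL_ - y[2] / dP_ - muP_ * y[2];

    ydot[3] = cov_ * beta_ * y[6] - y[3] / dE_ - muEt * y[3];
    ydot[4] = y[3] / dE_ - y[4] / dL_ - muLt * y[4];
    ydot[5] = y[4] / dL_ - y[5] / dP_ - ups * muP_ * y[5];

    ydot[6] = fem_ * (y[2] + y[5]) / dP_ - muM_ * y[6];
}

/* Pupacide (PPF): y = (E, L, P, E_T, L_T, P_T, M).
 * Treated-site larvae develop and compete normally but only a fraction
 * (1 - F_PPF) of their pupae emerge as adults. */
void mosq_ppf(int *neq, double *t, double *y, double *ydot,
              double *yout, int *ip)
{
    double Ku = (1.0 - cov_) * K_, Kt = cov_ * K_;
    double Fppf = xtra_;

    double xu = dens(y[0], y[1], Ku);
    double muEu = muE0_ * (1.0 + xu);
    double muLu = muL0_ * (1.0 + gam_ * xu);

    double xt = dens(y[3], y[4], Kt);
    double muEt = muE0_ * (1.0 + xt);
    double muLt = muL0_ * (1.0 + gam_ * xt);

    ydot[0] = (1.0 - cov_) * beta_ * y[6] - y[0] / dE_ - muEu * y[0];
    ydot[1] = y[0] / dE_ - y[1] / dL_ - muLu * y[1];
    ydot[2] = y[1] / dL_ - y[2] / dP_ - muP_ * y[2];

    ydot[3] = cov_ * beta_ * y[6] - y[3] / dE_ - muEt * y[3];
    ydot[4] = y[3] / dE_ - y[4] / dL_ - muLt * y[4];
    ydot[5] = y[4] / dL_ - y[5] / dP_ - muP_ * y[5];

    ydot[6] = fem_ * (y[2] + (1.0 - Fppf) * y[5]) / dP_ - muM_ * y[6];
}

/* Constant-emergence comparator: y = (M); emergence rate in slot 0. */
void mosq_const_emerge(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    ydot[0] = parms[0] - muM_ * y[0];
}
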