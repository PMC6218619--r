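/* Compiled right-hand side of the three-compartment left-heart model for
 * deSolve. Mirrors the reference R implementation in R/system.R; the two are
 * cross-checked in the test suite at random states.
 *
 * States y[0..8]:
 *   0 V_la   left-atrial volume (mL)
 *   1 V_lv   left-ventricular volume (mL)
 *   2 Q_pv   pulmonary-venous inflow to the LA (mL/s)
 *   3 Q_mv   mitral valve flow state (mL/s, regularized; clamped >= 0 in use)
 *   4 Q_av   aortic valve flow state (mL/s, regularized; clamped >= 0 in use)
 *   5 Q_aa   ascending-aortic segment flow (mL/s)
 *   6 V_cpv  volume in pulmonary-venous compliance (mL)
 *   7 V_caa  volume in ascending-aortic compliance (mL)
 *   8 V_cwk  volume in Windkessel compliance (mL)
 *
 * Extra outputs yout[0..9]:
 *   P_la, P_lv, P_aa, P_wk, E_la, E_lv, Q_mv+, Q_av+, Q_in (source), Q_out (R_p)
 */

#include <R.h>
#include <math.h>

static double parms[44];

#define P_T        parms[0]
/* chamber blocks: Emax, Emin, Rc, Rr, aS, aD, Vo, onset, K, Pext, alpha */
#define LA_OFF     1
#define LV_OFF     12
#define P_B_MV     parms[23]
#define P_M_MV     parms[24]
#define P_B_AV     parms[25]
#define P_M_AV     parms[26]
#define P_RCL      parms[27]
#define P_W        parms[28]
#define P_QW       parms[29]
#define P_PV_PSRC  parms[30]
#define P_PV_R     parms[31]
#define P_PV_RV    parms[32]
#define P_PV_C     parms[33]
#define P_PV_L     parms[34]
#define P_PV_V0    parms[35]
#define P_AO_R     parms[36]
#define P_AO_RV    parms[37]
#define P_AO_C     parms[38]
#define P_AO_L     parms[39]
#define P_WK_RP    parms[40]
#define P_WK_C     parms[41]
#define P_WK_RV    parms[42]
#define P_WK_POUT  parms[43]

void cardio_init(void (*odeparms)(int *, double *))
{
    int n = 44;
    odeparms(&n, parms);
}

/* Double-Hill elastance, bounded rational evaluation (no overflow for large
 * exponents: the Hill factors are computed in log space). */
static double double_hill(double t, const double *cp, double T)
{
    double Emax = cp[0], Emin = cp[1], Rc = cp[2], Rr = cp[3];
    double aS = cp[4], aD = cp[5], onset = cp[7], alpha = cp[10];
    double tt, x, y, h1, h2, e1, e2;

    tt = fmod(t - onset, T);
    if (tt < 0.0) tt += T;
    if (tt <= 0.0) return Emin;

    x = tt / (aS * T);
    y = tt / (aD * T);
    e1 = -Rc * log(x);           /* h1 = 1 / (1 + x^-Rc) */
    if (e1 > 700.0) e1 = 700.0;
    h1 = 1.0 / (1.0 + exp(e1));
    e2 = Rr * log(y);            /* h2 = 1 / (1 + y^Rr) */
    if (e2 > 700.0) e2 = 700.0;
    h2 = 1.0 / (1.0 + exp(e2));

    return alpha * (Emax - Emin) * h1 * h2 + Emin;
}

/* Smoothed diode: 1 when (dP > 0 or Q > 0), 0 when closed. */
static double valve_open(double dP, double Q, double w, double qw)
{
    double sp = 0.5 * (1.0 + tanh(dP / w));
    if (Q <= 0.0) return sp;
    return 1.0 - (1.0 - sp) * (1.0 - tanh(Q / qw));
}

void cardio_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double V_la = y[0], V_lv = y[1], Q_pv = y[2], Q_mv = y[3], Q_av = y[4];
    double Q_aa = y[5], V_cpv = y[6], V_caa = y[7], V_cwk = y[8];
    double Qmvp = Q_mv > 0.0 ? Q_mv : 0.0;
    double Qavp = Q_av > 0.0 ? Q_av : 0.0;
    double E_la, E_lv, P_la, P_lv, P_n, P_aa, P_wk, x_wk, Q_src, Q_rp;
    double dP_mv, dP_av, s_mv, s_av;

    if (*neq < 9) error("cardio_derivs: expected 9 states");

    E_la = double_hill(*t, parms + LA_OFF, P_T);
    E_lv = double_hill(*t, parms + LV_OFF, P_T);

    /* chamber pressures: elastance + viscous wall damping + external */
    P_la = E_la * (V_la - parms[LA_OFF + 6])
         + parms[LA_OFF + 8] * (Q_pv - Qmvp) + parms[LA_OFF + 9];
    P_lv = E_lv * (V_lv - parms[LV_OFF + 6])
         + parms[LV_OFF + 8] * (Qmvp - Qavp) + parms[LV_OFF + 9];

    /* pulmonary venous: source -> R -> viscoelastic node -> L -> LA */
    P_n = ((V_cpv - P_PV_V0) / P_PV_C
           + P_PV_RV * (P_PV_PSRC / P_PV_R - Q_pv))
        / (1.0 + P_PV_RV / P_PV_R);
    Q_src = (P_PV_PSRC - P_n) / P_PV_R;

    /* ascending aorta: viscoelastic node fed by AV, then R-L to Windkessel */
    P_aa = V_caa / P_AO_C + P_AO_RV * (Qavp - Q_aa);

    /* three-element viscoelastic Windkessel */
    x_wk = (Q_aa - (V_cwk / P_WK_C - P_WK_POUT) / P_WK_RP)
         / (1.0 + P_WK_RV / P_WK_RP);
    P_wk = V_cwk / P_WK_C + P_WK_RV * x_wk;
    Q_rp = (P_wk - P_WK_POUT) / P_WK_RP;

    /* valves */
    dP_mv = P_la - P_lv;
    dP_av = P_lv - P_aa;
    s_mv = valve_open(dP_mv, Q_mv, P_W, P_QW);
    s_av = valve_open(dP_av, Q_av, P_W, P_QW);

    ydot[0] = Q_pv - Qmvp;                               /* V_la  */
    ydot[1] = Qmvp - Qavp;                               /* V_lv  */
    ydot[2] = (P_n - P_la) / P_PV_L;                     /* Q_pv  */
    ydot[3] = (s_mv * dP_mv - P_B_MV * Qmvp * Qmvp
               - (1.0 - s_mv) * P_RCL * Q_mv) / P_M_MV;  /* Q_mv  */
    ydot[4] = (s_av * dP_av - P_B_AV * Qavp * Qavp
               - (1.0 - s_av) * P_RCL * Q_av) / P_M_AV;  /* Q_av  */
    ydot[5] = (P_aa - P_wk - P_AO_R * Q_aa) / P_AO_L;    /* Q_aa  */
    ydot[6] = Q_src - Q_pv;                              /* V_cpv */
    ydot[7] = Qavp - Q_aa;                               /* V_caa */
    ydot[8] = x_wk;                                      /* V_cwk */

    if (ip[0] >= 10) {
        yout[0] = P_la;
        yout[1] = P_lv;
        yout[2] = P_aa;
        yout[3] = P_wk;
        yout[4] = E_la;
        yout[5] = E_lv;
        yout[6] = Qmvp;
        yout[7] = Qavp;
        yout[8] = Q_src;
        yout[9] = Q_rp;
    }
}
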