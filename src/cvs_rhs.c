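/* Right-hand side of the closed-loop lumped-parameter cardiovascular
 * system model, in the form deSolve expects from compiled models.
 *
 * Units: volume m^3, pressure MPa, time s, flow m^3/s,
 *        resistance MPa.s/m^3, compliance m^3/MPa, elastance MPa/m^3.
 *
 * State vector (17 compartment volumes):
 *   0 q_RA   1 q_RV   2 q_LA   3 q_LV
 *   4 q_par  5 q_pvn  6 q_AO   7 q_CER
 *   8..14 terminal bed volumes: LE, BR, AC, EC, MC, PC, TR
 *   15 q_vub 16 q_vlb
 *
 * Parameter vector layout must match cvs_model_parm_vector() on the R side.
 */
#include <R.h>
#include <math.h>

#define N_PARMS 61
static double parms[N_PARMS];

/* parameter indices */
#define P_T        0
#define P_KVALVE   1
/* chambers: E_A, E_B, q_un, onset (fraction of T), duration (fraction of T) */
#define P_LV       2
#define P_RV       7
#define P_LA      12
#define P_RA      17
#define P_RTRV    22
#define P_RPUV    23
#define P_RMIV    24
#define P_RAOV    25
#define P_CPAR    26
#define P_RPAR    27
#define P_CPVN    28
#define P_RPVN    29
#define P_CAO     30
#define P_CCER    31
#define P_RSEGCER 32
#define P_RSEGBR  33
#define P_RSEGLE  34
#define P_RSEGTR  35
#define P_TERM    36  /* 7 x (R_T, C_T, R_V): LE, BR, AC, EC, MC, PC, TR */
#define P_CVUB    57
#define P_CVLB    58
#define P_RSVC    59
#define P_RIVC    60

void cvs_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

/* smooth one-way (diode) valve: softplus ramp of the pressure drop */
static double valve_flow(double dp, double R, double k)
{
    double x = k * dp;
    double q;
    if (x > 30.0)
        q = dp;
    else
        q = log1p(exp(x)) / k;
    return q / R;
}

/* smooth periodic activation in [0,1]; onset/duration as fractions of T */
static double activation(double t, double T, double onset, double dur)
{
    double phase = fmod(t, T);
    double w = phase - onset * T;
    if (w < 0.0) w += T;
    double durT = dur * T;
    if (w >= durT) return 0.0;
    double s = sin(M_PI * w / durT);
    return s * s;
}

static double chamber_pressure(double t, double T, double q, const double *cp)
{
    /* cp: E_A, E_B, q_un, onset, duration */
    double e = activation(t, T, cp[3], cp[4]);
    double E = (cp[0] - cp[1]) * e + cp[1];
    return E * (q - cp[2]);
}

void cvs_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double T = parms[P_T];
    const double k = parms[P_KVALVE];
    double tt = *t;

    double p_ra = chamber_pressure(tt, T, y[0], parms + P_RA);
    double p_rv = chamber_pressure(tt, T, y[1], parms + P_RV);
    double p_la = chamber_pressure(tt, T, y[2], parms + P_LA);
    double p_lv = chamber_pressure(tt, T, y[3], parms + P_LV);

    double p_par = y[4] / parms[P_CPAR];
    double p_pvn = y[5] / parms[P_CPVN];
    double p_ao  = y[6] / parms[P_CAO];
    double p_cer = y[7] / parms[P_CCER];
    double p_vub = y[15] / parms[P_CVUB];
    double p_vlb = y[16] / parms[P_CVLB];

    double v_trv = valve_flow(p_ra - p_rv, parms[P_RTRV], k);
    double v_puv = valve_flow(p_rv - p_par, parms[P_RPUV], k);
    double v_par = (p_par - p_pvn) / parms[P_RPAR];
    double v_pvn = (p_pvn - p_la) / parms[P_RPVN];
    double v_miv = valve_flow(p_la - p_lv, parms[P_RMIV], k);
    double v_aov = valve_flow(p_lv - p_ao, parms[P_RAOV], k);

    double v_cer = (p_ao - p_cer) / parms[P_RSEGCER];

    /* terminal beds: inflow through (segment +) terminal resistance into the
       bed compliance, outflow through the venous return resistance */
    double v_in[7], v_out[7];
    /* upstream source pressure and extra series segment resistance */
    double p_src[7] = {p_ao, p_ao, p_cer, p_cer, p_cer, p_cer, p_ao};
    double r_seg[7] = {parms[P_RSEGLE], parms[P_RSEGBR],
                       0.0, 0.0, 0.0, 0.0, parms[P_RSEGTR]};
    /* venous target: 0 = upper body (vub), 1 = lower body (vlb) */
    int ven[7] = {1, 0, 0, 0, 0, 0, 1};

    int i;
    for (i = 0; i < 7; i++) {
        const double *tp = parms + P_TERM + 3 * i; /* R_T, C_T, R_V */
        double p_term = y[8 + i] / tp[1];
        v_in[i]  = (p_src[i] - p_term) / (r_seg[i] + tp[0]);
        v_out[i] = (p_term - (ven[i] ? p_vlb : p_vub)) / tp[2];
    }

    double v_svc = (p_vub - p_ra) / parms[P_RSVC];
    double v_ivc = (p_vlb - p_ra) / parms[P_RIVC];

    ydot[0] = v_svc + v_ivc - v_trv;           /* RA */
    ydot[1] = v_trv - v_puv;                   /* RV */
    ydot[2] = v_pvn - v_miv;                   /* LA */
    ydot[3] = v_miv - v_aov;                   /* LV */
    ydot[4] = v_puv - v_par;                   /* pulmonary artery */
    ydot[5] = v_par - v_pvn;                   /* pulmonary vein */
    ydot[6] = v_aov - v_cer - v_in[0] - v_in[1] - v_in[6]; /* aortic root */
    ydot[7] = v_cer - v_in[2] - v_in[3] - v_in[4] - v_in[5]; /* cerebral */
    for (i = 0; i < 7; i++)
        ydot[8 + i] = v_in[i] - v_out[i];
    ydot[15] = v_out[1] + v_out[2] + v_out[3] + v_out[4] + v_out[5] - v_svc;
    ydot[16] = v_out[0] + v_out[6] - v_ivc;
}
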