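/* Compiled right-hand side of the reduced QSP immuno-oncology model.
 * Parameter and state ordering must match .qsp_param_names and
 * .qsp_state_names in R/parameters.R; the R reference implementation
 * (.qsp_rhs_r) is the readable form and the two are cross-checked in
 * the test suite. */

#include <R.h>
#include <math.h>

#define NPAR 65
static double p[NPAR];

/* parameter indices */
#define k_growth   p[0]
#define C_max      p[1]
#define k_kill     p[5]
#define K_kill     p[6]
#define K_treg     p[7]
#define pdl1_syn   p[8]
#define pdl2_syn   p[9]
#define K_pd       p[10]
#define k_exh      p[11]
#define K_rec      p[12]
#define k_T_in     p[13]
#define k_T_death  p[14]
#define k_c_death  p[15]
#define k_ln_out   p[16]
#define k_ln_death p[17]
#define A_pool     p[18]
#define k_apc_mat  p[19]
#define K_cyt      p[20]
#define k_apc_mig  p[21]
#define k_apc_death p[22]
#define k_apcln_death p[23]
#define k_pr8      p[24]
#define k_pr4      p[25]
#define k_prR      p[26]
#define K_TCC      p[27]
#define K_ag       p[28]
#define w4         p[29]
#define K4         p[30]
#define M_pool     p[31]
#define k_m1_rec   p[32]
#define k_m2_rec   p[33]
#define k_m12      p[34]
#define k_m_death  p[35]
#define k_cyt_prod p[36]
#define k_cyt_kill p[37]
#define K_kflux    p[38]
#define k_cyt_deg  p[39]
#define k_shed     p[40]
#define w_m2       p[41]
#define k_p_deg    p[42]
#define Kd_ab      p[44]
#define k_off_ab   p[45]
#define k_cl       p[46]
#define k_b_int    p[47]
#define k_mask     p[48]
#define k_cvg      p[50]
#define Kd_neo     p[51]
#define TCC        p[52]
#define V_C        p[54]
#define V_P        p[55]
#define V_T        p[56]
#define V_LN       p[57]
#define Q_T        p[58]
#define Q_P        p[59]
#define Q_LN       p[60]
#define sig_T      p[61]
#define sig_P      p[62]
#define sig_LN     p[63]
#define u_open     p[64]

void qspvct_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

static inline double nz(double x) { return x > 0.0 ? x : 0.0; }

void qspvct_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double C = nz(y[0]), T8 = nz(y[1]), T4 = nz(y[2]), Tr = nz(y[3]);
    double APC = nz(y[4]), M1 = nz(y[5]), M2 = nz(y[6]), Cyt = nz(y[7]);
    double APC_LN = nz(y[8]), T8_LN = nz(y[9]), T4_LN = nz(y[10]),
           Tr_LN = nz(y[11]);
    double T8_C = nz(y[12]), T4_C = nz(y[13]), Tr_C = nz(y[14]);
    double P = nz(y[15]);
    double Am_T = nz(y[16]), Ao_T = nz(y[17]), Ac_T = nz(y[18]);
    double Bo_T = nz(y[19]), Bc_T = nz(y[20]);
    double Am_C = nz(y[21]), Ao_C = nz(y[22]), Ac_C = nz(y[23]);
    double Am_P = nz(y[24]), Ao_P = nz(y[25]), Ac_P = nz(y[26]);
    double Am_L = nz(y[27]), Ao_L = nz(y[28]), Ac_L = nz(y[29]);

    double fC = C / (C + K_rec);
    double Btot = Bo_T + Bc_T;
    double theta = (P + Btot > 0.0) ? Btot / (P + Btot) : 0.0;
    double L = pdl1_syn * (1.0 - theta) + pdl2_syn;
    double H = L / (L + K_pd);

    double kill = k_kill * T8 * C / (C + K_kill) * (1.0 - H) /
        (1.0 + Tr / K_treg);
    double dC = k_growth * C * (1.0 - C / C_max) - kill;

    double infl8 = k_T_in * T8_C * fC;
    double infl4 = k_T_in * T4_C * fC;
    double inflR = k_T_in * Tr_C * fC;
    double dT8 = infl8 - k_T_death * T8 - k_exh * T8 * H * fC;
    double dT4 = infl4 - k_T_death * T4;
    double dTr = inflR - k_T_death * Tr;

    double sCyt = Cyt / (Cyt + K_cyt);
    double dAPC = k_apc_mat * A_pool * sCyt -
        (k_apc_mig + k_apc_death) * APC;
    double dM1 = k_m1_rec * M_pool * sCyt - k_m12 * M1 * fC -
        k_m_death * M1;
    double dM2 = k_m2_rec * M_pool * fC + k_m12 * M1 * fC -
        k_m_death * M2;
    double dCyt = k_cyt_prod * fC + k_cyt_kill * kill / (kill + K_kflux) -
        k_cyt_deg * Cyt;

    double ag = (TCC / (TCC + K_TCC)) * (K_ag / (K_ag + Kd_neo));
    double help4 = 1.0 + w4 * T4_LN / (T4_LN + K4);
    double k_out = k_ln_out + k_ln_death;
    double dAPC_LN = k_apc_mig * APC - k_apcln_death * APC_LN;
    double dT8_LN = k_pr8 * APC_LN * ag * help4 - k_out * T8_LN;
    double dT4_LN = k_pr4 * APC_LN * ag - k_out * T4_LN;
    double dTr_LN = k_prR * APC_LN - k_out * Tr_LN;

    double dT8_C = k_ln_out * T8_LN - k_c_death * T8_C - infl8;
    double dT4_C = k_ln_out * T4_LN - k_c_death * T4_C - infl4;
    double dTr_C = k_ln_out * Tr_LN - k_c_death * Tr_C - inflR;

    double k_on = k_off_ab / Kd_ab;
    double bind_o = k_on * Ao_T * P;
    double bind_c = k_on * Ac_T * P;
    double dP = k_shed * (C + w_m2 * M2) - k_p_deg * P -
        bind_o - bind_c + k_off_ab * Btot;

    double dBo = bind_o - (k_off_ab + k_cvg + k_b_int) * Bo_T;
    double dBc = bind_c + k_cvg * Bo_T - (k_off_ab + k_b_int) * Bc_T;

    double ko = k_mask * u_open;
    double kc = k_mask * (1.0 - u_open);

    double fl_m_T = Q_T * (sig_T * Am_C - Am_T);
    double fl_o_T = Q_T * (sig_T * Ao_C - Ao_T);
    double fl_c_T = Q_T * (sig_T * Ac_C - Ac_T);
    double fl_m_P = Q_P * (sig_P * Am_C - Am_P);
    double fl_o_P = Q_P * (sig_P * Ao_C - Ao_P);
    double fl_c_P = Q_P * (sig_P * Ac_C - Ac_P);
    double fl_m_L = Q_LN * (sig_LN * Am_C - Am_L);
    double fl_o_L = Q_LN * (sig_LN * Ao_C - Ao_L);
    double fl_c_L = Q_LN * (sig_LN * Ac_C - Ac_L);

    double ex_T = ko * Am_T - kc * Ao_T;
    double ex_C = ko * Am_C - kc * Ao_C;
    double ex_P = ko * Am_P - kc * Ao_P;
    double ex_L = ko * Am_L - kc * Ao_L;

    ydot[0] = dC;      ydot[1] = dT8;    ydot[2] = dT4;   ydot[3] = dTr;
    ydot[4] = dAPC;    ydot[5] = dM1;    ydot[6] = dM2;   ydot[7] = dCyt;
    ydot[8] = dAPC_LN; ydot[9] = dT8_LN; ydot[10] = dT4_LN;
    ydot[11] = dTr_LN;
    ydot[12] = dT8_C;  ydot[13] = dT4_C; ydot[14] = dTr_C;
    ydot[15] = dP;

    ydot[16] = fl_m_T / V_T - ex_T - k_cvg * Am_T;
    ydot[17] = fl_o_T / V_T + ex_T - k_cvg * Ao_T - bind_o +
        k_off_ab * Bo_T;
    ydot[18] = fl_c_T / V_T + k_cvg * (Am_T + Ao_T) - bind_c +
        k_off_ab * Bc_T;
    ydot[19] = dBo;
    ydot[20] = dBc;

    ydot[21] = -k_cl * Am_C - ex_C - (fl_m_T + fl_m_P + fl_m_L) / V_C;
    ydot[22] = -k_cl * Ao_C + ex_C - (fl_o_T + fl_o_P + fl_o_L) / V_C;
    ydot[23] = -k_cl * Ac_C - (fl_c_T + fl_c_P + fl_c_L) / V_C;

    ydot[24] = fl_m_P / V_P - ex_P;
    ydot[25] = fl_o_P / V_P + ex_P;
    ydot[26] = fl_c_P / V_P;

    ydot[27] = fl_m_L / V_LN - ex_L;
    ydot[28] = fl_o_L / V_LN + ex_L;
    ydot[29] = fl_c_L / V_LN;

    ydot[30] = k_cvg * (Am_T + Ao_T + Bo_T) * V_T;
}
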