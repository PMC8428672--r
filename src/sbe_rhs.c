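/* Right-hand side of the human-snake SBE model in the deSolve
 * compiled-model idiom.  State (18): S_U, S_E, I, T_E, T_L, V_E, V_L,
 * R_D, R_W, N_S, D, then seven cumulative-flow trackers C_inc, C_TE,
 * C_TL, C_VE, C_VL, C_RD, C_RW.
 *
 * parms (25): the 22 model parameters in canonical order, then u1, u2
 * and a variant flag (0 = constant-control system where delta_2 acts on
 * the late compartments unconditionally; 1 = time-dependent-control
 * system where late deaths carry a (1 - u2) factor).
 */
#include <R.h>
#include <R_ext/Rdynload.h>

#define N_PARMS 25
static double parms[N_PARMS];

#define Lambda_H parms[0]
#define Lambda_S parms[1]
#define mu_H     parms[2]
#define mu_S     parms[3]
#define beta     parms[4]
#define epsilon  parms[5]
#define theta    parms[6]
#define tau      parms[7]
#define kk       parms[8]
#define delta_1  parms[9]
#define delta_2  parms[10]
#define alpha_1  parms[11]
#define alpha_2  parms[12]
#define gamma_1  parms[13]
#define gamma_2  parms[14]
#define sigma_1  parms[15]
#define sigma_2  parms[16]
#define rho_1    parms[17]
#define rho_2    parms[18]
#define phi_1    parms[19]
#define phi_2    parms[20]
#define K_S      parms[21]
#define u1       parms[22]
#define u2       parms[23]
#define variant  parms[24]

void sbe_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void sbe_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    /* clip transient negative excursions (stiff-solver noise) to zero
     * when forming flows; large excursions are rejected in R. */
    double s[11];
    for (int i = 0; i < 11; i++)
        s[i] = y[i] > 0.0 ? y[i] : 0.0;

    double S_U = s[0], S_E = s[1], I = s[2], T_E = s[3], T_L = s[4],
           V_E = s[5], V_L = s[6], R_D = s[7], R_W = s[8], N_S = s[9];

    double N_H = S_U + S_E + I + T_E + T_L + V_E + V_L + R_D + R_W;
    double lam = (N_H + N_S) > 0.0 ? beta * N_S / (N_H + N_S) : 0.0;

    /* late-compartment death factor: delta_2 in the constant-control
     * system, (1 - u2) * delta_2 with time-dependent treatment */
    double d2 = (variant > 0.5) ? (1.0 - u2) * delta_2 : delta_2;

    double inc   = lam * ((1.0 - theta) * S_E + S_U);
    double to_TE = tau * u2 * kk * I;
    double to_TL = tau * u2 * (1.0 - kk) * I;
    double to_VE = alpha_1 * T_E;
    double to_VL = alpha_2 * T_L;
    double to_RD = sigma_1 * rho_1 * T_L + sigma_2 * rho_2 * V_L;
    double to_RW = gamma_1 * T_E + gamma_2 * V_E
                 + sigma_1 * (1.0 - rho_1) * T_L
                 + sigma_2 * (1.0 - rho_2) * V_L;

    ydot[0]  = Lambda_H - (lam + epsilon * u1 + mu_H) * S_U;
    ydot[1]  = epsilon * u1 * S_U + phi_1 * R_D + phi_2 * R_W
             - ((1.0 - theta) * lam + mu_H) * S_E;
    ydot[2]  = inc - (tau * u2 + delta_1 + mu_H) * I;
    ydot[3]  = to_TE - (alpha_1 + gamma_1 + mu_H) * T_E;
    ydot[4]  = to_TL - (alpha_2 + sigma_1 + d2 + mu_H) * T_L;
    ydot[5]  = to_VE - (gamma_2 + mu_H) * V_E;
    ydot[6]  = to_VL - (sigma_2 + d2 + mu_H) * V_L;
    ydot[7]  = to_RD - (phi_1 + mu_H) * R_D;
    ydot[8]  = to_RW - (phi_2 + mu_H) * R_W;
    ydot[9]  = Lambda_S * N_S * (1.0 - N_S / K_S) - mu_S * N_S;
    ydot[10] = delta_1 * I + (T_L + V_L) * d2;
    ydot[11] = inc;
    ydot[12] = to_TE;
    ydot[13] = to_TL;
    ydot[14] = to_VE;
    ydot[15] = to_VL;
    ydot[16] = to_RD;
    ydot[17] = to_RW;
}

static const R_CMethodDef cMethods[] = {
    {"sbe_initmod", (DL_FUNC) &sbe_initmod, 1},
    {"sbe_derivs",  (DL_FUNC) &sbe_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_sbecontrol(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
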