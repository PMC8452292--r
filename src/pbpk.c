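/* Reduced maternal-fetal PK model, compiled right-hand side for deSolve.
 *
 * States (mg): 0 depot_fast, 1 depot_slow, 2 a_maternal, 3 a_fetal,
 *              4 elim_maternal (cumulative), 5 elim_fetal (cumulative).
 * Parameters are passed per integration segment; zero-order infusion input
 * (in_rate, mg/h) is piecewise constant within a segment.
 */
#include <R.h>

static double parms[11];
#define KA_FAST   parms[0]
#define KA_SLOW   parms[1]
#define CL_TOTAL  parms[2]
#define CLPD_EFF  parms[3]
#define CL_PGP    parms[4]
#define FU_M      parms[5]
#define FU_F      parms[6]
#define V_M       parms[7]
#define V_F       parms[8]
#define CL_FETAL  parms[9]
#define IN_RATE   parms[10]

void pbpk_init(void (*odeparms)(int *, double *))
{
    int n = 11;
    odeparms(&n, parms);
}

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double abs_fast = KA_FAST * y[0];
    double abs_slow = KA_SLOW * y[1];
    double cm = y[2] / V_M;                       /* mg/L */
    double cf = y[3] / V_F;
    double mat_to_fet = CLPD_EFF * FU_M * cm;
    double fet_to_mat = (CLPD_EFF + CL_PGP) * FU_F * cf;

    ydot[0] = -abs_fast;
    ydot[1] = -abs_slow;
    ydot[2] = abs_fast + abs_slow + IN_RATE
              - CL_TOTAL * cm - mat_to_fet + fet_to_mat;
    ydot[3] = mat_to_fet - fet_to_mat - CL_FETAL * cf;
    ydot[4] = CL_TOTAL * cm;
    ydot[5] = CL_FETAL * cf;
}
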