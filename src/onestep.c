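/* Compiled right-hand side of the one-step (directly labelled vector)
 * compartment model, used by the parameter-fitting hot path via deSolve.
 *
 * States: y[0] = Vb (blood), y[1] = Tb (tumor-bound), y[2] = K (kidney),
 *         y[3] = X (cumulative excretion), amounts in nmol.
 * Parameters (in order): k_ren, f_kid, k_kid_rel, k_on, B_max, k_off, A0.
 */
#include <R.h>
#include <math.h>

static double parms[7];
#define k_ren     parms[0]
#define f_kid     parms[1]
#define k_kid_rel parms[2]
#define k_on      parms[3]
#define B_max     parms[4]
#define k_off     parms[5]

void onestep_init(void (*odeparms)(int *, double *))
{
    int n = 7;
    odeparms(&n, parms);
}

void onestep_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double free_sites = B_max - y[1];
    if (free_sites < 0.0) free_sites = 0.0;
    double bind = k_on * y[0] * free_sites;

    ydot[0] = -k_ren * y[0] - bind + k_off * y[1];
    ydot[1] = bind - k_off * y[1];
    ydot[2] = f_kid * k_ren * y[0] - k_kid_rel * y[2];
    ydot[3] = (1.0 - f_kid) * k_ren * y[0] + k_kid_rel * y[2];
}
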