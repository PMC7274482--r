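/* Lotka-Volterra competition with added mortality, deSolve compiled model.
 *
 *   dN_i/dt = N_i * ( r_i * (1 - sum_j alpha_ij N_j) - delta )
 *
 * with alpha_ii = 1 so that each species' self term is included in the sum.
 * Parameters arrive as a fixed-width block so one initializer serves any
 * community size up to LV_NMAX:
 *
 *   parms = [ n, delta, r_1..r_NMAX, alpha (row-major, NMAX x NMAX) ]
 */
#include <R.h>

#define LV_NMAX 8
#define LV_PLEN (2 + LV_NMAX + LV_NMAX * LV_NMAX)

static double parms[LV_PLEN];

void lv_init(void (*odeparms)(int *, double *))
{
    int N = LV_PLEN;
    odeparms(&N, parms);
}

void lv_deriv(int *neq, double *t, double *y, double *ydot,
              double *yout, int *ip)
{
    int n = (int) parms[0];
    double delta = parms[1];
    const double *r = parms + 2;
    const double *a = parms + 2 + LV_NMAX;
    int i, j;

    for (i = 0; i < n; i++) {
        double s = 0.0;
        for (j = 0; j < n; j++)
            s += a[i * LV_NMAX + j] * y[j];
        ydot[i] = y[i] * (r[i] * (1.0 - s) - delta);
    }
}
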