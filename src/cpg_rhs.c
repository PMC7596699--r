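/* Right-hand side of the 4-unit half-center network for deSolve's
   compiled-model interface.  Parameter vector layout (length 78):
     [ 14 unit params x 4 units | Eex Einh | d[4] | b[16] column-major ]
   Unit param order: C gL EL gNaP ENa VmNaP kmNaP VhNaP khNaP
                     tauNaPmax VtauNaP ktauNaP Vmin Vmax
   b is indexed [source, target] like the R-side matrix. */
#include <R.h>
#include <math.h>

#define NPAR 78
static double parms[NPAR];

void cpg_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, parms);
}

void cpg_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double *V = y, *h = y + 4;
    const double Eex = parms[56], Einh = parms[57];
    const double *d = parms + 58, *b = parms + 62;
    double f[4];
    int i, j;

    for (j = 0; j < 4; j++) {
        const double *p = parms + 14 * j;
        double vmin = p[12], vmax = p[13];
        f[j] = V[j] <= vmin ? 0.0 :
               (V[j] >= vmax ? 1.0 : (V[j] - vmin) / (vmax - vmin));
    }
    for (i = 0; i < 4; i++) {
        const double *p = parms + 14 * i;
        double minf = 1.0 / (1.0 + exp((V[i] - p[5]) / p[6]));
        double hinf = 1.0 / (1.0 + exp((V[i] - p[7]) / p[8]));
        double tau  = p[9] / cosh((V[i] - p[10]) / p[11]);
        double syn  = 0.0;
        for (j = 0; j < 4; j++)
            syn += b[j + 4 * i] * f[j];
        {
            double IL   = p[1] * (V[i] - p[2]);
            double INaP = p[3] * minf * h[i] * (V[i] - p[4]);
            double Isyn = d[i] * (V[i] - Eex) + syn * (V[i] - Einh);
            ydot[i]     = -(IL + INaP + Isyn) / p[0];
            ydot[4 + i] = (hinf - h[i]) / tau;
        }
    }
}
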