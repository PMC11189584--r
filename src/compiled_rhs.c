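/* Compiled right-hand sides for the two built-in models, in the standard
 * deSolve C-model form (initfunc copies the packed parameter vector, derivs
 * evaluates ydot). The state is node-major: y[(i-1)*n + comp].
 *
 * The parameter vector is packed on the R side (see pack_compiled_parms())
 * and zero-padded to PARMS_CAP, the fixed length requested here. Node
 * indices inside the packing are 1-based and stored as doubles.
 *
 * Lotka-Volterra packing:
 *   [0] N, [1..N] r, [N+1..2N] k,
 *   [2N+1] n1, then n1 triples (i, j, w)      -- dx_i += w * x_i * x_j
 *   [...]  n2, then n2 quadruples (i, j, k, w) -- dx_i += w * x_i * x_j * x_k
 *
 * Rossler packing:
 *   [0] N, [1] a, [2] b, [3] c, [4] sigma1, [5] sigma2,
 *   [6] n1, then n1 triples (i, j, w)          -- dx_i += s1 * w * (x_j - x_i)
 *   [...] n2, then n2 quadruples (i, j, k, w)
 *        -- dx_i += s2 * w * (x_j^2 x_k + x_j x_k^2 - 2 x_i^3)
 */
#include <R.h>

#define PARMS_CAP 25000

static double lv_p[PARMS_CAP];
static double ro_p[PARMS_CAP];

void hordyn_lv_init(void (*odeparms)(int *, double *))
{
    int n = PARMS_CAP;
    odeparms(&n, lv_p);
}

void hordyn_lv_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    const double *p = lv_p;
    int N = (int) p[0];
    const double *r = p + 1;
    const double *k = p + 1 + N;
    long pos = 1 + 2 * N;
    int m, e;

    for (m = 0; m < N; m++)
        ydot[m] = r[m] * y[m] * (1.0 - y[m] / k[m]);

    int n1 = (int) p[pos++];
    for (e = 0; e < n1; e++) {
        int i = (int) p[pos++] - 1;
        int j = (int) p[pos++] - 1;
        double w = p[pos++];
        ydot[i] += w * y[i] * y[j];
    }
    int n2 = (int) p[pos++];
    for (e = 0; e < n2; e++) {
        int i = (int) p[pos++] - 1;
        int j = (int) p[pos++] - 1;
        int kk = (int) p[pos++] - 1;
        double w = p[pos++];
        ydot[i] += w * y[i] * y[j] * y[kk];
    }
}

void hordyn_rossler_init(void (*odeparms)(int *, double *))
{
    int n = PARMS_CAP;
    odeparms(&n, ro_p);
}

void hordyn_rossler_derivs(int *neq, double *t, double *y, double *ydot,
                           double *yout, int *ip)
{
    const double *p = ro_p;
    int N = (int) p[0];
    double a = p[1], b = p[2], c = p[3], s1 = p[4], s2 = p[5];
    long pos = 6;
    int m, e;

    for (m = 0; m < N; m++) {
        double x = y[3 * m], yv = y[3 * m + 1], z = y[3 * m + 2];
        ydot[3 * m]     = -yv - z;
        ydot[3 * m + 1] = x + a * yv;
        ydot[3 * m + 2] = b + z * (x - c);
    }
    int n1 = (int) p[pos++];
    for (e = 0; e < n1; e++) {
        int i = (int) p[pos++] - 1;
        int j = (int) p[pos++] - 1;
        double w = p[pos++];
        ydot[3 * i] += s1 * w * (y[3 * j] - y[3 * i]);
    }
    int n2 = (int) p[pos++];
    for (e = 0; e < n2; e++) {
        int i = (int) p[pos++] - 1;
        int j = (int) p[pos++] - 1;
        int kk = (int) p[pos++] - 1;
        double w = p[pos++];
        double xj = y[3 * j], xk = y[3 * kk], xi = y[3 * i];
        ydot[3 * i] += s2 * w * (xj * xj * xk + xj * xk * xk
                                 - 2.0 * xi * xi * xi);
    }
}
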