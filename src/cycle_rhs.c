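/* Right-hand side and Jacobian of the multi-state catalytic-cycle ODE
 * system, in the form expected by deSolve's compiled-model interface.
 *
 * The network is linear (first-order exchange, hydrolysis and product
 * release edges, encoded in a dense generator A) except for bimolecular
 * association of free ligand into the binding-competent conformations,
 * encoded as triples (iE, iES, c): flux = c * y[iS] * y[iE] feeding
 * y[iES] and draining y[iE] and y[iS].
 *
 * deSolve's odeparms handshake requires the parameter length to be known
 * here, so the R wrapper always pads the vector to CYCLE_PARMS_LEN.
 * Layout (doubles, 0-based indices):
 *   [0]            n        number of states (n <= CYCLE_MAX_N)
 *   [1]            iS       index of the free-ligand state
 *   [2]            nb       number of association triples
 *   [3 .. 3+n*n-1] A        dense n x n matrix, column-major; dy = A y
 *   then nb triples (iE, iES, c); remainder padding.
 */

#include <R.h>

#define CYCLE_MAX_N 96
#define CYCLE_PARMS_LEN (3 + CYCLE_MAX_N * CYCLE_MAX_N + 3 * CYCLE_MAX_N)

static double parms_vec[CYCLE_PARMS_LEN];

void cycle_init(void (*odeparms)(int *, double *))
{
    int len = CYCLE_PARMS_LEN;
    odeparms(&len, parms_vec);
}

void cycle_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    const int n = (int) parms_vec[0];
    const int iS = (int) parms_vec[1];
    const int nb = (int) parms_vec[2];
    const double *A = parms_vec + 3;
    const double *tri = parms_vec + 3 + n * n;

    for (int i = 0; i < n; i++) ydot[i] = 0.0;
    for (int j = 0; j < n; j++) {
        const double yj = y[j];
        if (yj != 0.0) {
            const double *col = A + (size_t) j * n;
            for (int i = 0; i < n; i++) ydot[i] += col[i] * yj;
        }
    }
    const double S = y[iS];
    for (int b = 0; b < nb; b++) {
        const int iE  = (int) tri[3 * b];
        const int iES = (int) tri[3 * b + 1];
        const double f = tri[3 * b + 2] * S * y[iE];
        ydot[iES] += f;
        ydot[iE]  -= f;
        ydot[iS]  -= f;
    }
}

void cycle_jac(int *neq, double *t, double *y, int *ml, int *mu,
               double *pd, int *nrowpd, double *yout, int *ip)
{
    const int n = (int) parms_vec[0];
    const int iS = (int) parms_vec[1];
    const int nb = (int) parms_vec[2];
    const double *A = parms_vec + 3;
    const double *tri = parms_vec + 3 + n * n;
    const int nr = *nrowpd;

    for (int j = 0; j < n; j++)
        for (int i = 0; i < n; i++)
            pd[i + (size_t) j * nr] = A[i + (size_t) j * n];

    const double S = y[iS];
    for (int b = 0; b < nb; b++) {
        const int iE  = (int) tri[3 * b];
        const int iES = (int) tri[3 * b + 1];
        const double c = tri[3 * b + 2];
        /* d f / d y[iE] = c * S */
        pd[iES + (size_t) iE * nr] += c * S;
        pd[iE  + (size_t) iE * nr] -= c * S;
        pd[iS  + (size_t) iE * nr] -= c * S;
        /* d f / d y[iS] = c * y[iE] */
        pd[iES + (size_t) iS * nr] += c * y[iE];
        pd[iE  + (size_t) iS * nr] -= c * y[iE];
        pd[iS  + (size_t) iS * nr] -= c * y[iE];
    }
}
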