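/* Generic mass-action ODE right-hand side for deSolve's compiled interface.
 *
 * The network structure and rate constants are packed by the R side into a
 * single numeric `parms` vector (padded to MA_PARMS_LEN, see pack_ode_parms):
 *
 *   [0] n_species
 *   [1] n_reactions
 *   [2] nnz (stoichiometry non-zeros)
 *   [3 .. 3+nr-1]                rate constants k_r
 *   [.. + 3*nr]                  up to 3 one-based species factor indices per
 *                                reaction (0 = unused slot); the rate is
 *                                k_r * prod over factors of y[idx]
 *   [.. + 3*nnz]                 stoichiometry triplets (i, j, v)
 *
 * Rates use max(y, 0) so that tiny negative excursions of the stiff solver
 * cannot produce negative fluxes.
 */

#include <R.h>
#include <R_ext/Rdynload.h>

#define MA_PARMS_LEN 4096

static double ma_p[MA_PARMS_LEN];

void hgfdyn_initmod(void (*odeparms)(int *, double *))
{
    int n = MA_PARMS_LEN;
    odeparms(&n, ma_p);
}

void hgfdyn_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const int ns = (int) ma_p[0];
    const int nr = (int) ma_p[1];
    const int nnz = (int) ma_p[2];
    const double *k = ma_p + 3;
    const double *fac = ma_p + 3 + nr;
    const double *tri = ma_p + 3 + nr + 3 * nr;
    double rate[512];
    int r, m;

    for (r = 0; r < nr; r++) {
        double v = k[r];
        for (m = 0; m < 3; m++) {
            int idx = (int) fac[3 * r + m];
            if (idx > 0) {
                double x = y[idx - 1];
                v *= (x > 0.0) ? x : 0.0;
            }
        }
        rate[r] = v;
    }
    for (r = 0; r < ns; r++)
        ydot[r] = 0.0;
    for (m = 0; m < nnz; m++) {
        int i = (int) tri[3 * m];     /* one-based species   */
        int j = (int) tri[3 * m + 1]; /* one-based reaction  */
        double v = tri[3 * m + 2];
        ydot[i - 1] += v * rate[j - 1];
    }
}

static const R_CMethodDef cMethods[] = {
    {"hgfdyn_initmod", (DL_FUNC) &hgfdyn_initmod, 1},
    {"hgfdyn_derivs",  (DL_FUNC) &hgfdyn_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_hgfdyn(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
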