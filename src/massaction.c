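#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

/* Generic mass-action ODE right-hand side for deSolve's compiled-model
 * interface.  One static parameter block holds the mechanism, packed by
 * the R side and padded to MA_PARLEN:
 *
 *   [0] ns_dyn   number of integrated species
 *   [1] ns_tot   total species incl. constant-concentration ones
 *   [2] nr       number of reactions
 *   [3 .. 3+nc-1]              constant-species concentrations (nc = ns_tot - ns_dyn)
 *   [.. + nr]                  rate constants k_j
 *   [.. + nr*ns_tot]           reactant orders, reaction-major
 *   [.. + nr*ns_dyn]           stoichiometric changes, reaction-major
 *
 * Concentrations are clamped at zero inside the rate law so that tiny
 * negative solver excursions cannot produce negative rates.
 */

#define MA_PARLEN 4096
#define MA_MAXSPEC 64
static double ma_parms[MA_PARLEN];

void massaction_init(void (*odeparms)(int *, double *))
{
    int N = MA_PARLEN;
    odeparms(&N, ma_parms);
}

void massaction_derivs(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    const int ns_dyn = (int) ma_parms[0];
    const int ns_tot = (int) ma_parms[1];
    const int nr     = (int) ma_parms[2];
    const int nc     = ns_tot - ns_dyn;
    const double *cconst = ma_parms + 3;
    const double *k      = cconst + nc;
    const double *ord    = k + nr;
    const double *sto    = ord + (size_t) nr * ns_tot;
    double conc[MA_MAXSPEC];
    int j, s;

    for (s = 0; s < ns_dyn; s++) conc[s] = y[s] > 0 ? y[s] : 0.0;
    for (s = 0; s < nc; s++)     conc[ns_dyn + s] = cconst[s];
    for (s = 0; s < ns_dyn; s++) ydot[s] = 0.0;

    for (j = 0; j < nr; j++) {
        double rate = k[j];
        const double *oj = ord + (size_t) j * ns_tot;
        for (s = 0; s < ns_tot; s++) {
            double o = oj[s];
            if (o == 0.0) continue;
            if (o == 1.0)      rate *= conc[s];
            else if (o == 2.0) rate *= conc[s] * conc[s];
            else               rate *= pow(conc[s], o);
        }
        if (rate != 0.0) {
            const double *sj = sto + (size_t) j * ns_dyn;
            for (s = 0; s < ns_dyn; s++) ydot[s] += sj[s] * rate;
        }
    }
}

static const R_CMethodDef CEntries[] = {
    {"massaction_init",   (DL_FUNC) &massaction_init,   1},
    {"massaction_derivs", (DL_FUNC) &massaction_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_ibuopt(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
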