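#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_tp06_rhs(SEXP ys, SEXP ps);
void tp06_initmod(void (*odeparms)(int *, double *));
void tp06_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip);

static const R_CallMethodDef callMethods[] = {
    {"C_tp06_rhs", (DL_FUNC) &C_tp06_rhs, 2},
    {NULL, NULL, 0}
};

void R_init_mtp06(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, TRUE);  /* deSolve looks up tp06_* by name */
}
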