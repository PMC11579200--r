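#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void qspvct_initmod(void (*odeparms)(int *, double *));
void qspvct_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {NULL, NULL, 0}
};

void R_init_qspvct(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    /* deSolve looks the model functions up by name */
    R_useDynamicSymbols(dll, TRUE);
}
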