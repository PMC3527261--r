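#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP tfode_lin_recurse(SEXP, SEXP);
extern SEXP tfode_lin_recurse_mat(SEXP, SEXP);

static const R_CallMethodDef callMethods[] = {
    {"tfode_lin_recurse",     (DL_FUNC) &tfode_lin_recurse,     2},
    {"tfode_lin_recurse_mat", (DL_FUNC) &tfode_lin_recurse_mat, 2},
    {NULL, NULL, 0}
};

void R_init_tfode(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
    R_forceSymbols(info, TRUE);
}
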