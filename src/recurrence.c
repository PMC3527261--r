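/* First-order linear recurrences used by the explicit ODE solutions:
 *   y[0] = z[0];  y[k] = z[k] + alpha * y[k-1]
 * evaluated for a single series or column-wise for a matrix with a
 * per-column coefficient (one gene per column). */

#include <R.h>
#include <Rinternals.h>

SEXP tfode_lin_recurse(SEXP z, SEXP alpha)
{
    R_xlen_t n = XLENGTH(z);
    SEXP out = PROTECT(allocVector(REALSXP, n));
    double *zp = REAL(z), *yp = REAL(out);
    double a = asReal(alpha), acc = 0.0;
    for (R_xlen_t k = 0; k < n; k++) {
        acc = zp[k] + a * acc;
        yp[k] = acc;
    }
    UNPROTECT(1);
    return out;
}

SEXP tfode_lin_recurse_mat(SEXP z, SEXP alpha)
{
    SEXP dim = getAttrib(z, R_DimSymbol);
    int n = INTEGER(dim)[0], m = INTEGER(dim)[1];
    SEXP out = PROTECT(allocMatrix(REALSXP, n, m));
    double *zp = REAL(z), *yp = REAL(out), *ap = REAL(alpha);
    for (int j = 0; j < m; j++) {
        double a = ap[j], acc = 0.0;
        double *zc = zp + (R_xlen_t) j * n, *yc = yp + (R_xlen_t) j * n;
        for (int k = 0; k < n; k++) {
            acc = zc[k] + a * acc;
            yc[k] = acc;
        }
    }
    UNPROTECT(1);
    return out;
}
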