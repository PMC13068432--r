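/* Compiled kernels: ODE right-hand sides for the GEF-Rho-GAP circuit
 * (full and GAP quasi-steady-state variants) called through deSolve, and
 * a bootstrap percentile CI of the per-timepoint median used by the
 * ensemble aggregator. */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

/* Parameter vector layout (16 slots, passed from R):
 *  0 k_on_larg   1 k_off_larg
 *  2 v_on_gap    3 km_gap      4 k_off_gap
 *  5 v_on_rho    6 km_on_rho   7 v_off_rho   8 km_off_rho
 *  9 variant: 0 = WT, 1 = KO, 2 = QSS-WT, 3 = QSS-KO
 * 10 t_start    11 light_duration  12 amplitude
 * 13 input shape: 0 = boxcar, 1 = exponential decay
 * 14 decay_rate 15 (reserved)
 *
 * QSS variants eliminate the fast GAP state: the deactivation flux uses
 * gap = v_on_gap/k_off_gap * rho/(km_gap+rho) (QSS-WT) or the constant
 * v_on_gap/k_off_gap (QSS-KO). Callers fold lumped constants into the
 * same slots. */

static double pp[16];

void rhoflux_init(void (*odeparms)(int *, double *))
{
    int n = 16;
    odeparms(&n, pp);
}

static double gef_input(double t)
{
    double t_start = pp[10], dur = pp[11], amp = pp[12];
    if (pp[13] < 0.5) {
        return (t >= t_start && t < t_start + dur) ? amp : 0.0;
    }
    return (t >= t_start) ? amp * exp(-pp[14] * (t - t_start)) : 0.0;
}

void rhoflux_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double larg = y[0];
    int variant = (int) (pp[9] + 0.5);

    ydot[0] = pp[0] * gef_input(*t) - pp[1] * larg;

    if (variant <= 1) {
        double gap = y[1], rho = y[2];
        ydot[1] = (variant == 0)
            ? pp[2] * rho / (pp[3] + rho) - pp[4] * gap
            : pp[2] - pp[4] * gap;
        ydot[2] = pp[5] * larg / (pp[6] + larg)
            - pp[7] * gap * rho / (pp[8] + rho);
    } else {
        double rho = y[2];
        double gap = (variant == 2)
            ? pp[2] / pp[4] * rho / (pp[3] + rho)
            : pp[2] / pp[4];
        ydot[1] = 0.0;
        ydot[2] = pp[5] * larg / (pp[6] + larg)
            - pp[7] * gap * rho / (pp[8] + rho);
    }
}

/* ---- bootstrap CI of the median --------------------------------------- */

/* Hoare quickselect: k-th smallest (0-based) of x[0..n-1], in place. */
static double qselect(double *x, int n, int k)
{
    int lo = 0, hi = n - 1;
    while (lo < hi) {
        double pivot = x[k];
        int i = lo, j = hi;
        do {
            while (x[i] < pivot) i++;
            while (x[j] > pivot) j--;
            if (i <= j) {
                double tmp = x[i]; x[i] = x[j]; x[j] = tmp;
                i++; j--;
            }
        } while (i <= j);
        if (j < k) lo = i;
        if (k < i) hi = j;
    }
    return x[k];
}

static double median_inplace(double *x, int n)
{
    if (n % 2 == 1)
        return qselect(x, n, n / 2);
    double hi = qselect(x, n, n / 2);
    /* after selecting n/2, positions 0..n/2-1 hold the lower half */
    double lo = x[0];
    for (int i = 1; i < n / 2; i++)
        if (x[i] > lo) lo = x[i];
    return (lo + hi) / 2.0;
}

/* type-7 quantile of a sorted-in-place-by-selection vector */
static double quantile7(double *x, int n, double p)
{
    double h = (n - 1) * p;
    int k = (int) floor(h);
    if (k >= n - 1) return qselect(x, n, n - 1);
    double g = h - k;
    double xk1 = qselect(x, n, k + 1);
    double xk = x[0];
    for (int i = 1; i <= k; i++)
        if (x[i] > xk) xk = x[i];
    if (k == 0) xk = qselect(x, n, 0);
    return xk + g * (xk1 - xk);
}

/* traces: n_roi x n_time column-major matrix (already fold-change
 * normalised). Returns a 3 x n_time matrix: median, ci_low, ci_high.
 * Uses the R RNG so results follow set.seed(). */
SEXP C_aggregate_median_ci(SEXP traces, SEXP s_n_boot, SEXP s_ci_level)
{
    SEXP dim = getAttrib(traces, R_DimSymbol);
    int n_roi = INTEGER(dim)[0], n_time = INTEGER(dim)[1];
    int n_boot = asInteger(s_n_boot);
    double ci = asReal(s_ci_level);
    double alpha = (1.0 - ci) / 2.0;

    SEXP ans = PROTECT(allocMatrix(REALSXP, 3, n_time));
    double *x = REAL(traces), *out = REAL(ans);

    double *buf = (double *) R_alloc(n_roi, sizeof(double));
    double *boots = (double *) R_alloc((size_t) n_boot, sizeof(double));
    int *idx = (int *) R_alloc(n_roi, sizeof(int));

    /* point estimate: per-timepoint median over ROIs */
    for (int t = 0; t < n_time; t++) {
        for (int i = 0; i < n_roi; i++) buf[i] = x[i + (size_t) t * n_roi];
        out[3 * t] = median_inplace(buf, n_roi);
    }

    if (n_boot < 1) {
        for (int t = 0; t < n_time; t++) {
            out[3 * t + 1] = out[3 * t];
            out[3 * t + 2] = out[3 * t];
        }
        UNPROTECT(1);
        return ans;
    }

    GetRNGstate();
    /* resample ROIs jointly across timepoints (each bootstrap draw is a
     * resample of whole traces, not of single frames) */
    double *bootmat = (double *) R_alloc((size_t) n_boot * n_time,
                                         sizeof(double));
    for (int b = 0; b < n_boot; b++) {
        for (int i = 0; i < n_roi; i++) {
            int j = (int) (unif_rand() * n_roi);
            if (j == n_roi) j = n_roi - 1;
            idx[i] = j;
        }
        for (int t = 0; t < n_time; t++) {
            for (int i = 0; i < n_roi; i++)
                buf[i] = x[idx[i] + (size_t) t * n_roi];
            bootmat[b + (size_t) t * n_boot] = median_inplace(buf, n_roi);
        }
    }
    PutRNGstate();

    for (int t = 0; t < n_time; t++) {
        for (int b = 0; b < n_boot; b++)
            boots[b] = bootmat[b + (size_t) t * n_boot];
        out[3 * t + 1] = quantile7(boots, n_boot, alpha);
        for (int b = 0; b < n_boot; b++)
            boots[b] = bootmat[b + (size_t) t * n_boot];
        out[3 * t + 2] = quantile7(boots, n_boot, 1.0 - alpha);
    }

    UNPROTECT(1);
    return ans;
}

static const R_CallMethodDef call_entries[] = {
    {"C_aggregate_median_ci", (DL_FUNC) &C_aggregate_median_ci, 3},
    {NULL, NULL, 0}
};

void R_init_rhoflux(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE); /* deSolve looks up the RHS by name */
}
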