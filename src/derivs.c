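/* Compiled right-hand side of the scaled phage-communication model.
 *
 * State layout: y = (s, l[1..n], p[1..n], A), n = n_phi * n_theta
 * variants ordered with the propensity axis varying fastest.
 * Parameters are installed by set_phage_parms() before each solve:
 *   pv = (g, k, a_hat, B_eff, delta_hat, alpha_hat, u_hat,
 *         mu_phi, mu_theta, n_phi, n_theta, phi_max[n], theta[n])
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define MAX_VARIANTS 4096
#define PARMS_MAX (11 + 2 * MAX_VARIANTS)

static double parms_buf[PARMS_MAX];
static double work1[MAX_VARIANTS];
static double work2[MAX_VARIANTS];
static int parms_set = 0;

void set_phage_parms(double *pv, int *len, int *status)
{
    int i;
    *status = 1;
    if (*len > PARMS_MAX || *len < 13) return;
    for (i = 0; i < *len; i++) parms_buf[i] = pv[i];
    parms_set = 1;
    *status = 0;
}

/* one-axis nearest-neighbour mutation kernel on w (length n_axis,
 * stride `stride`, n_block blocks offset by block_off) */
static void mutate_axis(double *w, double *tmp, int n_axis, int stride,
                        int n_block, int block_off, double mu)
{
    int b, i;
    double half;
    if (n_axis <= 1 || mu == 0.0) return;
    for (b = 0; b < n_block; b++) {
        double *base = w + b * block_off;
        for (i = 0; i < n_axis; i++) tmp[i] = base[i * stride];
        for (i = 0; i < n_axis; i++) {
            double out = (1.0 - mu) * tmp[i];
            half = 0.5 * mu;
            if (i > 0) out += half * tmp[i - 1];
            else out += half * tmp[i];          /* boundary retention */
            if (i < n_axis - 1) out += half * tmp[i + 1];
            else out += half * tmp[i];          /* boundary retention */
            base[i * stride] = out;
        }
    }
}

void phage_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double g, k, a_hat, B_eff, delta_hat, alpha_hat, u_hat;
    double mu_phi, mu_theta;
    int n_phi, n_theta, n, i;
    double s, A, sum_l, sum_p, n_tot, growth, as;
    const double *phi_max, *theta;

    if (!parms_set)
        error("phage model parameters have not been installed");

    g = parms_buf[0]; k = parms_buf[1]; a_hat = parms_buf[2];
    B_eff = parms_buf[3]; delta_hat = parms_buf[4];
    alpha_hat = parms_buf[5]; u_hat = parms_buf[6];
    mu_phi = parms_buf[7]; mu_theta = parms_buf[8];
    n_phi = (int) parms_buf[9]; n_theta = (int) parms_buf[10];
    n = n_phi * n_theta;
    if (*neq != 2 * n + 2)
        error("state length inconsistent with installed parameters");
    phi_max = parms_buf + 11;
    theta = parms_buf + 11 + n;

    s = y[0];
    A = y[2 * n + 1];
    sum_l = 0.0; sum_p = 0.0;
    for (i = 0; i < n; i++) {
        sum_l += y[1 + i];
        sum_p += y[1 + n + i];
    }
    n_tot = s + sum_l;
    growth = g * (1.0 - n_tot / k);
    as = a_hat * s;

    ydot[0] = growth * s - as * sum_p;
    ydot[2 * n + 1] = as * sum_p - u_hat * n_tot * A;

    for (i = 0; i < n; i++) {
        double l = y[1 + i], p = y[1 + n + i];
        double phi = (A >= theta[i]) ? phi_max[i] : 0.0;
        double infect = as * p;
        ydot[1 + i] = growth * l + phi * infect - alpha_hat * l;
        work1[i] = B_eff * (alpha_hat * l + (1.0 - phi) * infect);
    }
    /* mutation: propensity axis (stride 1 within theta blocks), then
     * threshold axis (stride n_phi) */
    mutate_axis(work1, work2, n_phi, 1, n_theta, n_phi, mu_phi);
    mutate_axis(work1, work2, n_theta, n_phi, n_phi, 1, mu_theta);

    for (i = 0; i < n; i++) {
        double p = y[1 + n + i];
        ydot[1 + n + i] = work1[i] - delta_hat * p - a_hat * n_tot * p;
    }
}

static const R_CMethodDef cMethods[] = {
    {"set_phage_parms", (DL_FUNC) &set_phage_parms, 3},
    {"phage_derivs", (DL_FUNC) &phage_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_arbitrium(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
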