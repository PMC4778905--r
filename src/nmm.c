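/* Compiled right-hand sides for the neural mass model, in the form
 * expected by deSolve's compiled-model interface: plain state equations,
 * the forward-sensitivity-augmented system, and analytic Jacobians for
 * the implicit BDF solver.
 *
 * Parameter vector (see nmm_parms() on the R side):
 *   p[0]  regions (1 or 2)
 *   p[1]  backward connection present (0/1)
 *   p[2]  tau_e   p[3] tau_i   p[4] H_e   p[5] H_i
 *   p[6]  intrinsic delay d0
 *   p[7]  input_amp  p[8] input_peak  p[9] input_width  p[10] input_gain
 *   p[11..20] theta: a12 a21 d12 d21 g1 g2 g3 g4 r1 r2
 *
 * State layout per region (base b = 9*(r-1)):
 *   b+0 v_s  b+1 dv_s | b+2 v_pe b+3 dv_pe | b+4 v_pi b+5 dv_pi
 *   b+6 v_i  b+7 dv_i | b+8 v_p (= v_pe - v_pi, integrated directly)
 */

#include <R.h>
#include <math.h>

#define NPAR 21
#define NP 10
#define NXMAX 18

static double p[NPAR];

void nmm_init(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

static double sig(double x, double r1, double r2)
{
    return 1.0 / (1.0 + exp(-r1 * (x - r2))) - 1.0 / (1.0 + exp(r1 * r2));
}

static double sig_dx(double x, double r1, double r2)
{
    double s = 1.0 / (1.0 + exp(-r1 * (x - r2)));
    return r1 * s * (1.0 - s);
}

static void sig_dr(double x, double r1, double r2, double *d1, double *d2)
{
    double s = 1.0 / (1.0 + exp(-r1 * (x - r2)));
    double s0 = 1.0 / (1.0 + exp(r1 * r2));
    double ss = s * (1.0 - s), ss0 = s0 * (1.0 - s0);
    *d1 = (x - r2) * ss + r2 * ss0;
    *d2 = r1 * (ss0 - ss);
}

/* Core evaluation: f always; A (nx x nx, row-major) and B (nx x NP,
 * row-major, already chain-ruled to the unconstrained scale) if non-NULL */
static void nmm_core(double t, double *y, double *f, double *A, double *B)
{
    int nr = (int) p[0];
    int backward = (int) p[1];
    int nx = 9 * nr;
    double tau_e = p[2], tau_i = p[3], H_e = p[4], H_i = p[5];
    double d0 = p[6];
    double amp = p[7], peak = p[8], width = p[9], gu = p[10];
    const double *th = p + 11;
    double a12 = (nr == 2 && backward) ? th[0] : 0.0;
    double a21 = (nr == 2) ? th[1] : 0.0;
    double d12 = th[2], d21 = th[3];
    double g1 = th[4], g2 = th[5], g3 = th[6], g4 = th[7];
    double r1 = th[8], r2 = th[9];
    double ke = H_e / tau_e, ki = H_i / tau_i;
    double ae = 2.0 / tau_e, be = 1.0 / (tau_e * tau_e);
    double ai = 2.0 / tau_i, bi = 1.0 / (tau_i * tau_i);
    double u, vp1, vs1, vi1, vp2 = 0, vs2 = 0, vi2 = 0, c21 = 0, c12 = 0;
    int i, j;

    u = amp * exp(-(t - peak) * (t - peak) / (2.0 * width * width));
    vp1 = y[8] - d0 * (y[3] - y[5]);
    vs1 = y[0] - d0 * y[1];
    vi1 = y[6] - d0 * y[7];
    if (nr == 2) {
        vp2 = y[17] - d0 * (y[12] - y[14]);
        vs2 = y[9] - d0 * y[10];
        vi2 = y[15] - d0 * y[16];
        c21 = y[17] - d12 * (y[12] - y[14]);
        c12 = y[8] - d21 * (y[3] - y[5]);
    }

    f[0] = y[1];
    f[2] = y[3];
    f[4] = y[5];
    f[6] = y[7];
    f[1] = ke * (gu * sig(u, r1, r2) + g1 * sig(vp1, r1, r2))
        - ae * y[1] - be * y[0];
    f[3] = ke * (g2 * sig(vs1, r1, r2) + a12 * sig(c21, r1, r2))
        - ae * y[3] - be * y[2];
    f[5] = ki * g4 * sig(vi1, r1, r2) - ai * y[5] - bi * y[4];
    f[7] = ke * (g3 * sig(vp1, r1, r2) + a12 * sig(c21, r1, r2))
        - ae * y[7] - be * y[6];
    f[8] = y[3] - y[5];
    if (nr == 2) {
        f[9] = y[10];
        f[11] = y[12];
        f[13] = y[14];
        f[15] = y[16];
        f[10] = ke * (g1 * sig(vp2, r1, r2) + a21 * sig(c12, r1, r2))
            - ae * y[10] - be * y[9];
        f[12] = ke * g2 * sig(vs2, r1, r2) - ae * y[12] - be * y[11];
        f[14] = ki * g4 * sig(vi2, r1, r2) - ai * y[14] - bi * y[13];
        f[16] = ke * g3 * sig(vp2, r1, r2) - ae * y[16] - be * y[15];
        f[17] = y[12] - y[14];
    }

    if (A != NULL) {
        double spp1 = sig_dx(vp1, r1, r2), sps1 = sig_dx(vs1, r1, r2);
        double spi1 = sig_dx(vi1, r1, r2);
        for (i = 0; i < nx * nx; i++) A[i] = 0.0;
#define AA(i, j) A[(i) * nx + (j)]
        for (int r = 0; r < nr; r++) {
            int b = 9 * r;
            AA(b + 0, b + 1) = 1.0;
            AA(b + 2, b + 3) = 1.0;
            AA(b + 4, b + 5) = 1.0;
            AA(b + 6, b + 7) = 1.0;
            AA(b + 1, b + 0) -= be; AA(b + 1, b + 1) -= ae;
            AA(b + 3, b + 2) -= be; AA(b + 3, b + 3) -= ae;
            AA(b + 5, b + 4) -= bi; AA(b + 5, b + 5) -= ai;
            AA(b + 7, b + 6) -= be; AA(b + 7, b + 7) -= ae;
            AA(b + 8, b + 3) = 1.0;
            AA(b + 8, b + 5) = -1.0;
        }
        AA(1, 8) += ke * g1 * spp1;
        AA(1, 3) += ke * g1 * spp1 * (-d0);
        AA(1, 5) += ke * g1 * spp1 * d0;
        AA(7, 8) += ke * g3 * spp1;
        AA(7, 3) += ke * g3 * spp1 * (-d0);
        AA(7, 5) += ke * g3 * spp1 * d0;
        AA(3, 0) += ke * g2 * sps1;
        AA(3, 1) += ke * g2 * sps1 * (-d0);
        AA(5, 6) += ki * g4 * spi1;
        AA(5, 7) += ki * g4 * spi1 * (-d0);
        if (nr == 2) {
            double spp2 = sig_dx(vp2, r1, r2), sps2 = sig_dx(vs2, r1, r2);
            double spi2 = sig_dx(vi2, r1, r2);
            double spc21 = sig_dx(c21, r1, r2), spc12 = sig_dx(c12, r1, r2);
            AA(10, 17) += ke * g1 * spp2;
            AA(10, 12) += ke * g1 * spp2 * (-d0);
            AA(10, 14) += ke * g1 * spp2 * d0;
            AA(16, 17) += ke * g3 * spp2;
            AA(16, 12) += ke * g3 * spp2 * (-d0);
            AA(16, 14) += ke * g3 * spp2 * d0;
            AA(12, 9) += ke * g2 * sps2;
            AA(12, 10) += ke * g2 * sps2 * (-d0);
            AA(14, 15) += ki * g4 * spi2;
            AA(14, 16) += ki * g4 * spi2 * (-d0);
            AA(3, 17) += ke * a12 * spc21;
            AA(3, 12) += ke * a12 * spc21 * (-d12);
            AA(3, 14) += ke * a12 * spc21 * d12;
            AA(7, 17) += ke * a12 * spc21;
            AA(7, 12) += ke * a12 * spc21 * (-d12);
            AA(7, 14) += ke * a12 * spc21 * d12;
            AA(10, 8) += ke * a21 * spc12;
            AA(10, 3) += ke * a21 * spc12 * (-d21);
            AA(10, 5) += ke * a21 * spc12 * d21;
        }
#undef AA
    }

    if (B != NULL) {
        double du1, du2, dp1a, dp1b, ds1a, ds1b, di1a, di1b;
        for (i = 0; i < nx * NP; i++) B[i] = 0.0;
#define BB(i, k) B[(i) * NP + (k)]
        sig_dr(u, r1, r2, &du1, &du2);
        sig_dr(vp1, r1, r2, &dp1a, &dp1b);
        sig_dr(vs1, r1, r2, &ds1a, &ds1b);
        sig_dr(vi1, r1, r2, &di1a, &di1b);
        BB(1, 4) = ke * sig(vp1, r1, r2);
        BB(3, 5) = ke * sig(vs1, r1, r2);
        BB(7, 6) = ke * sig(vp1, r1, r2);
        BB(5, 7) = ki * sig(vi1, r1, r2);
        BB(1, 8) = ke * (gu * du1 + g1 * dp1a);
        BB(1, 9) = ke * (gu * du2 + g1 * dp1b);
        BB(3, 8) = ke * g2 * ds1a;
        BB(3, 9) = ke * g2 * ds1b;
        BB(5, 8) = ki * g4 * di1a;
        BB(5, 9) = ki * g4 * di1b;
        BB(7, 8) = ke * g3 * dp1a;
        BB(7, 9) = ke * g3 * dp1b;
        if (nr == 2) {
            double dp2a, dp2b, ds2a, ds2b, di2a, di2b;
            double dc21a, dc21b, dc12a, dc12b;
            double spc21 = sig_dx(c21, r1, r2), spc12 = sig_dx(c12, r1, r2);
            sig_dr(vp2, r1, r2, &dp2a, &dp2b);
            sig_dr(vs2, r1, r2, &ds2a, &ds2b);
            sig_dr(vi2, r1, r2, &di2a, &di2b);
            sig_dr(c21, r1, r2, &dc21a, &dc21b);
            sig_dr(c12, r1, r2, &dc12a, &dc12b);
            BB(10, 4) = ke * sig(vp2, r1, r2);
            BB(12, 5) = ke * sig(vs2, r1, r2);
            BB(16, 6) = ke * sig(vp2, r1, r2);
            BB(14, 7) = ki * sig(vi2, r1, r2);
            BB(10, 8) = ke * (g1 * dp2a + a21 * dc12a);
            BB(10, 9) = ke * (g1 * dp2b + a21 * dc12b);
            BB(12, 8) = ke * g2 * ds2a;
            BB(12, 9) = ke * g2 * ds2b;
            BB(14, 8) = ki * g4 * di2a;
            BB(14, 9) = ki * g4 * di2b;
            BB(16, 8) = ke * g3 * dp2a;
            BB(16, 9) = ke * g3 * dp2b;
            BB(10, 1) = ke * sig(c12, r1, r2);
            BB(10, 3) = -ke * a21 * spc12 * (y[3] - y[5]);
            if (backward) {
                BB(3, 0) = ke * sig(c21, r1, r2);
                BB(7, 0) = BB(3, 0);
                BB(3, 2) = -ke * a12 * spc21 * (y[12] - y[14]);
                BB(7, 2) = BB(3, 2);
                BB(3, 8) += ke * a12 * dc21a;
                BB(3, 9) += ke * a12 * dc21b;
                BB(7, 8) += ke * a12 * dc21a;
                BB(7, 9) += ke * a12 * dc21b;
            }
        }
        /* chain rule: theta_k = theta0_k exp(w_k) => dtheta_k/dw_k = theta_k */
        for (i = 0; i < nx; i++)
            for (j = 0; j < NP; j++)
                BB(i, j) *= th[j];
#undef BB
    }
}

/* plain state derivatives */
void nmm_deriv(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    nmm_core(*t, y, ydot, NULL, NULL);
}

/* full Jacobian of the plain system (pd column-major, nrowpd rows) */
void nmm_jac(int *neq, double *t, double *y, int *ml, int *mu,
             double *pd, int *nrowpd, double *yout, int *ip)
{
    double f[NXMAX], A[NXMAX * NXMAX];
    int nx = *neq, i, j;
    nmm_core(*t, y, f, A, NULL);
    for (j = 0; j < nx; j++)
        for (i = 0; i < nx; i++)
            pd[j * (*nrowpd) + i] = A[i * nx + j];
}

/* state + forward sensitivity derivatives: y = [x, S(:,1), ..., S(:,NP)] */
void nmm_sens(int *neq, double *t, double *y, double *ydot,
              double *yout, int *ip)
{
    double A[NXMAX * NXMAX], B[NXMAX * NP];
    int nx = *neq / (NP + 1), i, j, k;
    nmm_core(*t, y, ydot, A, B);
    for (k = 0; k < NP; k++) {
        double *S = y + nx * (k + 1);
        double *dS = ydot + nx * (k + 1);
        for (i = 0; i < nx; i++) {
            double acc = B[i * NP + k];
            const double *Ai = A + i * nx;
            for (j = 0; j < nx; j++)
                acc += Ai[j] * S[j];
            dS[i] = acc;
        }
    }
}

/* block-diagonal Jacobian approximation for the augmented system (exact up
 * to second-derivative coupling terms; affects only Newton convergence) */
void nmm_sens_jac(int *neq, double *t, double *y, int *ml, int *mu,
                  double *pd, int *nrowpd, double *yout, int *ip)
{
    double f[NXMAX], A[NXMAX * NXMAX];
    int n = *neq, nx = n / (NP + 1), i, j, k;
    nmm_core(*t, y, f, A, NULL);
    for (i = 0; i < n * (*nrowpd); i++) pd[i] = 0.0;
    for (k = 0; k <= NP; k++) {
        int b = k * nx;
        for (j = 0; j < nx; j++)
            for (i = 0; i < nx; i++)
                pd[(b + j) * (*nrowpd) + (b + i)] = A[i * nx + j];
    }
}
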