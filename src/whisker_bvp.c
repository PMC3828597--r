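/* Right-hand side of the whisker contact boundary-value problem, in the
 * shooting form used by deSolve.
 *
 * State (all SI units, angles in radians):
 *   y[0] = x(sigma)         position along the whisker
 *   y[1] = y(sigma)
 *   y[2] = theta(sigma)     tangent angle vs the x-axis
 *   y[3] = F                contact force magnitude     (constant unknown)
 *   y[4] = theta_obj        whisker angle at contact    (constant unknown)
 *   y[5] = s_obj            arclength base -> contact   (constant unknown)
 *
 * sigma = s / s_obj runs over [0, 1].  The last three derivatives are
 * identically zero: those states are the shooting unknowns.
 *
 * The bending rate combines the intrinsic curvature of the undeflected
 * parabola with the moment produced by a frictionless point force acting
 * normal to the whisker at the contact point on the pole circle.
 */

#include <R.h>
#include <math.h>

static double parms[10];
#define XCEN  parms[0]          /* pole centre x (m)                      */
#define YCEN  parms[1]          /* pole centre y (m)                      */
#define RPOLE parms[2]          /* pole radius (m)                        */
#define EMOD  parms[3]          /* Young's modulus (Pa)                   */
#define ACOEF parms[4]          /* parabola coefficient (1/m)             */
#define XVERT parms[5]          /* parabola vertex offset (m)             */
#define TAPER parms[6]          /* 1 conical, 0 cylindrical               */
#define LVIRT parms[7]          /* virtual full-cone length (m)           */
#define RBASE parms[8]          /* base radius (m)                        */
#define SIDE  parms[9]          /* +1: pole right of the tangent; -1: left */

void whisker_init(void (*odeparms)(int *, double *))
{
    int n = 10;
    odeparms(&n, parms);
}

/* Arclength of y = A (x - xv)^2 from local x = 0 to x (A > 0). */
static double parab_arclen(double x)
{
    double u0 = -2.0 * ACOEF * XVERT;
    double u1 = 2.0 * ACOEF * (x - XVERT);
    double S0 = u0 * sqrt(1.0 + u0 * u0) + asinh(u0);
    double S1 = u1 * sqrt(1.0 + u1 * u1) + asinh(u1);
    return (S1 - S0) / (4.0 * ACOEF);
}

/* Invert the arclength map by Newton iteration (ds/dx >= 1, monotone). */
static double parab_x_of_s(double s)
{
    double x = s, f, u;
    int i;
    for (i = 0; i < 100; i++) {
        u = 2.0 * ACOEF * (x - XVERT);
        f = parab_arclen(x) - s;
        x -= f / sqrt(1.0 + u * u);
        if (fabs(f) < 1e-15 + 1e-13 * fabs(s))
            break;
    }
    return x;
}

/* Signed intrinsic curvature at arclength s from the base. */
static double parab_kappa(double s)
{
    double x, u;
    if (fabs(ACOEF) < 1e-12)
        return 0.0;
    x = parab_x_of_s(s);
    u = 2.0 * ACOEF * (x - XVERT);
    return 2.0 * ACOEF / pow(1.0 + u * u, 1.5);
}

void whisker_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double F = y[3], th_obj = y[4], s_obj = y[5];
    double s = s_obj * (*t);
    double rw, I, mom, kap;

    if (TAPER > 0.5) {
        rw = RBASE * (LVIRT - s) / LVIRT;
        /* keep the stiffness finite just short of the virtual tip so the
           Newton iteration gets a rejectable (huge) residual instead of NaN */
        if (rw < 1e-6 * RBASE)
            rw = 1e-6 * RBASE;
    } else {
        rw = RBASE;
    }
    I = M_PI * rw * rw * rw * rw / 4.0;

    kap = parab_kappa(s);

    /* contact point and force direction both flip with the pole side */
    mom = (XCEN - SIDE * RPOLE * sin(th_obj) - y[0]) * cos(th_obj)
        + (YCEN + SIDE * RPOLE * cos(th_obj) - y[1]) * sin(th_obj);

    ydot[0] = s_obj * cos(y[2]);
    ydot[1] = s_obj * sin(y[2]);
    ydot[2] = s_obj * (kap + SIDE * F / (EMOD * I) * mom);
    ydot[3] = 0.0;
    ydot[4] = 0.0;
    ydot[5] = 0.0;
}
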