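#include <R.h>
#include <math.h>

/* Normal Pontryagin extremal flow on SIM(2), model case alpha = beta = 1.
 * State y = (x, y, theta, sigma, h1, h2, h3, h4).
 * Horizontal part: xdot = h1 e^sigma cos(theta), ydot = h1 e^sigma sin(theta),
 * thetadot = h3, sigmadot = h4.
 * Vertical part: h1dot = h3 h2 + h4 h1, h2dot = -h3 h1 + h4 h2,
 * h3dot = -h1 h2, h4dot = -h1^2.
 * Called through deSolve's compiled-model interface. */
void sim2_normal(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double th = y[2], sg = y[3];
    double h1 = y[4], h2 = y[5], h3 = y[6], h4 = y[7];
    double es = exp(sg);

    ydot[0] = h1 * es * cos(th);
    ydot[1] = h1 * es * sin(th);
    ydot[2] = h3;
    ydot[3] = h4;
    ydot[4] = h3 * h2 + h4 * h1;
    ydot[5] = -h3 * h1 + h4 * h2;
    ydot[6] = -h1 * h2;
    ydot[7] = -h1 * h1;
}

/* Vertical subsystem alone; state y = (h1, h2, h3, h4). */
void sim2_vertical(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double h1 = y[0], h2 = y[1], h3 = y[2], h4 = y[3];

    ydot[0] = h3 * h2 + h4 * h1;
    ydot[1] = -h3 * h1 + h4 * h2;
    ydot[2] = -h1 * h2;
    ydot[3] = -h1 * h1;
}
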