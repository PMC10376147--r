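/* Compiled rhs of the cultivation model for deSolve: glucose-partitioning
 * growth kinetics with overflow acetate production, acetate recycling,
 * maintenance, a respiratory capacity cap and the kLa oxygen balance.
 * Mirrors the R-level rate laws in R/kinetics.R (cross-checked by tests).
 */
#include <R.h>

static double p[18];
#define qSmax   p[0]
#define KS      p[1]
#define qApmax  p[2]
#define qAcmax  p[3]
#define qOmax   p[4]
#define qm0     p[5]
#define Yem     p[6]
#define Yox     p[7]
#define Yas     p[8]
#define Yxa     p[9]
#define KA      p[10]
#define KO      p[11]
#define cOm     p[12]
#define KIS     p[13]
#define dotconv p[14]   /* 100 / C_O2_star */
#define kla     p[15]
#define lagh    p[16]
#define sthr    p[17]   /* pulse trigger threshold, g/L */

void colibatch_init(void (*odeparms)(int *, double *))
{
    int n = 18;
    odeparms(&n, p);
}

void colibatch_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double X = y[0];
    double S = y[1] > 0 ? y[1] : 0;
    double A = y[2] > 0 ? y[2] : 0;
    double DOT = y[3] > 0 ? y[3] : 0;

    if (*t < lagh) { /* lag phase: no metabolic activity */
        ydot[0] = ydot[1] = ydot[2] = 0;
        ydot[3] = kla * (100 - y[3]);
        return;
    }

    double monod = S > 0 ? S / (S + KS) : 0;
    double qS = qSmax * monod;
    double qAp = qApmax * monod;
    double qAc = A > 0
        ? qAcmax * (A / (A + KA)) * (KIS / (KIS + S)) * (DOT / (DOT + KO))
        : 0;
    /* maintenance shuts off smoothly over a negligible glucose scale */
    double qm = qm0 * S / (S + 1e-4);

    double mu = (qS - qm - qAp / Yas) * Yem + qAc * Yxa;
    if (mu < 0) mu = 0;

    double qOd = (Yox * mu + cOm * qm) * (DOT / (DOT + KO));
    double qO;
    if (qOd > qOmax) { /* respiratory cap: shortfall spills into acetate */
        qO = qOmax;
        double mu2 = (qOmax - cOm * qm) / Yox;
        if (mu2 < 0) mu2 = 0;
        qAp += Yas * (mu - mu2) / Yem;
        mu = mu2;
    } else {
        qO = qOd;
    }

    ydot[0] = mu * X;
    ydot[1] = -qS * X;
    ydot[2] = (qAp - qAc) * X;
    ydot[3] = kla * (100 - y[3]) - qO * X * dotconv;
}

/* root: glucose crosses the pulse trigger threshold */
void colibatch_root(int *neq, double *t, double *y, int *ng,
                    double *gout, double *out, int *ip)
{
    gout[0] = y[1] - sthr;
}
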