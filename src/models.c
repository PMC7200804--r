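/* Compiled right-hand sides for the two tacrolimus models, called by
 * deSolve::lsoda.  Dose inputs are zero-order windows; the R side splits
 * the integration at every window boundary so each lsoda call sees a
 * smooth vector field.
 */
#include <R.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define MAXDOSE 40
#define PK_NP   (13 + 3 * MAXDOSE)
#define PBPK_NP (30 + 3 * MAXDOSE)

static double pk_p[PK_NP];
static double pbpk_p[PBPK_NP];

void chronotac_pk_init(void (*odeparms)(int *, double *))
{
    int n = PK_NP;
    odeparms(&n, pk_p);
}

void chronotac_pbpk_init(void (*odeparms)(int *, double *))
{
    int n = PBPK_NP;
    odeparms(&n, pbpk_p);
}

/* 24-h periodic waveform: 1 during the diurnal phase, r_chr during the
 * nocturnal phase, 2-h linear ramps between.  Phase offset tchr shifts
 * the diurnal onset. */
static double fw24(double t, double tchr, double rchr,
                   double t1, double t2, double t3, double t4)
{
    double u = fmod(t - tchr, 24.0);
    if (u < 0.0) u += 24.0;
    if (u < t1) return 1.0;
    if (u < t2) return 1.0 + (rchr - 1.0) * (u - t1) / (t2 - t1);
    if (u < t3) return rchr;
    if (u < t4) return rchr + (1.0 - rchr) * (u - t3) / (t4 - t3);
    return 1.0;
}

/* summed zero-order input rate (mg/h) of all dose windows active at t;
 * layout at p[off]: ndose, then (start, duration, rate) triples */
static double dose_rate(double t, const double *p, int off)
{
    int nd = (int) p[off];
    double rate = 0.0;
    for (int i = 0; i < nd; i++) {
        double start = p[off + 1 + 3 * i];
        double dur   = p[off + 2 + 3 * i];
        if (t >= start && t < start + dur)
            rate += p[off + 3 + 3 * i];
    }
    return rate;
}

/* PK/CAT3 parameters:
 *  0 kt  1 kta  2 Cl  3 Cld  4 Vc  5 Vp  6 rchr  7 tchr  8-11 t1..t4
 *  12.. dose block
 * states (mg):
 *  0 stomach 1 si1 2 si2 3 si3 4 colon 5 central 6 peripheral
 *  7 eliminated 8 absorbed 9 input
 */
void chronotac_pk_derivs(int *neq, double *t, double *y, double *ydot,
                         double *yout, int *ip)
{
    const double *p = pk_p;
    double fwv = fw24(*t, p[7], p[6], p[8], p[9], p[10], p[11]);
    double in  = dose_rate(*t, p, 12);
    double kt = p[0], kta = p[1] * fwv;
    double cc = y[5] / p[4], cp = y[6] / p[5];
    double absr = kta * (y[1] + y[2] + y[3]);
    double elim = p[2] * fwv * cc;

    ydot[0] = in - kt * y[0];
    ydot[1] = kt * y[0] - kt * y[1] - kta * y[1];
    ydot[2] = kt * y[1] - kt * y[2] - kta * y[2];
    ydot[3] = kt * y[2] - kt * y[3] - kta * y[3];
    ydot[4] = kt * y[3];
    ydot[5] = absr + p[3] * (cp - cc) - elim;
    ydot[6] = p[3] * (cc - cp);
    ydot[7] = elim;
    ydot[8] = absr;
    ydot[9] = in;
}

/* saturable RBC binding: whole blood = plasma + Hct * Bmax*Cp/(Kd+Cp) */
static double pl2bl(double cp, double hct, double bmax, double kd)
{
    return cp + hct * bmax * cp / (kd + cp);
}

/* invert pl2bl: plasma concentration given whole-blood concentration */
static double bl2pl(double cb, double hct, double bmax, double kd)
{
    double b, q;
    if (cb <= 0.0) return 0.0;
    b = kd + hct * bmax - cb;
    q = b * b + 4.0 * kd * cb;
    return 0.5 * (-b + sqrt(q));
}

/* PBPK parameters:
 *  0 Kabs  1 Kelib  2 ClintTot (Clih*Vl, L/h)  3 fup  4 Hct
 *  5 Bmax (mg/L)  6 Kd (mg/L)  7 Vb  8 rchr  9 tchr  10-13 t1..t4
 *  14-18 V gut,liver,kidney,fat,others  19-23 R (tissue:plasma)
 *  24-28 Q portal, hepatic artery, kidney, fat, others
 *  29.. dose block (liberation windows)
 * states (mg):
 *  0 lumen 1 gut 2 liver 3 kidney 4 fat 5 others 6 blood
 *  7 eliminated 8 lumen loss 9 absorbed 10 input
 */
void chronotac_pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                           double *yout, int *ip)
{
    const double *p = pbpk_p;
    double fwv = fw24(*t, p[9], p[8], p[10], p[11], p[12], p[13]);
    double lib = dose_rate(*t, p, 29);
    double hct = p[4], bmax = p[5], kd = p[6];
    double cb = y[6] / p[7];
    double cvg, cvl, cvk, cvf, cvo, cpvl, absr, elim, qlv;

    cpvl = (y[2] / p[15]) / p[20];
    cvg  = pl2bl((y[1] / p[14]) / p[19], hct, bmax, kd);
    cvl  = pl2bl(cpvl, hct, bmax, kd);
    cvk  = pl2bl((y[3] / p[16]) / p[21], hct, bmax, kd);
    cvf  = pl2bl((y[4] / p[17]) / p[22], hct, bmax, kd);
    cvo  = pl2bl((y[5] / p[18]) / p[23], hct, bmax, kd);

    absr = p[0] * fwv * y[0];
    elim = p[2] * fwv * p[3] * cpvl;
    qlv  = p[24] + p[25];

    ydot[0]  = lib - absr - p[1] * y[0];
    ydot[1]  = absr + p[24] * (cb - cvg);
    ydot[2]  = p[25] * cb + p[24] * cvg - qlv * cvl - elim;
    ydot[3]  = p[26] * (cb - cvk);
    ydot[4]  = p[27] * (cb - cvf);
    ydot[5]  = p[28] * (cb - cvo);
    ydot[6]  = qlv * cvl + p[26] * cvk + p[27] * cvf + p[28] * cvo
               - (qlv + p[26] + p[27] + p[28]) * cb;
    ydot[7]  = elim;
    ydot[8]  = p[1] * y[0];
    ydot[9]  = absr;
    ydot[10] = lib;
}

/* single-point helpers so R code and tests can evaluate the compiled
 * waveform and binding inversion directly */
void chronotac_fw_eval(double *t, double *tchr, double *rchr, double *bp,
                       double *out, int *n)
{
    for (int i = 0; i < *n; i++)
        out[i] = fw24(t[i], *tchr, *rchr, bp[0], bp[1], bp[2], bp[3]);
}

void chronotac_bl2pl_eval(double *cb, double *hct, double *bmax, double *kd,
                          double *out, int *n)
{
    for (int i = 0; i < *n; i++)
        out[i] = bl2pl(cb[i], *hct, *bmax, *kd);
}

static const R_CMethodDef cMethods[] = {
    {"chronotac_pk_init",     (DL_FUNC) &chronotac_pk_init,     1},
    {"chronotac_pbpk_init",   (DL_FUNC) &chronotac_pbpk_init,   1},
    {"chronotac_pk_derivs",   (DL_FUNC) &chronotac_pk_derivs,   6},
    {"chronotac_pbpk_derivs", (DL_FUNC) &chronotac_pbpk_derivs, 6},
    {"chronotac_fw_eval",     (DL_FUNC) &chronotac_fw_eval,     6},
    {"chronotac_bl2pl_eval",  (DL_FUNC) &chronotac_bl2pl_eval,  6},
    {NULL, NULL, 0}
};

void R_init_chronotac(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
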