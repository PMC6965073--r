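/* ten Tusscher-Panfilov 2006 human ventricular myocyte model, M-cell
 * parameterisation, with multiplicative scaling knobs and per-variable
 * freeze flags (used for K_i / Na_i fixing, voltage clamping and slow-fast
 * subsystem reduction).
 *
 * Units: ms, mV, mM, pA/pF.  State layout (0-based):
 *   0 V, 1 m, 2 h, 3 j, 4 d, 5 f, 6 f2, 7 fCass, 8 xr1, 9 xr2, 10 xs,
 *   11 r, 12 s, 13 Rbar, 14 Nai, 15 Ki, 16 Cai, 17 Cass, 18 CaSR
 */
#include <R.h>
#include <Rinternals.h>
#include <math.h>

#define N_STATE 19
#define N_PARMS 42
#define N_AUX   16

/* physical constants */
static const double Rgas = 8314.472;    /* mJ/(mol K) */
static const double Temp = 310.0;       /* K */
static const double Frdy = 96485.3415;  /* C/mol */
static const double Cmem = 0.185;       /* membrane capacitance factor */
static const double Vcyt = 0.016404;    /* cytoplasmic volume */
static const double Vsr  = 0.001094;    /* SR volume */
static const double Vss  = 0.00005468;  /* subspace volume */

/* fixed model constants not exposed as scaling knobs */
static const double KmK    = 1.0;
static const double KmNa   = 40.0;
static const double KmNai  = 87.5;
static const double KmCa   = 1.38;
static const double ksat   = 0.1;
static const double ncx_g  = 0.35;   /* NCX voltage-dependence gamma */
static const double ncx_a  = 2.5;    /* NCX alpha factor */
static const double KpCa   = 0.0005;
static const double pKNa   = 0.03;
static const double Kup    = 0.00025;
static const double k1p    = 0.15;
static const double k2p    = 0.045;
static const double k3     = 0.060;
static const double k4     = 0.005;
static const double ECsr   = 1.5;
static const double maxsr  = 2.5;
static const double minsr  = 1.0;
static const double Bufc   = 0.2;
static const double Kbufc  = 0.001;
static const double Bufsr  = 10.0;
static const double Kbufsr = 0.3;
static const double Bufss  = 0.4;
static const double Kbufss = 0.00025;

/* parameter vector layout (effective values, scalings already applied):
 *  0 gNa 1 gK1 2 gto 3 gKr 4 gKs 5 gCaL 6 gbNa 7 gbCa 8 gpK 9 gpCa
 * 10 PNaK 11 kNaCa 12 Vmaxup 13 Vrel 14 Vleak 15 Vxfer
 * 16 Ko 17 Nao 18 Cao 19 tauf_scale 20 tauf2_scale
 * 21 stim (pA/pF, depolarising positive) 22 stim_in_Ki flag
 * 23..41 freeze flags for state 0..18 (1 = derivative forced to 0)
 */
static double parms[N_PARMS];

void tp06_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

static void tp06_core(const double *p, const double *y,
                      double *dy, double *aux)
{
    const double V = y[0], m = y[1], h = y[2], j = y[3], d = y[4],
        f = y[5], f2 = y[6], fCass = y[7], xr1 = y[8], xr2 = y[9],
        xs = y[10], r = y[11], s = y[12], Rbar = y[13], Nai = y[14],
        Ki = y[15], Cai = y[16], Cass = y[17], CaSR = y[18];

    const double gNa = p[0], gK1 = p[1], gto = p[2], gKr = p[3], gKs = p[4],
        gCaL = p[5], gbNa = p[6], gbCa = p[7], gpK = p[8], gpCa = p[9],
        PNaK = p[10], kNaCa = p[11], Vmaxup = p[12], Vrel = p[13],
        Vleak = p[14], Vxfer = p[15], Ko = p[16], Nao = p[17], Cao = p[18],
        tauf_sc = p[19], tauf2_sc = p[20], stim = p[21], stim_Ki = p[22];

    const double RTF = Rgas * Temp / Frdy;
    const double EK  = RTF * log(Ko / Ki);
    const double ENa = RTF * log(Nao / Nai);
    const double EKs = RTF * log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
    const double ECa = 0.5 * RTF * log(Cao / Cai);

    /* fast Na+ current */
    const double INa = gNa * m * m * m * h * j * (V - ENa);

    /* L-type Ca2+ current (GHK-like driving term, V offset 15 mV) */
    const double vf = 2.0 * (V - 15.0) / RTF;
    double ICaL;
    if (fabs(vf) < 1e-7) {  /* removable singularity at V = 15 mV */
        ICaL = gCaL * d * f * f2 * fCass * 2.0 * Frdy *
            (0.25 * Cass - Cao) ;
    } else {
        ICaL = gCaL * d * f * f2 * fCass * 2.0 * Frdy * vf *
            (0.25 * Cass * exp(vf) - Cao) / (exp(vf) - 1.0);
    }

    /* delayed rectifiers, Ito, IK1, pumps, exchangers, backgrounds */
    const double IKr = gKr * sqrt(Ko / 5.4) * xr1 * xr2 * (V - EK);
    const double IKs = gKs * xs * xs * (V - EKs);
    const double Ito = gto * r * s * (V - EK);

    const double aK1 = 0.1 / (1.0 + exp(0.06 * (V - EK - 200.0)));
    const double bK1 = (3.0 * exp(0.0002 * (V - EK + 100.0)) +
                        exp(0.1 * (V - EK - 10.0))) /
                       (1.0 + exp(-0.5 * (V - EK)));
    const double IK1 = gK1 * sqrt(Ko / 5.4) * aK1 / (aK1 + bK1) * (V - EK);

    const double IpK = gpK * (V - EK) / (1.0 + exp((25.0 - V) / 5.98));
    const double IbNa = gbNa * (V - ENa);
    const double IbCa = gbCa * (V - ECa);
    const double IpCa = gpCa * Cai / (Cai + KpCa);

    const double INaK = PNaK * Ko * Nai /
        ((Ko + KmK) * (Nai + KmNa) *
         (1.0 + 0.1245 * exp(-0.1 * V / RTF) + 0.0353 * exp(-V / RTF)));

    const double eg  = exp(ncx_g * V / RTF);
    const double eg1 = exp((ncx_g - 1.0) * V / RTF);
    const double INCX = kNaCa *
        (eg * Nai * Nai * Nai * Cao - eg1 * Nao * Nao * Nao * Cai * ncx_a) /
        ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
         (1.0 + ksat * eg1));

    /* SR Ca2+ fluxes */
    const double kcasr = maxsr - (maxsr - minsr) /
        (1.0 + (ECsr / CaSR) * (ECsr / CaSR));
    const double k1 = k1p / kcasr;
    const double k2 = k2p * kcasr;
    const double Orel = k1 * Cass * Cass * Rbar / (k3 + k1 * Cass * Cass);
    const double Irel  = Vrel * Orel * (CaSR - Cass);
    const double Iup   = Vmaxup / (1.0 + Kup * Kup / (Cai * Cai));
    const double Ileak = Vleak * (CaSR - Cai);
    const double Ixfer = Vxfer * (Cass - Cai);

    /* gate kinetics */
    double v2, am, bm, ah, bh, aj, bj;
    const double minf = 1.0 / ((1.0 + exp((-56.86 - V) / 9.03)) *
                               (1.0 + exp((-56.86 - V) / 9.03)));
    am = 1.0 / (1.0 + exp((-60.0 - V) / 5.0));
    bm = 0.1 / (1.0 + exp((V + 35.0) / 5.0)) +
         0.1 / (1.0 + exp((V - 50.0) / 200.0));
    const double taum = am * bm;

    const double hinf = 1.0 / ((1.0 + exp((V + 71.55) / 7.43)) *
                               (1.0 + exp((V + 71.55) / 7.43)));
    if (V < -40.0) {
        ah = 0.057 * exp(-(V + 80.0) / 6.8);
        bh = 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V);
    } else {
        ah = 0.0;
        bh = 0.77 / (0.13 * (1.0 + exp(-(V + 10.66) / 11.1)));
    }
    const double tauh = 1.0 / (ah + bh);

    if (V < -40.0) {
        aj = (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
             (V + 37.78) / (1.0 + exp(0.311 * (V + 79.23)));
        bj = 0.02424 * exp(-0.01052 * V) /
             (1.0 + exp(-0.1378 * (V + 40.14)));
    } else {
        aj = 0.0;
        bj = 0.6 * exp(0.057 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
    }
    const double tauj = 1.0 / (aj + bj);

    const double dinf = 1.0 / (1.0 + exp((-8.0 - V) / 7.5));
    const double ad = 1.4 / (1.0 + exp((-35.0 - V) / 13.0)) + 0.25;
    const double bd = 1.4 / (1.0 + exp((V + 5.0) / 5.0));
    const double gd = 1.0 / (1.0 + exp((50.0 - V) / 20.0));
    const double taud = ad * bd + gd;

    const double finf = 1.0 / (1.0 + exp((V + 20.0) / 7.0));
    v2 = (V + 27.0) * (V + 27.0);
    double tauf = 1102.5 * exp(-v2 / 225.0) +
        200.0 / (1.0 + exp((13.0 - V) / 10.0)) +
        180.0 / (1.0 + exp((V + 30.0) / 10.0)) + 20.0;
    tauf *= tauf_sc;

    const double f2inf = 0.67 / (1.0 + exp((V + 35.0) / 7.0)) + 0.33;
    double tauf2 = 562.0 * exp(-v2 / 240.0) +
        31.0 / (1.0 + exp((25.0 - V) / 10.0)) +
        80.0 / (1.0 + exp((V + 30.0) / 10.0));
    tauf2 *= tauf2_sc;

    const double css2 = (Cass / 0.05) * (Cass / 0.05);
    const double fCinf = 0.6 / (1.0 + css2) + 0.4;
    const double taufC = 80.0 / (1.0 + css2) + 2.0;

    const double xr1inf = 1.0 / (1.0 + exp((-26.0 - V) / 7.0));
    const double axr1 = 450.0 / (1.0 + exp((-45.0 - V) / 10.0));
    const double bxr1 = 6.0 / (1.0 + exp((V + 30.0) / 11.5));
    const double tauxr1 = axr1 * bxr1;

    const double xr2inf = 1.0 / (1.0 + exp((V + 88.0) / 24.0));
    const double axr2 = 3.0 / (1.0 + exp((-60.0 - V) / 20.0));
    const double bxr2 = 1.12 / (1.0 + exp((V - 60.0) / 20.0));
    const double tauxr2 = axr2 * bxr2;

    const double xsinf = 1.0 / (1.0 + exp((-5.0 - V) / 14.0));
    const double axs = 1400.0 / sqrt(1.0 + exp((5.0 - V) / 6.0));
    const double bxs = 1.0 / (1.0 + exp((V - 35.0) / 15.0));
    const double tauxs = axs * bxs + 80.0;

    const double rinf = 1.0 / (1.0 + exp((20.0 - V) / 6.0));
    const double taur = 9.5 * exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;

    const double sinf = 1.0 / (1.0 + exp((V + 20.0) / 5.0));
    const double taus = 85.0 * exp(-(V + 45.0) * (V + 45.0) / 320.0) +
        5.0 / (1.0 + exp((V - 20.0) / 5.0)) + 3.0;

    /* derivatives */
    const double Isum = IK1 + Ito + IKr + IKs + ICaL + INaK + INa + IbNa +
        INCX + IbCa + IpK + IpCa;
    dy[0] = stim - Isum;
    dy[1] = (minf - m) / taum;
    dy[2] = (hinf - h) / tauh;
    dy[3] = (hinf - j) / tauj;  /* j shares its steady state with h */
    dy[4] = (dinf - d) / taud;
    dy[5] = (finf - f) / tauf;
    dy[6] = (f2inf - f2) / tauf2;
    dy[7] = (fCinf - fCass) / taufC;
    dy[8] = (xr1inf - xr1) / tauxr1;
    dy[9] = (xr2inf - xr2) / tauxr2;
    dy[10] = (xsinf - xs) / tauxs;
    dy[11] = (rinf - r) / taur;
    dy[12] = (sinf - s) / taus;
    dy[13] = -k2 * Cass * Rbar + k4 * (1.0 - Rbar);
    dy[14] = -(INa + IbNa + 3.0 * INaK + 3.0 * INCX) * Cmem / (Vcyt * Frdy);
    /* stimulus charge optionally carried by K+ (stim enters with -stim
     * because the depolarising stimulus is an inward cation flux) */
    dy[15] = -(IK1 + Ito + IKr + IKs + IpK - stim_Ki * stim - 2.0 * INaK) *
        Cmem / (Vcyt * Frdy);

    const double bufc = 1.0 /
        (1.0 + Bufc * Kbufc / ((Cai + Kbufc) * (Cai + Kbufc)));
    const double bufsr = 1.0 /
        (1.0 + Bufsr * Kbufsr / ((CaSR + Kbufsr) * (CaSR + Kbufsr)));
    const double bufss = 1.0 /
        (1.0 + Bufss * Kbufss / ((Cass + Kbufss) * (Cass + Kbufss)));
    dy[16] = bufc * ((Ileak - Iup) * Vsr / Vcyt + Ixfer -
                     (IbCa + IpCa - 2.0 * INCX) * Cmem / (2.0 * Vcyt * Frdy));
    dy[17] = bufss * (-ICaL * Cmem / (2.0 * Vss * Frdy) +
                      Irel * Vsr / Vss - Ixfer * Vcyt / Vss);
    dy[18] = bufsr * (Iup - Irel - Ileak);

    for (int i = 0; i < N_STATE; i++)
        if (p[23 + i] != 0.0) dy[i] = 0.0;

    if (aux) {
        aux[0] = INa;  aux[1] = ICaL; aux[2] = IKr;  aux[3] = IKs;
        aux[4] = Ito;  aux[5] = IK1;  aux[6] = IpK;  aux[7] = IbNa;
        aux[8] = IbCa; aux[9] = INaK; aux[10] = INCX; aux[11] = IpCa;
        aux[12] = Iup; aux[13] = Irel; aux[14] = Ileak; aux[15] = Ixfer;
    }
}

void tp06_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    tp06_core(parms, y, ydot, (*ip >= N_AUX) ? yout : NULL);
}

/* direct evaluation from R: returns list(dy, currents) */
SEXP C_tp06_rhs(SEXP ys, SEXP ps)
{
    if (LENGTH(ys) != N_STATE) error("state vector must have length %d", N_STATE);
    if (LENGTH(ps) != N_PARMS) error("parameter vector must have length %d", N_PARMS);
    SEXP dy = PROTECT(allocVector(REALSXP, N_STATE));
    SEXP aux = PROTECT(allocVector(REALSXP, N_AUX));
    tp06_core(REAL(ps), REAL(ys), REAL(dy), REAL(aux));
    SEXP out = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(out, 0, dy);
    SET_VECTOR_ELT(out, 1, aux);
    SEXP nm = PROTECT(allocVector(STRSXP, 2));
    SET_STRING_ELT(nm, 0, mkChar("deriv"));
    SET_STRING_ELT(nm, 1, mkChar("aux"));
    setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(4);
    return out;
}
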