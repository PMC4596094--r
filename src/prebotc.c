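/* Compiled right-hand side of the two-compartment eupnea/sigh model,
 * in the deSolve compiled-model convention (initfunc + derivs).
 *
 * The parameter vector is laid out as [eupnea block | sigh block | coupling
 * flag]; one compartment block is NPARC doubles in the order fixed by
 * .param_order on the R side (R/parameters.R).  The two must stay in sync.
 *
 * State vector: (V, h, s, Ca_i, Ca_ER, l) for eupnea, then the same six for
 * sigh.  Units: mV, ms, nS, pF, uM.
 */

#include <R.h>
#include <math.h>

#define NPARC 40

enum {
  CM, GNAP, GK, GCAN, GCA, GH, GSYN,
  VNAP, VK, VCA, VSYN, EH, KCAN,
  M_VHALF, M_SLOPE,
  H_VHALF, H_SLOPE, H_TAUBAR,
  N_VHALF, N_SLOPE,
  S_VHALF, S_SLOPE, S_TAUBAR,
  KSYN, S_TAU_VDEP,
  ALPHA, VPMCA, KPMCA, LAM, FI, SIGMA,
  IP3, A_IP3, KD, KI, KA,
  VSERCA, KSERCA, LIP3R, PIP3R
};

static double P[2 * NPARC + 1];

void prebotc_init(void (*odeparms)(int *, double *))
{
  int n = 2 * NPARC + 1;
  odeparms(&n, P);
}

static double sigm(double V, double Vhalf, double slope)
{
  return 1.0 / (1.0 + exp((V - Vhalf) / slope));
}

/* Six derivatives of one compartment.  s_pre is the synaptic activation of
 * the presynaptic compartment; g_in/V_in are the conductance and reversal of
 * the synapse onto THIS compartment (zero when uncoupled). */
static void comp_deriv(const double *p, const double *y,
                       double s_pre, double g_in, double V_in, double *dy)
{
  double V = y[0], h = y[1], s = y[2], ca = y[3], caer = y[4], l = y[5];

  double minf = sigm(V, p[M_VHALF], p[M_SLOPE]);
  double inap = p[GNAP] * minf * h * (V - p[VNAP]);
  double ica  = p[GCA] * minf * (V - p[VCA]);   /* shares the NaP activation */
  double ican = p[GCAN] * ca / (ca + p[KCAN]) * (V - p[VNAP]);
  double ileak = p[GK] * (V - p[VK]);
  double ih   = p[GH] * sigm(V, p[N_VHALF], p[N_SLOPE]) * (V - p[EH]);
  double isyn = g_in * s_pre * (V - V_in);

  dy[0] = -(inap + ileak + ica + ican + ih + isyn) / p[CM];

  double tauh = p[H_TAUBAR] / cosh((V - p[H_VHALF]) / (2.0 * p[H_SLOPE]));
  dy[1] = (sigm(V, p[H_VHALF], p[H_SLOPE]) - h) / tauh;

  double H = sigm(V, p[S_VHALF], p[S_SLOPE]);
  double taus = p[S_TAUBAR];
  if (p[S_TAU_VDEP] > 0.5)
    taus /= cosh((V - p[S_VHALF]) / (2.0 * p[S_SLOPE]));
  dy[2] = ((1.0 - s) * H - p[KSYN] * s) / taus;

  double x = p[IP3] * ca * l / ((p[IP3] + p[KI]) * (ca + p[KA]));
  double jerin  = (p[LIP3R] + p[PIP3R] * x * x * x) * (caer - ca);
  double jerout = p[VSERCA] * ca * ca / (p[KSERCA] * p[KSERCA] + ca * ca);
  double jpmin  = -p[ALPHA] * ica;
  double jpmout = p[VPMCA] * ca * ca / (p[KPMCA] * p[KPMCA] + ca * ca);

  /* ER-release term enters with the physical sign (release raises Ca_i and
   * drains Ca_ER); the source equations print the opposite sign, which
   * contradicts their own prose and yields no slow rhythm. */
  dy[3] = p[FI] * ((jpmin - jpmout) / p[LAM] + (jerin - jerout));
  dy[4] = -(p[FI] / p[SIGMA]) * (jerin - jerout);
  dy[5] = p[A_IP3] * (p[KD] - l * (ca + p[KD]));
}

/* Coupled network: eupnea receives the excitatory synapse (its own gsyn/Vsyn
 * column) driven by sigh's s; sigh receives the inhibitory synapse driven by
 * eupnea's s.  The trailing parameter is the coupling flag (0/1). */
void prebotc_deriv_network(int *neq, double *t, double *y, double *ydot,
                           double *yout, int *ip)
{
  double c = P[2 * NPARC];
  comp_deriv(P, y, y[8], c * P[GSYN], P[VSYN], ydot);
  comp_deriv(P + NPARC, y + 6, y[2],
             c * P[NPARC + GSYN], P[NPARC + VSYN], ydot + 6);
}

/* Single compartment with zero synaptic input (first parameter block). */
void prebotc_deriv_single(int *neq, double *t, double *y, double *ydot,
                          double *yout, int *ip)
{
  comp_deriv(P, y, 0.0, 0.0, 0.0, ydot);
}
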