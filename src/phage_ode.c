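/* Whole-body PBPK right-hand side for labeled phage plus the twin
 * free-label model, in a form usable as a deSolve compiled model.
 *
 * State layout (all amounts, %ID of one administration):
 *   for each organ i (0..n-1), 4 slots:
 *     y[4i+0] A_vas   labeled phage in vascular space
 *     y[4i+1] A_int   labeled phage in interstitial space
 *     y[4i+2] A_mps   labeled phage inside the MPS compartment
 *     y[4i+3] A_fmp   free label still resident in the MPS pool
 *   then, base = 4n:
 *     base+0 A_ven        venous blood phage
 *     base+1 A_art        arterial blood phage
 *     base+2 A_stoc       stomach-contents pool (total label)
 *     base+3 A_sto_sink   cumulative gastric outflow (unmeasured GI sink)
 *     base+4 A_urine      urine pool (total label)
 *     base+5 A_urine_sink cumulative urine outflow
 *     base+6 A_freeb      free label in blood (well mixed)
 *     base+7 A_thy        free label taken up by thyroid
 *     base+8 A_fel        cumulative eliminated free label
 *
 * Parameter vector (padded to NPARMS from R):
 *   [0] n_organs
 *   [1] P        permeability coefficient
 *   [2] k_up_max 1/h
 *   [3] k_rel    1/h
 *   [4] k_deg    1/h
 *   [5] k_deconj 1/h
 *   [6] k_mps_release 1/h
 *   [7] k_thy    1/h
 *   [8] k_free_elim 1/h
 *   [9] k_sto_out 1/h
 *   [10] k_u_out 1/h
 *   [11] V_ven   L
 *   [12] V_art   L
 *   [13] inf_rate %ID/h (zero-order venous input, constant per segment)
 *   [14] CO      L/h
 *   then per organ i, base 15 + 10 i:
 *     +0 Q (L/h), +1 V_vas (L), +2 V_int (L), +3 Kp,
 *     +4 A_max (%ID; <= 0 disables the MPS in that organ),
 *     +5 CL (L/h active surface clearance allocated to the organ),
 *     +6 route (0 none, 1 urinary, 2 gastric),
 *     +7 type (0 parallel, 1 lung in series, 2 liver, 3 portal organ),
 *     +8 mps_src (0: MPS fed from interstitium; 1: from vascular space,
 *        for organs whose resident macrophages are intravascular),
 *     +9 spare
 */

#include <R.h>
#include <math.h>

#define MAXORG 32
#define NGLOB 15
#define NPARMS (NGLOB + 10 * MAXORG)

static double parms[NPARMS];

void phage_init(void (*odeparms)(int *, double *))
{
    int N = NPARMS;
    odeparms(&N, parms);
}

void phage_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    const int n = (int) parms[0];
    const double P = parms[1], kup_max = parms[2], krel = parms[3],
        kdeg = parms[4], kdec = parms[5], kmps = parms[6], kthy = parms[7],
        kfel = parms[8], ksto = parms[9], kuo = parms[10], Vven = parms[11],
        Vart = parms[12], inf = parms[13], CO = parms[14];
    const int base = 4 * n;

    const double Aven = y[base + 0], Aart = y[base + 1];
    const double Cven = Aven / Vven, Cart = Aart / Vart;

    double ven_in = 0.0;       /* phage flow into venous pool, %ID/h  */
    double portal_in = 0.0;    /* portal venous inflow to liver       */
    double Q_portal = 0.0;     /* portal blood flow total             */
    double urine_in = 0.0, gastric_in = 0.0;
    double free_to_blood = 0.0;
    double Clung_v = 0.0;
    int liver = -1;

    /* first pass: everything except liver flow terms */
    for (int i = 0; i < n; i++) {
        const double *op = parms + NGLOB + 10 * i;
        const double Q = op[0], Vv = op[1], Vint = op[2], Kp = op[3],
            Amax = op[4], CL = op[5];
        const int route = (int) op[6], type = (int) op[7],
            mps_src = (int) op[8];
        const double Av = y[4 * i], Ai = y[4 * i + 1],
            Am = y[4 * i + 2], Af = y[4 * i + 3];
        const double Cv = Av / Vv, Cint = Ai / Vint;

        const double J = P * Q * (Cv - Cint / Kp); /* vasc -> interstitium */
        double kup = 0.0;
        if (Amax > 0.0) {
            kup = kup_max * (1.0 - Am / Amax);
            if (kup < 0.0) kup = 0.0;
        }
        /* active surface-site clearance samples the perfusing (vascular)
         * concentration at the epithelial interface */
        const double clearance = CL * Cv;
        /* MPS uptake draws on the space its phagocytes reside in */
        const double uptake = kup * (mps_src == 1 ? Av : Ai);

        double dAv = -J - clearance - kdec * Av;
        double dAi = J - kdec * Ai;
        double dAm = uptake - (krel + kdeg + kdec) * Am;
        double dAf = (kdeg + kdec) * Am - kmps * Af;
        if (mps_src == 1) {
            dAv += -uptake + krel * Am;
        } else {
            dAi += -uptake + krel * Am;
        }

        if (type == 1) {            /* lung, in series */
            dAv += CO * (Cven - Cv);
            Clung_v = Cv;
        } else if (type == 2) {     /* liver, flows added in second pass */
            liver = i;
        } else {                    /* parallel organ */
            dAv += Q * (Cart - Cv);
            if (type == 3) {        /* portal organ: outflow to liver */
                portal_in += Q * Cv;
                Q_portal += Q;
            } else {
                ven_in += Q * Cv;
            }
        }

        if (route == 1) urine_in += clearance;
        else if (route == 2) gastric_in += clearance;

        free_to_blood += kmps * Af + kdec * (Av + Ai);

        ydot[4 * i] = dAv;
        ydot[4 * i + 1] = dAi;
        ydot[4 * i + 2] = dAm;
        ydot[4 * i + 3] = dAf;
    }

    if (liver >= 0) {
        const double *op = parms + NGLOB + 10 * liver;
        const double Qha = op[0], Vv = op[1];
        const double Cv = y[4 * liver] / Vv;
        const double Qout = Qha + Q_portal;
        ydot[4 * liver] += Qha * Cart + portal_in - Qout * Cv;
        ven_in += Qout * Cv;
    }

    ydot[base + 0] = ven_in - CO * Cven - kdec * Aven + inf;      /* venous  */
    ydot[base + 1] = CO * Clung_v - CO * Cart - kdec * Aart;      /* arterial*/
    ydot[base + 2] = gastric_in - ksto * y[base + 2];             /* stomach contents */
    ydot[base + 3] = ksto * y[base + 2];
    ydot[base + 4] = urine_in - kuo * y[base + 4];                /* urine   */
    ydot[base + 5] = kuo * y[base + 4];
    free_to_blood += kdec * (Aven + Aart);
    ydot[base + 6] = free_to_blood - (kthy + kfel) * y[base + 6]; /* free label */
    ydot[base + 7] = kthy * y[base + 6];
    ydot[base + 8] = kfel * y[base + 6];

    if (*ip >= 1) {
        double tot = 0.0;
        for (int k = 0; k < *neq; k++) tot += y[k];
        yout[0] = tot;
    }
}
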