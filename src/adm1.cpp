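// ADM1 (Anaerobic Digestion Model No. 1) for a CSTR with gas headspace,
// in the benchmark DAE reformulation: pH/ion speciation and dissolved H2
// are algebraic (fast equilibria / quasi-steady), the remaining balances
// are integrated with fixed-step RK4. Concentrations in kg COD m^-3 except
// S_IC, S_IN (kmol m^-3); time in days.
//
// State layout (length 33):
//  0 S_su   1 S_aa   2 S_fa   3 S_va   4 S_bu   5 S_pro  6 S_ac   7 S_h2
//  8 S_ch4  9 S_IC  10 S_IN  11 S_I   12 X_c   13 X_ch  14 X_pr  15 X_li
// 16 X_su  17 X_aa  18 X_fa  19 X_c4  20 X_pro 21 X_ac  22 X_h2  23 X_I
// 24 S_va- 25 S_bu- 26 S_pro- 27 S_ac- 28 S_hco3- 29 S_nh3
// 30 S_gas_h2 31 S_gas_ch4 32 S_gas_co2

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct AdmParams {
  // stoichiometry
  double f_sI_xc, f_xI_xc, f_ch_xc, f_pr_xc, f_li_xc;
  double f_fa_li, f_h2_su, f_bu_su, f_pro_su, f_ac_su;
  double f_h2_aa, f_va_aa, f_bu_aa, f_pro_aa, f_ac_aa;
  double Y_su, Y_aa, Y_fa, Y_c4, Y_pro, Y_ac, Y_h2;
  // carbon / nitrogen contents (kmol per kg COD)
  double C_su, C_aa, C_fa, C_va, C_bu, C_pro, C_ac, C_ch4, C_sI, C_xI,
         C_xc, C_ch, C_pr, C_li, C_bac;
  double N_xc, N_I, N_aa, N_bac;
  // kinetics
  double k_dis, k_hyd_ch, k_hyd_pr, k_hyd_li;
  double K_S_IN;
  double k_m_su, K_S_su, k_m_aa, K_S_aa, k_m_fa, K_S_fa, K_Ih2_fa;
  double k_m_c4, K_S_c4, K_Ih2_c4, k_m_pro, K_S_pro, K_Ih2_pro;
  double k_m_ac, K_S_ac, K_I_nh3, k_m_h2, K_S_h2, k_dec;
  double pHUL_aa, pHLL_aa, pHUL_ac, pHLL_ac, pHUL_h2, pHLL_h2;
  // physico-chemical
  double T_op, K_w, K_a_va, K_a_bu, K_a_pro, K_a_ac, K_a_co2, K_a_IN;
  double K_H_h2, K_H_ch4, K_H_co2, p_gas_h2o, k_La, k_p, P_atm, R_gas;
  double S_cat, S_an;
  // reactor
  double V_liq, V_gas;
  // numerics
  double neg_tol;
};

static double gp(const List& p, const char* nm) {
  if (!p.containsElementNamed(nm)) stop("missing ADM1 parameter '%s'", nm);
  return as<double>(p[nm]);
}

static AdmParams load_params(const List& p) {
  AdmParams P;
  P.f_sI_xc = gp(p,"f_sI_xc"); P.f_xI_xc = gp(p,"f_xI_xc");
  P.f_ch_xc = gp(p,"f_ch_xc"); P.f_pr_xc = gp(p,"f_pr_xc"); P.f_li_xc = gp(p,"f_li_xc");
  P.f_fa_li = gp(p,"f_fa_li");
  P.f_h2_su = gp(p,"f_h2_su"); P.f_bu_su = gp(p,"f_bu_su");
  P.f_pro_su = gp(p,"f_pro_su"); P.f_ac_su = gp(p,"f_ac_su");
  P.f_h2_aa = gp(p,"f_h2_aa"); P.f_va_aa = gp(p,"f_va_aa"); P.f_bu_aa = gp(p,"f_bu_aa");
  P.f_pro_aa = gp(p,"f_pro_aa"); P.f_ac_aa = gp(p,"f_ac_aa");
  P.Y_su = gp(p,"Y_su"); P.Y_aa = gp(p,"Y_aa"); P.Y_fa = gp(p,"Y_fa");
  P.Y_c4 = gp(p,"Y_c4"); P.Y_pro = gp(p,"Y_pro"); P.Y_ac = gp(p,"Y_ac"); P.Y_h2 = gp(p,"Y_h2");
  P.C_su = gp(p,"C_su"); P.C_aa = gp(p,"C_aa"); P.C_fa = gp(p,"C_fa");
  P.C_va = gp(p,"C_va"); P.C_bu = gp(p,"C_bu"); P.C_pro = gp(p,"C_pro");
  P.C_ac = gp(p,"C_ac"); P.C_ch4 = gp(p,"C_ch4"); P.C_sI = gp(p,"C_sI");
  P.C_xI = gp(p,"C_xI"); P.C_xc = gp(p,"C_xc"); P.C_ch = gp(p,"C_ch");
  P.C_pr = gp(p,"C_pr"); P.C_li = gp(p,"C_li"); P.C_bac = gp(p,"C_bac");
  P.N_xc = gp(p,"N_xc"); P.N_I = gp(p,"N_I"); P.N_aa = gp(p,"N_aa"); P.N_bac = gp(p,"N_bac");
  P.k_dis = gp(p,"k_dis"); P.k_hyd_ch = gp(p,"k_hyd_ch");
  P.k_hyd_pr = gp(p,"k_hyd_pr"); P.k_hyd_li = gp(p,"k_hyd_li");
  P.K_S_IN = gp(p,"K_S_IN");
  P.k_m_su = gp(p,"k_m_su"); P.K_S_su = gp(p,"K_S_su");
  P.k_m_aa = gp(p,"k_m_aa"); P.K_S_aa = gp(p,"K_S_aa");
  P.k_m_fa = gp(p,"k_m_fa"); P.K_S_fa = gp(p,"K_S_fa"); P.K_Ih2_fa = gp(p,"K_Ih2_fa");
  P.k_m_c4 = gp(p,"k_m_c4"); P.K_S_c4 = gp(p,"K_S_c4"); P.K_Ih2_c4 = gp(p,"K_Ih2_c4");
  P.k_m_pro = gp(p,"k_m_pro"); P.K_S_pro = gp(p,"K_S_pro"); P.K_Ih2_pro = gp(p,"K_Ih2_pro");
  P.k_m_ac = gp(p,"k_m_ac"); P.K_S_ac = gp(p,"K_S_ac"); P.K_I_nh3 = gp(p,"K_I_nh3");
  P.k_m_h2 = gp(p,"k_m_h2"); P.K_S_h2 = gp(p,"K_S_h2"); P.k_dec = gp(p,"k_dec");
  P.pHUL_aa = gp(p,"pHUL_aa"); P.pHLL_aa = gp(p,"pHLL_aa");
  P.pHUL_ac = gp(p,"pHUL_ac"); P.pHLL_ac = gp(p,"pHLL_ac");
  P.pHUL_h2 = gp(p,"pHUL_h2"); P.pHLL_h2 = gp(p,"pHLL_h2");
  P.T_op = gp(p,"T_op"); P.K_w = gp(p,"K_w");
  P.K_a_va = gp(p,"K_a_va"); P.K_a_bu = gp(p,"K_a_bu");
  P.K_a_pro = gp(p,"K_a_pro"); P.K_a_ac = gp(p,"K_a_ac");
  P.K_a_co2 = gp(p,"K_a_co2"); P.K_a_IN = gp(p,"K_a_IN");
  P.K_H_h2 = gp(p,"K_H_h2"); P.K_H_ch4 = gp(p,"K_H_ch4"); P.K_H_co2 = gp(p,"K_H_co2");
  P.p_gas_h2o = gp(p,"p_gas_h2o"); P.k_La = gp(p,"k_La"); P.k_p = gp(p,"k_p");
  P.P_atm = gp(p,"P_atm"); P.R_gas = gp(p,"R_gas");
  P.S_cat = gp(p,"S_cat"); P.S_an = gp(p,"S_an");
  P.V_liq = gp(p,"V_liq"); P.V_gas = gp(p,"V_gas");
  P.neg_tol = gp(p,"neg_tol");
  return P;
}

// Charge balance f(SH) is strictly increasing in SH: safeguarded Newton.
static double solve_ph(const double* s, const AdmParams& P, double sh_guess) {
  const double sIN = std::max(s[10], 0.0), sIC = std::max(s[9], 0.0);
  const double sva = std::max(s[3], 0.0), sbu = std::max(s[4], 0.0);
  const double spro = std::max(s[5], 0.0), sac = std::max(s[6], 0.0);
  double lo = 1e-14, hi = 1.0;
  double sh = (sh_guess > lo && sh_guess < hi) ? sh_guess : 1e-7;
  for (int it = 0; it < 100; ++it) {
    double f = P.S_cat + sIN * sh / (P.K_a_IN + sh) + sh
      - sIC * P.K_a_co2 / (P.K_a_co2 + sh)
      - (sac / 64.0) * P.K_a_ac / (P.K_a_ac + sh)
      - (spro / 112.0) * P.K_a_pro / (P.K_a_pro + sh)
      - (sbu / 160.0) * P.K_a_bu / (P.K_a_bu + sh)
      - (sva / 208.0) * P.K_a_va / (P.K_a_va + sh)
      - P.S_an - P.K_w / sh;
    if (f > 0) hi = sh; else lo = sh;
    double df = sIN * P.K_a_IN / std::pow(P.K_a_IN + sh, 2) + 1.0
      + sIC * P.K_a_co2 / std::pow(P.K_a_co2 + sh, 2)
      + (sac / 64.0) * P.K_a_ac / std::pow(P.K_a_ac + sh, 2)
      + (spro / 112.0) * P.K_a_pro / std::pow(P.K_a_pro + sh, 2)
      + (sbu / 160.0) * P.K_a_bu / std::pow(P.K_a_bu + sh, 2)
      + (sva / 208.0) * P.K_a_va / std::pow(P.K_a_va + sh, 2)
      + P.K_w / (sh * sh);
    double step = f / df;
    double shn = sh - step;
    if (!(shn > lo && shn < hi)) shn = std::sqrt(lo * hi);  // bisect in log space
    if (std::fabs(shn - sh) < 1e-16 + 1e-12 * sh) { sh = shn; break; }
    sh = shn;
  }
  return sh;
}

struct Rates {
  double rho[20];      // 1..19 used
  double I_pH_aa, I_pH_ac, I_pH_h2, I_IN, I_nh3;
  double sh;           // H+ concentration
};

static double ph_inhib(double pH, double UL, double LL) {
  if (pH >= UL) return 1.0;
  double z = (pH - UL) / (UL - LL);
  return std::exp(-3.0 * z * z);
}

// process rates given state, with dissolved H2 supplied explicitly
static void calc_rates(const double* s, double sh2, const AdmParams& P,
                       double sh, Rates& R) {
  double pH = -std::log10(sh);
  R.sh = sh;
  R.I_pH_aa = ph_inhib(pH, P.pHUL_aa, P.pHLL_aa);
  R.I_pH_ac = ph_inhib(pH, P.pHUL_ac, P.pHLL_ac);
  R.I_pH_h2 = ph_inhib(pH, P.pHUL_h2, P.pHLL_h2);
  double sIN = std::max(s[10], 0.0);
  R.I_IN = sIN / (sIN + P.K_S_IN);
  double snh3 = sIN * P.K_a_IN / (P.K_a_IN + sh);
  R.I_nh3 = 1.0 / (1.0 + snh3 / P.K_I_nh3);
  double I_h2_fa = 1.0 / (1.0 + sh2 / P.K_Ih2_fa);
  double I_h2_c4 = 1.0 / (1.0 + sh2 / P.K_Ih2_c4);
  double I_h2_pro = 1.0 / (1.0 + sh2 / P.K_Ih2_pro);
  double I1 = R.I_pH_aa * R.I_IN;
  R.rho[1] = P.k_dis * s[12];
  R.rho[2] = P.k_hyd_ch * s[13];
  R.rho[3] = P.k_hyd_pr * s[14];
  R.rho[4] = P.k_hyd_li * s[15];
  R.rho[5] = P.k_m_su * s[0] / (P.K_S_su + s[0]) * s[16] * I1;
  R.rho[6] = P.k_m_aa * s[1] / (P.K_S_aa + s[1]) * s[17] * I1;
  R.rho[7] = P.k_m_fa * s[2] / (P.K_S_fa + s[2]) * s[18] * I1 * I_h2_fa;
  R.rho[8] = P.k_m_c4 * s[3] / (P.K_S_c4 + s[3]) * s[19]
             * s[3] / (s[3] + s[4] + 1e-6) * I1 * I_h2_c4;
  R.rho[9] = P.k_m_c4 * s[4] / (P.K_S_c4 + s[4]) * s[19]
             * s[4] / (s[3] + s[4] + 1e-6) * I1 * I_h2_c4;
  R.rho[10] = P.k_m_pro * s[5] / (P.K_S_pro + s[5]) * s[20] * I1 * I_h2_pro;
  R.rho[11] = P.k_m_ac * s[6] / (P.K_S_ac + s[6]) * s[21]
              * R.I_pH_ac * R.I_IN * R.I_nh3;
  R.rho[12] = P.k_m_h2 * sh2 / (P.K_S_h2 + sh2) * s[22] * R.I_pH_h2 * R.I_IN;
  for (int i = 0; i < 7; ++i) R.rho[13 + i] = P.k_dec * s[16 + i];
}

// reaction part of dS_h2/dt (production - uptake), no transfer/dilution
static double h2_reaction(const Rates& R, const AdmParams& P) {
  return (1 - P.Y_su) * P.f_h2_su * R.rho[5]
       + (1 - P.Y_aa) * P.f_h2_aa * R.rho[6]
       + (1 - P.Y_fa) * 0.3 * R.rho[7]
       + (1 - P.Y_c4) * 0.15 * R.rho[8]
       + (1 - P.Y_c4) * 0.2 * R.rho[9]
       + (1 - P.Y_pro) * 0.43 * R.rho[10]
       - R.rho[12];
}

// quasi-steady dissolved hydrogen: residual is strictly decreasing in sh2
static double solve_sh2(const double* s, const AdmParams& P, double sh,
                        double q, double sh2_in, double p_gas_h2) {
  double lo = 0.0, hi = 1e-3;
  Rates R;
  for (int it = 0; it < 100; ++it) {
    double mid = 0.5 * (lo + hi);
    calc_rates(s, mid, P, sh, R);
    double f = q / P.V_liq * (sh2_in - mid) + h2_reaction(R, P)
      - P.k_La * (mid - 16.0 * P.K_H_h2 * p_gas_h2);
    if (f > 0) lo = mid; else hi = mid;
    if (hi - lo < 1e-18 + 1e-10 * hi) break;
  }
  return 0.5 * (lo + hi);
}

// Full right-hand side. s: 33-state. sin24: influent for states 0..23.
// aux out: [0]=q_gas, [1]=pH, [2]=sh2, [3]=cod_out_flux, [4]=n_out_flux,
//          [5]=gas_cod_flux, [6]=gas_ch4_flux
static void adm1_rhs(const double* s, const double* sin24, double q,
                     const AdmParams& P, double sh_guess,
                     double* ds, double* aux) {
  double sh = solve_ph(s, P, sh_guess);
  double p_gas_h2 = s[30] * P.R_gas * P.T_op / 16.0;
  double p_gas_ch4 = s[31] * P.R_gas * P.T_op / 64.0;
  double p_gas_co2 = s[32] * P.R_gas * P.T_op;
  double P_gas = p_gas_h2 + p_gas_ch4 + p_gas_co2 + P.p_gas_h2o;
  double q_gas = P.k_p * (P_gas - P.P_atm) * P_gas / P.P_atm;
  if (q_gas < 0) q_gas = 0;

  double sh2 = solve_sh2(s, P, sh, q, sin24[7], p_gas_h2);
  Rates R;
  calc_rates(s, sh2, P, sh, R);
  const double* r = R.rho;

  double snh3 = std::max(s[10], 0.0) * P.K_a_IN / (P.K_a_IN + sh);
  double shco3 = std::max(s[9], 0.0) * P.K_a_co2 / (P.K_a_co2 + sh);
  double sco2 = std::max(s[9], 0.0) - shco3;

  double rhoT_h2 = P.k_La * (sh2 - 16.0 * P.K_H_h2 * p_gas_h2);
  double rhoT_ch4 = P.k_La * (s[8] - 64.0 * P.K_H_ch4 * p_gas_ch4);
  double rhoT_co2 = P.k_La * (sco2 - P.K_H_co2 * p_gas_co2);

  double d[33];
  for (int i = 0; i < 33; ++i) d[i] = 0.0;

  // reaction terms (COD-conserving by construction of the f/Y tables)
  d[0] = r[2] + (1 - P.f_fa_li) * r[4] - r[5];
  d[1] = r[3] - r[6];
  d[2] = P.f_fa_li * r[4] - r[7];
  d[3] = (1 - P.Y_aa) * P.f_va_aa * r[6] - r[8];
  d[4] = (1 - P.Y_su) * P.f_bu_su * r[5] + (1 - P.Y_aa) * P.f_bu_aa * r[6] - r[9];
  d[5] = (1 - P.Y_su) * P.f_pro_su * r[5] + (1 - P.Y_aa) * P.f_pro_aa * r[6]
       + (1 - P.Y_c4) * 0.54 * r[8] - r[10];
  d[6] = (1 - P.Y_su) * P.f_ac_su * r[5] + (1 - P.Y_aa) * P.f_ac_aa * r[6]
       + (1 - P.Y_fa) * 0.7 * r[7] + (1 - P.Y_c4) * 0.31 * r[8]
       + (1 - P.Y_c4) * 0.8 * r[9] + (1 - P.Y_pro) * 0.57 * r[10] - r[11];
  d[7] = 0.0;  // algebraic
  d[8] = (1 - P.Y_ac) * r[11] + (1 - P.Y_h2) * r[12];
  d[11] = P.f_sI_xc * r[1];
  d[12] = -r[1] + r[13] + r[14] + r[15] + r[16] + r[17] + r[18] + r[19];
  d[13] = P.f_ch_xc * r[1] - r[2];
  d[14] = P.f_pr_xc * r[1] - r[3];
  d[15] = P.f_li_xc * r[1] - r[4];
  d[16] = P.Y_su * r[5] - r[13];
  d[17] = P.Y_aa * r[6] - r[14];
  d[18] = P.Y_fa * r[7] - r[15];
  d[19] = P.Y_c4 * (r[8] + r[9]) - r[16];
  d[20] = P.Y_pro * r[10] - r[17];
  d[21] = P.Y_ac * r[11] - r[18];
  d[22] = P.Y_h2 * r[12] - r[19];
  d[23] = P.f_xI_xc * r[1];

  // inorganic carbon and nitrogen close the elemental balances exactly
  double dh2_react = h2_reaction(R, P);
  double carbon =
      P.C_su * d[0] + P.C_aa * d[1] + P.C_fa * d[2] + P.C_va * d[3]
    + P.C_bu * d[4] + P.C_pro * d[5] + P.C_ac * d[6] + P.C_ch4 * d[8]
    + P.C_sI * d[11] + P.C_xc * d[12] + P.C_ch * d[13] + P.C_pr * d[14]
    + P.C_li * d[15] + P.C_xI * d[23]
    + P.C_bac * (d[16] + d[17] + d[18] + d[19] + d[20] + d[21] + d[22]);
  d[9] = -carbon - rhoT_co2;  // (S_h2 carries no carbon)
  double nitrogen =
      P.N_aa * (d[1] + d[14]) + P.N_xc * d[12]
    + P.N_I * (d[11] + d[23])
    + P.N_bac * (d[16] + d[17] + d[18] + d[19] + d[20] + d[21] + d[22]);
  d[10] = -nitrogen;
  (void) dh2_react;

  // gas transfer on the liquid side
  d[8] -= rhoT_ch4;

  // dilution (CSTR: q_in = q_out, constant volume)
  if (q > 0) {
    double D = q / P.V_liq;
    for (int i = 0; i < 24; ++i) {
      if (i == 7) continue;  // algebraic
      d[i] += D * (sin24[i] - s[i]);
    }
  }

  // gas phase
  d[30] = -s[30] * q_gas / P.V_gas + rhoT_h2 * P.V_liq / P.V_gas;
  d[31] = -s[31] * q_gas / P.V_gas + rhoT_ch4 * P.V_liq / P.V_gas;
  d[32] = -s[32] * q_gas / P.V_gas + rhoT_co2 * P.V_liq / P.V_gas;

  for (int i = 0; i < 33; ++i) ds[i] = d[i];

  // fluxes for balance bookkeeping (per day)
  double cod = 0.0;
  for (int i = 0; i < 24; ++i) if (i != 9 && i != 10) cod += s[i];
  cod += sh2 - s[7];  // use algebraic value for S_h2
  double ntot = std::max(s[10], 0.0)
    + P.N_aa * (s[1] + s[14]) + P.N_xc * s[12] + P.N_I * (s[11] + s[23])
    + P.N_bac * (s[16] + s[17] + s[18] + s[19] + s[20] + s[21] + s[22]);
  aux[0] = q_gas;
  aux[1] = -std::log10(sh);
  aux[2] = sh2;
  aux[3] = q * cod;
  aux[4] = q * ntot;
  aux[5] = q_gas * (s[30] + s[31]);
  aux[6] = q_gas * s[31];
}

// write algebraic states (S_h2, ions, from pH) back into the state vector
static void refresh_algebraic(double* s, const AdmParams& P, double q,
                              const double* sin24) {
  double sh = solve_ph(s, P, 1e-7);
  double p_gas_h2 = s[30] * P.R_gas * P.T_op / 16.0;
  s[7] = solve_sh2(s, P, sh, q, sin24[7], p_gas_h2);
  s[24] = s[3] * P.K_a_va / (P.K_a_va + sh);
  s[25] = s[4] * P.K_a_bu / (P.K_a_bu + sh);
  s[26] = s[5] * P.K_a_pro / (P.K_a_pro + sh);
  s[27] = s[6] * P.K_a_ac / (P.K_a_ac + sh);
  s[28] = std::max(s[9], 0.0) * P.K_a_co2 / (P.K_a_co2 + sh);
  s[29] = std::max(s[10], 0.0) * P.K_a_IN / (P.K_a_IN + sh);
}

// [[Rcpp::export(.adm1_step_cpp)]]
List adm1_step_cpp(NumericVector state, NumericVector influent, double q,
                   double duration, double dt, List params) {
  if (state.size() != 33) stop("state must have length 33");
  if (influent.size() != 24) stop("influent must have length 24");
  if (duration < 0 || dt <= 0) stop("duration >= 0 and dt > 0 required");
  AdmParams P = load_params(params);
  double s[33], sin24[24];
  for (int i = 0; i < 33; ++i) s[i] = state[i];
  for (int i = 0; i < 24; ++i) sin24[i] = influent[i];

  int nstep = (int) std::ceil(duration / dt - 1e-9);
  double gas_vol = 0, ch4_vol_c = 0, cod_out = 0, n_out = 0, gas_cod = 0;
  double sh_guess = 1e-7;
  double k1[33], k2[33], k3[33], k4[33], tmp[33], aux[7];

  for (int step = 0; step < nstep; ++step) {
    double h = std::min(dt, duration - step * dt);
    adm1_rhs(s, sin24, q, P, sh_guess, k1, aux);
    sh_guess = std::pow(10.0, -aux[1]);
    double a0 = aux[0], a3 = aux[3], a4 = aux[4], a5 = aux[5], a6 = aux[6];
    for (int i = 0; i < 33; ++i) tmp[i] = s[i] + 0.5 * h * k1[i];
    adm1_rhs(tmp, sin24, q, P, sh_guess, k2, aux);
    double b0 = aux[0], b3 = aux[3], b4 = aux[4], b5 = aux[5], b6 = aux[6];
    for (int i = 0; i < 33; ++i) tmp[i] = s[i] + 0.5 * h * k2[i];
    adm1_rhs(tmp, sin24, q, P, sh_guess, k3, aux);
    double c0 = aux[0], c3 = aux[3], c4 = aux[4], c5 = aux[5], c6 = aux[6];
    for (int i = 0; i < 33; ++i) tmp[i] = s[i] + h * k3[i];
    adm1_rhs(tmp, sin24, q, P, sh_guess, k4, aux);
    for (int i = 0; i < 33; ++i)
      s[i] += h / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
    gas_vol += h / 6.0 * (a0 + 2 * b0 + 2 * c0 + aux[0]);
    cod_out += h / 6.0 * (a3 + 2 * b3 + 2 * c3 + aux[3]);
    n_out   += h / 6.0 * (a4 + 2 * b4 + 2 * c4 + aux[4]);
    gas_cod += h / 6.0 * (a5 + 2 * b5 + 2 * c5 + aux[5]);
    ch4_vol_c += h / 6.0 * (a6 + 2 * b6 + 2 * c6 + aux[6]);
    for (int i = 0; i < 33; ++i) {
      if (s[i] < 0) {
        if (s[i] < -P.neg_tol)
          stop("ADM1 state %d went negative (%g) at t=%g; reduce dt",
               i + 1, s[i], (step + 1) * h);
        s[i] = 0;
      }
    }
  }
  refresh_algebraic(s, P, q, sin24);

  NumericVector out(33);
  for (int i = 0; i < 33; ++i) out[i] = s[i];
  out.attr("names") = state.attr("names");
  double cod_in = 0;
  for (int i = 0; i < 24; ++i) if (i != 9 && i != 10) cod_in += sin24[i];
  double n_in = std::max(sin24[10], 0.0)
    + P.N_aa * (sin24[1] + sin24[14]) + P.N_xc * sin24[12]
    + P.N_I * (sin24[11] + sin24[23])
    + P.N_bac * (sin24[16] + sin24[17] + sin24[18] + sin24[19]
               + sin24[20] + sin24[21] + sin24[22]);
  return List::create(
    _["state"] = out,
    _["gas_volume"] = gas_vol,            // m3 biogas over the window
    _["ch4_mass"] = ch4_vol_c,            // kg COD CH4 leaving in gas
    _["cod_in"] = q * duration * cod_in,  // kg COD fed
    _["cod_out"] = cod_out,               // kg COD washed out (liquid)
    _["cod_gas"] = gas_cod,               // kg COD leaving as H2+CH4 gas
    _["n_in"] = q * duration * n_in,      // kmol N fed
    _["n_out"] = n_out);                  // kmol N washed out
}

// [[Rcpp::export(.adm1_rhs_cpp)]]
List adm1_rhs_cpp(NumericVector state, NumericVector influent, double q,
                  List params) {
  AdmParams P = load_params(params);
  double s[33], sin24[24], ds[33], aux[7];
  for (int i = 0; i < 33; ++i) s[i] = state[i];
  for (int i = 0; i < 24; ++i) sin24[i] = influent[i];
  adm1_rhs(s, sin24, q, P, 1e-7, ds, aux);
  return List::create(_["ds"] = NumericVector(ds, ds + 33),
                      _["q_gas"] = aux[0], _["pH"] = aux[1],
                      _["sh2"] = aux[2]);
}

// [[Rcpp::export(.adm1_rate_cpp)]]
double adm1_rate_cpp(NumericVector state, List params) {
  if (state.size() != 33) stop("state must have length 33");
  AdmParams P = load_params(params);
  double p_gas_h2 = state[30] * P.R_gas * P.T_op / 16.0;
  double p_gas_ch4 = state[31] * P.R_gas * P.T_op / 64.0;
  double p_gas_co2 = state[32] * P.R_gas * P.T_op;
  double P_gas = p_gas_h2 + p_gas_ch4 + p_gas_co2 + P.p_gas_h2o;
  double q_gas = P.k_p * (P_gas - P.P_atm) * P_gas / P.P_atm;
  return q_gas > 0 ? q_gas : 0;
}
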