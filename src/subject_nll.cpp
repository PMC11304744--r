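// Fast per-subject joint -2*log-likelihood for the rifabutin /
// des-rifabutin model. Mirrors the reference R implementation
// (.subject_h in R/likelihood.R) exactly; the two are compared in the
// test suite. The dataset structure is compiled once per fit into a
// persistent object; only the eta vector and the theta-dependent
// occasion parameters change between calls.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Occ {
  int mode; // 0 = steady state, 1 = baseline reset, 2 = explicit doses
  double dose_ug, tau;
  std::vector<double> t2, y2, infl2, t3, y3, infl3, dose_times;
  double predose_p, predose_m;
  std::vector<int> ip, im, lone_p, lone_m; // 0-based
};

struct Subj {
  std::vector<Occ> occs;
};

static const double TWO_PI = 6.283185307179586476925286766559;

// positive modulo without std::fmod (keeps the binary free of
// versioned libm symbols newer than the runtime loader provides)
static inline double pmod(double x, double m) {
  double w = x - std::floor(x / m) * m;
  if (w < 0) w += m;
  if (w >= m) w -= m;
  return w;
}

// exponential-mode decomposition; p = (cl_cyp, cl_conv, cl_met, vc_p,
// vp_p, q_p, vc_m, vp_m, q_m, f, ka, tlag)
struct Terms {
  double r[5], cp[5], cm[5];
  double k21, ke, k12, kem, k34, k43, kc, vc_p, vp_p, vc_m, vp_m;
  bool met;
};

static bool terms_fast(const double* p, double mw_ratio, bool want_met,
                       Terms& tm) {
  double cl_cyp = p[0], cl_conv = p[1], cl_met = p[2];
  double vc_p = p[3], vp_p = p[4], q_p = p[5];
  double vc_m = p[6], vp_m = p[7], q_m = p[8];
  double f = p[9], ka = p[10];

  double ke = (cl_cyp + cl_conv) / vc_p;
  double k12 = q_p / vc_p, k21 = q_p / vp_p;
  double s = ke + k12 + k21;
  double disc2 = s * s - 4.0 * ke * k21;
  double disc = std::sqrt(disc2 > 0 ? disc2 : 0);
  double a1 = (s + disc) / 2, a2 = (s - disc) / 2;
  if (a1 - a2 < 1e-7 * a1) a1 = a2 * (1 + 2e-7);
  if (std::fabs(ka - a1) < 1e-7 * ka) ka *= (1 + 3e-7);
  if (std::fabs(ka - a2) < 1e-7 * ka) ka *= (1 - 3e-7);

  double R_ka = (k21 - ka) / ((a1 - ka) * (a2 - ka));
  double R_a1 = (k21 - a1) / ((ka - a1) * (a2 - a1));
  double R_a2 = (k21 - a2) / ((ka - a2) * (a1 - a2));
  double fka = f * ka;

  tm.ke = ke; tm.k12 = k12; tm.k21 = k21;
  tm.vc_p = vc_p; tm.vp_p = vp_p; tm.met = want_met;
  if (!want_met) {
    tm.r[0] = ka; tm.r[1] = a1; tm.r[2] = a2; tm.r[3] = 0; tm.r[4] = 0;
    tm.cp[0] = R_ka * fka / vc_p; tm.cp[1] = R_a1 * fka / vc_p;
    tm.cp[2] = R_a2 * fka / vc_p; tm.cp[3] = 0; tm.cp[4] = 0;
    for (int j = 0; j < 5; j++) tm.cm[j] = 0;
    for (int j = 0; j < 3; j++)
      if (!std::isfinite(tm.cp[j]) || !std::isfinite(tm.r[j])) return false;
    return true;
  }
  double kem = cl_met / vc_m;
  double k34 = q_m / vc_m, k43 = q_m / vp_m;
  double sm = kem + k34 + k43;
  double discm2 = sm * sm - 4.0 * kem * k43;
  double discm = std::sqrt(discm2 > 0 ? discm2 : 0);
  double b1 = (sm + discm) / 2, b2 = (sm - discm) / 2;
  if (b1 - b2 < 1e-7 * b1) b1 = b2 * (1 + 2e-7);
  double qs[3] = {ka, a1, a2};
  for (int k = 0; k < 3; k++) {
    if (std::fabs(qs[k] - b1) < 1e-7 * b1) qs[k] *= (1 + 5e-7);
    double ref = b2 > 1e-12 ? b2 : 1e-12;
    if (std::fabs(qs[k] - b2) < 1e-7 * ref) qs[k] *= (1 - 5e-7);
  }
  ka = qs[0]; a1 = qs[1]; a2 = qs[2];
  double kc = mw_ratio * cl_conv / vc_p;
  double Rq[3] = {R_ka, R_a1, R_a2};
  double cm_b1 = 0, cm_b2 = 0, cm_q[3];
  for (int k = 0; k < 3; k++) {
    double bq = Rq[k] * kc * fka;
    cm_q[k] = bq * (k43 - qs[k]) / ((b1 - qs[k]) * (b2 - qs[k]));
    cm_b1 += bq * (k43 - b1) / ((qs[k] - b1) * (b2 - b1));
    cm_b2 += bq * (k43 - b2) / ((qs[k] - b2) * (b1 - b2));
  }
  tm.r[0] = ka; tm.r[1] = a1; tm.r[2] = a2; tm.r[3] = b1; tm.r[4] = b2;
  tm.cp[0] = R_ka * fka / vc_p; tm.cp[1] = R_a1 * fka / vc_p;
  tm.cp[2] = R_a2 * fka / vc_p; tm.cp[3] = 0; tm.cp[4] = 0;
  tm.cm[0] = cm_q[0] / vc_m; tm.cm[1] = cm_q[1] / vc_m;
  tm.cm[2] = cm_q[2] / vc_m; tm.cm[3] = cm_b1 / vc_m; tm.cm[4] = cm_b2 / vc_m;
  tm.kem = kem; tm.k34 = k34; tm.k43 = k43; tm.kc = kc;
  tm.vc_m = vc_m; tm.vp_m = vp_m;
  for (int j = 0; j < 5; j++)
    if (!std::isfinite(tm.cp[j]) || !std::isfinite(tm.cm[j]) ||
        !std::isfinite(tm.r[j])) return false;
  return true;
}

// decay of an initial state (ac_p, ap_p, ac_m, ap_m)
struct TransTerms { double r[4], cp[4], cm[4]; };

static void transient_fast(const Terms& tm, const double* x0, bool want_met,
                           TransTerms& tt) {
  double a1 = tm.r[1], a2 = tm.r[2];
  double d0 = -(tm.ke + tm.k12) * x0[0] + tm.k21 * x0[1];
  double A1 = (d0 + a2 * x0[0]) / (a2 - a1);
  double A2 = x0[0] - A1;
  tt.r[0] = a1; tt.r[1] = a2;
  tt.cp[0] = A1 / tm.vc_p; tt.cp[1] = A2 / tm.vc_p;
  tt.cp[2] = 0; tt.cp[3] = 0;
  if (!want_met) { tt.r[2] = tt.r[3] = 0; tt.cm[0] = tt.cm[1] = tt.cm[2] = tt.cm[3] = 0; return; }
  double b1 = tm.r[3], b2 = tm.r[4];
  double dm0 = -(tm.kem + tm.k34) * x0[2] + tm.k43 * x0[3];
  double M1 = (dm0 + b2 * x0[2]) / (b2 - b1);
  double M2 = x0[2] - M1;
  double qs[2] = {a1, a2}, Aq[2] = {A1, A2};
  double cm_b1 = M1, cm_b2 = M2, cm_q[2];
  for (int k = 0; k < 2; k++) {
    double bq = Aq[k] * tm.kc;
    cm_q[k] = bq * (tm.k43 - qs[k]) / ((b1 - qs[k]) * (b2 - qs[k]));
    cm_b1 += bq * (tm.k43 - b1) / ((qs[k] - b1) * (b2 - b1));
    cm_b2 += bq * (tm.k43 - b2) / ((qs[k] - b2) * (b1 - b2));
  }
  tt.r[2] = b1; tt.r[3] = b2;
  tt.cm[0] = cm_q[0] / tm.vc_m; tt.cm[1] = cm_q[1] / tm.vc_m;
  tt.cm[2] = cm_b1 / tm.vc_m; tt.cm[3] = cm_b2 / tm.vc_m;
}

static inline std::vector<double> asVec(SEXP x) {
  NumericVector v(x);
  return std::vector<double>(v.begin(), v.end());
}
static inline std::vector<int> asIdx0(SEXP x) {
  IntegerVector v(x);
  std::vector<int> out(v.size());
  for (int i = 0; i < v.size(); i++) out[i] = v[i] - 1;
  return out;
}

// [[Rcpp::export]]
SEXP compile_subject_cpp(List occs) {
  Subj* s = new Subj();
  for (int k = 0; k < occs.size(); k++) {
    List o(occs[k]);
    Occ oc;
    bool reset = as<bool>(o["reset"]);
    bool ss = as<bool>(o["ss"]);
    oc.mode = reset ? 1 : (ss ? 0 : 2);
    oc.dose_ug = as<double>(o["dose_mg"]) * 1000.0;
    oc.tau = as<double>(o["tau"]);
    oc.t2 = asVec(o["t2"]); oc.y2 = asVec(o["y2"]); oc.infl2 = asVec(o["infl2"]);
    oc.t3 = asVec(o["t3"]); oc.y3 = asVec(o["y3"]); oc.infl3 = asVec(o["infl3"]);
    oc.dose_times = asVec(o["dose_times"]);
    NumericVector pd(o["predose"]);
    oc.predose_p = (pd.size() > 0 && !NumericVector::is_na(pd[0])) ? pd[0] : 0.0;
    oc.predose_m = (pd.size() > 1 && !NumericVector::is_na(pd[1])) ? pd[1] : 0.0;
    oc.ip = asIdx0(o["ip"]); oc.im = asIdx0(o["im"]);
    oc.lone_p = asIdx0(o["lone_p"]); oc.lone_m = asIdx0(o["lone_m"]);
    s->occs.push_back(oc);
  }
  XPtr<Subj> xp(s, true);
  return xp;
}

// predictions of one occasion into fp / fm
static bool occ_pred(const Occ& oc, const Terms& tm, double tl, bool use_met,
                     std::vector<double>& fp, std::vector<double>& fm) {
  int np = oc.t2.size(), nm = use_met ? oc.t3.size() : 0;
  fp.assign(np, 0.0); fm.assign(nm, 0.0);
  double amt = oc.dose_ug;
  if (oc.mode == 0) { // steady state
    double gsp[5], gsm[5];
    for (int j = 0; j < 5; j++) {
      if (tm.cp[j] == 0 && tm.cm[j] == 0) { gsp[j] = 0; gsm[j] = 0; continue; }
      double den = 1.0 - std::exp(-tm.r[j] * oc.tau);
      gsp[j] = tm.cp[j] == 0 ? 0 : tm.cp[j] / den;
      gsm[j] = tm.cm[j] == 0 ? 0 : tm.cm[j] / den;
    }
    for (int i = 0; i < np; i++) {
      double w = pmod(oc.t2[i] - tl, oc.tau);
      double acc = 0;
      for (int j = 0; j < 5; j++) if (gsp[j] != 0) acc += gsp[j] * std::exp(-tm.r[j] * w);
      fp[i] = amt * acc;
    }
    for (int i = 0; i < nm; i++) {
      double w = pmod(oc.t3[i] - tl, oc.tau);
      double acc = 0;
      for (int j = 0; j < 5; j++) if (gsm[j] != 0) acc += gsm[j] * std::exp(-tm.r[j] * w);
      fm[i] = amt * acc;
    }
  } else if (oc.mode == 1) { // baseline reset + visit dose
    double x0[4] = {oc.predose_p * tm.vc_p, oc.predose_p * tm.vp_p,
                    use_met ? oc.predose_m * tm.vc_m : 0.0,
                    use_met ? oc.predose_m * tm.vp_m : 0.0};
    TransTerms tt;
    transient_fast(tm, x0, use_met, tt);
    for (int i = 0; i < np; i++) {
      double w = oc.t2[i] - tl, acc = 0;
      if (w >= 0)
        for (int j = 0; j < 5; j++) if (tm.cp[j] != 0) acc += tm.cp[j] * std::exp(-tm.r[j] * w);
      double acc2 = 0;
      for (int j = 0; j < 4; j++) if (tt.cp[j] != 0) acc2 += tt.cp[j] * std::exp(-tt.r[j] * oc.t2[i]);
      fp[i] = amt * acc + acc2;
    }
    for (int i = 0; i < nm; i++) {
      double w = oc.t3[i] - tl, acc = 0;
      if (w >= 0)
        for (int j = 0; j < 5; j++) if (tm.cm[j] != 0) acc += tm.cm[j] * std::exp(-tm.r[j] * w);
      double acc2 = 0;
      for (int j = 0; j < 4; j++) if (tt.cm[j] != 0) acc2 += tt.cm[j] * std::exp(-tt.r[j] * oc.t3[i]);
      fm[i] = amt * acc + acc2;
    }
  } else { // explicit dose list
    for (size_t d = 0; d < oc.dose_times.size(); d++) {
      double td = oc.dose_times[d];
      for (int i = 0; i < np; i++) {
        double w = oc.t2[i] - td - tl;
        if (w < 0) continue;
        double acc = 0;
        for (int j = 0; j < 5; j++) if (tm.cp[j] != 0) acc += tm.cp[j] * std::exp(-tm.r[j] * w);
        fp[i] += amt * acc;
      }
      for (int i = 0; i < nm; i++) {
        double w = oc.t3[i] - td - tl;
        if (w < 0) continue;
        double acc = 0;
        for (int j = 0; j < 5; j++) if (tm.cm[j] != 0) acc += tm.cm[j] * std::exp(-tm.r[j] * w);
        fm[i] += amt * acc;
      }
    }
  }
  for (int i = 0; i < np; i++) if (!std::isfinite(fp[i])) return false;
  for (int i = 0; i < nm; i++) if (!std::isfinite(fm[i])) return false;
  return true;
}

// [[Rcpp::export]]
List subject_h_cpp(SEXP xp_, NumericVector eta, NumericMatrix pocc,
                   NumericVector err, NumericVector om2,
                   IntegerVector layocc, int icl, int iclm,
                   bool use_met, double mw_ratio, bool want_pred) {
  XPtr<Subj> xp(xp_);
  const Subj& s = *xp;
  int nocc = s.occs.size();
  double prop_p = err[0], add_p = err[1], prop_m = err[2], add_m = err[3];
  double rho = use_met ? err[4] : 0.0;
  double l1mr2 = std::log(1.0 - rho * rho);

  double h = 0;
  int d = eta.size();
  for (int j = 0; j < d; j++)
    h += eta[j] * eta[j] / om2[j] + std::log(TWO_PI * om2[j]);

  std::vector<double> fstack, vstack;
  std::vector<double> fp, fm;
  bool bad = false;

  for (int k = 0; k < nocc && !bad; k++) {
    const Occ& oc = s.occs[k];
    double e_cl = icl > 0 ? std::exp(eta[icl - 1]) : 1.0;
    double e_clm = iclm > 0 ? std::exp(eta[iclm - 1]) : 1.0;
    int i_f = layocc[3 * k], i_ka = layocc[3 * k + 1], i_tl = layocc[3 * k + 2];
    double e_f = i_f > 0 ? std::exp(eta[i_f - 1]) : 1.0;
    double e_ka = i_ka > 0 ? std::exp(eta[i_ka - 1]) : 1.0;
    double e_tl = i_tl > 0 ? std::exp(eta[i_tl - 1]) : 1.0;

    double p[12];
    for (int j = 0; j < 12; j++) p[j] = pocc(j, k);
    p[0] *= e_cl; p[1] *= e_cl; p[2] *= e_clm;
    p[9] *= e_f; p[10] *= e_ka;
    double tl = p[11] * e_tl;
    bool ok = true;
    for (int j = 0; j < 12; j++) if (!std::isfinite(p[j])) ok = false;
    if (ok) {
      if (p[0] < 0 || p[1] <= 0 || p[2] <= 0 || p[10] <= 0 || tl < 0) ok = false;
      for (int j = 3; j <= 8; j++) if (p[j] <= 0) ok = false;
      if (p[9] <= 0) ok = false;
    }
    Terms tm;
    if (ok) ok = terms_fast(p, mw_ratio, use_met, tm);
    if (ok) ok = occ_pred(oc, tm, tl, use_met, fp, fm);
    if (!ok) { bad = true; break; }

    int np = oc.t2.size(), nm = use_met ? oc.t3.size() : 0;
    std::vector<double> v2(np), v3(nm);
    for (int i = 0; i < np; i++) {
      double a = prop_p * fp[i], b = add_p + oc.infl2[i];
      v2[i] = a * a + b * b;
    }
    for (int i = 0; i < nm; i++) {
      double a = prop_m * fm[i], b = add_m + oc.infl3[i];
      v3[i] = a * a + b * b;
    }
    if (use_met) {
      for (size_t q = 0; q < oc.ip.size(); q++) {
        int i = oc.ip[q], j = oc.im[q];
        double zp = (oc.y2[i] - fp[i]) / std::sqrt(v2[i]);
        double zm = (oc.y3[j] - fm[j]) / std::sqrt(v3[j]);
        h += std::log(TWO_PI * v2[i]) + std::log(TWO_PI * v3[j]) + l1mr2 +
          (zp * zp - 2 * rho * zp * zm + zm * zm) / (1 - rho * rho);
      }
      for (size_t q = 0; q < oc.lone_p.size(); q++) {
        int i = oc.lone_p[q];
        double r = oc.y2[i] - fp[i];
        h += std::log(TWO_PI * v2[i]) + r * r / v2[i];
      }
      for (size_t q = 0; q < oc.lone_m.size(); q++) {
        int i = oc.lone_m[q];
        double r = oc.y3[i] - fm[i];
        h += std::log(TWO_PI * v3[i]) + r * r / v3[i];
      }
    } else {
      for (int i = 0; i < np; i++) {
        double r = oc.y2[i] - fp[i];
        h += std::log(TWO_PI * v2[i]) + r * r / v2[i];
      }
    }
    if (want_pred) {
      fstack.insert(fstack.end(), fp.begin(), fp.end());
      vstack.insert(vstack.end(), v2.begin(), v2.end());
      if (use_met) {
        fstack.insert(fstack.end(), fm.begin(), fm.end());
        vstack.insert(vstack.end(), v3.begin(), v3.end());
      }
    }
  }
  if (bad || !std::isfinite(h)) {
    return List::create(Named("h") = 1e10, Named("ok") = false);
  }
  if (!want_pred) return List::create(Named("h") = h, Named("ok") = true);
  return List::create(Named("h") = h, Named("ok") = true,
                      Named("f") = wrap(fstack), Named("v") = wrap(vstack));
}
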