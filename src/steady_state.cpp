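#include <Rcpp.h>
using namespace Rcpp;

// Blood gas content relations used throughout the steady-state core.
// O2: Severinghaus-form dissociation curve + dissolved fraction.
// CO2: linear content approximation valid around the physiological range.

static inline double sat_o2(double po2) {
  return 1.0 / (1.0 + 23400.0 / (po2 * po2 * po2 + 150.0 * po2));
}

static inline double content_o2(double po2, double hb) {
  return 1.34 * hb * sat_o2(po2) + 0.003 * po2;
}

static inline double content_co2(double pco2) {
  return 0.45 * pco2 + 26.7;
}

// [[Rcpp::export]]
NumericVector cpp_o2_saturation(NumericVector po2) {
  int n = po2.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sat_o2(po2[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_o2_content(NumericVector po2, double hb) {
  int n = po2.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = content_o2(po2[i], hb);
  return out;
}

// Invert the O2 content relation: monotone bisection on [lo, hi].
static double invert_content_o2(double c, double hb, double lo, double hi,
                                double tol) {
  if (content_o2(hi, hb) <= c) return hi;
  if (content_o2(lo, hb) >= c) return lo;
  while (hi - lo > tol) {
    double mid = 0.5 * (lo + hi);
    if (content_o2(mid, hb) < c) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export]]
double cpp_invert_o2_content(double c, double hb) {
  return invert_content_o2(c, hb, 1e-3, 800.0, 1e-9);
}

// Per-compartment steady-state alveolar O2 balance:
//   gas side:   v * 1000 * (fio2 - pA / (pb - ph2o))      [mL O2 / min]
//   blood side: 10 * q * (content_o2(pA, hb) - cv_o2)     [mL O2 / min]
// f(pA) = gas - blood is strictly decreasing in pA, so bisection is safe.
static double solve_comp_o2(double v, double q, double fio2, double pb,
                            double ph2o, double hb, double cv_o2,
                            double tol) {
  double pio2 = fio2 * (pb - ph2o);
  double lo = 1.0, hi = pio2;
  double fhi = v * 1000.0 * (fio2 - hi / (pb - ph2o)) -
               10.0 * q * (content_o2(hi, hb) - cv_o2);
  if (fhi >= 0.0) return hi;  // venous blood richer than inspired equilibrium
  double flo = v * 1000.0 * (fio2 - lo / (pb - ph2o)) -
               10.0 * q * (content_o2(lo, hb) - cv_o2);
  if (flo <= 0.0) return lo;
  while (hi - lo > tol) {
    double mid = 0.5 * (lo + hi);
    double fm = v * 1000.0 * (fio2 - mid / (pb - ph2o)) -
                10.0 * q * (content_o2(mid, hb) - cv_o2);
    if (fm > 0.0) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// Per-compartment steady-state alveolar CO2 balance (inspired CO2 = 0):
//   gas side:   v * 1000 * pA / (pb - ph2o)               [mL CO2 / min]
//   blood side: 10 * q * (cv_co2 - content_co2(pA))       [mL CO2 / min]
// g(pA) = gas - blood is strictly increasing in pA; root clamped to [1, 100].
static double solve_comp_co2(double v, double q, double pb, double ph2o,
                             double cv_co2, double tol) {
  double lo = 1.0, hi = 100.0;
  double glo = v * 1000.0 * lo / (pb - ph2o) -
               10.0 * q * (cv_co2 - content_co2(lo));
  if (glo >= 0.0) return lo;
  double ghi = v * 1000.0 * hi / (pb - ph2o) -
               10.0 * q * (cv_co2 - content_co2(hi));
  if (ghi <= 0.0) return hi;
  while (hi - lo > tol) {
    double mid = 0.5 * (lo + hi);
    double gm = v * 1000.0 * mid / (pb - ph2o) -
                10.0 * q * (cv_co2 - content_co2(mid));
    if (gm < 0.0) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// Fixed-point iteration over mixed-venous contents for the whole lung.
// v_dot/q_dot are per-compartment alveolar ventilation and perfusion
// (L/min); closed compartments have v_dot = 0 and contribute their
// perfusion to the shunted (venous admixture) flow.
// [[Rcpp::export]]
List cpp_steady_state(NumericVector v_dot, NumericVector q_dot,
                      LogicalVector closed, double fs_anat, double q_total,
                      double fio2, double pb, double ph2o, double hb,
                      double vo2, double rq, double tol, int max_iter,
                      double pv_o2_init, double pv_co2_init,
                      double bisect_tol) {
  int n = v_dot.size();
  double cv_o2 = content_o2(pv_o2_init, hb);
  double cv_co2 = content_co2(pv_co2_init);
  double ca_o2 = cv_o2, ca_co2 = cv_co2;
  double q_shunt_anat = fs_anat * q_total;
  NumericVector pa_o2(n, NA_REAL), pa_co2(n, NA_REAL);
  NumericVector cc_o2(n), cc_co2(n);
  bool converged = false;
  int iter = 0;
  // The venous-update map is a contraction (slope ~ total shunt fraction
  // < 1), so undamped iteration converges monotonically and fastest.
  const double relax = 1.0;

  for (iter = 1; iter <= max_iter; ++iter) {
    double flow_c_o2 = 0.0, flow_c_co2 = 0.0, q_shunt_cc = 0.0;
    for (int i = 0; i < n; ++i) {
      if (closed[i] || v_dot[i] <= 0.0) {
        // perfused, not ventilated: blood passes through unchanged
        cc_o2[i] = cv_o2;
        cc_co2[i] = cv_co2;
        pa_o2[i] = NA_REAL;
        pa_co2[i] = NA_REAL;
        q_shunt_cc += q_dot[i];
      } else {
        double po2 = solve_comp_o2(v_dot[i], q_dot[i], fio2, pb, ph2o, hb,
                                   cv_o2, bisect_tol);
        double pco2 = solve_comp_co2(v_dot[i], q_dot[i], pb, ph2o, cv_co2,
                                     bisect_tol);
        pa_o2[i] = po2;
        pa_co2[i] = pco2;
        cc_o2[i] = content_o2(po2, hb);
        cc_co2[i] = content_co2(pco2);
        flow_c_o2 += q_dot[i] * cc_o2[i];
        flow_c_co2 += q_dot[i] * cc_co2[i];
      }
    }
    double q_shunt = q_shunt_anat + q_shunt_cc;
    ca_o2 = (flow_c_o2 + q_shunt * cv_o2) / q_total;
    ca_co2 = (flow_c_co2 + q_shunt * cv_co2) / q_total;

    // Fick principle venous update
    double t_o2 = ca_o2 - vo2 / (10.0 * q_total);
    double t_co2 = ca_co2 + rq * vo2 / (10.0 * q_total);
    if (t_o2 <= 0.05)
      stop("unsustainable VO2: metabolic demand exceeds deliverable O2");

    double d = std::max(std::fabs(t_o2 - cv_o2) / std::max(std::fabs(cv_o2), 1e-6),
                        std::fabs(t_co2 - cv_co2) / std::max(std::fabs(cv_co2), 1e-6));
    if (d < tol) {
      cv_o2 = t_o2;
      cv_co2 = t_co2;
      converged = true;
      break;
    }
    cv_o2 += relax * (t_o2 - cv_o2);
    cv_co2 += relax * (t_co2 - cv_co2);
  }

  // O2 uptake over the gas side; at a true steady state this equals vo2
  double uptake = 0.0, q_shunt_cc = 0.0;
  for (int i = 0; i < n; ++i) {
    if (closed[i] || v_dot[i] <= 0.0) {
      q_shunt_cc += q_dot[i];
    } else {
      uptake += v_dot[i] * 1000.0 * (fio2 - pa_o2[i] / (pb - ph2o));
    }
  }
  bool balance_ok = (vo2 <= 0.0) ||
                    (std::fabs(uptake - vo2) / vo2 <= 0.01);

  double pao2 = invert_content_o2(ca_o2, hb, 1e-3, 800.0, bisect_tol);
  double paco2 = std::max((ca_co2 - 26.7) / 0.45, 0.5);
  double pvo2 = invert_content_o2(cv_o2, hb, 1e-3, 800.0, bisect_tol);

  return List::create(
    _["pao2"] = pao2,
    _["paco2"] = paco2,
    _["sao2"] = sat_o2(pao2),
    _["ph"] = 6.1 + std::log10(24.0 / (0.03 * paco2)),
    _["svo2"] = sat_o2(pvo2),
    _["ca_o2"] = ca_o2,
    _["ca_co2"] = ca_co2,
    _["cv_o2"] = cv_o2,
    _["cv_co2"] = cv_co2,
    _["pa_o2"] = pa_o2,
    _["pa_co2"] = pa_co2,
    _["cc_o2"] = cc_o2,
    _["cc_co2"] = cc_co2,
    _["uptake_o2"] = uptake,
    _["shunt_fraction_total"] = (q_shunt_anat + q_shunt_cc) / q_total,
    _["converged"] = (converged && balance_ok),
    _["n_iter"] = iter > max_iter ? max_iter : iter
  );
}
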