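#include <Rcpp.h>
#include <numeric>
using namespace Rcpp;

// Linear interpolation on a lookup curve, clamped at both ends.
static double interp(double x, const NumericVector& xs, const NumericVector& ys) {
  int n = xs.size();
  if (x <= xs[0]) return ys[0];
  if (x >= xs[n - 1]) return ys[n - 1];
  for (int i = 1; i < n; ++i) {
    if (x <= xs[i]) {
      double w = (x - xs[i - 1]) / (xs[i] - xs[i - 1]);
      return ys[i - 1] + w * (ys[i] - ys[i - 1]);
    }
  }
  return ys[n - 1];
}

static double clamp01(double x) { return x < 0 ? 0 : (x > 1 ? 1 : x); }

// Saturation vapour pressure (kPa), Tetens.
static double svp(double t) { return 0.6108 * exp(17.27 * t / (t + 237.3)); }

// Daily thermal time: trapezoid cardinal response on daily mean temperature,
// base 0 degC, optimum 26 degC (peak 26 degCd/day), maximum 34 degC.
static double daily_tt(double tavg) {
  if (tavg <= 0) return 0;
  if (tavg <= 26) return tavg;
  if (tavg < 34) return 26 * (34 - tavg) / 8.0;
  return 0;
}

// [[Rcpp::export]]
NumericVector thermal_time_cpp(NumericVector tmin, NumericVector tmax) {
  int n = tmin.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = daily_tt(0.5 * (tmin[i] + tmax[i]));
  return out;
}

// Daily surrogate wheat model. All biomass pools in g/m2, water in mm,
// nitrogen in g/m2. Stages: 0 sown, 1 juvenile, 2 floral init->flowering,
// 3 flowering->start grain fill, 4 grain fill, 5 mature.
// [[Rcpp::export]]
List simulate_crop_cpp(NumericVector radn, NumericVector maxt, NumericVector mint,
                       NumericVector rain, NumericVector daylength,
                       int sow_idx, List soil, List mgmt, List pars, List curves,
                       bool return_daily) {
  const int ndays = radn.size();
  const int sow = sow_idx - 1;  // 0-based
  if (sow < 0 || sow >= ndays) stop("sowing index outside weather range");

  // parameters
  const double tt_emerg = as<double>(pars["tt_emerg"]);
  const double tt_juv = as<double>(pars["tt_juv"]);
  const double tt_fi = as<double>(pars["tt_fi"]);
  const double tt_sgf = as<double>(pars["tt_sgf"]);
  const double tt_gf = as<double>(pars["tt_gf"]);
  const double photop_sens = as<double>(pars["photop_sens"]);
  const double vern_sens = as<double>(pars["vern_sens"]);
  const double rue = as<double>(pars["rue"]);
  const double k_ext = as<double>(pars["k_ext"]);
  const double sla = as<double>(pars["sla"]);
  const double te_cf = as<double>(pars["te_cf"]);
  const double ll_mod = as<double>(pars["ll_mod"]);
  const double gpg_stem = as<double>(pars["gpg_stem"]);
  const double pgfr = as<double>(pars["pgfr"]);
  const double max_gs = as<double>(pars["max_gs"]);
  const double frac_pod = as<double>(pars["frac_pod"]);
  const double sen_rate = as<double>(pars["sen_rate"]);
  const double f_co2_rue = as<double>(pars["f_co2_rue"]);
  const double f_co2_te = as<double>(pars["f_co2_te"]);

  NumericVector tgf_x = curves["tgf_x"], tgf_y = curves["tgf_y"];
  NumericVector tgn_x = curves["tgn_x"], tgn_y = curves["tgn_y"];
  NumericVector swd_x = curves["swd_x"], swd_y = curves["swd_y"];

  // soil
  NumericVector thick = soil["thick"], ll = soil["ll"], dul = soil["dul"],
                kl = soil["kl"];
  NumericVector sw = clone(as<NumericVector>(soil["sw0"]));  // mm per layer
  double soil_n = as<double>(soil["no3"]);                   // g/m2 mineral N
  const double mineralisation = as<double>(soil["mineralisation"]);
  const int nl = thick.size();
  std::vector<double> top(nl), ll_mm(nl), dul_mm(nl), lladj_mm(nl);
  double z = 0, pawc = 0;
  for (int j = 0; j < nl; ++j) {
    top[j] = z; z += thick[j];
    ll_mm[j] = ll[j] * thick[j];
    dul_mm[j] = dul[j] * thick[j];
    lladj_mm[j] = ll_mm[j] / ll_mod;  // higher ll_modifier -> more extractable
    pawc += dul_mm[j] - ll_mm[j];
    if (sw[j] < 0 || sw[j] > dul_mm[j] + 1e-9) stop("initial layer water outside [0, DUL]");
  }
  const double profile_depth = z;

  // management: parallel vectors
  NumericVector f_amt = mgmt["amount"];      // g/m2
  IntegerVector f_stage = mgmt["stage"];     // 0 sowing, 1 tillering, 2 stem elongation
  IntegerVector f_cond = mgmt["condition"];  // 0 none, 1 rain>thr, 2 paw_frac>thr, 3 paw_mm>thr
  NumericVector f_thr = mgmt["threshold"];
  std::vector<bool> f_done(f_amt.size(), false);

  // state
  int stage = 0;
  double cum_emerg = 0, cum_juv = 0, cum_fi = 0, cum_sgf = 0, cum_gf = 0, cum_vd = 0;
  double lai = 0, leaf = 0, stem = 0, pod = 0, grain = 0, grain_n = 0;
  double crop_n = 0, grain_no = 0, remob_pool = 0, root_depth = 0;
  double gains_cum = 0, sen_loss = 0;
  double rain_cum = 0, evap_cum = 0, drain_cum = 0, transp_cum = 0;
  const double sw_init = std::accumulate(sw.begin(), sw.end(), 0.0);
  double sdr_sum = 0, fn_sum = 0; int stress_days = 0;
  int flowering_das = NA_INTEGER, maturity_das = NA_INTEGER, emerg_das = NA_INTEGER;
  double lai_flowering = NA_REAL;
  bool failed = false;

  std::vector<double> d_sdr, d_fn, d_lai, d_biom, d_stage, d_das;

  int day = sow;
  for (; day < ndays && stage < 5; ++day) {
    const int das = day - sow;
    const double tavg = 0.5 * (maxt[day] + mint[day]);

    const double dtt = daily_tt(tavg);

    // --- soil water: infiltration, drainage, evaporation -------------------
    rain_cum += rain[day];
    double w = rain[day];
    for (int j = 0; j < nl; ++j) {
      sw[j] += w;
      w = sw[j] > dul_mm[j] ? sw[j] - dul_mm[j] : 0;
      if (w > 0) sw[j] = dul_mm[j];
    }
    drain_cum += w;

    const double cover = 1 - exp(-k_ext * lai);
    double es = (1 - cover) * 0.15 * radn[day];
    double es_max = sw[0] - 0.3 * ll_mm[0];
    if (es_max < 0) es_max = 0;
    if (es > es_max) es = es_max;
    sw[0] -= es;
    evap_cum += es;

    // --- nitrogen supply ----------------------------------------------------
    soil_n += mineralisation;
    double paw = 0;
    for (int j = 0; j < nl; ++j) paw += std::max(0.0, sw[j] - ll_mm[j]);
    for (int k = 0; k < f_amt.size(); ++k) {
      if (f_done[k]) continue;
      bool at_stage =
        (f_stage[k] == 0 && das == 0) ||
        (f_stage[k] == 1 && stage == 1 && cum_juv >= 0.7 * tt_juv) ||
        (f_stage[k] == 2 && stage == 2 && cum_fi >= 0.5 * tt_fi);
      if (!at_stage) continue;
      f_done[k] = true;  // decision point reached: apply only if condition holds
      bool ok = true;
      if (f_cond[k] == 1) ok = rain_cum - rain[day] > f_thr[k];
      else if (f_cond[k] == 2) ok = paw > f_thr[k] * pawc;
      else if (f_cond[k] == 3) ok = paw > f_thr[k];
      if (ok) soil_n += f_amt[k];
    }

    // --- phenology ----------------------------------------------------------
    if (stage == 0) {
      cum_emerg += dtt;
      if (cum_emerg >= tt_emerg) {
        stage = 1; emerg_das = das;
        lai = 0.02; leaf = 1.2; stem = 0.8;
        crop_n = 0.04 * (leaf + stem);
        root_depth = 150;
      }
      if (return_daily) {
        d_das.push_back(das); d_stage.push_back(stage); d_sdr.push_back(1);
        d_fn.push_back(1); d_lai.push_back(lai); d_biom.push_back(0);
      }
      continue;
    }

    if (root_depth < profile_depth && stage <= 2) {
      root_depth += 20;
      if (root_depth > profile_depth) root_depth = profile_depth;
    }

    // --- water supply and demand -------------------------------------------
    double vpd = 0.75 * (svp(maxt[day]) - svp(mint[day]));
    if (vpd < 0.1) vpd = 0.1;
    const double db_pot = radn[day] * cover * rue * f_co2_rue;
    const double demand = db_pot * vpd / (te_cf * f_co2_te);
    double supply = 0;
    std::vector<double> avail(nl, 0.0);
    for (int j = 0; j < nl; ++j) {
      double rf = clamp01((root_depth - top[j]) / thick[j]);
      avail[j] = kl[j] * rf * std::max(0.0, sw[j] - lladj_mm[j]);
      supply += avail[j];
    }
    double transp = std::min(supply, demand);
    if (supply > 0 && transp > 0) {
      for (int j = 0; j < nl; ++j) sw[j] -= transp * avail[j] / supply;
    }
    transp_cum += transp;
    const double ratio = demand > 1e-9 ? supply / demand : 1.0;
    const double sdr = std::min(1.0, ratio);
    const double f_exp = clamp01(interp(ratio, swd_x, swd_y));

    // --- nitrogen uptake and stress ----------------------------------------
    const double b_veg = leaf + stem + pod;
    const double ncrit = 0.015 + 0.025 * exp(-b_veg / 300.0);
    const double nmin = 0.5 * ncrit;
    double n_demand = ncrit * b_veg - crop_n;
    if (n_demand < 0) n_demand = 0;
    double uptake = std::min(n_demand, soil_n * 0.1 * (0.3 + 0.7 * sdr));
    crop_n += uptake; soil_n -= uptake;
    const double conc = b_veg > 0 ? crop_n / b_veg : ncrit;
    const double fn = clamp01((conc - nmin) / (ncrit - nmin));

    // --- growth -------------------------------------------------------------
    const double db_rue = radn[day] * cover * rue * std::min(sdr, fn) * f_co2_rue;
    const double db_te = vpd > 0 ? transp * te_cf * f_co2_te / vpd : db_rue;
    double gain = std::min(db_rue, db_te);
    if (gain < 0) gain = 0;
    gains_cum += gain;

    double leaf_frac = stage == 1 ? 0.5 : (stage == 2 ? 0.25 : 0.0);
    double to_leaf = gain * leaf_frac;
    leaf += to_leaf;
    double rest = gain - to_leaf;

    // --- grain filling ------------------------------------------------------
    double fill = 0;
    if (stage == 4) {
      const double f_tgf = clamp01(interp(tavg, tgf_x, tgf_y));
      double pot = grain_no * pgfr * dtt * f_tgf;
      const double head_room = grain_no * max_gs - grain;
      if (pot > head_room) pot = head_room > 0 ? head_room : 0;
      fill = std::min(pot, rest + remob_pool);
      double from_assim = std::min(fill, rest);
      double from_remob = fill - from_assim;
      rest -= from_assim;
      remob_pool -= from_remob;
      stem -= from_remob;
      grain += fill;
      // nitrogen transfer to grain
      const double f_tgn = clamp01(interp(tavg, tgn_x, tgn_y));
      double n_pot = crop_n * 0.02 * f_tgn;
      double n_need = grain * 0.025 - grain_n;
      if (n_need < 0) n_need = 0;
      double n_fill = std::min(n_pot, n_need);
      grain_n += n_fill; crop_n -= n_fill;
    }
    // head (spike/rachis) growth competes with stem from floral initiation on
    if (stage >= 2) {
      pod += rest * frac_pod;
      stem += rest * (1 - frac_pod);
    } else {
      stem += rest;
    }

    // --- leaf area ----------------------------------------------------------
    lai += to_leaf * sla * f_exp;
    double sen = 0;
    if (stage >= 3) sen = lai * sen_rate * (1 + 2 * (1 - sdr));
    else if (sdr < 0.3) sen = lai * sen_rate * (0.3 - sdr) / 0.3;
    lai -= sen;
    if (lai < 0) lai = 0;

    // --- phase advance ------------------------------------------------------
    if (stage == 1) {
      const double dl = daylength[day];
      const double fp = clamp01(1 - 0.002 * photop_sens * (20 - dl) * (20 - dl));
      double dv = 0;
      if (tavg > 0 && tavg < 15) dv = 1;
      else if (tavg >= 15 && tavg < 18) dv = 0.5;
      cum_vd = std::min(50.0, cum_vd + dv);
      const double fv = clamp01(1 - (0.0054545 * vern_sens + 0.0003) * (50 - cum_vd));
      cum_juv += dtt * std::min(fp, fv);
      if (cum_juv >= tt_juv) stage = 2;
    } else if (stage == 2) {
      cum_fi += dtt;
      if (cum_fi >= tt_fi) {
        stage = 3;
        flowering_das = das;
        lai_flowering = lai;
        grain_no = gpg_stem * stem;
        remob_pool = 0.25 * (stem + pod);
      }
    } else if (stage == 3) {
      cum_sgf += dtt;
      if (cum_sgf >= tt_sgf) stage = 4;
    } else if (stage == 4) {
      cum_gf += dtt;
      if (cum_gf >= tt_gf) { stage = 5; maturity_das = das; }
    }

    sdr_sum += sdr; fn_sum += fn; ++stress_days;
    if (return_daily) {
      d_das.push_back(das); d_stage.push_back(stage); d_sdr.push_back(sdr);
      d_fn.push_back(fn); d_lai.push_back(lai);
      d_biom.push_back(leaf + stem + pod + grain);
    }
  }

  if (stage < 5) failed = true;  // never emerged or season ran out
  if (emerg_das == NA_INTEGER || flowering_das == NA_INTEGER) failed = true;

  double grain_size = grain_no > 0 ? grain / grain_no : 0;
  double yield_t = grain * 0.01;      // g/m2 -> t/ha
  double biomass_t = (leaf + stem + pod + grain) * 0.01;
  double protein = grain > 1e-9 ? 100 * 5.7 * grain_n / grain : 0;
  if (protein > 25) protein = 25;
  if (failed) { yield_t = 0; }
  double wstress = stress_days > 0 ? clamp01(1 - sdr_sum / stress_days) : 1;
  double nstress = stress_days > 0 ? clamp01(1 - fn_sum / stress_days) : 1;
  const double sw_final = std::accumulate(sw.begin(), sw.end(), 0.0);

  List out = List::create(
    _["flowering_das"] = flowering_das, _["maturity_das"] = maturity_das,
    _["lai_flowering"] = lai_flowering, _["biomass"] = biomass_t,
    _["grain_number"] = grain_no, _["grain_size"] = grain_size,
    _["grain_protein"] = protein, _["yield"] = yield_t,
    _["water_stress"] = wstress, _["nitrogen_stress"] = nstress,
    _["failed"] = failed,
    _["audit"] = List::create(
      _["gains_cum"] = gains_cum * 0.01, _["sen_loss"] = sen_loss * 0.01,
      _["biomass_init"] = (emerg_das == NA_INTEGER ? 0.0 : 0.02),
      _["sw_init"] = sw_init, _["sw_final"] = sw_final,
      _["rain"] = rain_cum, _["evaporation"] = evap_cum,
      _["transpiration"] = transp_cum, _["drainage"] = drain_cum)
  );
  if (return_daily) {
    out["daily"] = DataFrame::create(
      _["das"] = d_das, _["stage"] = d_stage, _["sd_ratio"] = d_sdr,
      _["n_factor"] = d_fn, _["lai"] = d_lai, _["biomass"] = d_biom);
  }
  return out;
}
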