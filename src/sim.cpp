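// Blinking-emitter simulator: continuous-time photokinetic traces and
// camera-frame rendering with an EMCCD noise model.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Continuous-time four-state kinetics: inactive -> on (activation),
// on <-> dark (blinking), on -> bleached. Exposure-integrated on-time per
// frame gives the expected photon count I_on * (fraction of frame on).
// Frames are contiguous: frame k covers [k*dt, (k+1)*dt).
// [[Rcpp::export]]
DataFrame cpp_simulate_traces(int n_emitters, int n_frames, double exposure,
                              double k_act, double k_off, double k_on,
                              double k_bl, double i_on,
                              double p_preactivated) {
  std::vector<int> v_em, v_fr;
  std::vector<double> v_ph;
  const double T = n_frames * exposure;
  std::vector<double> onfrac(n_frames);
  for (int e = 0; e < n_emitters; ++e) {
    std::fill(onfrac.begin(), onfrac.end(), 0.0);
    double t = 0.0;
    // state: 0 inactive, 1 on, 2 dark, 3 bleached
    int state = (unif_rand() < p_preactivated) ? 1 : 0;
    while (t < T && state != 3) {
      double rate;
      int next;
      if (state == 0) {
        rate = k_act;
        next = 1;
      } else if (state == 1) {
        rate = k_off + k_bl;
        next = -1;  // decided below
      } else {
        rate = k_on;
        next = 1;
      }
      double dwell = (rate > 0.0) ? exp_rand() / rate : R_PosInf;
      double t_end = std::min(t + dwell, T);
      if (state == 1 && t_end > t) {
        // accumulate on-time over the frames covered by [t, t_end)
        int f0 = (int)std::floor(t / exposure);
        int f1 = (int)std::floor((t_end - 1e-12) / exposure);
        if (f1 >= n_frames) f1 = n_frames - 1;
        for (int f = f0; f <= f1; ++f) {
          double a = std::max(t, f * exposure);
          double b = std::min(t_end, (f + 1) * exposure);
          if (b > a) onfrac[f] += (b - a) / exposure;
        }
      }
      t = t + dwell;
      if (t >= T) break;
      if (state == 1) {
        double u = unif_rand() * (k_off + k_bl);
        state = (u < k_bl) ? 3 : 2;
      } else {
        state = next;
      }
    }
    for (int f = 0; f < n_frames; ++f) {
      if (onfrac[f] > 0.0) {
        v_em.push_back(e + 1);
        v_fr.push_back(f + 1);
        v_ph.push_back(i_on * onfrac[f]);
      }
    }
  }
  return DataFrame::create(_["emitter"] = v_em, _["frame"] = v_fr,
                           _["photons"] = v_ph);
}

static inline double pixel_mass_1d(double lo, double hi, double mu,
                                   double sigma) {
  const double s = sigma * M_SQRT2;
  return 0.5 * (std::erf((hi - mu) / s) - std::erf((lo - mu) / s));
}

// Render frames from emitter positions and sparse photon traces.
// positions in nm; traces must be restricted to frames [frame0, frame0+nt).
// Returns counts array (ny, nx, nt). With noise = false the output is the
// noiseless expectation gain*(QE*photons + dark) + offset.
// [[Rcpp::export]]
NumericVector cpp_render_frames(NumericMatrix positions, IntegerVector tr_em,
                                IntegerVector tr_fr, NumericVector tr_ph,
                                int frame0, int nt, int ny, int nx,
                                double pixel, double sigma, double qe,
                                double gain, double read_noise, double dark,
                                double excess, double offset, bool noise,
                                double bg_photons) {
  NumericVector out(ny * (R_xlen_t)nx * nt);
  std::vector<double> expected(ny * (R_xlen_t)nx);
  const double trunc = 5.0 * sigma;
  R_xlen_t k = 0;
  const R_xlen_t ntr = tr_em.size();
  for (int t = 0; t < nt; ++t) {
    std::fill(expected.begin(), expected.end(), 0.0);
    const int frame = frame0 + t;
    // traces are sorted by frame; advance to this frame
    while (k < ntr && tr_fr[k] < frame) ++k;
    R_xlen_t k2 = k;
    while (k2 < ntr && tr_fr[k2] == frame) {
      const int e = tr_em[k2] - 1;
      const double ph = tr_ph[k2];
      const double x = positions(e, 0), y = positions(e, 1);
      int j0 = std::max(0, (int)std::floor((x - trunc) / pixel));
      int j1 = std::min(nx - 1, (int)std::floor((x + trunc) / pixel));
      int i0 = std::max(0, (int)std::floor((y - trunc) / pixel));
      int i1 = std::min(ny - 1, (int)std::floor((y + trunc) / pixel));
      for (int j = j0; j <= j1; ++j) {
        double mx = pixel_mass_1d(j * pixel, (j + 1) * pixel, x, sigma);
        if (mx <= 0) continue;
        for (int i = i0; i <= i1; ++i) {
          double my = pixel_mass_1d(i * pixel, (i + 1) * pixel, y, sigma);
          expected[i + (R_xlen_t)ny * j] += ph * mx * my;
        }
      }
      ++k2;
    }
    k = k2;
    double *frame_out = &out[(R_xlen_t)ny * nx * t];
    const double exf = std::sqrt(std::max(excess * excess - 1.0, 0.0));
    for (R_xlen_t p = 0; p < (R_xlen_t)ny * nx; ++p) {
      double mu = qe * (expected[p] + bg_photons) + dark;
      double val;
      if (noise) {
        double npe = R::rpois(mu);
        val = gain * npe + offset;
        if (exf > 0.0 && npe > 0.0)
          val += gain * std::sqrt(npe) * exf * norm_rand();
        if (read_noise > 0.0) val += read_noise * norm_rand();
        val = std::round(val);
        if (val < 0.0) val = 0.0;
        if (val > 65535.0) val = 65535.0;
      } else {
        val = gain * mu + offset;
      }
      frame_out[p] = val;
    }
  }
  out.attr("dim") = IntegerVector::create(ny, nx, nt);
  return out;
}

// Noiseless expected photo-electron image (no camera) of static emitters
// with given per-emitter photon weights; used for widefield references.
// [[Rcpp::export]]
NumericMatrix cpp_render_static(NumericMatrix positions, NumericVector weights,
                                int ny, int nx, double pixel, double sigma) {
  NumericMatrix out(ny, nx);
  const double trunc = 5.0 * sigma;
  for (int e = 0; e < positions.nrow(); ++e) {
    const double x = positions(e, 0), y = positions(e, 1);
    const double w = weights[e];
    int j0 = std::max(0, (int)std::floor((x - trunc) / pixel));
    int j1 = std::min(nx - 1, (int)std::floor((x + trunc) / pixel));
    int i0 = std::max(0, (int)std::floor((y - trunc) / pixel));
    int i1 = std::min(ny - 1, (int)std::floor((y + trunc) / pixel));
    for (int j = j0; j <= j1; ++j) {
      double mx = pixel_mass_1d(j * pixel, (j + 1) * pixel, x, sigma);
      if (mx <= 0) continue;
      for (int i = i0; i <= i1; ++i) {
        double my = pixel_mass_1d(i * pixel, (i + 1) * pixel, y, sigma);
        out(i, j) += w * mx * my;
      }
    }
  }
  return out;
}
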