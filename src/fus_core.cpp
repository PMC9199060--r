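#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Linear interpolation of a uniformly sampled signal w (sample 0 at t = 0,
// rate fs). Times outside the record contribute 0.
static inline double interp_at(const double* w, const int n, const double t,
                               const double fs) {
  const double u = t * fs;
  if (u < 0.0 || u > n - 1) return 0.0;
  const int i = (int)std::floor(u);
  if (i >= n - 1) return w[n - 1];
  const double f = u - i;
  return w[i] * (1.0 - f) + w[i + 1] * f;
}

static inline double spread(const double r, const double rmin) {
  return 1.0 / std::max(r, rmin);
}

// strip-element directivity: D(theta) = sinc(w sin(theta)/lambda) cos(theta)
// with sin(theta) = |dx|/r; dir_wl = w/lambda (0 disables, omni element)
static inline double directivity(const double dx, const double z,
                                 const double r, const double dir_wl) {
  if (dir_wl <= 0.0 || r <= 0.0) return 1.0;
  const double s = std::fabs(dx) / r;
  const double x = dir_wl * s;
  const double sinc = (x < 1e-9) ? 1.0 : std::sin(M_PI * x) / (M_PI * x);
  return sinc * (z / r); // cos(theta) = z/r
}

// Per-scatterer incident pressure trace: superposition of every transmit
// element's delayed, 1/r-weighted waveform replica at the scatterer.
// Returns the trace in buf (sampled at fs, first sample at *t_start).
static void incident_trace(const double sx, const double sz,
                           const NumericVector& ex,
                           const NumericVector& txd,
                           const NumericVector& apod,
                           const NumericVector& wave, const double fs,
                           const double c, const double rmin,
                           const double dir_wl,
                           std::vector<double>& buf, double* t_start,
                           std::vector<double>& r_cache) {
  const int ne = ex.size(), nw = wave.size();
  double tmin = R_PosInf, tmax = R_NegInf;
  for (int i = 0; i < ne; ++i) {
    const double dx = sx - ex[i];
    const double r = std::sqrt(dx * dx + sz * sz);
    r_cache[i] = r;
    const double a = txd[i] + r / c;
    if (a < tmin) tmin = a;
    if (a > tmax) tmax = a;
  }
  const double dur = (tmax - tmin) + (nw - 1) / fs;
  const int np = (int)std::ceil(dur * fs) + 2;
  buf.assign(np, 0.0);
  for (int i = 0; i < ne; ++i) {
    const double off = (txd[i] + r_cache[i] / c - tmin) * fs; // samples
    const double g = apod[i] * spread(r_cache[i], rmin) *
      directivity(sx - ex[i], sz, r_cache[i], dir_wl);
    if (g == 0.0) continue;
    const int n0 = (int)std::ceil(off);
    const int n1 = std::min(np - 1, (int)std::floor(off + nw - 1));
    for (int n = n0; n <= n1; ++n) {
      buf[n] += g * interp_at(&wave[0], nw, (n - off) / fs, fs);
    }
  }
  *t_start = tmin;
}

// wave is sampled at fs_sim (an oversampled copy of the excitation);
// the simulation runs internally at fs_sim while rf is emitted at the
// acquisition rate fs.
// [[Rcpp::export(name = ".cpp_synthesize_rf")]]
NumericMatrix cpp_synthesize_rf(NumericVector scat_x, NumericVector scat_z,
                                NumericVector amp, NumericVector elem_x,
                                NumericVector tx_delays,
                                NumericVector tx_apod, NumericVector wave,
                                double fs, double fs_sim, double c,
                                double rmin, double dir_wl, int n_samples,
                                double t0) {
  const int ns = scat_x.size(), ne = elem_x.size();
  // time-major layout so echo writes are contiguous; transposed in R
  NumericMatrix rft(n_samples, ne);
  std::vector<double> buf;
  std::vector<double> r_cache(ne);
  for (int s = 0; s < ns; ++s) {
    if (amp[s] == 0.0) continue;
    double tstart;
    incident_trace(scat_x[s], scat_z[s], elem_x, tx_delays, tx_apod, wave,
                   fs_sim, c, rmin, dir_wl, buf, &tstart, r_cache);
    const int np = (int)buf.size();
    const double dur = (np - 1) / fs_sim;
    const double step = fs_sim / fs; // fine samples per rf sample
    for (int j = 0; j < ne; ++j) {
      const double dx = scat_x[s] - elem_x[j];
      const double rj = std::sqrt(dx * dx + scat_z[s] * scat_z[s]);
      const double gain = amp[s] * spread(rj, rmin) *
        directivity(dx, scat_z[s], rj, dir_wl);
      // echo trace starts at tstart + rj/c on the acquisition clock
      const double arr = tstart + rj / c - t0; // seconds
      int m0 = (int)std::ceil(arr * fs);
      int m1 = (int)std::floor((arr + dur) * fs);
      if (m0 < 0) m0 = 0;
      if (m1 > n_samples - 1) m1 = n_samples - 1;
      double* col = &rft[(size_t)n_samples * j];
      double u = (m0 / fs - arr) * fs_sim; // fractional fine-sample index
      for (int m = m0; m <= m1; ++m, u += step) {
        const int i = (int)u;
        if (u >= 0.0 && i < np - 1) {
          const double f = u - i;
          col[m] += gain * (buf[i] * (1.0 - f) + buf[i + 1] * f);
        } else if (i == np - 1 && u <= np - 1) {
          col[m] += gain * buf[np - 1];
        }
      }
    }
  }
  return rft;
}

// [[Rcpp::export(name = ".cpp_incident_intensity")]]
NumericMatrix cpp_incident_intensity(NumericVector elem_x,
                                     NumericVector tx_delays,
                                     NumericVector tx_apod,
                                     NumericVector wave, double fs, double c,
                                     double rmin, double dir_wl,
                                     NumericVector grid_x,
                                     NumericVector grid_z) {
  const int nx = grid_x.size(), nz = grid_z.size();
  NumericMatrix field(nz, nx);
  std::vector<double> buf;
  std::vector<double> r_cache(elem_x.size());
  for (int ix = 0; ix < nx; ++ix) {
    for (int iz = 0; iz < nz; ++iz) {
      double tstart;
      incident_trace(grid_x[ix], grid_z[iz], elem_x, tx_delays, tx_apod,
                     wave, fs, c, rmin, dir_wl, buf, &tstart, r_cache);
      double acc = 0.0;
      for (size_t n = 0; n < buf.size(); ++n) acc += buf[n] * buf[n];
      field(iz, ix) = acc;
    }
  }
  return field;
}

// Symmetric Hann window value at index i of length N (rectangular for
// N <= 2, where the symmetric form degenerates to zeros).
static inline double hann_w(const int i, const int N) {
  if (N <= 2) return 1.0;
  return 0.5 - 0.5 * std::cos(2.0 * M_PI * i / (N - 1));
}

// DAS beamformer with dynamic receive focusing, dynamic f-number aperture,
// Hann apodization and optional GCF weighting.
//
// rf:      n_elem x n_samples channel data
// tau_tx:  n_z x n_x per-pixel transmit (one-way) delay to the pixel
// Per-channel delay: tau_tx[z,x] + sqrt(z^2 + (x - elem_x[k])^2)/c.
// [[Rcpp::export(name = ".cpp_das")]]
List cpp_das(NumericMatrix rf, double t0, double fs, NumericVector elem_x,
             NumericMatrix tau_tx, NumericVector grid_x, NumericVector grid_z,
             double c, double f_number, int M, bool use_gcf) {
  const int ne = elem_x.size(), nt = rf.ncol();
  const int nx = grid_x.size(), nz = grid_z.size();
  const double pitch = ne > 1 ? elem_x[1] - elem_x[0] : 1.0;
  NumericMatrix y(nz, nx), gcf_img(nz, nx);
  IntegerMatrix nsub(nz, nx);
  std::vector<double> s(ne);
  for (int ix = 0; ix < nx; ++ix) {
    const double x = grid_x[ix];
    // element nearest the pixel's lateral position (half rounds up, as in
    // the R reference route)
    int ic = (int)std::floor((x - elem_x[0]) / pitch + 0.5);
    if (ic < 0) ic = 0;
    if (ic > ne - 1) ic = ne - 1;
    for (int iz = 0; iz < nz; ++iz) {
      const double z = grid_z[iz];
      const int k = (int)std::floor((z / f_number) / (2.0 * pitch));
      const int i0 = std::max(0, ic - k);
      const int i1 = std::min(ne - 1, ic + k);
      const int N = i1 - i0 + 1;
      const double ttx = tau_tx(iz, ix);
      double ssum = 0.0, das = 0.0;
      for (int i = i0; i <= i1; ++i) {
        const double dx = x - elem_x[i];
        const double tau = ttx + std::sqrt(z * z + dx * dx) / c;
        // rf is column-major with ne rows: sample m of channel i at rf[i+ne*m]
        const double u = (tau - t0) * fs;
        double sv = 0.0;
        if (u >= 0.0 && u <= nt - 1) {
          const int m = (int)std::floor(u);
          const double f = u - m;
          const double a = rf[i + (size_t)ne * m];
          const double b = (m < nt - 1) ? rf[i + (size_t)ne * (m + 1)] : a;
          sv = a * (1.0 - f) + b * f;
        }
        s[i - i0] = sv;
        ssum += sv * sv;
        das += hann_w(i - i0, N) * sv;
      }
      double g = 1.0;
      if (use_gcf) {
        if (N == 1) {
          g = 1.0;
        } else if (ssum <= 0.0) {
          g = 0.0;
        } else {
          const int Meff = std::min(M, (N - 1) / 2);
          // real input: |S[-k]| = |S[k]|
          double num = 0.0;
          for (int kk = 0; kk <= Meff; ++kk) {
            double re = 0.0, im = 0.0;
            const double w0 = 2.0 * M_PI * kk / N;
            for (int n = 0; n < N; ++n) {
              re += s[n] * std::cos(w0 * n);
              im -= s[n] * std::sin(w0 * n);
            }
            num += (kk == 0 ? 1.0 : 2.0) * (re * re + im * im);
          }
          g = num / (N * ssum);
          if (g > 1.0) g = 1.0; // round-off guard at the Parseval bound
        }
        y(iz, ix) = g * das;
        gcf_img(iz, ix) = g;
      } else {
        y(iz, ix) = das;
        gcf_img(iz, ix) = 1.0;
      }
      nsub(iz, ix) = N;
    }
  }
  return List::create(_["y"] = y, _["gcf"] = gcf_img, _["nsub"] = nsub);
}
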