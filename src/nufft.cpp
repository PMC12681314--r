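// Kaiser-Bessel gridding NUFFT (type 2 forward / type 1 adjoint) on a 2x
// oversampled Cartesian grid.  Conventions (shared with the R layer):
//   forward:  s(k) = sum_r x(r) exp(-2*pi*i k.r),  r integer pixel offsets
//             centred at the grid midpoint (zero-based index N/2), k in
//             cycles/pixel;
//   adjoint:  exact conjugate-transpose of the forward map (no 1/N^2), so the
//             inner-product identity <Fx, y> = <x, F^H y> holds to rounding.
// Deapodisation uses the analytic Fourier transform of the KB kernel, so
// accuracy is governed only by kernel width/beta (Beatty's choice).
// Interpolation indices/weights can be precomputed once per trajectory
// ("plan") and reused across images and solver iterations.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cmath>

using namespace arma;

static inline double kb_i0(double x) {
  // modified Bessel I0; series/asymptotic hybrid (Abramowitz & Stegun 9.8)
  double ax = std::fabs(x);
  if (ax < 3.75) {
    double t = x / 3.75, t2 = t * t;
    return 1.0 + t2 * (3.5156229 + t2 * (3.0899424 + t2 * (1.2067492 +
           t2 * (0.2659732 + t2 * (0.0360768 + t2 * 0.0045813)))));
  }
  double t = 3.75 / ax;
  return (std::exp(ax) / std::sqrt(ax)) *
         (0.39894228 + t * (0.01328592 + t * (0.00225319 + t * (-0.00157565 +
          t * (0.00916281 + t * (-0.02057706 + t * (0.02635537 +
          t * (-0.01647633 + t * 0.00392377))))))));
}

static inline double kb_kernel(double u, double width, double beta) {
  double t = 2.0 * u / width;
  double arg = 1.0 - t * t;
  if (arg < 0.0) return 0.0;
  return kb_i0(beta * std::sqrt(arg));
}

// analytic FT of the (unnormalised) KB kernel at image frequency f = p/G
static inline double kb_apod(double f, double width, double beta) {
  double arg = beta * beta - M_PI * M_PI * width * width * f * f;
  if (arg > 0.0) {
    double s = std::sqrt(arg);
    return width * std::sinh(s) / s;
  }
  double s = std::sqrt(-arg);
  if (s < 1e-12) return width;
  return width * std::sin(s) / s;
}

static vec apod_vector(int n, int grid, double width, double beta) {
  vec a(n);
  for (int i = 0; i < n; ++i) {
    double f = (double)(i - n / 2) / (double)grid;
    a(i) = kb_apod(f, width, beta);
  }
  return a;
}

static inline int imod(int a, int m) {
  int r = a % m;
  return r < 0 ? r + m : r;
}

// Precompute per-sample interpolation indices and weights.
// [[Rcpp::export]]
Rcpp::List cpp_nufft_plan(const arma::mat& coords, int n, int osf, int width,
                          double beta) {
  const int grid = osf * n;
  const int K = coords.n_rows;
  // width x K layout: one contiguous column per sample
  imat i1(width, K), i2(width, K);
  mat w1(width, K), w2(width, K);
  for (int k = 0; k < K; ++k) {
    double u = coords(k, 0) * grid;
    double v = coords(k, 1) * grid;
    int g1 = (int)std::ceil(u - width / 2.0);
    int g2 = (int)std::ceil(v - width / 2.0);
    for (int t = 0; t < width; ++t) {
      w1(t, k) = kb_kernel(u - (g1 + t), width, beta);
      i1(t, k) = imod(g1 + t, grid);
      w2(t, k) = kb_kernel(v - (g2 + t), width, beta);
      i2(t, k) = imod(g2 + t, grid);
    }
  }
  return Rcpp::List::create(Rcpp::Named("i1") = i1, Rcpp::Named("i2") = i2,
                            Rcpp::Named("w1") = w1, Rcpp::Named("w2") = w2);
}

// [[Rcpp::export]]
arma::cx_mat cpp_nufft_forward(const arma::cx_cube& images,
                               const arma::imat& i1, const arma::imat& i2,
                               const arma::mat& w1, const arma::mat& w2,
                               int osf, int width, double beta) {
  const int n = images.n_rows;
  const int m = images.n_slices;
  const int grid = osf * n;
  const int K = i1.n_cols;
  const vec apod = apod_vector(n, grid, width, beta);
  cx_mat out(K, m);
  cx_mat padded(grid, grid);

  for (int s = 0; s < m; ++s) {
    padded.zeros();
    for (int j = 0; j < n; ++j) {
      int cj = imod(j - n / 2, grid);
      for (int i = 0; i < n; ++i) {
        padded(imod(i - n / 2, grid), cj) = images(i, j, s) / (apod(i) * apod(j));
      }
    }
    cx_mat spec = arma::fft2(padded);
    const std::complex<double>* sp = spec.memptr();
    for (int k = 0; k < K; ++k) {
      const double* w1k = w1.colptr(k);
      const double* w2k = w2.colptr(k);
      const sword* i1k = i1.colptr(k);
      const sword* i2k = i2.colptr(k);
      std::complex<double> acc(0.0, 0.0);
      for (int b = 0; b < width; ++b) {
        if (w2k[b] == 0.0) continue;
        const std::complex<double>* col = sp + (size_t)i2k[b] * grid;
        std::complex<double> row(0.0, 0.0);
        for (int a = 0; a < width; ++a) {
          if (w1k[a] != 0.0) row += w1k[a] * col[i1k[a]];
        }
        acc += w2k[b] * row;
      }
      out(k, s) = acc;
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cx_cube cpp_nufft_adjoint(const arma::cx_mat& samples,
                                const arma::imat& i1, const arma::imat& i2,
                                const arma::mat& w1, const arma::mat& w2,
                                int n, int osf, int width, double beta,
                                const arma::vec& weights) {
  const int m = samples.n_cols;
  const int grid = osf * n;
  const int K = i1.n_cols;
  const bool use_w = weights.n_elem > 0;
  const vec apod = apod_vector(n, grid, width, beta);
  const double g2scale = (double)grid * (double)grid;
  cx_cube out(n, n, m);
  cx_mat grid_ks(grid, grid);

  for (int s = 0; s < m; ++s) {
    grid_ks.zeros();
    std::complex<double>* gp = grid_ks.memptr();
    for (int k = 0; k < K; ++k) {
      std::complex<double> val = samples(k, s);
      if (use_w) val *= weights(k);
      const double* w1k = w1.colptr(k);
      const double* w2k = w2.colptr(k);
      const sword* i1k = i1.colptr(k);
      const sword* i2k = i2.colptr(k);
      for (int b = 0; b < width; ++b) {
        if (w2k[b] == 0.0) continue;
        std::complex<double>* col = gp + (size_t)i2k[b] * grid;
        std::complex<double> vb = w2k[b] * val;
        for (int a = 0; a < width; ++a) {
          if (w1k[a] != 0.0) col[i1k[a]] += w1k[a] * vb;
        }
      }
    }
    cx_mat img = arma::ifft2(grid_ks) * g2scale;  // unnormalised inverse DFT
    for (int j = 0; j < n; ++j) {
      int cj = imod(j - n / 2, grid);
      for (int i = 0; i < n; ++i) {
        out(i, j, s) = img(imod(i - n / 2, grid), cj) / (apod(i) * apod(j));
      }
    }
  }
  return out;
}
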