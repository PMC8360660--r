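#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Joint log-likelihood grid for Bayesian quantal analysis.
//
// Component density for k released sites: sum of k iid gamma quantal
// amplitudes (mean q, CV cv) plus Gaussian baseline noise.  The gamma
// convolution is evaluated exactly by Gauss-Hermite quadrature over the
// noise when the gamma shape parameter k/cv^2 is small (skewed component);
// for large shape the component is effectively normal and the
// moment-matched normal is used.  The release probability p is
// marginalized per condition over a uniform grid.

static const double GH_X[8] = {
  -2.930637420257244, -1.981656756695843, -1.157193712446780,
  -0.381186990207322,  0.381186990207322,  1.157193712446780,
   1.981656756695843,  2.930637420257244};
static const double GH_W[8] = {
  1.996040722113676e-04, 1.707798300741347e-02, 2.078023258148919e-01,
  6.611470125582413e-01, 6.611470125582413e-01, 2.078023258148919e-01,
  1.707798300741347e-02, 1.996040722113676e-04};
// weights above are for integral w.r.t. exp(-x^2); normalize by 1/sqrt(pi)
static const double INV_SQRT_PI = 0.5641895835477563;
static const double INV_SQRT_2PI = 0.3989422804014327;

static inline double dgamma_ls(double x, double shape, double scale,
                               double lgam_shape) {
  if (x <= 0.0) return 0.0;
  double lx = std::log(x);
  return std::exp((shape - 1.0) * lx - x / scale -
                  shape * std::log(scale) - lgam_shape);
}

// [[Rcpp::export]]
NumericVector bqa_loglik_cpp(List amps, int n_max, NumericVector q_grid,
                             NumericVector p_grid, NumericVector cv_grid,
                             NumericVector noise_grid,
                             double shape_normal_threshold) {
  int n_cond = amps.size();
  int n_q = q_grid.size(), n_p = p_grid.size();
  int n_cv = cv_grid.size(), n_sg = noise_grid.size();
  std::vector<std::vector<double>> y(n_cond);
  for (int c = 0; c < n_cond; ++c)
    y[c] = as<std::vector<double>>(amps[c]);

  NumericVector ll(n_max * n_q * n_cv * n_sg);
  std::vector<double> W((n_max + 1) * n_p);
  std::vector<double> llp(n_p);

  for (int N = 1; N <= n_max; ++N) {
    int K = N + 1;
    // binomial weights W[k + K*ip]
    for (int ip = 0; ip < n_p; ++ip) {
      double p = p_grid[ip];
      for (int k = 0; k < K; ++k)
        W[k + K * ip] = R::dbinom(k, N, p, 0);
    }
    for (int icv = 0; icv < n_cv; ++icv) {
      double cv = cv_grid[icv];
      double shape1 = (cv > 0) ? 1.0 / (cv * cv) : 0.0;
      for (int isg = 0; isg < n_sg; ++isg) {
        double sg = noise_grid[isg];
        for (int iq = 0; iq < n_q; ++iq) {
          double q = q_grid[iq];
          double scale = (cv > 0) ? q * cv * cv : 0.0;
          double total = 0.0;
          for (int c = 0; c < n_cond; ++c) {
            const std::vector<double> &yy = y[c];
            int nt = (int)yy.size();
            // component densities D[t + nt*k]
            std::vector<double> D(nt * K);
            for (int t = 0; t < nt; ++t)
              D[t] = INV_SQRT_2PI / sg *
                std::exp(-0.5 * yy[t] * yy[t] / (sg * sg));
            for (int k = 1; k < K; ++k) {
              double sh = k * shape1;
              if (cv == 0.0 || sh > shape_normal_threshold) {
                double mu = k * q;
                double vr = sg * sg + k * q * q * cv * cv;
                double sd = std::sqrt(vr);
                for (int t = 0; t < nt; ++t) {
                  double z = (yy[t] - mu) / sd;
                  D[t + nt * k] = INV_SQRT_2PI / sd * std::exp(-0.5 * z * z);
                }
              } else {
                double lgam = std::lgamma(sh);
                for (int t = 0; t < nt; ++t) {
                  double acc = 0.0;
                  for (int m = 0; m < 8; ++m) {
                    double arg = yy[t] - M_SQRT2 * sg * GH_X[m];
                    acc += GH_W[m] * dgamma_ls(arg, sh, scale, lgam);
                  }
                  D[t + nt * k] = acc * INV_SQRT_PI;
                }
              }
            }
            // log-likelihood per p, then log-mean-exp over the p grid
            for (int ip = 0; ip < n_p; ++ip) {
              double s = 0.0;
              for (int t = 0; t < nt; ++t) {
                double m = 0.0;
                for (int k = 0; k < K; ++k)
                  m += D[t + nt * k] * W[k + K * ip];
                s += std::log(m > 1e-300 ? m : 1e-300);
              }
              llp[ip] = s;
            }
            double mx = llp[0];
            for (int ip = 1; ip < n_p; ++ip) if (llp[ip] > mx) mx = llp[ip];
            double acc = 0.0;
            for (int ip = 0; ip < n_p; ++ip) acc += std::exp(llp[ip] - mx);
            total += mx + std::log(acc / n_p);
          }
          ll[(N - 1) + n_max * (iq + n_q * (icv + n_cv * isg))] = total;
        }
      }
    }
  }
  ll.attr("dim") = IntegerVector::create(n_max, n_q, n_cv, n_sg);
  return ll;
}
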