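// Slice-within-Gibbs sampler for the full-likelihood vaccine-efficacy model.
//
// Coordinates are logit transforms of bounded quantities:
//   z1 = logit(u),          u = (1 - VE) / (2 - VE)   (VE support (-inf, 1))
//   z2 = logit(pi_c)
//   z3 = logit(mu_c / D),   z4 = logit(sigma2_c / D^2)
//   z5 = logit(mu_v / D),   z6 = logit(sigma2_v / D^2)
// The target includes the Beta(a0, 1) prior on u and the logistic Jacobians;
// the uniform nuisance priors contribute only constants. Each coordinate is
// updated by univariate stepping-out slice sampling (Neal 2003), which needs
// no tuning and decorrelates fast enough that the published thinning leaves
// near-independent draws.
//
// Invalid parameter points (vaccine-arm infection probability outside (0,1),
// non-positive conditional variance) have log-density -inf and can never be
// accepted: the uniform priors are implicitly truncated to the jointly valid
// region. Arms with n = 0 contribute no likelihood, so a data-free run
// samples the untruncated prior exactly.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

static inline double invlogit(double z) { return 1.0 / (1.0 + std::exp(-z)); }

struct FbTarget {
  double nc, xc, sc, nv, xv, sv, D, a0;

  double logpost(const double* z) const {
    const double u   = invlogit(z[0]);
    const double pic = invlogit(z[1]);
    const double muc = D * invlogit(z[2]);
    const double s2c = D * D * invlogit(z[3]);
    const double muv = D * invlogit(z[4]);
    const double s2v = D * D * invlogit(z[5]);
    if (u <= 0.0 || u >= 1.0 || pic <= 0.0 || pic >= 1.0 ||
        muc <= 0.0 || s2c <= 0.0 || muv <= 0.0 || s2v <= 0.0)
      return R_NegInf;

    const double ve   = (1.0 - 2.0 * u) / (1.0 - u);
    const double lamc = pic / muc;
    const double lamv = (1.0 - ve) * lamc;

    double ll = 0.0;
    if (nc > 0.0) {
      const double cc = lamc * (s2c - muc * muc) / 2.0;
      const double vt = pic * (1.0 - pic);
      const double cv = s2c - cc * cc / vt;
      if (cv <= 0.0) return R_NegInf;
      ll += R::dbinom(xc, nc, pic, 1);
      ll += R::dnorm(sc, nc * muc + (cc / vt) * (xc - nc * pic),
                     std::sqrt(nc * cv), 1);
    }
    if (nv > 0.0) {
      const double piv = lamv * muv;
      if (piv <= 0.0 || piv >= 1.0) return R_NegInf;
      const double cvv = lamv * (s2v - muv * muv) / 2.0;
      const double vt = piv * (1.0 - piv);
      const double cv = s2v - cvv * cvv / vt;
      if (cv <= 0.0) return R_NegInf;
      ll += R::dbinom(xv, nv, piv, 1);
      ll += R::dnorm(sv, nv * muv + (cvv / vt) * (xv - nv * piv),
                     std::sqrt(nv * cv), 1);
    }
    if (!R_finite(ll)) return R_NegInf;

    // prior + Jacobians on the z scale
    double lp = a0 * std::log(u) + std::log1p(-u);
    for (int j = 1; j < 6; ++j) {
      const double p = invlogit(z[j]);
      lp += std::log(p) + std::log1p(-p);
    }
    return ll + lp;
  }
};

// one stepping-out + shrinkage slice update of coordinate j;
// returns the log-density at the new point
static double slice_update(const FbTarget& tgt, double* z, int j, double lp,
                           double w, int max_steps) {
  const double y = lp - R::exp_rand();
  const double zj = z[j];
  double L = zj - w * R::unif_rand();
  double R_ = L + w;
  int k = max_steps;
  while (k-- > 0) {
    z[j] = L;
    if (tgt.logpost(z) <= y) break;
    L -= w;
  }
  k = max_steps;
  while (k-- > 0) {
    z[j] = R_;
    if (tgt.logpost(z) <= y) break;
    R_ += w;
  }
  for (;;) {
    const double prop = L + (R_ - L) * R::unif_rand();
    z[j] = prop;
    const double lp_new = tgt.logpost(z);
    if (lp_new > y) return lp_new;
    if (prop < zj) L = prop; else R_ = prop;
    if (R_ - L < 1e-12) {  // numerical degeneracy: stay put
      z[j] = zj;
      return lp;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix fb_slice_mcmc(double nc, double xc, double sc,
                            double nv, double xv, double sv,
                            double D, double a0,
                            int iterations, int burn_in, int thin,
                            NumericMatrix inits) {
  const int n_chains = inits.nrow();
  const int n_keep = (iterations - burn_in) / thin;
  NumericMatrix out(n_chains * n_keep, 7);
  FbTarget tgt{nc, xc, sc, nv, xv, sv, D, a0};
  const double w = 1.0;
  const int max_steps = 100;

  int row = 0;
  for (int ch = 0; ch < n_chains; ++ch) {
    double z[6];
    for (int j = 0; j < 6; ++j) z[j] = inits(ch, j);
    double lp = tgt.logpost(z);
    if (!R_finite(lp))
      stop("initial point of chain %d has zero posterior density", ch + 1);
    int kept = 0;
    for (int it = 1; it <= iterations && kept < n_keep; ++it) {
      for (int j = 0; j < 6; ++j) lp = slice_update(tgt, z, j, lp, w, max_steps);
      if (it > burn_in && (it - burn_in) % thin == 0) {
        const double u = invlogit(z[0]);
        out(row, 0) = ch + 1;
        out(row, 1) = (1.0 - 2.0 * u) / (1.0 - u);
        out(row, 2) = invlogit(z[1]);
        out(row, 3) = D * invlogit(z[2]);
        out(row, 4) = D * D * invlogit(z[3]);
        out(row, 5) = D * invlogit(z[4]);
        out(row, 6) = D * D * invlogit(z[5]);
        ++row;
        ++kept;
      }
    }
  }
  return out;
}
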