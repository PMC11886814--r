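// Quartet likelihood kernel.
//
// Likelihood of 4-state site patterns on the unrooted quartet ((A,B),(C,D))
// with five branch lengths (tA,tB,tC,tD,tI) under a reversible GTR(+Gamma4)
// model.  The full 256-entry pattern-probability vector is returned because
// the convergence correction integrates pattern probabilities over explicit
// pattern classes.  Pattern index (0-based): 64*a + 16*b + 4*c + 4th state d,
// states 0..3 = A,C,G,T.
//
// The fitter is a deterministic coordinate-wise bounded line search
// (golden-section per coordinate, sweeps until the log-likelihood improves
// by less than `tol`).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct GtrEigen {
  arma::mat U;        // eigenvectors of the symmetrized rate matrix
  arma::vec lambda;   // eigenvalues (rate-normalized)
  arma::vec sqrt_pi;
};

// Build the rate-normalized GTR generator and its symmetric eigensystem.
// exch order: AC, AG, AT, CG, CT, GT.
GtrEigen gtr_eigen(const arma::vec &pi, const arma::vec &exch) {
  arma::mat Q(4, 4, arma::fill::zeros);
  int pair = 0;
  for (int i = 0; i < 4; ++i)
    for (int j = i + 1; j < 4; ++j) {
      Q(i, j) = exch(pair) * pi(j);
      Q(j, i) = exch(pair) * pi(i);
      ++pair;
    }
  for (int i = 0; i < 4; ++i) Q(i, i) = -arma::accu(Q.row(i)) + Q(i, i);
  double mu = 0.0;
  for (int i = 0; i < 4; ++i) mu -= pi(i) * Q(i, i);
  if (mu <= 0) stop("degenerate rate matrix");
  Q /= mu;

  GtrEigen e;
  e.sqrt_pi = arma::sqrt(pi);
  arma::mat B = arma::diagmat(e.sqrt_pi) * Q * arma::diagmat(1.0 / e.sqrt_pi);
  B = 0.5 * (B + B.t());  // exact up to round-off for reversible Q
  arma::eig_sym(e.lambda, e.U, B);
  return e;
}

// P(t) = D^{-1/2} U exp(lambda t) U' D^{1/2}
arma::mat pmat(const GtrEigen &e, double t) {
  arma::vec el = arma::exp(e.lambda * t);
  arma::mat P = arma::diagmat(1.0 / e.sqrt_pi) * e.U * arma::diagmat(el) *
                e.U.t() * arma::diagmat(e.sqrt_pi);
  P.elem(arma::find(P < 0)).zeros();
  return P;
}

// Discrete-gamma category rates (quantile medians, normalized to mean 1).
arma::vec gamma_rates(double alpha, int ncat) {
  arma::vec r(ncat, arma::fill::ones);
  if (ncat <= 1) return r;
  for (int k = 0; k < ncat; ++k)
    r(k) = R::qgamma((k + 0.5) / ncat, alpha, 1.0 / alpha, 1, 0);
  r /= arma::mean(r);
  return r;
}

// per-category transition matrices for the five branches
// order: A, B, C, D, internal
typedef std::vector<std::array<arma::mat, 5>> Pset;

Pset pset_from(const GtrEigen &e, const arma::vec &rates,
               const arma::vec &bl) {
  Pset P(rates.n_elem);
  for (size_t k = 0; k < rates.n_elem; ++k)
    for (int br = 0; br < 5; ++br) P[k][br] = pmat(e, bl(br) * rates(k));
  return P;
}

// probs(ab,cd) = sum_u sum_v pi_u PA(u,a) PB(u,b) PI(u,v) PC(v,c) PD(v,d),
// averaged over rate categories
arma::vec probs_from_pset(const Pset &P, const arma::vec &pi) {
  arma::vec probs(256, arma::fill::zeros);
  for (size_t k = 0; k < P.size(); ++k) {
    const arma::mat &PA = P[k][0], &PB = P[k][1], &PC = P[k][2],
                    &PD = P[k][3], &PI = P[k][4];
    arma::mat M = arma::diagmat(pi) * PI;
    arma::mat S(4, 16), T(4, 16);
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b)
        for (int u = 0; u < 4; ++u) S(u, 4 * a + b) = PA(u, a) * PB(u, b);
    for (int c = 0; c < 4; ++c)
      for (int d = 0; d < 4; ++d)
        for (int v = 0; v < 4; ++v) T(v, 4 * c + d) = PC(v, c) * PD(v, d);
    arma::mat p16 = S.t() * M * T;  // 16 x 16, rows ab, cols cd
    for (int ab = 0; ab < 16; ++ab)
      for (int cd = 0; cd < 16; ++cd) probs(16 * ab + cd) += p16(ab, cd);
  }
  probs /= static_cast<double>(P.size());
  return probs;
}

// 256-pattern probability vector for ((A,B),(C,D)).
arma::vec pattern_probs_cpp(const arma::vec &bl, const arma::vec &pi,
                            const arma::vec &exch, double alpha, int ncat) {
  GtrEigen e = gtr_eigen(pi, exch);
  arma::vec rates = gamma_rates(alpha, ncat);
  return probs_from_pset(pset_from(e, rates, bl), pi);
}

double loglik_from_probs(const arma::vec &probs, const arma::vec &counts) {
  double ll = 0.0;
  for (int i = 0; i < 256; ++i)
    if (counts(i) > 0) {
      double p = probs(i) > 1e-300 ? probs(i) : 1e-300;
      ll += counts(i) * std::log(p);
    }
  return ll;
}

// --- parameter packing for the fitter ------------------------------------
// theta = [log bl (5)] [log exch(0..4), GT fixed at 1]? [freq weights w0..w2]
//         [log alpha]
// which blocks are present depends on flags.
struct FitSpec {
  bool fit_exch, fit_freq, fit_alpha;
  int ncat;
  arma::vec pi0, exch0;
  double alpha0;
};

void unpack(const arma::vec &theta, const FitSpec &fs, arma::vec &bl,
            arma::vec &pi, arma::vec &exch, double &alpha) {
  bl = arma::exp(theta.subvec(0, 4));
  int off = 5;
  exch = fs.exch0;
  if (fs.fit_exch) {
    for (int i = 0; i < 5; ++i) exch(i) = std::exp(theta(off + i));
    exch(5) = 1.0;
    off += 5;
  }
  pi = fs.pi0;
  if (fs.fit_freq) {
    arma::vec w(4);
    for (int i = 0; i < 3; ++i) w(i) = theta(off + i);
    w(3) = 0.0;
    w = arma::exp(w - w.max());
    pi = w / arma::accu(w);
    off += 3;
  }
  alpha = fs.alpha0;
  if (fs.fit_alpha) alpha = std::exp(theta(off));
}

double neg_ll(const arma::vec &theta, const FitSpec &fs,
              const arma::vec &counts) {
  arma::vec bl, pi, exch;
  double alpha;
  unpack(theta, fs, bl, pi, exch, alpha);
  arma::vec probs = pattern_probs_cpp(bl, pi, exch, alpha, fs.ncat);
  return -loglik_from_probs(probs, counts);
}

// golden-section minimization along one coordinate within [lo, hi].
// `eval` maps a coordinate value to the negative log-likelihood; the best
// point is written back into theta only when it improves on fcur.
template <class Eval>
double golden_coord(arma::vec &theta, int ci, double lo, double hi,
                    double fcur, Eval eval, double xtol) {
  const double gr = 0.6180339887498949;
  double a = lo, b = hi;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = eval(x1), f2 = eval(x2);
  while (b - a > xtol) {
    if (f1 <= f2) {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a);
      f1 = eval(x1);
    } else {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a);
      f2 = eval(x2);
    }
  }
  double xbest = (f1 <= f2) ? x1 : x2, fbest = std::min(f1, f2);
  if (fcur <= fbest) return fcur;
  theta(ci) = xbest;
  return fbest;
}

}  // namespace

// [[Rcpp::export(name = ".quartetPatternProbsCpp")]]
NumericVector quartet_pattern_probs_cpp(NumericVector bl, NumericVector pi,
                                        NumericVector exch, double alpha,
                                        int ncat) {
  arma::vec probs = pattern_probs_cpp(as<arma::vec>(bl), as<arma::vec>(pi),
                                      as<arma::vec>(exch), alpha, ncat);
  return wrap(probs);
}

// [[Rcpp::export(name = ".quartetLoglikCpp")]]
double quartet_loglik_cpp(NumericVector counts, NumericVector bl,
                          NumericVector pi, NumericVector exch, double alpha,
                          int ncat) {
  arma::vec probs = pattern_probs_cpp(as<arma::vec>(bl), as<arma::vec>(pi),
                                      as<arma::vec>(exch), alpha, ncat);
  return loglik_from_probs(probs, as<arma::vec>(counts));
}

// [[Rcpp::export(name = ".fitQuartetCpp")]]
List fit_quartet_cpp(NumericVector counts_, NumericVector bl0,
                     NumericVector pi0, NumericVector exch0, double alpha0,
                     bool fit_exch, bool fit_freq, bool fit_alpha, int ncat,
                     double tol, int max_sweeps) {
  arma::vec counts = as<arma::vec>(counts_);
  FitSpec fs;
  fs.fit_exch = fit_exch;
  fs.fit_freq = fit_freq;
  fs.fit_alpha = fit_alpha;
  fs.ncat = ncat;
  fs.pi0 = as<arma::vec>(pi0);
  fs.exch0 = as<arma::vec>(exch0);
  fs.alpha0 = alpha0;

  int np = 5 + (fit_exch ? 5 : 0) + (fit_freq ? 3 : 0) + (fit_alpha ? 1 : 0);
  arma::vec theta(np), lo(np), hi(np);
  for (int i = 0; i < 5; ++i) {
    theta(i) = std::log(std::max(bl0[i], 1e-8));
    lo(i) = std::log(1e-8);
    hi(i) = std::log(10.0);
  }
  int off = 5;
  if (fit_exch) {
    for (int i = 0; i < 5; ++i) {
      theta(off + i) = std::log(std::max(exch0[i], 1e-3));
      lo(off + i) = std::log(1e-3);
      hi(off + i) = std::log(1e3);
    }
    off += 5;
  }
  if (fit_freq) {
    for (int i = 0; i < 3; ++i) {
      theta(off + i) = std::log(std::max(pi0[i], 1e-6) / std::max(pi0[3], 1e-6));
      lo(off + i) = -12.0;
      hi(off + i) = 12.0;
    }
    off += 3;
  }
  if (fit_alpha) {
    theta(off) = std::log(std::max(alpha0, 0.05));
    lo(off) = std::log(0.05);
    hi(off) = std::log(50.0);
  }

  double f = neg_ll(theta, fs, counts);
  bool converged = false;
  int sweeps = 0;
  for (; sweeps < max_sweeps; ++sweeps) {
    double f_prev = f;
    // branch-length coordinates: the model (eigensystem, rate categories)
    // and the other four transition matrices are fixed during each line
    // search, so only one P matrix is recomputed per trial point
    {
      arma::vec bl, pi, exch;
      double alpha;
      unpack(theta, fs, bl, pi, exch, alpha);
      GtrEigen e = gtr_eigen(pi, exch);
      arma::vec rates = gamma_rates(alpha, fs.ncat);
      Pset P = pset_from(e, rates, bl);
      for (int ci = 0; ci < 5; ++ci) {
        auto eval = [&](double x) {
          double t = std::exp(x);
          for (size_t k = 0; k < rates.n_elem; ++k)
            P[k][ci] = pmat(e, t * rates(k));
          return -loglik_from_probs(probs_from_pset(P, pi), counts);
        };
        f = golden_coord(theta, ci, lo(ci), hi(ci), f, eval, 1e-4);
        double t = std::exp(theta(ci));  // restore accepted matrix
        for (size_t k = 0; k < rates.n_elem; ++k)
          P[k][ci] = pmat(e, t * rates(k));
      }
    }
    // model-parameter coordinates: full recomputation per trial point
    for (int ci = 5; ci < np; ++ci) {
      auto eval = [&](double x) {
        arma::vec th = theta;
        th(ci) = x;
        return neg_ll(th, fs, counts);
      };
      f = golden_coord(theta, ci, lo(ci), hi(ci), f, eval, 1e-4);
    }
    if (f_prev - f < tol) {
      converged = true;
      break;
    }
  }

  arma::vec bl, pi, exch;
  double alpha;
  unpack(theta, fs, bl, pi, exch, alpha);
  arma::vec probs = pattern_probs_cpp(bl, pi, exch, alpha, fs.ncat);
  return List::create(
      _["loglik"] = -f, _["bl"] = wrap(bl), _["pi"] = wrap(pi),
      _["exch"] = wrap(exch), _["alpha"] = alpha, _["probs"] = wrap(probs),
      _["converged"] = converged, _["sweeps"] = sweeps);
}
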