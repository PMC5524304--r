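#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Goldman-Yang style codon rate matrix over the 61 sense codons.
// type(i, j): 0 = multi-nucleotide change, 1 = synonymous transversion,
// 2 = synonymous transition, 3 = nonsynonymous transversion,
// 4 = nonsynonymous transition. Off-diagonal q_ij = pi_j * (kappa if
// transition) * (omega if nonsynonymous). The matrix is scaled so the
// expected number of substitutions per codon per unit time is 1.
static arma::mat build_q(double kappa, double omega, const arma::vec &pi,
                         const arma::imat &type) {
  const int n = pi.n_elem;
  arma::mat Q(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    double rowsum = 0.0;
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      double r = 0.0;
      switch (type(i, j)) {
        case 1: r = pi(j); break;
        case 2: r = kappa * pi(j); break;
        case 3: r = omega * pi(j); break;
        case 4: r = omega * kappa * pi(j); break;
        default: r = 0.0;
      }
      Q(i, j) = r;
      rowsum += r;
    }
    Q(i, i) = -rowsum;
  }
  double scale = -arma::dot(pi, Q.diag());
  if (scale > 0) Q /= scale;
  return Q;
}

// [[Rcpp::export(name = ".cpp_build_q")]]
arma::mat cpp_build_q(double kappa, double omega, const arma::vec &pi,
                      const arma::imat &type) {
  return build_q(kappa, omega, pi, type);
}

struct EigenQ {
  arma::mat A;     // D^{-1/2} V
  arma::mat Ainv;  // V' D^{1/2}
  arma::vec lam;
};

// eigendecomposition of the reversible Q via its symmetrized form
static EigenQ eigen_q(const arma::mat &Q, const arma::vec &pi) {
  arma::vec sq = arma::sqrt(pi);
  arma::mat B = Q;
  const int n = Q.n_rows;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) B(i, j) = sq(i) * Q(i, j) / sq(j);
  B = 0.5 * (B + B.t());  // clean numerical asymmetry
  arma::vec lam;
  arma::mat V;
  if (!arma::eig_sym(lam, V, B)) stop("eigendecomposition failed");
  EigenQ e;
  e.A = V;
  e.Ainv = V.t();
  for (int i = 0; i < n; ++i) {
    e.A.row(i) /= sq(i);
    e.Ainv.col(i) *= sq(i);
  }
  e.lam = lam;
  return e;
}

static arma::mat pmat(const EigenQ &e, double t) {
  arma::mat M = e.A;
  for (arma::uword j = 0; j < e.lam.n_elem; ++j)
    M.col(j) *= std::exp(e.lam(j) * t);
  arma::mat P = M * e.Ainv;
  P.clamp(0.0, arma::datum::inf);  // round tiny negatives up to 0
  return P;
}

// [[Rcpp::export(name = ".cpp_pmat")]]
arma::mat cpp_pmat(const arma::mat &Q, const arma::vec &pi, double t) {
  return pmat(eigen_q(Q, pi), t);
}

// Felsenstein pruning over the 61 codon states with per-branch rate classes.
//
// edge: E x 2 matrix of 0-based node ids (postorder: children before
//   parents), tips 0..ntip-1, root = edge(E-1, 0).
// elen: branch lengths; eclass: 0-based omega-class index per branch.
// tipstate: ntip x npat matrix of 0-based codon states.
// w: pattern weights. omegas: one omega per class.
// [[Rcpp::export(name = ".cpp_codon_lnl")]]
double cpp_codon_lnl(const arma::imat &edge, const arma::vec &elen,
                     const arma::ivec &eclass, const arma::imat &tipstate,
                     const arma::vec &w, double kappa, const arma::vec &omegas,
                     const arma::vec &pi, const arma::imat &type) {
  const int nstate = pi.n_elem;
  const int npat = tipstate.n_cols;
  const int ntip = tipstate.n_rows;
  const int nedge = edge.n_rows;
  const int nnode = ntip + nedge;  // upper bound on node count

  std::vector<EigenQ> eig(omegas.n_elem);
  for (arma::uword k = 0; k < omegas.n_elem; ++k)
    eig[k] = eigen_q(build_q(kappa, omegas(k), pi, type), pi);

  std::vector<arma::mat> partial(nnode);
  std::vector<bool> touched(nnode, false);
  arma::rowvec logscale(npat, arma::fill::zeros);

  for (int e = 0; e < nedge; ++e) {
    int parent = edge(e, 0), child = edge(e, 1);
    arma::mat P = pmat(eig[eclass(e)], elen(e));
    arma::mat M(nstate, npat);
    if (child < ntip) {
      for (int p = 0; p < npat; ++p) M.col(p) = P.col(tipstate(child, p));
    } else {
      arma::mat &Lc = partial[child];
      // scale child partial to avoid underflow
      for (int p = 0; p < npat; ++p) {
        double mx = Lc.col(p).max();
        if (mx > 0 && mx < 1e-100) { Lc.col(p) /= mx; logscale(p) += std::log(mx); }
        else if (mx <= 0) return -arma::datum::inf;
      }
      M = P * Lc;
    }
    if (!touched[parent]) {
      partial[parent] = M;
      touched[parent] = true;
    } else {
      partial[parent] %= M;
    }
  }

  int root = edge(nedge - 1, 0);
  arma::rowvec site = pi.t() * partial[root];
  double lnl = 0.0;
  for (int p = 0; p < npat; ++p) {
    if (site(p) <= 0) return -arma::datum::inf;
    lnl += w(p) * (std::log(site(p)) + logscale(p));
  }
  return lnl;
}
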