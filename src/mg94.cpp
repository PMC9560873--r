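// MG94-style codon-model log-likelihood by Felsenstein pruning.
//
// The rate matrix allows single-nucleotide codon changes only; the rate of a
// change is (kappa if transition) * (position-specific frequency of the
// target nucleotide, F3x4) * (omega if nonsynonymous).  The chain is
// reversible with stationary distribution proportional to the product of the
// position-specific nucleotide frequencies, so the matrix is symmetrized by
// sqrt(pi) scaling and exponentiated through a symmetric eigendecomposition.
// Branch lengths are expected substitutions per codon under that branch's
// own omega (each omega class is normalized separately).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void mg94_eigen(const IntegerMatrix& pairs, const arma::vec& tfreq,
                       const arma::vec& pi, double kappa, double omega,
                       arma::mat& V, arma::vec& lam) {
  int ns = pi.n_elem;
  arma::mat Q(ns, ns, arma::fill::zeros);
  int np = pairs.nrow();
  for (int k = 0; k < np; ++k) {
    int i = pairs(k, 0), j = pairs(k, 1);
    double r = tfreq(pairs(k, 4));
    if (pairs(k, 2)) r *= kappa;
    if (!pairs(k, 3)) r *= omega;
    Q(i, j) = r;
  }
  arma::vec rs = arma::sum(Q, 1);
  double mu = arma::dot(pi, rs);
  if (mu <= 0) stop("degenerate rate matrix");
  Q /= mu;
  rs /= mu;
  arma::vec sp = arma::sqrt(pi);
  arma::mat S(ns, ns);
  for (int i = 0; i < ns; ++i) {
    for (int j = 0; j < ns; ++j)
      S(i, j) = Q(i, j) * sp(i) / sp(j);
    S(i, i) = -rs(i);
  }
  S = 0.5 * (S + S.t());
  arma::eig_sym(lam, V, S);
}

// edge: 2-column (parent, child), 0-based node ids, tips 0..ntip-1, ordered
//       so that every child's subtree is finished before its edge is used
//       (ape "postorder").
// tip_pat: ntip x npat codon state matrix, 0..ns-1, -1 = missing.
// omega_edge: omega used on each edge; t_edge: branch lengths.
// [[Rcpp::export]]
double mg94_loglik_cpp(IntegerMatrix edge, NumericVector t_edge,
                       NumericVector omega_edge, double kappa,
                       IntegerMatrix tip_pat, NumericVector weights,
                       IntegerMatrix pairs, NumericVector tfreq_,
                       NumericVector pi_, int nnode) {
  const int ntip = tip_pat.nrow(), npat = tip_pat.ncol();
  const int nedge = edge.nrow(), ns = pi_.size();
  arma::vec pi(pi_.begin(), ns), tfreq(tfreq_.begin(), tfreq_.size());
  arma::vec sp = arma::sqrt(pi);

  // eigen systems per distinct omega
  std::vector<double> uomega;
  std::vector<int> omap(nedge);
  for (int e = 0; e < nedge; ++e) {
    int idx = -1;
    for (size_t u = 0; u < uomega.size(); ++u)
      if (uomega[u] == omega_edge[e]) { idx = (int)u; break; }
    if (idx < 0) { uomega.push_back(omega_edge[e]); idx = (int)uomega.size() - 1; }
    omap[e] = idx;
  }
  std::vector<arma::mat> Vs(uomega.size());
  std::vector<arma::vec> lams(uomega.size());
  for (size_t u = 0; u < uomega.size(); ++u)
    mg94_eigen(pairs, tfreq, pi, kappa, uomega[u], Vs[u], lams[u]);

  std::vector<arma::mat> clv(nnode);
  std::vector<bool> has(nnode, false), ischild(nnode, false);
  arma::rowvec logscale(npat, arma::fill::zeros);

  for (int e = 0; e < nedge; ++e) {
    int parent = edge(e, 0), child = edge(e, 1);
    ischild[child] = true;
    const arma::mat& V = Vs[omap[e]];
    const arma::vec& lam = lams[omap[e]];
    arma::mat M = V * arma::diagmat(arma::exp(lam * t_edge[e])) * V.t();
    arma::mat P(ns, ns);
    for (int i = 0; i < ns; ++i)
      for (int j = 0; j < ns; ++j) {
        double v = M(i, j) * sp(j) / sp(i);
        P(i, j) = v > 0 ? v : 0.0;
      }
    arma::mat contrib(ns, npat);
    if (child < ntip) {
      for (int p = 0; p < npat; ++p) {
        int s = tip_pat(child, p);
        if (s < 0) contrib.col(p).ones();
        else contrib.col(p) = P.col(s);
      }
    } else {
      if (!has[child]) stop("edge ordering is not postorder");
      contrib = P * clv[child];
      clv[child].reset();
    }
    // column rescaling to avoid underflow; the factor moves into logscale
    arma::rowvec mx = arma::max(contrib, 0);
    for (int p = 0; p < npat; ++p) {
      if (mx(p) <= 0) return -1e300;
      contrib.col(p) /= mx(p);
    }
    logscale += arma::log(mx);
    if (!has[parent]) { clv[parent] = contrib; has[parent] = true; }
    else clv[parent] %= contrib;
  }

  int root = -1;
  for (int v = 0; v < nnode; ++v)
    if (has[v] && !ischild[v]) { root = v; break; }
  if (root < 0) stop("could not locate root node");

  arma::rowvec lik = pi.t() * clv[root];
  double total = 0.0;
  for (int p = 0; p < npat; ++p) {
    if (lik(p) <= 0) return -1e300;
    total += weights[p] * (std::log(lik(p)) + logscale(p));
  }
  return total;
}
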