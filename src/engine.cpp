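// Codon substitution likelihood engine: reversible generator exponentials and
// Felsenstein pruning over sense-codon states, with subtree caching for the
// branch-site site-class mixture.
#include <RcppArmadillo.h>
#include <map>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct EigQ {
  arma::mat U;
  arma::vec lam;
  arma::vec sqp;
};

// Eigendecomposition of a reversible generator via the similarity transform
// B = D^{1/2} Q D^{-1/2} (symmetric when pi Q is balanced).
static EigQ eig_of_Q(const arma::mat& Q, const arma::vec& pi) {
  EigQ e;
  e.sqp = arma::sqrt(pi);
  const int n = Q.n_rows;
  arma::mat B(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      B(i, j) = e.sqp(i) * Q(i, j) / e.sqp(j);
  B = 0.5 * (B + B.t());
  arma::eig_sym(e.lam, e.U, B);
  return e;
}

static arma::mat pmat_from_eig(const EigQ& e, double t) {
  arma::mat M = e.U * arma::diagmat(arma::exp(e.lam * t)) * e.U.t();
  const int n = M.n_rows;
  arma::mat P(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double v = M(i, j) * e.sqp(j) / e.sqp(i);
      P(i, j) = v > 0.0 ? v : 0.0;
    }
  return P;
}

// [[Rcpp::export]]
arma::mat cpp_pmat(const arma::mat& Q, const arma::vec& pi, double t) {
  EigQ e = eig_of_Q(Q, pi);
  return pmat_from_eig(e, t);
}

struct Partial {
  arma::mat L;          // ncod x npat conditional likelihoods
  arma::rowvec logscale; // per-pattern log scaling
};

class Pruner {
public:
  const arma::imat& tip_pat; // ntaxa x npat, 0-based codon state, -1 missing
  const arma::imat& edge;    // E x 2 (parent, child), 0-based, postorder
  const arma::vec& elen;
  const arma::ivec& fg;      // 0/1 per edge
  const arma::vec& pi;
  std::vector<EigQ> eigs;    // one per rate matrix
  int ntaxa, npat, ncod, nnodes, root;
  std::vector<std::vector<int> > child_edges; // per node
  std::vector<bool> hasfg;                    // any foreground edge below node
  std::map<long long, arma::mat> pcache;      // (edge, widx) -> P
  std::map<long long, int> ncache;            // node/class key -> store idx
  std::vector<Partial> store;

  Pruner(const arma::imat& tp, const arma::imat& ed, const arma::vec& el,
         const arma::ivec& f, const List& Qs, const arma::vec& p)
      : tip_pat(tp), edge(ed), elen(el), fg(f), pi(p) {
    ntaxa = tp.n_rows;
    npat = tp.n_cols;
    ncod = p.n_elem;
    int mx = 0;
    for (arma::uword i = 0; i < ed.n_rows; ++i)
      mx = std::max(mx, std::max(ed(i, 0), ed(i, 1)));
    nnodes = mx + 1;
    child_edges.resize(nnodes);
    hasfg.assign(nnodes, false);
    for (arma::uword e = 0; e < ed.n_rows; ++e)
      child_edges[ed(e, 0)].push_back((int)e);
    // postorder: child rows precede parent rows, so one sweep suffices
    for (arma::uword e = 0; e < ed.n_rows; ++e) {
      int pnode = ed(e, 0), cnode = ed(e, 1);
      if (f(e) == 1 || hasfg[cnode]) hasfg[pnode] = true;
    }
    root = ed(ed.n_rows - 1, 0);
    eigs.reserve(Qs.size());
    for (int k = 0; k < Qs.size(); ++k)
      eigs.push_back(eig_of_Q(as<arma::mat>(Qs[k]), p));
  }

  const arma::mat& pmat(int e, int w) {
    long long key = (long long)e * 64 + w;
    std::map<long long, arma::mat>::iterator it = pcache.find(key);
    if (it != pcache.end()) return it->second;
    pcache[key] = pmat_from_eig(eigs[w], elen(e));
    return pcache[key];
  }

  // conditional likelihoods of the subtree below node v when background
  // branches use matrix bg and foreground branches matrix fgw
  int node_partial(int v, int bg, int fgw) {
    long long key = (long long)v * 64 + bg * 8 + (hasfg[v] ? fgw : 7);
    std::map<long long, int>::iterator it = ncache.find(key);
    if (it != ncache.end()) return it->second;
    Partial part;
    part.L.ones(ncod, npat);
    part.logscale.zeros(npat);
    for (size_t k = 0; k < child_edges[v].size(); ++k) {
      int e = child_edges[v][k];
      int c = edge(e, 1);
      int w = fg(e) == 1 ? fgw : bg;
      const arma::mat& P = pmat(e, w);
      if (c < ntaxa) {
        for (int h = 0; h < npat; ++h) {
          int s = tip_pat(c, h);
          if (s < 0) continue; // missing: contribution 1 (row sums of P are 1)
          part.L.col(h) %= P.col(s);
        }
      } else {
        int ci = node_partial(c, bg, fgw);
        part.L %= (P * store[ci].L);
        part.logscale += store[ci].logscale;
      }
    }
    arma::rowvec mx = arma::max(part.L, 0);
    for (int h = 0; h < npat; ++h) {
      double m = mx(h);
      if (m <= 0.0) m = 1e-300;
      part.L.col(h) /= m;
      part.logscale(h) += std::log(m);
    }
    store.push_back(part);
    int idx = (int)store.size() - 1;
    ncache[key] = idx;
    return idx;
  }

  arma::rowvec root_loglik(int bg, int fgw) {
    int ri = node_partial(root, bg, fgw);
    arma::rowvec out(npat);
    const Partial& part = store[ri];
    for (int h = 0; h < npat; ++h) {
      double lik = arma::dot(pi, part.L.col(h));
      out(h) = std::log(lik > 0.0 ? lik : 1e-300) + part.logscale(h);
    }
    return out;
  }
};

// Per-pattern log-likelihoods of the four branch-site classes.
// Qs = list(Q_omega0, Q_omega1, Q_omega2), already mixture-scaled.
// Columns: class 0 (bg w0 / fg w0), 1 (w1/w1), 2a (w0/w2), 2b (w1/w2).
// [[Rcpp::export]]
arma::mat cpp_bs_class_loglik(const arma::imat& tip_pat, const arma::imat& edge,
                              const arma::vec& elen, const arma::ivec& fg,
                              const List& Qs, const arma::vec& pi) {
  Pruner pr(tip_pat, edge, elen, fg, Qs, pi);
  arma::mat out(pr.npat, 4);
  out.col(0) = pr.root_loglik(0, 0).t();
  out.col(1) = pr.root_loglik(1, 1).t();
  out.col(2) = pr.root_loglik(0, 2).t();
  out.col(3) = pr.root_loglik(1, 2).t();
  return out;
}

// Per-pattern log-likelihood under a single rate matrix on every branch
// (optionally a distinct matrix on foreground branches).
// [[Rcpp::export]]
arma::vec cpp_site_loglik(const arma::imat& tip_pat, const arma::imat& edge,
                          const arma::vec& elen, const arma::ivec& fg,
                          const List& Qs, const arma::vec& pi,
                          int bg_idx, int fg_idx) {
  Pruner pr(tip_pat, edge, elen, fg, Qs, pi);
  return pr.root_loglik(bg_idx, fg_idx).t();
}
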