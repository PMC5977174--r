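// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Felsenstein pruning for a finite-state substitution mixture on a fixed
// postorder edge list. `tipstate` holds 1-based state indices (0 = missing,
// contributing a partial likelihood of ones). `edge_P` maps (edge, class)
// to a 1-based index into `P_list`, so transition matrices shared between
// classes or equal-length branches are computed once on the R side.
// [[Rcpp::export]]
List prune_mixture(const IntegerMatrix tipstate,
                   const NumericVector weights,
                   const IntegerMatrix edge,
                   const int n_node,
                   const List P_list,
                   const IntegerMatrix edge_P,
                   const NumericVector root_freq,
                   const NumericVector class_prob) {
  const int n_tip = tipstate.nrow();
  const int n_pat = tipstate.ncol();
  const int n_state = root_freq.size();
  const int n_edge = edge.nrow();
  const int n_class = class_prob.size();

  std::vector<arma::mat> P(P_list.size());
  for (int i = 0; i < P_list.size(); ++i) P[i] = as<arma::mat>(P_list[i]);

  const int root = edge(n_edge - 1, 0);
  const arma::vec pi = as<arma::vec>(root_freq);
  arma::rowvec tot(n_pat, arma::fill::zeros);

  for (int c = 0; c < n_class; ++c) {
    std::vector<arma::mat> partial(n_node);
    std::vector<bool> init(n_node, false);
    for (int e = 0; e < n_edge; ++e) {
      const int par = edge(e, 0) - 1;
      const int ch = edge(e, 1) - 1;
      const arma::mat &Pm = P[edge_P(e, c) - 1];
      arma::mat msg(n_state, n_pat);
      if (ch < n_tip) {
        for (int j = 0; j < n_pat; ++j) {
          const int s = tipstate(ch, j);
          if (s == 0)
            msg.col(j).ones();
          else
            msg.col(j) = Pm.col(s - 1);
        }
      } else {
        msg = Pm * partial[ch];
      }
      if (!init[par]) {
        partial[par] = msg;
        init[par] = true;
      } else {
        partial[par] %= msg;
      }
    }
    tot += class_prob[c] * (pi.t() * partial[root - 1]);
  }

  NumericVector site_lnl(n_pat);
  double lnl = 0.0;
  for (int j = 0; j < n_pat; ++j) {
    site_lnl[j] = std::log(tot[j]);
    lnl += weights[j] * site_lnl[j];
  }
  return List::create(_["lnl"] = lnl, _["site_lnl"] = site_lnl);
}
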