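#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------
// Reversible-generator eigendecompositions
//
// A reversible generator Q with stationary distribution pi satisfies
// detailed balance, so S = D^{1/2} Q D^{-1/2} (D = diag(pi)) is
// symmetric with real spectrum and P(t) = U exp(Lambda t) V with
// U = D^{-1/2} W, V = W' D^{1/2}.
// ---------------------------------------------------------------------

struct EigSys {
  arma::mat U;
  arma::vec lam;
  arma::mat V;
};

static EigSys eig_rev(const arma::mat& Q, const arma::vec& pi) {
  arma::vec sq = arma::sqrt(pi);
  arma::mat S = Q;
  S.each_col() %= sq;
  S.each_row() /= sq.t();
  S = 0.5 * (S + S.t());
  EigSys es;
  arma::mat W;
  if (!arma::eig_sym(es.lam, W, S))
    stop("eigendecomposition of rate matrix failed");
  es.U = W;
  es.U.each_col() /= sq;
  es.V = W.t();
  es.V.each_row() %= sq.t();
  return es;
}

// [[Rcpp::export(name = ".eig_rev_cpp")]]
List eig_rev_cpp(const arma::mat& Q, const arma::vec& pi) {
  EigSys es = eig_rev(Q, pi);
  return List::create(_["U"] = es.U, _["lambda"] = es.lam, _["V"] = es.V);
}

// [[Rcpp::export(name = ".trans_prob_cpp")]]
arma::mat trans_prob_cpp(const arma::mat& U, const arma::vec& lam,
                         const arma::mat& V, double t) {
  arma::mat P = U * arma::diagmat(arma::exp(lam * t)) * V;
  P.clamp(0.0, arma::datum::inf);
  return P;
}

// ---------------------------------------------------------------------
// Pruning likelihood over several rate classes
//
// edge:     nedge x 2 matrix of 1-based ape node indices (tips
//           1..ntip, root ntip+1), rows in postorder.
// blen:     branch length per edge row.
// esys:     nedge x ncat matrix, 1-based index into `gens`: which
//           generator governs each edge in each rate class.
// gens:     list whose elements are either a rate-matrix (numeric
//           61 x 61 matrix) or a precomputed eigensystem
//           list(U, lambda, V) as returned by .eig_rev_cpp (callers
//           cache eigensystems across evaluations this way).
// tipstate: ntip x npat 0-based codon states, -1 = missing data.
// pi:       root (stationary) codon frequencies.
//
// Returns an ncat x npat matrix of per-pattern log-likelihoods
// conditional on the rate class.
// ---------------------------------------------------------------------
// [[Rcpp::export(name = ".class_loglik_cpp")]]
arma::mat class_loglik_cpp(const IntegerMatrix& edge, const arma::vec& blen,
                           const IntegerMatrix& esys, const List& gens,
                           const IntegerMatrix& tipstate, const arma::vec& pi,
                           int n_node_total) {
  const int ntip = tipstate.nrow();
  const int npat = tipstate.ncol();
  const int nedge = edge.nrow();
  const int ncat = esys.ncol();
  const int nstate = pi.n_elem;
  const int nsys = gens.size();

  // resolve eigensystems once
  std::vector<EigSys> sys(nsys);
  for (int s = 0; s < nsys; ++s) {
    RObject g = gens[s];
    if (Rf_isMatrix(g)) {
      sys[s] = eig_rev(as<arma::mat>(g), pi);
    } else {
      List es(g);
      sys[s].U = as<arma::mat>(es["U"]);
      sys[s].lam = as<arma::vec>(es["lambda"]);
      sys[s].V = as<arma::mat>(es["V"]);
    }
  }

  arma::mat out(ncat, npat);
  std::vector<arma::mat> part(n_node_total + 1);
  std::vector<bool> has(n_node_total + 1);
  arma::mat contrib(nstate, npat);
  arma::cube P(nstate, nstate, nedge);
  arma::mat B(nstate, nstate * nedge);

  for (int c = 0; c < ncat; ++c) {
    // transition matrices, batched per eigensystem for one big GEMM
    for (int s = 0; s < nsys; ++s) {
      std::vector<int> es_edges;
      for (int e = 0; e < nedge; ++e)
        if (esys(e, c) - 1 == s) es_edges.push_back(e);
      if (es_edges.empty()) continue;
      const int m = (int)es_edges.size();
      for (int q = 0; q < m; ++q) {
        arma::vec w = arma::exp(sys[s].lam * blen[es_edges[q]]);
        arma::mat Bq(B.colptr((arma::uword)q * nstate), nstate, nstate,
                     false, true);
        Bq = sys[s].V;
        Bq.each_col() %= w;
      }
      arma::mat Ball(B.memptr(), nstate, (arma::uword)m * nstate, false, true);
      arma::mat PP = sys[s].U * Ball;
      PP.clamp(0.0, arma::datum::inf);
      for (int q = 0; q < m; ++q)
        P.slice(es_edges[q]) =
            PP.cols((arma::uword)q * nstate, (arma::uword)(q + 1) * nstate - 1);
    }

    std::fill(has.begin(), has.end(), false);
    arma::rowvec logscale(npat, arma::fill::zeros);

    for (int e = 0; e < nedge; ++e) {
      const int u = edge(e, 0), v = edge(e, 1);
      const arma::mat& Pe = P.slice(e);
      if (v <= ntip) {
        for (int s = 0; s < npat; ++s) {
          const int st = tipstate(v - 1, s);
          if (st < 0)
            contrib.col(s).ones();
          else
            contrib.col(s) = Pe.col(st);
        }
      } else {
        if (!has[v]) stop("postorder violated: child partial missing");
        arma::mat& cp = part[v];
        arma::rowvec m = arma::max(cp, 0);
        m.transform([](double x) { return x > 0.0 ? x : 1.0; });
        cp.each_row() /= m;
        logscale += arma::log(m);
        contrib = Pe * cp;
      }
      if (!has[u]) {
        part[u] = contrib;
        has[u] = true;
      } else {
        part[u] %= contrib;
      }
    }

    const int root = ntip + 1;
    if (!has[root]) stop("root partial missing (bad edge matrix)");
    arma::rowvec rootlik = pi.t() * part[root];
    for (int s = 0; s < npat; ++s) {
      double x = rootlik[s];
      out(c, s) = (x > 0.0 ? std::log(x) : -arma::datum::inf) + logscale[s];
    }
  }
  return out;
}
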