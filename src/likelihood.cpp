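// Numerical kernels: transition-probability cubes from a cached spectral
// decomposition, Felsenstein pruning over compressed site patterns, and an
// affine-gap query-vs-profile aligner with frozen reference columns.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// P(t) = A * diag(exp(lambda * t)) * B for each t, where A = D^{-1/2} V and
// B = V' D^{1/2} come from the symmetrized reversible generator. Tiny
// negative entries from roundoff are clamped to zero.
// [[Rcpp::export]]
arma::cube pmat_cube(const arma::mat& A, const arma::mat& B,
                     const arma::vec& lambda, const arma::vec& tvec) {
  const arma::uword k = A.n_rows, ne = tvec.n_elem;
  arma::cube P(k, k, ne);
  for (arma::uword e = 0; e < ne; ++e) {
    arma::mat slice = A * arma::diagmat(arma::exp(lambda * tvec[e])) * B;
    slice.clamp(0.0, arma::datum::inf);
    P.slice(e) = slice;
  }
  return P;
}

// Pruning over a postorder edge list. Nodes are 1-based on the R side:
// tips 1..ntip, internals ntip+1..nnode. tip_part holds one k x npat
// partial-likelihood matrix per tip (all-ones columns encode missing data).
// Each edge row is (parent, child); edges must be sorted so every child's
// subtree is complete before its parent edge is processed. Returns per-pattern
// log-likelihoods; per-edge rescaling guards against underflow.
// [[Rcpp::export]]
arma::vec pruning_loglik(const arma::cube& P, const arma::imat& edges,
                         const List& tip_part, int nnode, int ntip, int root,
                         const arma::vec& pi) {
  const arma::uword k = pi.n_elem;
  const arma::mat tip0 = as<arma::mat>(tip_part[0]);
  const arma::uword npat = tip0.n_cols;
  std::vector<arma::mat> part(nnode);
  for (int n = ntip; n < nnode; ++n) part[n] = arma::mat(k, npat, arma::fill::ones);
  arma::vec scaler(npat, arma::fill::zeros);
  for (arma::uword e = 0; e < edges.n_rows; ++e) {
    const int parent = edges(e, 0) - 1, child = edges(e, 1) - 1;
    arma::mat up;
    if (child < ntip) up = P.slice(e) * as<arma::mat>(tip_part[child]);
    else              up = P.slice(e) * part[child];
    part[parent] %= up;
    arma::rowvec mx = arma::max(part[parent], 0);
    for (arma::uword j = 0; j < npat; ++j) {
      if (mx[j] > 0 && mx[j] < 1e-100) { part[parent].col(j) /= mx[j]; scaler[j] += std::log(mx[j]); }
    }
  }
  arma::rowvec site = pi.t() * part[root - 1];
  arma::vec out(npat);
  for (arma::uword j = 0; j < npat; ++j)
    out[j] = (site[j] > 0 ? std::log(site[j]) : -arma::datum::inf) + scaler[j];
  return out;
}

// Build the GY94 codon generator for (kappa, omega, pi) from the
// precomputed single-nucleotide pair skeleton and return its spectral
// decomposition in the pi-symmetrized basis: P(t) = A exp(lambda t) B.
// ii/jj are 0-based pair indices; ts/ns flag transitions and nonsynonymous
// changes.
// [[Rcpp::export]]
List gy94_decomp(const arma::vec& pi, double kappa, double omega,
                 const arma::uvec& ii, const arma::uvec& jj,
                 const arma::uvec& ts, const arma::uvec& ns) {
  const arma::uword k = pi.n_elem;
  arma::mat Q(k, k, arma::fill::zeros);
  for (arma::uword p = 0; p < ii.n_elem; ++p) {
    double r = pi[jj[p]];
    if (ts[p]) r *= kappa;
    if (ns[p]) r *= omega;
    Q(ii[p], jj[p]) = r;
  }
  Q.diag() = -arma::sum(Q, 1);
  arma::vec d = arma::sqrt(pi);
  arma::mat S = Q;
  S.each_col() %= d;          // row i scaled by d_i
  S.each_row() /= d.t();      // column j scaled by 1/d_j
  S = 0.5 * (S + S.t());
  arma::vec lam; arma::mat V;
  arma::eig_sym(lam, V, S);
  arma::mat A = V; A.each_col() /= d;
  arma::mat B = V.t(); B.each_row() %= d.t();
  return List::create(_["A"] = A, _["B"] = B, _["lambda"] = lam);
}

// Pruning specialised to tips coded as integer states (1..k, 0 = missing):
// a tip's partial is a unit vector, so the edge update is a column gather
// instead of a matrix product. Used by the 61-state codon engine.
// [[Rcpp::export]]
arma::vec pruning_loglik_states(const arma::cube& P, const arma::imat& edges,
                                const arma::imat& tip_states, int nnode,
                                int root, const arma::vec& pi) {
  const arma::uword k = pi.n_elem;
  const int ntip = tip_states.n_rows;
  const arma::uword npat = tip_states.n_cols;
  std::vector<arma::mat> part(nnode);
  for (int n = ntip; n < nnode; ++n) part[n] = arma::mat(k, npat, arma::fill::ones);
  arma::vec scaler(npat, arma::fill::zeros);
  arma::mat up(k, npat);
  for (arma::uword e = 0; e < edges.n_rows; ++e) {
    const int parent = edges(e, 0) - 1, child = edges(e, 1) - 1;
    const arma::mat& Pe = P.slice(e);
    if (child < ntip) {
      for (arma::uword j = 0; j < npat; ++j) {
        const int s = tip_states(child, j);
        if (s > 0) up.col(j) = Pe.col(s - 1); else up.col(j).ones();
      }
      part[parent] %= up;
    } else {
      part[parent] %= Pe * part[child];
    }
    arma::rowvec mx = arma::max(part[parent], 0);
    for (arma::uword j = 0; j < npat; ++j) {
      if (mx[j] > 0 && mx[j] < 1e-100) { part[parent].col(j) /= mx[j]; scaler[j] += std::log(mx[j]); }
    }
  }
  arma::rowvec site = pi.t() * part[root - 1];
  arma::vec out(npat);
  for (arma::uword j = 0; j < npat; ++j)
    out[j] = (site[j] > 0 ? std::log(site[j]) : -arma::datum::inf) + scaler[j];
  return out;
}

// Pruning with tips coded as indices into a shared lookup matrix L
// (k x nstates) of partial-likelihood columns — the IUPAC alphabet for the
// nucleotide engine. Per edge, P * L is computed once (k x nstates) and tip
// updates become column gathers.
// [[Rcpp::export]]
arma::vec pruning_loglik_lookup(const arma::cube& P, const arma::imat& edges,
                                const arma::imat& tip_states,
                                const arma::mat& L, int nnode, int root,
                                const arma::vec& pi) {
  const arma::uword k = pi.n_elem;
  const int ntip = tip_states.n_rows;
  const arma::uword npat = tip_states.n_cols;
  std::vector<arma::mat> part(nnode);
  for (int n = ntip; n < nnode; ++n) part[n] = arma::mat(k, npat, arma::fill::ones);
  arma::vec scaler(npat, arma::fill::zeros);
  arma::mat up(k, npat);
  for (arma::uword e = 0; e < edges.n_rows; ++e) {
    const int parent = edges(e, 0) - 1, child = edges(e, 1) - 1;
    if (child < ntip) {
      arma::mat PL = P.slice(e) * L;
      for (arma::uword j = 0; j < npat; ++j)
        up.col(j) = PL.col(tip_states(child, j) - 1);
      part[parent] %= up;
    } else {
      part[parent] %= P.slice(e) * part[child];
    }
    arma::rowvec mx = arma::max(part[parent], 0);
    for (arma::uword j = 0; j < npat; ++j) {
      if (mx[j] > 0 && mx[j] < 1e-100) { part[parent].col(j) /= mx[j]; scaler[j] += std::log(mx[j]); }
    }
  }
  arma::rowvec site = pi.t() * part[root - 1];
  arma::vec out(npat);
  for (arma::uword j = 0; j < npat; ++j)
    out[j] = (site[j] > 0 ? std::log(site[j]) : -arma::datum::inf) + scaler[j];
  return out;
}

// Single-class (M0) log-likelihood with the analytic gradient over branch
// lengths, by the standard two-pass algorithm on a rooted binary tree:
// up partials by pruning, down partials by sibling messages, and
// d lnL / d t_e = sum_s w_s F_e' (Q P_e) up_e / L_s, where QP holds Q * P(t)
// per edge. Unscaled partials (fine at the tree depths used here).
// [[Rcpp::export]]
List m0_loglik_grad(const arma::cube& P, const arma::cube& QP,
                    const arma::imat& edges, const arma::imat& tip_states,
                    int nnode, int root, const arma::vec& pi,
                    const arma::vec& weights) {
  const arma::uword k = pi.n_elem;
  const int ntip = tip_states.n_rows;
  const arma::uword npat = tip_states.n_cols, ne = edges.n_rows;
  std::vector<arma::mat> up(nnode), msg(ne), down(nnode);
  for (int n = ntip; n < nnode; ++n) up[n] = arma::mat(k, npat, arma::fill::ones);
  std::vector<int> sib(ne, -1), parent_edge(nnode, -1);
  for (arma::uword e = 0; e < ne; ++e) parent_edge[edges(e, 1) - 1] = e;
  for (arma::uword e = 0; e < ne; ++e)
    for (arma::uword f = 0; f < ne; ++f)
      if (f != e && edges(f, 0) == edges(e, 0)) { sib[e] = f; break; }
  for (arma::uword e = 0; e < ne; ++e) {
    const int parent = edges(e, 0) - 1, child = edges(e, 1) - 1;
    const arma::mat& Pe = P.slice(e);
    arma::mat m(k, npat);
    if (child < ntip) {
      for (arma::uword j = 0; j < npat; ++j) {
        const int s = tip_states(child, j);
        if (s > 0) m.col(j) = Pe.col(s - 1); else m.col(j).ones();
      }
    } else m = Pe * up[child];
    msg[e] = m;
    up[parent] %= m;
  }
  arma::rowvec L = pi.t() * up[root - 1];
  double loglik = 0.0;
  for (arma::uword j = 0; j < npat; ++j) loglik += weights[j] * std::log(L[j]);
  down[root - 1] = arma::repmat(pi, 1, npat);
  arma::vec grad(ne, arma::fill::zeros);
  // preorder = reverse postorder
  for (int e = ne - 1; e >= 0; --e) {
    const int parent = edges(e, 0) - 1, child = edges(e, 1) - 1;
    arma::mat F = down[parent];
    if (sib[e] >= 0) F %= msg[sib[e]];
    arma::mat X;  // (Q P_e) * up[child]
    const arma::mat& QPe = QP.slice(e);
    if (child < ntip) {
      X.set_size(k, npat);
      for (arma::uword j = 0; j < npat; ++j) {
        const int s = tip_states(child, j);
        if (s > 0) X.col(j) = QPe.col(s - 1); else X.col(j).zeros();
      }
    } else {
      X = QPe * up[child];
      down[child] = P.slice(e).t() * F;
    }
    arma::rowvec num = arma::sum(F % X, 0);
    grad[e] = arma::dot(weights, num / L);
  }
  return List::create(_["loglik"] = loglik, _["gradient"] = grad);
}

// Placement support: for every reference edge, precompute the midpoint
// "docking" partial D_e(x, s) = (P_{t/2}' F_e)(x, s) * (P_{t/2} up_v)(x, s),
// where up_v is the upward partial of the child subtree and F_e the
// complement (outside) partial at the parent. Attaching a query with
// pendant length p at the midpoint of edge e then gives the site likelihood
// sum_x D_e(x, s) * (P(p) q_s)(x) without re-running full pruning.
// P holds P(t_e), Phalf holds P(t_e/2). One rate category per call.
// [[Rcpp::export]]
arma::cube placement_docking(const arma::cube& P, const arma::cube& Phalf,
                             const arma::imat& edges,
                             const arma::imat& tip_states, const arma::mat& L,
                             int nnode, int root, const arma::vec& pi) {
  const arma::uword k = pi.n_elem;
  const int ntip = tip_states.n_rows;
  const arma::uword ncol_ = tip_states.n_cols, ne = edges.n_rows;
  std::vector<arma::mat> up(nnode), msg(ne), down(nnode);
  for (int n = ntip; n < nnode; ++n) up[n] = arma::mat(k, ncol_, arma::fill::ones);
  auto tipmat = [&](int child) {
    arma::mat m(k, ncol_);
    for (arma::uword j = 0; j < ncol_; ++j)
      m.col(j) = L.col(tip_states(child, j) - 1);
    return m;
  };
  for (arma::uword e = 0; e < ne; ++e) {
    const int parent = edges(e, 0) - 1, child = edges(e, 1) - 1;
    msg[e] = P.slice(e) * (child < ntip ? tipmat(child) : up[child]);
    up[parent] %= msg[e];
  }
  down[root - 1] = arma::repmat(pi, 1, ncol_);
  arma::cube D(k, ncol_, ne);
  for (int e = ne - 1; e >= 0; --e) {
    const int parent = edges(e, 0) - 1, child = edges(e, 1) - 1;
    // outside partial at the parent, excluding this edge (msgs are strictly
    // positive for positive branch lengths, so division is safe)
    arma::mat F = down[parent] % up[parent] / msg[e];
    if (child >= ntip) down[child] = P.slice(e).t() * F;
    arma::mat upv = (child < ntip ? tipmat(child) : up[child]);
    D.slice(e) = (Phalf.slice(e).t() * F) % (Phalf.slice(e) * upv);
  }
  return D;
}

// Total log-likelihood of attaching a query at one edge midpoint, for each
// candidate pendant length. D_cats: list over rate categories of the edge's
// docking matrix (k x ncol). The query's tip states index the lookup matrix
// L; the pendant evolves at each category's rate.
// [[Rcpp::export]]
arma::vec pendant_scan(const List& D_cats, const arma::mat& A,
                       const arma::mat& B, const arma::vec& lambda,
                       const arma::vec& rates, const arma::ivec& qcodes,
                       const arma::mat& L, const arma::vec& pvec) {
  const arma::uword ncat = rates.n_elem, np = pvec.n_elem;
  const arma::uword ncol_ = qcodes.n_elem;
  std::vector<arma::mat> D(ncat);
  for (arma::uword c = 0; c < ncat; ++c) D[c] = as<arma::mat>(D_cats[c]);
  arma::vec out(np);
  arma::vec sitelik(ncol_);
  for (arma::uword ip = 0; ip < np; ++ip) {
    sitelik.zeros();
    for (arma::uword c = 0; c < ncat; ++c) {
      arma::mat Pp = A * arma::diagmat(arma::exp(lambda * pvec[ip] * rates[c])) * B;
      Pp.clamp(0.0, arma::datum::inf);
      arma::mat PL = Pp * L;
      for (arma::uword s = 0; s < ncol_; ++s)
        sitelik[s] += arma::dot(D[c].col(s), PL.col(qcodes[s] - 1));
    }
    out[ip] = arma::accu(arma::log(sitelik / ncat));
  }
  return out;
}

// Semi-global affine alignment of a query against a fixed-column profile.
// S(i,j): score of query residue i against profile column j. Profile columns
// are never created or destroyed: the query either occupies a column, leaves
// it gapped, or has a residue dropped (query-only insertion). Profile-side
// end gaps are free. Returns, per query residue, its 1-based column (0 =
// dropped). gap_open is the cost of a gap's first character, gap_ext of each
// further one.
// [[Rcpp::export]]
IntegerVector profile_align_dp(const arma::mat& S, double gap_open, double gap_ext) {
  const int nq = S.n_rows, np = S.n_cols;
  const double NEG = -1e18;
  // state 0 = M (residue in column), 1 = D (column gapped), 2 = I (residue dropped)
  arma::mat M(nq + 1, np + 1), D(nq + 1, np + 1), I(nq + 1, np + 1);
  arma::imat bM(nq + 1, np + 1), bD(nq + 1, np + 1), bI(nq + 1, np + 1);
  M.fill(NEG); D.fill(NEG); I.fill(NEG);
  M(0, 0) = 0.0;
  for (int j = 1; j <= np; ++j) { D(0, j) = 0.0; bD(0, j) = 1; }  // free leading columns
  for (int i = 1; i <= nq; ++i) {
    I(i, 0) = -gap_open - gap_ext * (i - 1);
    bI(i, 0) = 2;
    for (int j = 1; j <= np; ++j) {
      double a = M(i - 1, j - 1), b = D(i - 1, j - 1), c = I(i - 1, j - 1);
      int arg = 0; double best = a;
      if (b > best) { best = b; arg = 1; }
      if (c > best) { best = c; arg = 2; }
      M(i, j) = best + S(i - 1, j - 1); bM(i, j) = arg;
      a = M(i, j - 1) - gap_open; b = D(i, j - 1) - gap_ext;
      if (a >= b) { D(i, j) = a; bD(i, j) = 0; } else { D(i, j) = b; bD(i, j) = 1; }
      a = M(i - 1, j) - gap_open; c = I(i - 1, j) - gap_ext;
      if (a >= c) { I(i, j) = a; bI(i, j) = 0; } else { I(i, j) = c; bI(i, j) = 2; }
    }
  }
  // free trailing columns: best score over states at i = nq for any j
  int bestj = np, bests = 0; double best = NEG;
  for (int j = 0; j <= np; ++j) {
    double vm = M(nq, j), vi = I(nq, j);
    if (vm > best) { best = vm; bestj = j; bests = 0; }
    if (vi > best) { best = vi; bestj = j; bests = 2; }
  }
  IntegerVector col(nq);
  int i = nq, j = bestj, s = bests;
  while (i > 0 || j > 0) {
    if (s == 0) {
      if (i == 0 && j == 0) break;
      if (i == 0) { s = 1; continue; }
      col[i - 1] = j; s = bM(i, j); --i; --j;
    } else if (s == 1) {
      if (j == 0) { s = 0; continue; }
      s = bD(i, j); --j;
    } else {
      col[i - 1] = 0; s = bI(i, j); --i;
    }
    if (i == 0 && j == 0) break;
  }
  return col;
}
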