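#include <Rcpp.h>
using namespace Rcpp;

// Nucleotide codes in X: 0 = missing, 1..4 = A, C, G, T.

// Log-likelihood of each cell's BCR sequence under each hypercluster profile.
// X: M x L codes; logB: array dim c(4, L, Q) of log nucleotide frequencies.
// Missing positions are skipped (missing-at-random).
// [[Rcpp::export]]
NumericMatrix bcr_loglik_cpp(IntegerMatrix X, NumericVector logB) {
  IntegerVector dims = logB.attr("dim");
  if (dims.size() != 3 || dims[0] != 4)
    stop("logB must be a 4 x L x Q array");
  int L = dims[1], Q = dims[2];
  int M = X.nrow();
  if (X.ncol() != L) stop("X and logB disagree on L");
  NumericMatrix out(M, Q);
  for (int q = 0; q < Q; ++q) {
    const double* Bq = logB.begin() + (R_xlen_t)q * 4 * L;
    for (int j = 0; j < M; ++j) {
      double s = 0.0;
      for (int l = 0; l < L; ++l) {
        int x = X(j, l);
        if (x > 0) s += Bq[4 * l + (x - 1)];
      }
      out(j, q) = s;
    }
  }
  return out;
}

// Counts of each nucleotide per (position, hypercluster).
// Returns array dim c(4, L, Q); missing codes are not counted.
// [[Rcpp::export]]
NumericVector nuc_counts_cpp(IntegerMatrix X, IntegerVector t, int Q) {
  int M = X.nrow(), L = X.ncol();
  NumericVector cnt((R_xlen_t)4 * L * Q);
  for (int j = 0; j < M; ++j) {
    int q = t[j] - 1;
    if (q < 0 || q >= Q) stop("cluster label out of range");
    double* cq = cnt.begin() + (R_xlen_t)q * 4 * L;
    for (int l = 0; l < L; ++l) {
      int x = X(j, l);
      if (x > 0) cq[4 * l + (x - 1)] += 1.0;
    }
  }
  cnt.attr("dim") = IntegerVector::create(4, L, Q);
  return cnt;
}

static inline void draw_dirichlet(const double* g, int n, double* out) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    out[i] = R::rgamma(g[i], 1.0);
    s += out[i];
  }
  if (s <= 0.0) {
    // numerical underflow at very small shapes: limit is a one-hot draw
    int c = (int)(unif_rand() * n);
    if (c >= n) c = n - 1;
    for (int i = 0; i < n; ++i) out[i] = 0.0;
    out[c] = 1.0;
    s = 1.0;
  }
  for (int i = 0; i < n; ++i) out[i] /= s;
}

// One Gibbs pass over T with the BCR profiles collapsed (partially
// collapsed Gibbs).  Existing clusters are scored with the
// Dirichlet-multinomial predictive of the cell's BCR sequence given the
// cluster's current nucleotide counts (cell j removed); a new cluster is
// scored with the prior predictive and with the clone label marginalised
// over its uniform prior.  When a new cluster is opened its clone label is
// drawn from its full conditional; the profiles B are reinstantiated from
// their conditionals by the caller after the sweep.  This kernel targets
// the same joint posterior as the uncollapsed auxiliary kernel below but
// mixes across cluster merges/splits at realistic sequence lengths.
// [[Rcpp::export]]
List sweep_t_collapsed_cpp(IntegerVector t_in, IntegerVector I_in,
                           NumericMatrix CL, IntegerMatrix X,
                           double alpha0, NumericMatrix g, int K) {
  int M = X.nrow(), L = X.ncol();
  int Q = I_in.size();
  if (g.nrow() != L || g.ncol() != 4) stop("g must be L x 4");
  IntegerVector t = clone(t_in);
  std::vector<int> I(I_in.begin(), I_in.end());
  std::vector<std::vector<double> > cnt(Q);   // per cluster: 4 x L counts
  std::vector<std::vector<double> > ntot(Q);  // per cluster: observed per l
  std::vector<int> nq(Q, 0);
  for (int q = 0; q < Q; ++q) {
    cnt[q].assign((size_t)4 * L, 0.0);
    ntot[q].assign(L, 0.0);
  }
  for (int j = 0; j < M; ++j) {
    int q = t[j] - 1;
    if (q < 0 || q >= Q) stop("cluster label out of range");
    nq[q]++;
    for (int l = 0; l < L; ++l) {
      int x = X(j, l);
      if (x > 0) { cnt[q][4 * l + (x - 1)] += 1.0; ntot[q][l] += 1.0; }
    }
  }
  std::vector<double> Gl(L);       // prior strength per position
  for (int l = 0; l < L; ++l)
    Gl[l] = g(l, 0) + g(l, 1) + g(l, 2) + g(l, 3);
  // prior predictive of each cell's observed BCR positions
  std::vector<double> prior_pred(M, 0.0);
  for (int j = 0; j < M; ++j)
    for (int l = 0; l < L; ++l) {
      int x = X(j, l);
      if (x > 0) prior_pred[j] += std::log(g(l, x - 1) / Gl[l]);
    }
  std::vector<double> w;

  for (int j = 0; j < M; ++j) {
    int q_old = t[j] - 1;
    nq[q_old]--;
    for (int l = 0; l < L; ++l) {
      int x = X(j, l);
      if (x > 0) { cnt[q_old][4 * l + (x - 1)] -= 1.0; ntot[q_old][l] -= 1.0; }
    }
    if (nq[q_old] == 0) {
      cnt.erase(cnt.begin() + q_old);
      ntot.erase(ntot.begin() + q_old);
      nq.erase(nq.begin() + q_old);
      I.erase(I.begin() + q_old);
      for (int m = 0; m < M; ++m)
        if (t[m] > q_old + 1) t[m]--;
      t[j] = NA_INTEGER;
    }
    int Qcur = (int)nq.size();

    // marginal read weight of a new cluster: mean over clones
    double clmax = R_NegInf;
    for (int k = 0; k < K; ++k) if (CL(j, k) > clmax) clmax = CL(j, k);
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += std::exp(CL(j, k) - clmax);
    double cl_marg = clmax + std::log(s / K);

    w.assign(Qcur + 1, 0.0);
    double wmax = R_NegInf;
    for (int q = 0; q < Qcur; ++q) {
      double dm = 0.0;
      for (int l = 0; l < L; ++l) {
        int x = X(j, l);
        if (x > 0)
          dm += std::log((g(l, x - 1) + cnt[q][4 * l + (x - 1)]) /
                         (Gl[l] + ntot[q][l]));
      }
      w[q] = std::log((double)nq[q]) + CL(j, I[q] - 1) + dm;
      if (w[q] > wmax) wmax = w[q];
    }
    w[Qcur] = std::log(alpha0) + cl_marg + prior_pred[j];
    if (w[Qcur] > wmax) wmax = w[Qcur];
    if (!R_FINITE(wmax)) stop("non-finite hypercluster weights for a cell");

    double tot = 0.0;
    for (int q = 0; q <= Qcur; ++q) {
      w[q] = std::exp(w[q] - wmax);
      tot += w[q];
    }
    double u = unif_rand() * tot, acc = 0.0;
    int pick = Qcur;
    for (int q = 0; q <= Qcur; ++q) {
      acc += w[q];
      if (u <= acc) { pick = q; break; }
    }

    if (pick == Qcur) {
      // instantiate the new cluster's clone label from its conditional
      double u2 = unif_rand() * s, acc2 = 0.0;
      int I_new = K - 1;
      for (int k = 0; k < K; ++k) {
        acc2 += std::exp(CL(j, k) - clmax);
        if (u2 <= acc2) { I_new = k; break; }
      }
      I.push_back(I_new + 1);
      nq.push_back(1);
      cnt.push_back(std::vector<double>((size_t)4 * L, 0.0));
      ntot.push_back(std::vector<double>(L, 0.0));
      t[j] = Qcur + 1;
      q_old = Qcur;
    } else {
      nq[pick]++;
      t[j] = pick + 1;
      q_old = pick;
    }
    for (int l = 0; l < L; ++l) {
      int x = X(j, l);
      if (x > 0) { cnt[q_old][4 * l + (x - 1)] += 1.0; ntot[q_old][l] += 1.0; }
    }
  }
  return List::create(_["t"] = t, _["I"] = wrap(I));
}

// One Gibbs pass over the hypercluster assignments T (Neal's Algorithm 8
// with one auxiliary component).  For each cell in turn the cell is removed
// from its cluster and one auxiliary cluster is offered alongside the
// existing ones: its clone label and BCR profile are drawn fresh from their
// priors, except when the removal emptied the cell's cluster, in which case
// that cluster's parameters become the auxiliary (required for detailed
// balance).  The cell then joins an existing or the auxiliary cluster with
// CRP-weighted posterior probabilities; an unselected auxiliary is
// discarded, and labels stay compacted with no empty clusters.
//
// t: M labels (1-based, contiguous); I: Q clone labels (1-based);
// B: array c(4, L, Q) of profiles (probabilities); BL: M x Q BCR log-lik
// matrix consistent with B; CL: M x K per-cell per-clone read log-likelihood
// (constant terms may be dropped); X: M x L codes; g: L x 4 Dirichlet prior.
// [[Rcpp::export]]
List sweep_t_cpp(IntegerVector t_in, IntegerVector I_in, NumericVector B,
                 NumericMatrix BL, NumericMatrix CL, IntegerMatrix X,
                 double alpha0, NumericMatrix g, int K) {
  IntegerVector dims = B.attr("dim");
  int L = dims[1];
  int Q = dims[2];
  int M = X.nrow();
  if (g.nrow() != L || g.ncol() != 4) stop("g must be L x 4");

  IntegerVector t = clone(t_in);
  std::vector<int> I(I_in.begin(), I_in.end());
  std::vector<std::vector<double> > Bcols(Q), BLcols(Q);
  std::vector<int> nq(Q, 0);
  for (int q = 0; q < Q; ++q) {
    Bcols[q].assign(B.begin() + (R_xlen_t)q * 4 * L,
                    B.begin() + (R_xlen_t)(q + 1) * 4 * L);
    BLcols[q].assign(BL.begin() + (R_xlen_t)q * M,
                     BL.begin() + (R_xlen_t)(q + 1) * M);
  }
  for (int j = 0; j < M; ++j) nq[t[j] - 1]++;

  std::vector<double> freshB((R_xlen_t)4 * L);
  std::vector<double> freshBL;
  std::vector<double> gl(4);
  std::vector<double> w;

  for (int j = 0; j < M; ++j) {
    int q_old = t[j] - 1;
    nq[q_old]--;
    bool reuse = (nq[q_old] == 0);
    int I_new;
    double bl_new;
    bool have_bl_col = false;
    if (reuse) {
      // the departing singleton's parameters become the auxiliary component
      freshB = Bcols[q_old];
      freshBL = BLcols[q_old];
      I_new = I[q_old] - 1;
      bl_new = freshBL[j];
      have_bl_col = true;
      Bcols.erase(Bcols.begin() + q_old);
      BLcols.erase(BLcols.begin() + q_old);
      nq.erase(nq.begin() + q_old);
      I.erase(I.begin() + q_old);
      for (int m = 0; m < M; ++m)
        if (t[m] > q_old + 1) t[m]--;
      t[j] = NA_INTEGER;  // placeholder until reassigned
    } else {
      // fresh auxiliary cluster from the priors
      I_new = (int)(unif_rand() * K);
      if (I_new >= K) I_new = K - 1;
      bl_new = 0.0;
      for (int l = 0; l < L; ++l) {
        for (int n = 0; n < 4; ++n) gl[n] = g(l, n);
        draw_dirichlet(gl.data(), 4, &freshB[4 * l]);
        int x = X(j, l);
        if (x > 0) bl_new += std::log(freshB[4 * l + (x - 1)]);
      }
    }
    int Qcur = (int)nq.size();

    w.assign(Qcur + 1, 0.0);
    double wmax = R_NegInf;
    for (int q = 0; q < Qcur; ++q) {
      w[q] = std::log((double)nq[q]) + CL(j, I[q] - 1) + BLcols[q][j];
      if (w[q] > wmax) wmax = w[q];
    }
    w[Qcur] = std::log(alpha0) + CL(j, I_new) + bl_new;
    if (w[Qcur] > wmax) wmax = w[Qcur];
    if (!R_FINITE(wmax)) stop("non-finite hypercluster weights for a cell");

    double tot = 0.0;
    for (int q = 0; q <= Qcur; ++q) {
      w[q] = std::exp(w[q] - wmax);
      tot += w[q];
    }
    double u = unif_rand() * tot, acc = 0.0;
    int pick = Qcur;
    for (int q = 0; q <= Qcur; ++q) {
      acc += w[q];
      if (u <= acc) { pick = q; break; }
    }

    if (pick == Qcur) {
      // open the auxiliary cluster: keep its parameters
      Bcols.push_back(freshB);
      I.push_back(I_new + 1);
      nq.push_back(1);
      if (!have_bl_col) {
        freshBL.resize(M);
        for (int m = 0; m < M; ++m) {
          double s = 0.0;
          for (int l = 0; l < L; ++l) {
            int x = X(m, l);
            if (x > 0) s += std::log(freshB[4 * l + (x - 1)]);
          }
          freshBL[m] = s;
        }
      }
      BLcols.push_back(freshBL);
      t[j] = Qcur + 1;
    } else {
      nq[pick]++;
      t[j] = pick + 1;
    }
  }

  int Qout = (int)nq.size();
  NumericVector Bout((R_xlen_t)4 * L * Qout);
  NumericMatrix BLout(M, Qout);
  for (int q = 0; q < Qout; ++q) {
    std::copy(Bcols[q].begin(), Bcols[q].end(),
              Bout.begin() + (R_xlen_t)q * 4 * L);
    for (int m = 0; m < M; ++m) BLout(m, q) = BLcols[q][m];
  }
  Bout.attr("dim") = IntegerVector::create(4, L, Qout);
  return List::create(_["t"] = t, _["I"] = wrap(I), _["B"] = Bout,
                      _["BL"] = BLout);
}
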