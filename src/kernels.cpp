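// Hot kernels for the attention encoders: per-subject multi-head
// self-attention and node-centric attention aggregation, with hand-derived
// backward passes. Token rows are laid out subject-major: row b*seq + i is
// region i of subject b (0-based). Internally the loops run on transposed
// copies so each token is a contiguous column.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Node-centric attention aggregation layer.
// Scores: s_{c,j} = w2' relu(W1t' h_c + W1b' h_j + b1) + b2, j != c within
// the subject; alpha = softmax_j; out_c = h_c + sum_j alpha_j h_j.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List ncaa_forward_cpp(const arma::mat& H, const arma::mat& W1t,
                      const arma::mat& W1b, const arma::vec& b1,
                      const arma::vec& w2, double b2, int B, int seq) {
  const int A = W1t.n_cols;
  const int ns = seq - 1;
  const arma::mat HT = H.t();                  // D x n, token per column
  const arma::mat Pt = W1t.t() * HT;           // A x n, center part
  const arma::mat Pb = W1b.t() * HT;           // A x n, neighbor part
  arma::mat alpha(ns, B * seq);
  arma::mat OT = HT;
  arma::vec svec(ns);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < seq; ++i) {
      const int c = b * seq + i;
      const double* pc = Pt.colptr(c);
      int s = 0;
      for (int j = 0; j < seq; ++j) {
        if (j == i) continue;
        const double* pj = Pb.colptr(b * seq + j);
        double sc = b2;
        for (int k = 0; k < A; ++k) {
          const double a = pc[k] + pj[k] + b1[k];
          if (a > 0) sc += w2[k] * a;
        }
        svec[s] = sc;
        ++s;
      }
      const double mx = svec.max();
      arma::vec e = arma::exp(svec - mx);
      const double tot = arma::accu(e);
      s = 0;
      for (int j = 0; j < seq; ++j) {
        if (j == i) continue;
        const double al = e[s] / tot;
        alpha(s, c) = al;
        OT.col(c) += al * HT.col(b * seq + j);
        ++s;
      }
    }
  }
  return List::create(_["out"] = OT.t(), _["alpha"] = alpha);
}

// [[Rcpp::export]]
List ncaa_backward_cpp(const arma::mat& G, const arma::mat& H,
                       const arma::mat& W1t, const arma::mat& W1b,
                       const arma::vec& b1, const arma::vec& w2,
                       const arma::mat& alpha, int B, int seq) {
  const int A = W1t.n_cols;
  const int D = H.n_cols;
  const int ns = seq - 1;
  const arma::mat HT = H.t();
  const arma::mat GT = G.t();
  const arma::mat W1tT = W1t.t();              // A x D
  const arma::mat W1bT = W1b.t();
  const arma::mat Pt = W1tT * HT;              // A x n, center pre-activations
  const arma::mat Pb = W1bT * HT;
  arma::mat dHT = GT;
  arma::mat dW1t(D, A, arma::fill::zeros);
  arma::mat dW1b(D, A, arma::fill::zeros);
  arma::vec db1(A, arma::fill::zeros);
  arma::vec dw2(A, arma::fill::zeros);
  double db2 = 0;
  arma::vec dal(ns), ds(ns), da(A);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < seq; ++i) {
      const int c = b * seq + i;
      const double* gc = GT.colptr(c);
      const double* pc = Pt.colptr(c);
      int s = 0;
      double dot_ad = 0;
      for (int j = 0; j < seq; ++j) {
        if (j == i) continue;
        const int jr = b * seq + j;
        double acc = 0;
        const double* hj = HT.colptr(jr);
        for (int k = 0; k < D; ++k) acc += gc[k] * hj[k];
        dal[s] = acc;
        const double al = alpha(s, c);
        double* dj = dHT.colptr(jr);
        for (int k = 0; k < D; ++k) dj[k] += al * gc[k];
        dot_ad += al * acc;
        ++s;
      }
      for (s = 0; s < ns; ++s) ds[s] = alpha(s, c) * (dal[s] - dot_ad);
      s = 0;
      for (int j = 0; j < seq; ++j) {
        if (j == i) continue;
        const int jr = b * seq + j;
        const double dss = ds[s];
        db2 += dss;
        const double* pj = Pb.colptr(jr);
        for (int k = 0; k < A; ++k) {
          const double a = pc[k] + pj[k] + b1[k];
          if (a > 0) {
            dw2[k] += dss * a;
            da[k] = dss * w2[k];
            db1[k] += da[k];
          } else {
            da[k] = 0;
          }
        }
        const double* hc = HT.colptr(c);
        const double* hj = HT.colptr(jr);
        double* dc = dHT.colptr(c);
        double* dj = dHT.colptr(jr);
        for (int k = 0; k < A; ++k) {
          const double dak = da[k];
          if (dak == 0) continue;
          double* w1tc = dW1t.colptr(k);
          double* w1bc = dW1b.colptr(k);
          for (int d = 0; d < D; ++d) {
            w1tc[d] += hc[d] * dak;
            w1bc[d] += hj[d] * dak;
          }
          // dH through the scorer input: columns of W1tT/W1bT are rows of W1
          const double* wtk = W1tT.memptr() + (long)k;
          const double* wbk = W1bT.memptr() + (long)k;
          for (int d = 0; d < D; ++d) {
            dc[d] += dak * wtk[(long)d * A];
            dj[d] += dak * wbk[(long)d * A];
          }
        }
        ++s;
      }
    }
  }
  return List::create(_["dH"] = dHT.t(), _["dW1t"] = dW1t, _["dW1b"] = dW1b,
                      _["db1"] = db1, _["dw2"] = dw2, _["db2"] = db2);
}

// ---------------------------------------------------------------------------
// Multi-head self-attention over each subject's seq tokens.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List msa_forward_cpp(const arma::mat& H, const arma::mat& Wq,
                     const arma::mat& Wk, const arma::mat& Wv,
                     const arma::mat& Wo, int heads, int B, int seq) {
  const int D = H.n_cols;
  const int dk = D / heads;
  const double scale = 1.0 / std::sqrt((double)dk);
  arma::mat Q = H * Wq, K = H * Wk, V = H * Wv;
  arma::cube Acube(seq, seq, B * heads);
  arma::mat Oc(H.n_rows, D);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * seq, r1 = b * seq + seq - 1;
    for (int h = 0; h < heads; ++h) {
      const int c0 = h * dk, c1 = h * dk + dk - 1;
      arma::mat S = Q.submat(r0, c0, r1, c1) *
                    K.submat(r0, c0, r1, c1).t() * scale;
      for (int i = 0; i < seq; ++i) {
        arma::rowvec row = S.row(i);
        row -= row.max();
        arma::rowvec e = arma::exp(row);
        S.row(i) = e / arma::accu(e);
      }
      Acube.slice(b * heads + h) = S;
      Oc.submat(r0, c0, r1, c1) = S * V.submat(r0, c0, r1, c1);
    }
  }
  arma::mat out = Oc * Wo;
  return List::create(_["out"] = out, _["Q"] = Q, _["K"] = K, _["V"] = V,
                      _["Acube"] = Acube, _["Oc"] = Oc);
}

// [[Rcpp::export]]
List msa_backward_cpp(const arma::mat& G, const arma::mat& H,
                      const arma::mat& Wq, const arma::mat& Wk,
                      const arma::mat& Wv, const arma::mat& Wo,
                      const arma::mat& Q, const arma::mat& K,
                      const arma::mat& V, const arma::cube& Acube,
                      const arma::mat& Oc, int heads, int B, int seq) {
  const int D = H.n_cols;
  const int dk = D / heads;
  const double scale = 1.0 / std::sqrt((double)dk);
  arma::mat dOc = G * Wo.t();
  arma::mat dWo = Oc.t() * G;
  arma::mat dQ(arma::size(Q), arma::fill::zeros);
  arma::mat dK(arma::size(K), arma::fill::zeros);
  arma::mat dV(arma::size(V), arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * seq, r1 = b * seq + seq - 1;
    for (int h = 0; h < heads; ++h) {
      const int c0 = h * dk, c1 = h * dk + dk - 1;
      const arma::mat& A = Acube.slice(b * heads + h);
      arma::mat dOb = dOc.submat(r0, c0, r1, c1);
      arma::mat dA = dOb * V.submat(r0, c0, r1, c1).t();
      dV.submat(r0, c0, r1, c1) = A.t() * dOb;
      arma::mat dS(seq, seq);
      for (int i = 0; i < seq; ++i) {
        const double rdot = arma::dot(dA.row(i), A.row(i));
        dS.row(i) = A.row(i) % (dA.row(i) - rdot);
      }
      dS *= scale;
      dQ.submat(r0, c0, r1, c1) = dS * K.submat(r0, c0, r1, c1);
      dK.submat(r0, c0, r1, c1) = dS.t() * Q.submat(r0, c0, r1, c1);
    }
  }
  arma::mat dH = dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
  return List::create(_["dH"] = dH,
                      _["dWq"] = H.t() * dQ, _["dWk"] = H.t() * dK,
                      _["dWv"] = H.t() * dV, _["dWo"] = dWo);
}
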