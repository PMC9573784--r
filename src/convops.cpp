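// Compute kernels for the segmentation network. Feature maps are C x N'
// matrices over a zero-padded (H+2) x (W+2) pixel grid, flat pixel index
// p = col*(H+2) + row (0-based, column-major). With a guaranteed zero
// border, a 3x3 "same" convolution is nine accumulating GEMMs on
// pointer-offset views of the same buffer -- no im2col materialisation.
// Border output pixels pick up wrap-around garbage and are re-zeroed, which
// also re-establishes the padding invariant for the next layer.

#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
// [[Rcpp::depends(RcppArmadillo)]]

static void zero_border(double* Y, const int C, const int H, const int W) {
  const int Hp = H + 2, Wp = W + 2;
  // first and last padded column blocks
  std::memset(Y, 0, sizeof(double) * C * Hp);
  std::memset(Y + (size_t)(Wp - 1) * Hp * C, 0, sizeof(double) * C * Hp);
  for (int c = 1; c < Wp - 1; ++c) {
    std::memset(Y + ((size_t)c * Hp) * C, 0, sizeof(double) * C);
    std::memset(Y + ((size_t)c * Hp + Hp - 1) * C, 0, sizeof(double) * C);
  }
}

// [[Rcpp::export]]
arma::mat conv3p_fw(const arma::mat& X, const arma::mat& W,
                    const arma::vec& b, const int H, const int Wd) {
  const int Cin = X.n_rows, Cout = W.n_rows;
  const int Np = (H + 2) * (Wd + 2);
  arma::mat Y(Cout, Np);
  for (int p = 0; p < Np; ++p)
    std::memcpy(Y.colptr(p), b.memptr(), sizeof(double) * Cout);
  const double one = 1.0;
  int k = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      const int s = dc * (H + 2) + dr;
      const int lo = std::max(0, -s), hi = Np - 1 - std::max(0, s);
      const int len = hi - lo + 1;
      const double* Wk = W.memptr() + (size_t)k * Cin * Cout;
      F77_CALL(dgemm)("N", "N", &Cout, &len, &Cin, &one,
                      Wk, &Cout,
                      X.memptr() + (size_t)(lo + s) * Cin, &Cin,
                      &one, Y.memptr() + (size_t)lo * Cout, &Cout
                      FCONE FCONE);
      ++k;
    }
  }
  zero_border(Y.memptr(), Cout, H, Wd);
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv3p_bw(const arma::mat& dY, const arma::mat& X,
                     const arma::mat& W, const int H, const int Wd) {
  const int Cin = X.n_rows, Cout = W.n_rows;
  const int Np = (H + 2) * (Wd + 2);
  arma::mat dW(Cout, 9 * Cin, arma::fill::zeros);
  arma::mat dX(Cin, Np, arma::fill::zeros);
  const double one = 1.0, zero = 0.0;
  int k = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      const int s = dc * (H + 2) + dr;
      const int lo = std::max(0, -s), hi = Np - 1 - std::max(0, s);
      const int len = hi - lo + 1;
      const double* Wk = W.memptr() + (size_t)k * Cin * Cout;
      // dX[, p + s] += Wk^T dY[, p]
      F77_CALL(dgemm)("T", "N", &Cin, &len, &Cout, &one,
                      Wk, &Cout,
                      dY.memptr() + (size_t)lo * Cout, &Cout,
                      &one, dX.memptr() + (size_t)(lo + s) * Cin, &Cin
                      FCONE FCONE);
      // dW_k = dY[, lo:hi] X[, lo+s:hi+s]^T  (border dY is zero)
      F77_CALL(dgemm)("N", "T", &Cout, &Cin, &len, &one,
                      dY.memptr() + (size_t)lo * Cout, &Cout,
                      X.memptr() + (size_t)(lo + s) * Cin, &Cin,
                      &zero, dW.memptr() + (size_t)k * Cin * Cout, &Cout
                      FCONE FCONE);
      ++k;
    }
  }
  zero_border(dX.memptr(), Cin, H, Wd);
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("dX") = dX,
                            Rcpp::Named("db") = arma::vec(arma::sum(dY, 1)));
}

// 2x2 max pooling between padded grids; argmax (1-based flat index into the
// padded fine grid) is returned for exact gradient routing. Ties go to the
// first candidate in (r, c) order, so pooling is deterministic.
// [[Rcpp::export]]
Rcpp::List maxpool2p(const arma::mat& X, const int H, const int Wd) {
  const int C = X.n_rows;
  const int H2 = H / 2, W2 = Wd / 2;
  const int Hp = H + 2, Np2 = (H2 + 2) * (W2 + 2);
  arma::mat out(C, Np2, arma::fill::zeros);
  arma::imat amax(C, Np2, arma::fill::zeros);
  for (int cc = 0; cc < W2; ++cc) {
    for (int rc = 0; rc < H2; ++rc) {
      const int q = (cc + 1) * (H2 + 2) + rc + 1;
      const int p00 = (2 * cc + 1) * Hp + 2 * rc + 1;
      const int cand[4] = {p00, p00 + 1, p00 + Hp, p00 + Hp + 1};
      for (int ch = 0; ch < C; ++ch) {
        double best = X(ch, cand[0]);
        int bi = cand[0];
        for (int t = 1; t < 4; ++t) {
          const double v = X(ch, cand[t]);
          if (v > best) { best = v; bi = cand[t]; }
        }
        out(ch, q) = best;
        amax(ch, q) = bi + 1;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("argmax") = amax);
}

// [[Rcpp::export]]
arma::mat maxpool2p_bw(const arma::mat& dY, const arma::imat& amax,
                       const int n_fine) {
  const int C = dY.n_rows;
  arma::mat dX(C, n_fine, arma::fill::zeros);
  for (arma::uword q = 0; q < dY.n_cols; ++q)
    for (int ch = 0; ch < C; ++ch)
      if (amax(ch, q) > 0) dX(ch, amax(ch, q) - 1) += dY(ch, q);
  return dX;
}

// Nearest-neighbour 2x upsampling between padded grids.
// [[Rcpp::export]]
arma::mat upsample2p(const arma::mat& X, const int H2, const int W2) {
  const int C = X.n_rows;
  const int H = 2 * H2, Wd = 2 * W2;
  const int Hp = H + 2, H2p = H2 + 2;
  arma::mat out(C, Hp * (Wd + 2), arma::fill::zeros);
  for (int c = 0; c < Wd; ++c) {
    const int qc = c / 2 + 1;
    for (int r = 0; r < H; ++r) {
      const int q = qc * H2p + r / 2 + 1;
      std::memcpy(out.colptr((c + 1) * Hp + r + 1), X.colptr(q),
                  sizeof(double) * C);
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat upsample2p_bw(const arma::mat& dY, const int H2, const int W2) {
  const int C = dY.n_rows;
  const int H = 2 * H2, Wd = 2 * W2;
  const int Hp = H + 2, H2p = H2 + 2;
  arma::mat dX(C, H2p * (W2 + 2), arma::fill::zeros);
  for (int c = 0; c < Wd; ++c) {
    const int qc = c / 2 + 1;
    for (int r = 0; r < H; ++r) {
      const int q = qc * H2p + r / 2 + 1;
      const double* src = dY.colptr((c + 1) * Hp + r + 1);
      double* dst = dX.colptr(q);
      for (int ch = 0; ch < C; ++ch) dst[ch] += src[ch];
    }
  }
  return dX;
}
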