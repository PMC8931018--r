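// Dilated GRU feature extractor: batched forward and backward passes.
//
// A stack of GRU layers in which layer l updates its hidden state from the
// state d_l steps back (skip recurrence). The d_l recurrence chains of a
// layer are mutually independent, so all time steps inside one "phase
// block" of d_l consecutive steps advance together; with the state cubes
// laid out as (hidden, batch, time), a block and its predecessor block are
// contiguous in memory and every block update is a handful of large GEMMs
// on zero-copy views.
//
// Gate row order in the stacked weight matrices is [z; r; c]:
//   z_t = sigmoid(Wz x_t + Uz h_prev + bz)        (update gate)
//   r_t = sigmoid(Wr x_t + Ur h_prev + br)        (reset gate)
//   c_t = tanh   (Wc x_t + Uc (r_t o h_prev) + bc)
//   h_t = (1 - z_t) o h_prev + z_t o c_t,  h_prev = h_{t - d_l}  (0 for t < d_l)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// writable zero-copy view of `dd` consecutive slices starting at t0
static inline mat slab(cube& C, int t0, int dd) {
  return mat(C.slice_memptr(t0), C.n_rows, C.n_cols * dd, false, true);
}
static inline const mat cslab(const cube& C, int t0, int dd) {
  return mat(const_cast<double*>(C.slice_memptr(t0)), C.n_rows, C.n_cols * dd,
             false, true);
}

struct LayerCache {
  cube Z, R, C, H;  // each (hidden, batch, T)
};

static void forward_layer(const mat& W, const mat& U, const vec& b,
                          const cube& input, int d, LayerCache& cc) {
  const int H3 = W.n_rows, hidden = H3 / 3;
  const int B = input.n_cols, T = input.n_slices;
  // x-projection for all time steps in one GEMM
  mat Gx = W * cslab(input, 0, T);
  Gx.each_col() += b;
  cc.Z.set_size(hidden, B, T);
  cc.R.set_size(hidden, B, T);
  cc.C.set_size(hidden, B, T);
  cc.H.set_size(hidden, B, T);
  const mat Uzr = U.rows(0, 2 * hidden - 1);
  const mat Uc = U.rows(2 * hidden, 3 * hidden - 1);
  const mat zeros0(hidden, B * d, fill::zeros);
  for (int t0 = 0; t0 < T; t0 += d) {
    const int dd = std::min(d, T - t0);
    const mat Hprev = (t0 == 0) ? mat(zeros0.memptr(), hidden, B * dd)
                                : cslab(cc.H, t0 - d, dd);
    mat Zv = slab(cc.Z, t0, dd), Rv = slab(cc.R, t0, dd);
    mat Cv = slab(cc.C, t0, dd), Hv = slab(cc.H, t0, dd);
    const int c0 = t0 * B, c1 = (t0 + dd) * B - 1;
    mat Azr = Gx.submat(0, c0, 2 * hidden - 1, c1) + Uzr * Hprev;
    Zv = 1.0 / (1.0 + exp(-Azr.rows(0, hidden - 1)));
    Rv = 1.0 / (1.0 + exp(-Azr.rows(hidden, 2 * hidden - 1)));
    Cv = tanh(Gx.submat(2 * hidden, c0, 3 * hidden - 1, c1) + Uc * (Rv % Hprev));
    Hv = (1.0 - Zv) % Hprev + Zv % Cv;
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_drnn_forward(Rcpp::List params, const arma::mat& X,
                            Rcpp::IntegerVector dilations, bool want_cache,
                            int pool = 1) {
  const int T = X.n_rows, B = X.n_cols;
  const int L = params.size();
  if ((int)dilations.size() != L)
    Rcpp::stop("length(dilations) must equal the number of layers");
  int dmax = 0;
  for (int l = 0; l < L; ++l) dmax = std::max(dmax, (int)dilations[l]);
  if (T < dmax) Rcpp::stop("sequence shorter than the maximum dilation");
  if (pool < 1 || pool > T) Rcpp::stop("invalid readout pool size");
  std::vector<LayerCache> caches(L);
  cube input(1, B, T);
  // time-major input rows become slices of a (1, B, T) cube
  mat(input.memptr(), B, T, false, true) = X.t();
  for (int l = 0; l < L; ++l) {
    Rcpp::List lay = params[l];
    mat W = Rcpp::as<mat>(lay["W"]);
    mat U = Rcpp::as<mat>(lay["U"]);
    vec b = Rcpp::as<vec>(lay["b"]);
    forward_layer(W, U, b, l == 0 ? input : caches[l - 1].H,
                  dilations[l], caches[l]);
  }
  // readout state: mean of the top layer's last `pool` hidden states
  // (pool = d_L covers every recurrence chain of the top layer once)
  mat h_last = caches[L - 1].H.slice(T - 1);
  for (int t = T - pool; t < T - 1; ++t) h_last += caches[L - 1].H.slice(t);
  h_last /= (double)pool;
  if (!want_cache) return Rcpp::List::create(Rcpp::Named("h_last") = h_last);
  Rcpp::List cl(L);
  for (int l = 0; l < L; ++l) {
    cl[l] = Rcpp::List::create(Rcpp::Named("Z") = caches[l].Z,
                               Rcpp::Named("R") = caches[l].R,
                               Rcpp::Named("C") = caches[l].C,
                               Rcpp::Named("H") = caches[l].H);
  }
  return Rcpp::List::create(Rcpp::Named("h_last") = h_last,
                            Rcpp::Named("cache") = cl);
}

// [[Rcpp::export]]
Rcpp::List cpp_drnn_backward(Rcpp::List params, const arma::mat& X,
                             Rcpp::List cache, const arma::mat& dh_last,
                             Rcpp::IntegerVector dilations, int pool = 1) {
  const int T = X.n_rows, B = X.n_cols;
  const int L = params.size();
  Rcpp::List grads(L);
  cube dH_below;  // gradient w.r.t. the input of the layer just processed
  cube input0;
  for (int l = L - 1; l >= 0; --l) {
    Rcpp::List lay = params[l];
    mat W = Rcpp::as<mat>(lay["W"]);
    mat U = Rcpp::as<mat>(lay["U"]);
    const int H3 = W.n_rows, hidden = H3 / 3, in_dim = W.n_cols;
    const int d = dilations[l];
    Rcpp::List cc = cache[l];
    cube Z = Rcpp::as<cube>(cc["Z"]);
    cube R = Rcpp::as<cube>(cc["R"]);
    cube C = Rcpp::as<cube>(cc["C"]);
    cube H = Rcpp::as<cube>(cc["H"]);
    // this layer's input sequence
    const cube* inp;
    cube in_lower;
    if (l == 0) {
      input0.set_size(1, B, T);
      mat(input0.memptr(), B, T, false, true) = X.t();
      inp = &input0;
    } else {
      Rcpp::List ccb = cache[l - 1];
      in_lower = Rcpp::as<cube>(ccb["H"]);
      inp = &in_lower;
    }
    cube dH(hidden, B, T, fill::zeros);
    if (l == L - 1) {
      for (int t = T - pool; t < T; ++t) dH.slice(t) = dh_last / (double)pool;
    } else {
      dH = std::move(dH_below);
    }
    const mat Uzr = U.rows(0, 2 * hidden - 1);
    const mat Uc = U.rows(2 * hidden, 3 * hidden - 1);
    mat dW(H3, in_dim, fill::zeros), dU(H3, hidden, fill::zeros);
    vec db(H3, fill::zeros);
    cube dIn(in_dim, B, T);
    const mat zeros0(hidden, B * d, fill::zeros);
    for (int t0 = ((T - 1) / d) * d; t0 >= 0; t0 -= d) {
      const int dd = std::min(d, T - t0);
      const mat Hprev = (t0 == 0) ? mat(zeros0.memptr(), hidden, B * dd)
                                  : cslab(H, t0 - d, dd);
      const mat Zb = cslab(Z, t0, dd), Rb = cslab(R, t0, dd),
                Cb = cslab(C, t0, dd), dHb = cslab(dH, t0, dd),
                Inb = cslab(*inp, t0, dd);
      mat dz = dHb % (Cb - Hprev) % Zb % (1.0 - Zb);
      mat dc = dHb % Zb % (1.0 - Cb % Cb);
      mat dhprev = dHb % (1.0 - Zb);
      mat q = Uc.t() * dc;
      mat dr = q % Hprev % Rb % (1.0 - Rb);
      dhprev += q % Rb;
      mat dzr = join_cols(dz, dr);
      dhprev += Uzr.t() * dzr;
      dW.rows(0, 2 * hidden - 1) += dzr * Inb.t();
      dW.rows(2 * hidden, 3 * hidden - 1) += dc * Inb.t();
      db.subvec(0, 2 * hidden - 1) += sum(dzr, 1);
      db.subvec(2 * hidden, 3 * hidden - 1) += sum(dc, 1);
      dU.rows(0, 2 * hidden - 1) += dzr * Hprev.t();
      dU.rows(2 * hidden, 3 * hidden - 1) += dc * (Rb % Hprev).t();
      mat dInb = slab(dIn, t0, dd);
      dInb = W.rows(0, 2 * hidden - 1).t() * dzr +
             W.rows(2 * hidden, 3 * hidden - 1).t() * dc;
      if (t0 >= d) {
        mat acc = slab(dH, t0 - d, dd);
        acc += dhprev;
      }
    }
    grads[l] = Rcpp::List::create(Rcpp::Named("W") = dW,
                                  Rcpp::Named("U") = dU,
                                  Rcpp::Named("b") = db);
    dH_below = dIn;
  }
  return grads;
}
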