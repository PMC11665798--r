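// Two-layer LSTM with step / instrument / RSD heads, prior-step-context
// input features, weighted cross-entropy + Smooth L1 losses and truncated
// BPTT. The context path (previous step probabilities appended to the
// input) is treated as data during backprop (stop-gradient), matching
// teacher-free online unrolling.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct NetConfig {
  int D, F, S, nI, H;
  bool use_step, use_instr, use_context;
  int t_hat;
  double beta;           // Smooth L1 transition point
  double lw_step, lw_instr, lw_rsd;
  int tbptt;
};

static NetConfig read_config(const Rcpp::List& cfg) {
  NetConfig c;
  c.D = Rcpp::as<int>(cfg["D"]);
  c.S = Rcpp::as<int>(cfg["S"]);
  c.nI = Rcpp::as<int>(cfg["n_instruments"]);
  c.H = Rcpp::as<int>(cfg["H"]);
  c.use_step = Rcpp::as<bool>(cfg["use_step"]);
  c.use_instr = Rcpp::as<bool>(cfg["use_instr"]);
  c.use_context = Rcpp::as<bool>(cfg["use_context"]);
  c.t_hat = Rcpp::as<int>(cfg["t_hat"]);
  c.beta = Rcpp::as<double>(cfg["beta"]);
  c.lw_step = Rcpp::as<double>(cfg["lw_step"]);
  c.lw_instr = Rcpp::as<double>(cfg["lw_instr"]);
  c.lw_rsd = Rcpp::as<double>(cfg["lw_rsd"]);
  c.tbptt = Rcpp::as<int>(cfg["tbptt"]);
  c.F = c.D + 1 + (c.use_context ? 2 * c.S : 0);
  return c;
}

struct Params {
  mat W1, U1, W2, U2, Ws, Wi;
  vec b1, b2, bs, bi, Wr; // Wr: H-vector for the scalar RSD head
  double br;
};

static Params read_params(const Rcpp::List& p) {
  Params q;
  q.W1 = Rcpp::as<mat>(p["W1"]); q.U1 = Rcpp::as<mat>(p["U1"]);
  q.b1 = Rcpp::as<vec>(p["b1"]);
  q.W2 = Rcpp::as<mat>(p["W2"]); q.U2 = Rcpp::as<mat>(p["U2"]);
  q.b2 = Rcpp::as<vec>(p["b2"]);
  q.Ws = Rcpp::as<mat>(p["Ws"]); q.bs = Rcpp::as<vec>(p["bs"]);
  q.Wi = Rcpp::as<mat>(p["Wi"]); q.bi = Rcpp::as<vec>(p["bi"]);
  q.Wr = Rcpp::as<vec>(p["Wr"]); q.br = Rcpp::as<double>(p["br"]);
  return q;
}

static inline vec sigmoid(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

static inline vec softmax_vec(const vec& z) {
  vec e = exp(z - z.max());
  return e / accu(e);
}

// running prior-step-context state: previous step probs + FIFO mean
struct ContextState {
  int S, t_hat;
  std::deque<vec> buffer;
  vec last;
  vec buf_sum;
  ContextState(int S_, int t_hat_) : S(S_), t_hat(t_hat_) {
    last = vec(S, fill::value(1.0 / S));
    buf_sum = vec(S, fill::zeros);
  }
  vec block() const {
    vec out(2 * S);
    out.subvec(0, S - 1) = last;
    if (buffer.empty()) {
      out.subvec(S, 2 * S - 1) = vec(S, fill::value(1.0 / S));
    } else {
      out.subvec(S, 2 * S - 1) = buf_sum / (double)buffer.size();
    }
    return out;
  }
  void push(const vec& p) {
    last = p;
    buffer.push_back(p);
    buf_sum += p;
    if ((int)buffer.size() > t_hat) {
      buf_sum -= buffer.front();
      buffer.pop_front();
    }
  }
};

static vec build_input(const NetConfig& c, const vec& feat, double elapsed_sec,
                       const ContextState& ctx) {
  vec x(c.F);
  x.subvec(0, c.D - 1) = feat;
  x(c.D) = elapsed_sec / 3600.0;
  if (c.use_context) x.subvec(c.D + 1, c.F - 1) = ctx.block();
  return x;
}

struct ChunkCache {
  mat X;                                  // F x L inputs
  mat I1, F1, G1, O1, C1, H1;             // layer-1 activations
  mat I2, F2, G2, O2, C2, H2;             // layer-2 activations
  vec h1_in, c1_in, h2_in, c2_in;         // carried state entering the chunk
};

static void forward_step(const NetConfig& c, const Params& p, const vec& x,
                         vec& h1, vec& c1, vec& h2, vec& c2,
                         vec& i1, vec& f1, vec& g1, vec& o1,
                         vec& i2, vec& f2, vec& g2, vec& o2) {
  int H = c.H;
  vec a1 = p.W1 * x + p.U1 * h1 + p.b1;
  i1 = sigmoid(a1.subvec(0, H - 1));
  f1 = sigmoid(a1.subvec(H, 2 * H - 1));
  g1 = tanh(a1.subvec(2 * H, 3 * H - 1));
  o1 = sigmoid(a1.subvec(3 * H, 4 * H - 1));
  c1 = f1 % c1 + i1 % g1;
  h1 = o1 % tanh(c1);
  vec a2 = p.W2 * h1 + p.U2 * h2 + p.b2;
  i2 = sigmoid(a2.subvec(0, H - 1));
  f2 = sigmoid(a2.subvec(H, 2 * H - 1));
  g2 = tanh(a2.subvec(2 * H, 3 * H - 1));
  o2 = sigmoid(a2.subvec(3 * H, 4 * H - 1));
  c2 = f2 % c2 + i2 % g2;
  h2 = o2 % tanh(c2);
}

static inline double smooth_l1(double r, double beta, double& grad) {
  double ar = std::fabs(r);
  if (ar < beta) { grad = r / beta; return 0.5 * r * r / beta; }
  grad = (r > 0) ? 1.0 : -1.0;
  return ar - 0.5 * beta;
}

// Forward + truncated BPTT over one video. Returns total/mean losses and
// gradients for all parameters. Unused heads yield zero gradients.
// [[Rcpp::export]]
Rcpp::List lstm_grad_video_cpp(Rcpp::List params, const arma::mat& feat,
                               const arma::vec& elapsed,
                               const arma::ivec& y_step,
                               const arma::ivec& y_instr,
                               const arma::vec& rsd_norm,
                               const arma::vec& w_step,
                               const arma::vec& w_instr,
                               Rcpp::List cfg) {
  NetConfig c = read_config(cfg);
  Params p = read_params(params);
  int T = feat.n_cols, H = c.H;
  if ((int)feat.n_rows != c.D) Rcpp::stop("feature dimension mismatch");

  mat gW1(size(p.W1), fill::zeros), gU1(size(p.U1), fill::zeros);
  mat gW2(size(p.W2), fill::zeros), gU2(size(p.U2), fill::zeros);
  mat gWs(size(p.Ws), fill::zeros), gWi(size(p.Wi), fill::zeros);
  vec gb1(size(p.b1), fill::zeros), gb2(size(p.b2), fill::zeros);
  vec gbs(size(p.bs), fill::zeros), gbi(size(p.bi), fill::zeros);
  vec gWr(size(p.Wr), fill::zeros);
  double gbr = 0.0;

  double loss_step = 0.0, loss_instr = 0.0, loss_rsd = 0.0;

  ContextState ctx(c.S, c.t_hat);
  vec h1(H, fill::zeros), c1(H, fill::zeros), h2(H, fill::zeros), c2(H, fill::zeros);

  int a = 0;
  while (a < T) {
    int b = std::min(T, a + c.tbptt);
    int L = b - a;
    ChunkCache cc;
    cc.X.set_size(c.F, L);
    cc.I1.set_size(H, L); cc.F1.set_size(H, L); cc.G1.set_size(H, L);
    cc.O1.set_size(H, L); cc.C1.set_size(H, L); cc.H1.set_size(H, L);
    cc.I2.set_size(H, L); cc.F2.set_size(H, L); cc.G2.set_size(H, L);
    cc.O2.set_size(H, L); cc.C2.set_size(H, L); cc.H2.set_size(H, L);
    cc.h1_in = h1; cc.c1_in = c1; cc.h2_in = h2; cc.c2_in = c2;

    mat P(c.S, L, fill::zeros);        // step probabilities
    mat Pi(c.use_instr ? c.nI : 1, L, fill::zeros);
    vec rsd_res_grad(L, fill::zeros);  // d smoothL1 / d pred

    // ---- forward over the chunk ----
    for (int t = a; t < b; ++t) {
      int k = t - a;
      vec x = build_input(c, feat.col(t), elapsed(t), ctx);
      cc.X.col(k) = x;
      vec i1v, f1v, g1v, o1v, i2v, f2v, g2v, o2v;
      forward_step(c, p, x, h1, c1, h2, c2, i1v, f1v, g1v, o1v, i2v, f2v, g2v, o2v);
      cc.I1.col(k) = i1v; cc.F1.col(k) = f1v; cc.G1.col(k) = g1v; cc.O1.col(k) = o1v;
      cc.C1.col(k) = c1;  cc.H1.col(k) = h1;
      cc.I2.col(k) = i2v; cc.F2.col(k) = f2v; cc.G2.col(k) = g2v; cc.O2.col(k) = o2v;
      cc.C2.col(k) = c2;  cc.H2.col(k) = h2;

      if (c.use_step || c.use_context) {
        vec zs = p.Ws * h2 + p.bs;
        P.col(k) = softmax_vec(zs);
      }
      if (c.use_step && y_step(t) >= 0) {
        double py = std::max(P(y_step(t), k), 1e-12);
        loss_step += w_step(y_step(t)) * (-std::log(py));
      }
      if (c.use_instr) {
        vec zi = p.Wi * h2 + p.bi;
        Pi.col(k) = softmax_vec(zi);
        if (y_instr(t) >= 0) {
          double py = std::max(Pi(y_instr(t), k), 1e-12);
          loss_instr += w_instr(y_instr(t)) * (-std::log(py));
        }
      }
      double pred = dot(p.Wr, h2) + p.br;
      double g;
      loss_rsd += smooth_l1(pred - rsd_norm(t), c.beta, g);
      rsd_res_grad(k) = g;

      if (c.use_context) ctx.push(P.col(k));
    }

    // ---- backward over the chunk (stop-gradient at chunk entry) ----
    vec dh1_next(H, fill::zeros), dc1_next(H, fill::zeros);
    vec dh2_next(H, fill::zeros), dc2_next(H, fill::zeros);
    double inv_T = 1.0 / (double)T;
    for (int k = L - 1; k >= 0; --k) {
      int t = a + k;
      vec h2k = cc.H2.col(k);
      vec dh2 = dh2_next;
      // heads
      if (c.use_step && c.lw_step != 0.0 && y_step(t) >= 0) {
        vec dz = P.col(k);
        dz(y_step(t)) -= 1.0;
        dz *= w_step(y_step(t)) * c.lw_step * inv_T;
        gWs += dz * h2k.t();
        gbs += dz;
        dh2 += p.Ws.t() * dz;
      }
      if (c.use_instr && c.lw_instr != 0.0 && y_instr(t) >= 0) {
        vec dz = Pi.col(k);
        dz(y_instr(t)) -= 1.0;
        dz *= w_instr(y_instr(t)) * c.lw_instr * inv_T;
        gWi += dz * h2k.t();
        gbi += dz;
        dh2 += p.Wi.t() * dz;
      }
      if (c.lw_rsd != 0.0) {
        double dr = rsd_res_grad(k) * c.lw_rsd * inv_T;
        gWr += dr * h2k;
        gbr += dr;
        dh2 += dr * p.Wr;
      }
      // layer 2 cell backward
      vec tc2 = tanh(cc.C2.col(k));
      vec dc2 = dc2_next + dh2 % cc.O2.col(k) % (1.0 - tc2 % tc2);
      vec c2prev = (k == 0) ? cc.c2_in : vec(cc.C2.col(k - 1));
      vec di2 = dc2 % cc.G2.col(k) % cc.I2.col(k) % (1.0 - cc.I2.col(k));
      vec df2 = dc2 % c2prev % cc.F2.col(k) % (1.0 - cc.F2.col(k));
      vec dg2 = dc2 % cc.I2.col(k) % (1.0 - cc.G2.col(k) % cc.G2.col(k));
      vec do2 = dh2 % tc2 % cc.O2.col(k) % (1.0 - cc.O2.col(k));
      vec da2 = join_vert(join_vert(di2, df2), join_vert(dg2, do2));
      vec h1k = cc.H1.col(k);
      vec h2prev = (k == 0) ? cc.h2_in : vec(cc.H2.col(k - 1));
      gW2 += da2 * h1k.t();
      gU2 += da2 * h2prev.t();
      gb2 += da2;
      dc2_next = dc2 % cc.F2.col(k);
      dh2_next = p.U2.t() * da2;
      vec dh1 = dh1_next + p.W2.t() * da2;
      // layer 1 cell backward
      vec tc1 = tanh(cc.C1.col(k));
      vec dc1 = dc1_next + dh1 % cc.O1.col(k) % (1.0 - tc1 % tc1);
      vec c1prev = (k == 0) ? cc.c1_in : vec(cc.C1.col(k - 1));
      vec di1 = dc1 % cc.G1.col(k) % cc.I1.col(k) % (1.0 - cc.I1.col(k));
      vec df1 = dc1 % c1prev % cc.F1.col(k) % (1.0 - cc.F1.col(k));
      vec dg1 = dc1 % cc.I1.col(k) % (1.0 - cc.G1.col(k) % cc.G1.col(k));
      vec do1 = dh1 % tc1 % cc.O1.col(k) % (1.0 - cc.O1.col(k));
      vec da1 = join_vert(join_vert(di1, df1), join_vert(dg1, do1));
      vec h1prev = (k == 0) ? cc.h1_in : vec(cc.H1.col(k - 1));
      gW1 += da1 * cc.X.col(k).t();
      gU1 += da1 * h1prev.t();
      gb1 += da1;
      dc1_next = dc1 % cc.F1.col(k);
      dh1_next = p.U1.t() * da1;
    }
    a = b;
  }

  double inv_T = (T > 0) ? 1.0 / (double)T : 0.0;
  double ls = loss_step * inv_T, li = loss_instr * inv_T, lr = loss_rsd * inv_T;
  return Rcpp::List::create(
    Rcpp::Named("loss") = c.lw_step * ls + c.lw_instr * li + c.lw_rsd * lr,
    Rcpp::Named("loss_step") = ls,
    Rcpp::Named("loss_instr") = li,
    Rcpp::Named("loss_rsd") = lr,
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("W1") = gW1, Rcpp::Named("U1") = gU1, Rcpp::Named("b1") = gb1,
      Rcpp::Named("W2") = gW2, Rcpp::Named("U2") = gU2, Rcpp::Named("b2") = gb2,
      Rcpp::Named("Ws") = gWs, Rcpp::Named("bs") = gbs,
      Rcpp::Named("Wi") = gWi, Rcpp::Named("bi") = gbi,
      Rcpp::Named("Wr") = gWr, Rcpp::Named("br") = gbr
    )
  );
}

// Strictly causal online inference over one video: output at second t is a
// function of frames 0..t only. Returns normalized RSD predictions, step
// (and instrument) probability series and optionally the realized input
// trace (for context-construction checks).
// [[Rcpp::export]]
Rcpp::List lstm_predict_video_cpp(Rcpp::List params, const arma::mat& feat,
                                  const arma::vec& elapsed, Rcpp::List cfg,
                                  bool return_inputs = false) {
  NetConfig c = read_config(cfg);
  Params p = read_params(params);
  int T = feat.n_cols, H = c.H;
  if (T > 0 && (int)feat.n_rows != c.D) Rcpp::stop("feature dimension mismatch");

  vec rsd_pred(T, fill::zeros);
  mat P(c.S, T, fill::zeros);
  mat Pi(c.use_instr ? c.nI : 1, c.use_instr ? T : 0, fill::zeros);
  mat X;
  if (return_inputs) X.set_size(c.F, T);

  ContextState ctx(c.S, c.t_hat);
  vec h1(H, fill::zeros), c1(H, fill::zeros), h2(H, fill::zeros), c2(H, fill::zeros);
  for (int t = 0; t < T; ++t) {
    vec x = build_input(c, feat.col(t), elapsed(t), ctx);
    if (return_inputs) X.col(t) = x;
    vec i1v, f1v, g1v, o1v, i2v, f2v, g2v, o2v;
    forward_step(c, p, x, h1, c1, h2, c2, i1v, f1v, g1v, o1v, i2v, f2v, g2v, o2v);
    if (c.use_step || c.use_context) P.col(t) = softmax_vec(p.Ws * h2 + p.bs);
    if (c.use_instr) Pi.col(t) = softmax_vec(p.Wi * h2 + p.bi);
    rsd_pred(t) = dot(p.Wr, h2) + p.br;
    if (c.use_context) ctx.push(P.col(t));
  }
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("rsd_norm") = rsd_pred,
    Rcpp::Named("step_probs") = P,
    Rcpp::Named("instr_probs") = Pi
  );
  if (return_inputs) out["inputs"] = X;
  return out;
}
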