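// Bootstrap forward/backward stepwise selection scored by median
// out-of-bootstrap balanced accuracy of a ridge-stabilized IRLS logistic
// model. The full loop lives here because it evaluates thousands of small
// logistic fits: per-resample row subsets are gathered once per call, every
// fit warm starts from the full-sample solution of its column set, and a
// tiny ridge (1e-6) keeps Newton steps finite under separation.
// Predictions threshold the linear predictor at 0.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double RIDGE = 1e-6;

static void irls(const arma::mat& X, const arma::vec& y, arma::vec& beta,
                 int max_iter, double tol) {
  arma::mat A(X.n_cols, X.n_cols);
  arma::vec bnew;
  for (int iter = 0; iter < max_iter; ++iter) {
    arma::vec eta = arma::clamp(X * beta, -30.0, 30.0);
    arma::vec p = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = p % (1.0 - p) + 1e-10;
    A = X.t() * (X.each_col() % w);
    A.diag() += RIDGE;
    if (!arma::solve(bnew, A, X.t() * (y - p) + A * beta,
                     arma::solve_opts::likely_sympd)) {
      return;
    }
    double delta = arma::abs(bnew - beta).max();
    beta = bnew;
    if (delta < tol) break;
  }
}

static double bac(const arma::vec& y, const arma::vec& eta) {
  double tp = 0, fn = 0, tn = 0, fp = 0;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    bool pred = eta(i) > 0;
    if (y(i) > 0.5) { if (pred) tp++; else fn++; }
    else            { if (pred) fp++; else tn++; }
  }
  if (tp + fn == 0 || tn + fp == 0) return NA_REAL; // single-class OOB draw
  return 0.5 * (tp / (tp + fn) + tn / (tn + fp));
}

// median of the finite values plus the large-sample standard error of the
// median (1.2533 * sd / sqrt(n)), used to scale the forward-improvement bar
struct MedSE { double med, se; };

static MedSE median_finite(std::vector<double>& v) {
  std::vector<double> f;
  f.reserve(v.size());
  for (double x : v) if (R_finite(x)) f.push_back(x);
  if (f.empty()) return {NA_REAL, NA_REAL};
  std::sort(f.begin(), f.end());
  size_t n = f.size();
  double med = n % 2 ? f[n / 2] : 0.5 * (f[n / 2 - 1] + f[n / 2]);
  double mean = 0, ss = 0;
  for (double x : f) mean += x;
  mean /= n;
  for (double x : f) ss += (x - mean) * (x - mean);
  double sd = n > 1 ? std::sqrt(ss / (n - 1)) : 0.0;
  return {med, 1.2533 * sd / std::sqrt((double)n)};
}

namespace {

// all candidate columns of X with intercept in column 0, plus the row
// subsets of every bootstrap resample, gathered once
struct StepData {
  arma::mat X1;                    // n x (C+1)
  arma::vec y;
  std::vector<arma::mat> Xtr, Xte; // per resample
  std::vector<arma::vec> ytr, yte;

  StepData(const arma::mat& X, const arma::vec& y_,
           const List& tr, const List& te) : y(y_) {
    X1.set_size(X.n_rows, X.n_cols + 1);
    X1.col(0).ones();
    if (X.n_cols > 0) X1.cols(1, X.n_cols) = X;
    const int B = tr.size();
    Xtr.reserve(B); Xte.reserve(B); ytr.reserve(B); yte.reserve(B);
    for (int b = 0; b < B; ++b) {
      arma::uvec itr = as<arma::uvec>(tr[b]);
      arma::uvec ite = as<arma::uvec>(te[b]);
      Xtr.push_back(X1.rows(itr));
      Xte.push_back(X1.rows(ite));
      ytr.push_back(y.elem(itr));
      yte.push_back(y.elem(ite));
    }
  }

  // median OOB BAC of the logistic model on 1-based candidate columns
  // (0 = intercept, always included)
  MedSE score(const std::vector<int>& cols) const {
    if (cols.empty()) return {0.5, 0.0};
    arma::uvec use(cols.size() + 1);
    use(0) = 0;
    for (size_t j = 0; j < cols.size(); ++j) use(j + 1) = cols[j];
    arma::vec beta0(use.n_elem, arma::fill::zeros);
    irls(X1.cols(use), y, beta0, 8, 1e-7); // warm-start solution
    std::vector<double> bacs(Xtr.size());
    for (size_t b = 0; b < Xtr.size(); ++b) {
      arma::vec beta = beta0;
      // two capped Newton refinements from the full-sample optimum are
      // enough to rank models by OOB BAC; predictions need only sign(eta)
      irls(Xtr[b].cols(use), ytr[b], beta, 2, 1e-6);
      bacs[b] = bac(yte[b], Xte[b].cols(use) * beta);
    }
    return median_finite(bacs);
  }
};

} // namespace

// median OOB BAC of one column set (1-based columns of X); exposed for the
// R-level scoring used in diagnostics
// [[Rcpp::export(name = ".oob_score")]]
double oob_score(const arma::mat& X, const arma::vec& y,
                 const List& train_idx, const List& oob_idx,
                 const IntegerVector& cols) {
  StepData sd(X, y, train_idx, oob_idx);
  return sd.score(std::vector<int>(cols.begin(), cols.end())).med;
}

// full forward/backward stepwise over the candidate columns of X (which
// holds ONLY the candidates, ordered lexicographically by variable id so
// that first-maximum tie-breaking is lexicographic). Returns the 1-based
// selected column indices.
// [[Rcpp::export(name = ".stepwise_select")]]
IntegerVector stepwise_select(const arma::mat& X, const arma::vec& y,
                              const List& train_idx, const List& oob_idx,
                              double tol) {
  StepData sd(X, y, train_idx, oob_idx);
  const int C = X.n_cols;
  std::vector<int> selected;            // insertion order, 1-based
  std::vector<bool> in_model(C + 1, false);
  double current = 0.5;

  // forward: add the best improver, ties to the lowest index; the
  // improvement must exceed max(tol, 2 * SE(median)) so that Monte-Carlo
  // jitter of the median cannot admit a variable
  while ((int)selected.size() < C) {
    double best_score = -1.0, best_se = 0.0;
    int best_col = -1;
    std::vector<int> trial = selected;
    trial.push_back(0);
    for (int c = 1; c <= C; ++c) {
      if (in_model[c]) continue;
      trial.back() = c;
      MedSE s = sd.score(trial);
      if (R_finite(s.med) && s.med > best_score) {
        best_score = s.med; best_se = s.se; best_col = c;
      }
    }
    double bar = current + std::max(tol, 2.0 * best_se);
    if (best_col < 0 || !(best_score > bar)) break;
    selected.push_back(best_col);
    in_model[best_col] = true;
    current = best_score;
  }

  // backward: one sweep in lexicographic (column) order, removing each
  // variable whose removal does not reduce the running score
  std::vector<int> order = selected;
  std::sort(order.begin(), order.end());
  for (int c : order) {
    if (selected.size() <= 1) break;
    std::vector<int> without;
    for (int s : selected) if (s != c) without.push_back(s);
    MedSE s = sd.score(without);
    if (R_finite(s.med) && s.med >= current) {
      selected = without;
      in_model[c] = false;
      current = s.med;
    }
  }
  std::sort(selected.begin(), selected.end());
  return wrap(selected);
}
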