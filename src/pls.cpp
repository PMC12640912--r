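// Single-response PLS (NIPALS) core and the cross-validated exhaustive
// subset search. Kept in C++ because the search evaluates every nonempty
// subset of up to 20 screened candidates, each under 10-fold CV.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Predictions on Xte for every component count 1..kmax, training on
// (Xtr, ytr). Columns of the result are cumulative component predictions;
// if the response deflates to numerical zero before kmax, remaining
// columns repeat the last valid prediction.
static mat pls1_predict_path(const mat& Xtr, const vec& ytr, const mat& Xte,
                             int kmax) {
  rowvec mx = mean(Xtr, 0);
  rowvec sx = stddev(Xtr, 0, 0);
  sx.replace(0.0, 1.0);
  mat E = Xtr.each_row() - mx;
  E.each_row() /= sx;
  mat Te = Xte.each_row() - mx;
  Te.each_row() /= sx;
  double my = mean(ytr);
  vec f = ytr - my;

  mat preds(Xte.n_rows, kmax);
  vec acc(Xte.n_rows, fill::zeros);
  for (int k = 0; k < kmax; ++k) {
    vec w = E.t() * f;
    double nw = norm(w);
    if (nw < 1e-12) {
      for (int kk = k; kk < kmax; ++kk) preds.col(kk) = acc + my;
      return preds;
    }
    w /= nw;
    vec t = E * w;
    double tt = dot(t, t);
    if (tt < 1e-12) {
      for (int kk = k; kk < kmax; ++kk) preds.col(kk) = acc + my;
      return preds;
    }
    vec p = E.t() * t / tt;
    double q = dot(f, t) / tt;
    vec tte = Te * w;
    acc += tte * q;
    preds.col(k) = acc + my;
    E -= t * p.t();
    f -= t * q;
    Te -= tte * p.t();
  }
  return preds;
}

// PRESS_k (k = 1..kmax) over a fixed fold partition (fold ids 1..n_folds).
static vec cv_press_core(const mat& X, const vec& y, const ivec& fold,
                         int kmax) {
  int n_folds = fold.max();
  vec press(kmax, fill::zeros);
  for (int f = 1; f <= n_folds; ++f) {
    uvec te = find(fold == f);
    uvec tr = find(fold != f);
    if (te.n_elem == 0) continue;
    mat P = pls1_predict_path(X.rows(tr), y.elem(tr), X.rows(te), kmax);
    for (int k = 0; k < kmax; ++k) {
      vec r = y.elem(te) - P.col(k);
      press(k) += dot(r, r);
    }
  }
  return press;
}

// [[Rcpp::export]]
arma::vec cpp_cv_press(const arma::mat& X, const arma::vec& y,
                       const arma::ivec& fold, int kmax) {
  return cv_press_core(X, y, fold, kmax);
}

// BIC_k = n log(PRESS_k / n) + (k + 1) log(n); argmin, ties to smaller k.
static int bic_argmin(const vec& press, int n, vec& bic) {
  int kmax = press.n_elem;
  bic.set_size(kmax);
  int best = 0;
  for (int k = 0; k < kmax; ++k) {
    double pk = std::max(press(k), 1e-300);
    bic(k) = n * std::log(pk / n) + (k + 2) * std::log((double)n);
    if (bic(k) < bic(best) - 1e-12) best = k;
  }
  return best + 1;  // 1-based component count
}

// Exhaustive search over every nonempty subset of the candidate columns of
// X. Each subset selects its component count by CV-PRESS BIC
// (kmax = min(|subset|, kcap)) and is scored by CV R^2 on the same folds.
// Ties break to fewer features, then to the lexicographically smaller
// name-rank sequence (name_rank: alphabetical rank of each candidate).
// [[Rcpp::export]]
Rcpp::List cpp_subset_search(const arma::mat& X, const arma::vec& y,
                             const arma::ivec& fold, int kcap,
                             const arma::ivec& name_rank) {
  int p = X.n_cols;
  int n = X.n_rows;
  double tss = 0.0, my = mean(y);
  for (int i = 0; i < n; ++i) tss += (y(i) - my) * (y(i) - my);

  unsigned long n_subsets = (1UL << p) - 1UL;
  double best_r2 = -datum::inf;
  unsigned long best_mask = 0;
  int best_k = 1, best_size = p + 1;
  std::vector<int> best_names;

  for (unsigned long mask = 1; mask <= n_subsets; ++mask) {
    int sz = __builtin_popcountl(mask);
    uvec cols(sz);
    std::vector<int> names(sz);
    int j = 0;
    for (int c = 0; c < p; ++c)
      if (mask & (1UL << c)) { cols(j) = c; names[j] = name_rank(c); ++j; }
    std::sort(names.begin(), names.end());

    mat Xs = X.cols(cols);
    int kmax = std::min(sz, kcap);
    vec press = cv_press_core(Xs, y, fold, kmax);
    vec bic;
    int k = bic_argmin(press, n, bic);
    double r2 = 1.0 - press(k - 1) / tss;

    bool better = false;
    if (r2 > best_r2 + 1e-12) better = true;
    else if (r2 > best_r2 - 1e-12) {
      if (sz < best_size) better = true;
      else if (sz == best_size && names < best_names) better = true;
    }
    if (better) {
      best_r2 = r2; best_mask = mask; best_k = k; best_size = sz;
      best_names = names;
    }
  }

  Rcpp::IntegerVector sel;
  for (int c = 0; c < p; ++c)
    if (best_mask & (1UL << c)) sel.push_back(c + 1);  // 1-based
  return Rcpp::List::create(
    Rcpp::Named("columns") = sel,
    Rcpp::Named("n_components") = best_k,
    Rcpp::Named("cv_r2") = best_r2,
    Rcpp::Named("n_subsets_evaluated") = (double)n_subsets);
}

// Lean fit-and-R2 used by the adjusted-R2 permutation null: fits a k-component
// PLS on (X, y) and returns the in-sample R^2.
// [[Rcpp::export]]
double cpp_pls_insample_r2(const arma::mat& X, const arma::vec& y, int k) {
  mat P = pls1_predict_path(X, y, X, k);
  vec r = y - P.col(k - 1);
  double my = mean(y), tss = 0.0;
  for (unsigned int i = 0; i < y.n_elem; ++i)
    tss += (y(i) - my) * (y(i) - my);
  return 1.0 - dot(r, r) / tss;
}
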