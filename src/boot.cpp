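#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Weighted discrimination metrics on a fixed fold, evaluated many times
// with changing resample weights. Scores never change across replicates,
// so the sort order and tie groups are precomputed once per (model, fold).

struct FoldModel {
  std::vector<int> ord;   // positions sorted by score ascending
  std::vector<int> grp;   // tie-group id per sorted position (ascending)
  int n_groups;
};

static FoldModel prepare_fold(const NumericVector& scores) {
  int m = scores.size();
  FoldModel fm;
  fm.ord.resize(m);
  for (int i = 0; i < m; ++i) fm.ord[i] = i;
  std::stable_sort(fm.ord.begin(), fm.ord.end(),
                   [&](int a, int b) { return scores[a] < scores[b]; });
  fm.grp.resize(m);
  int g = 0;
  for (int i = 0; i < m; ++i) {
    if (i > 0 && scores[fm.ord[i]] != scores[fm.ord[i - 1]]) ++g;
    fm.grp[i] = g;
  }
  fm.n_groups = m ? g + 1 : 0;
  return fm;
}

// metric codes: 1 = ROC-AUC, 2 = average precision, 3 = Brier
static double weighted_metric(int code, const FoldModel& fm,
                              const std::vector<int>& yl,
                              const NumericVector& scores,
                              const std::vector<double>& w,
                              bool& valid) {
  int m = yl.size();
  double Wp = 0.0, Wn = 0.0;
  for (int i = 0; i < m; ++i) {
    if (yl[i] == 1) Wp += w[i]; else Wn += w[i];
  }
  valid = (Wp > 0.0 && Wn > 0.0);
  if (!valid) return NA_REAL;
  if (code == 3) {  // Brier
    double s = 0.0;
    for (int i = 0; i < m; ++i) {
      double d = scores[i] - yl[i];
      s += w[i] * d * d;
    }
    return s / (Wp + Wn);
  }
  if (code == 1) {  // AUC, ascending pass with half credit for ties
    double conc = 0.0, cum_neg = 0.0;
    int i = 0;
    while (i < m) {
      int g = fm.grp[i];
      double wp = 0.0, wn = 0.0;
      while (i < m && fm.grp[i] == g) {
        int j = fm.ord[i];
        if (yl[j] == 1) wp += w[j]; else wn += w[j];
        ++i;
      }
      conc += wp * (cum_neg + 0.5 * wn);
      cum_neg += wn;
    }
    return conc / (Wp * Wn);
  }
  if (code == 2) {  // noninterpolated AP, descending pass
    double ap = 0.0, tp = 0.0, fp = 0.0;
    int i = m - 1;
    while (i >= 0) {
      int g = fm.grp[i];
      double wp = 0.0, wn = 0.0;
      while (i >= 0 && fm.grp[i] == g) {
        int j = fm.ord[i];
        if (yl[j] == 1) wp += w[j]; else wn += w[j];
        --i;
      }
      tp += wp; fp += wn;
      if (wp > 0.0) ap += (wp / Wp) * (tp / (tp + fp));
    }
    return ap;
  }
  stop("unknown metric code");
}

// Confidence-interval bootstrap for the fold mean: per replicate a
// stratified with-replacement patient resample of the full sample S is
// drawn, masked to each fold's test members, the metric computed per
// fold, and the mean taken over a with-replacement resample of folds.
// All models share the patient and fold draws (the pairing contract).
// [[Rcpp::export]]
List cpp_boot_ci(IntegerVector y, List fold_idx, List model_fold_scores,
                 int n_rep, int metric_code, int n_fold_draws) {
  int n = y.size();
  int n_folds = fold_idx.size();
  int n_models = model_fold_scores.size();

  std::vector<int> pos, neg;
  for (int i = 0; i < n; ++i) (y[i] == 1 ? pos : neg).push_back(i);
  int npos = pos.size(), nneg = neg.size();

  std::vector< std::vector<int> > tidx(n_folds);
  std::vector< std::vector<int> > yl(n_folds);
  for (int f = 0; f < n_folds; ++f) {
    IntegerVector fi = fold_idx[f];
    tidx[f].resize(fi.size());
    yl[f].resize(fi.size());
    for (int i = 0; i < fi.size(); ++i) {
      tidx[f][i] = fi[i] - 1;  // to 0-based cohort index
      yl[f][i] = y[tidx[f][i]];
    }
  }
  std::vector< std::vector<FoldModel> > prep(n_models);
  std::vector< std::vector<NumericVector> > sc(n_models);
  for (int m = 0; m < n_models; ++m) {
    List folds_m = model_fold_scores[m];
    if (folds_m.size() != n_folds) stop("model/fold geometry mismatch");
    prep[m].reserve(n_folds);
    for (int f = 0; f < n_folds; ++f) {
      NumericVector s = folds_m[f];
      if ((int)s.size() != (int)tidx[f].size())
        stop("scores misaligned with fold test set");
      sc[m].push_back(s);
      prep[m].push_back(prepare_fold(s));
    }
  }

  NumericMatrix reps(n_rep, n_models);
  IntegerVector skipped(n_models);
  std::vector<int> counts(n);
  std::vector<double> fold_val(n_folds);
  std::vector<bool> fold_ok(n_folds), fold_done(n_folds);
  std::vector<int> draws(n_fold_draws);
  std::vector<double> w;

  for (int r = 0; r < n_rep; ++r) {
    std::fill(counts.begin(), counts.end(), 0);
    for (int j = 0; j < npos; ++j) {
      int k = (int)(unif_rand() * npos); if (k == npos) k = npos - 1;
      ++counts[pos[k]];
    }
    for (int j = 0; j < nneg; ++j) {
      int k = (int)(unif_rand() * nneg); if (k == nneg) k = nneg - 1;
      ++counts[neg[k]];
    }
    for (int d = 0; d < n_fold_draws; ++d) {
      int k = (int)(unif_rand() * n_folds); if (k == n_folds) k = n_folds - 1;
      draws[d] = k;
    }
    for (int m = 0; m < n_models; ++m) {
      // lazy per-fold evaluation: only folds actually drawn are scored
      std::fill(fold_done.begin(), fold_done.end(), false);
      double s = 0.0; int used = 0;
      for (int d = 0; d < n_fold_draws; ++d) {
        int f = draws[d];
        if (!fold_done[f]) {
          int fs = tidx[f].size();
          w.resize(fs);
          for (int i = 0; i < fs; ++i) w[i] = counts[tidx[f][i]];
          bool ok;
          fold_val[f] = weighted_metric(metric_code, prep[m][f], yl[f],
                                        sc[m][f], w, ok);
          fold_ok[f] = ok;
          fold_done[f] = true;
        }
        if (fold_ok[f]) { s += fold_val[f]; ++used; }
        else ++skipped[m];
      }
      reps(r, m) = used ? s / used : NA_REAL;
    }
  }
  return List::create(_["replicates"] = reps, _["skipped"] = skipped,
                      _["total_draws"] = n_rep * n_fold_draws);
}

// Prediction-interval bootstrap for a single realized split: per
// replicate one fold is drawn uniformly (the training-set choice) and
// its test set resampled with replacement, stratified by outcome.
// Models share the fold draw and the resample.
// [[Rcpp::export]]
List cpp_boot_pi(IntegerVector y, List fold_idx, List model_fold_scores,
                 int n_rep, int metric_code) {
  int n_folds = fold_idx.size();
  int n_models = model_fold_scores.size();

  std::vector< std::vector<int> > yl(n_folds);
  std::vector< std::vector<int> > fpos(n_folds), fneg(n_folds);
  for (int f = 0; f < n_folds; ++f) {
    IntegerVector fi = fold_idx[f];
    yl[f].resize(fi.size());
    for (int i = 0; i < fi.size(); ++i) {
      yl[f][i] = y[fi[i] - 1];
      (yl[f][i] == 1 ? fpos[f] : fneg[f]).push_back(i);
    }
  }
  std::vector< std::vector<FoldModel> > prep(n_models);
  std::vector< std::vector<NumericVector> > sc(n_models);
  for (int m = 0; m < n_models; ++m) {
    List folds_m = model_fold_scores[m];
    if (folds_m.size() != n_folds) stop("model/fold geometry mismatch");
    for (int f = 0; f < n_folds; ++f) {
      NumericVector s = folds_m[f];
      if ((int)s.size() != (int)yl[f].size())
        stop("scores misaligned with fold test set");
      sc[m].push_back(s);
      prep[m].push_back(prepare_fold(s));
    }
  }

  NumericMatrix reps(n_rep, n_models);
  IntegerVector skipped(n_models);
  std::vector<double> w;
  for (int r = 0; r < n_rep; ++r) {
    int f = (int)(unif_rand() * n_folds); if (f == n_folds) f = n_folds - 1;
    int fs = yl[f].size();
    int np = fpos[f].size(), nn = fneg[f].size();
    w.assign(fs, 0.0);
    for (int j = 0; j < np; ++j) {
      int k = (int)(unif_rand() * np); if (k == np) k = np - 1;
      w[fpos[f][k]] += 1.0;
    }
    for (int j = 0; j < nn; ++j) {
      int k = (int)(unif_rand() * nn); if (k == nn) k = nn - 1;
      w[fneg[f][k]] += 1.0;
    }
    for (int m = 0; m < n_models; ++m) {
      bool ok;
      reps(r, m) = weighted_metric(metric_code, prep[m][f], yl[f],
                                   sc[m][f], w, ok);
      if (!ok) ++skipped[m];
    }
  }
  return List::create(_["replicates"] = reps, _["skipped"] = skipped,
                      _["total_draws"] = n_rep);
}
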