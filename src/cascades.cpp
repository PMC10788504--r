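#include <Rcpp.h>
using namespace Rcpp;

// Branching cascade on a weighted directed graph.
//
// out_idx[i] / out_w[i]: 0-based targets and transmission probabilities of
// region i's outgoing edges (the diagonal self-persistence edge included).
// Each region active at bin t triggers each outgoing edge independently at
// t+1. Spontaneous initiations arrive as seed events: with probability
// `seed_rate` per bin, 1 + Poisson(cluster_lambda) distinct regions are
// activated together (clustered initiations are what give avalanches
// multi-event first bins, which the within-avalanche branching estimator
// needs to be unbiased). `init` lists 0-based regions forced active at
// bin 0. Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
LogicalMatrix simulate_raster_cpp(List out_idx, List out_w, int n_regions,
                                  double seed_rate, double cluster_lambda,
                                  int n_bins, IntegerVector init) {
  LogicalMatrix raster(n_regions, n_bins);
  std::vector<char> mark(n_regions, 0);
  std::vector<int> active, pool(n_regions);
  active.reserve(n_regions);
  for (int r = 0; r < n_regions; ++r) pool[r] = r;
  for (int k = 0; k < init.size(); ++k) mark[init[k]] = 1;
  for (int t = 0; t < n_bins; ++t) {
    if (seed_rate > 0 && unif_rand() < seed_rate) {
      int k = 1 + (int)R::rpois(cluster_lambda);
      if (k > n_regions) k = n_regions;
      // partial Fisher-Yates draw of k distinct regions
      for (int d = 0; d < k; ++d) {
        int j = d + (int)(unif_rand() * (n_regions - d));
        std::swap(pool[d], pool[j]);
        mark[pool[d]] = 1;
      }
    }
    active.clear();
    for (int r = 0; r < n_regions; ++r)
      if (mark[r]) { active.push_back(r); raster(r, t) = true; }
    std::fill(mark.begin(), mark.end(), 0);
    if (t + 1 < n_bins) {
      for (size_t a = 0; a < active.size(); ++a) {
        IntegerVector idx = out_idx[active[a]];
        NumericVector w = out_w[active[a]];
        for (int k = 0; k < idx.size(); ++k)
          if (!mark[idx[k]] && unif_rand() < w[k]) mark[idx[k]] = 1;
      }
    }
  }
  return raster;
}

// Trial-level avalanche transition matrix.
//
// raster: regions x bins (already binned); starts/ends: 0-based inclusive
// spans of the avalanches to use (callers pass spans of duration >= 2).
// pooled = false: average the per-avalanche conditional probabilities
// edge-wise; pooled = true: pool transition counts across avalanches and
// normalize once. Rows whose source region never has a successor frame are 0.
// [[Rcpp::export]]
List trial_atm_cpp(LogicalMatrix raster, IntegerVector starts,
                   IntegerVector ends, bool pooled) {
  int R = raster.nrow();
  NumericMatrix atm(R, R);
  std::vector<double> den_pool(R, 0.0);
  std::vector<double> num(R * R), den(R);
  std::vector<int> now, nxt;
  int used = 0;
  for (int a = 0; a < starts.size(); ++a) {
    int s = starts[a], e = ends[a];
    if (e - s < 1) continue;
    ++used;
    std::fill(num.begin(), num.end(), 0.0);
    std::fill(den.begin(), den.end(), 0.0);
    for (int t = s; t < e; ++t) {
      now.clear(); nxt.clear();
      for (int i = 0; i < R; ++i) {
        if (raster(i, t)) now.push_back(i);
        if (raster(i, t + 1)) nxt.push_back(i);
      }
      for (size_t ii = 0; ii < now.size(); ++ii) {
        int i = now[ii];
        den[i] += 1.0;
        for (size_t jj = 0; jj < nxt.size(); ++jj)
          num[i * R + nxt[jj]] += 1.0;
      }
    }
    if (pooled) {
      for (int i = 0; i < R; ++i) {
        den_pool[i] += den[i];
        for (int j = 0; j < R; ++j) atm(i, j) += num[i * R + j];
      }
    } else {
      for (int i = 0; i < R; ++i) {
        if (den[i] == 0.0) continue;
        for (int j = 0; j < R; ++j) atm(i, j) += num[i * R + j] / den[i];
      }
    }
  }
  if (used > 0) {
    if (pooled) {
      for (int i = 0; i < R; ++i)
        for (int j = 0; j < R; ++j)
          atm(i, j) = den_pool[i] > 0.0 ? atm(i, j) / den_pool[i] : 0.0;
    } else {
      for (int i = 0; i < R; ++i)
        for (int j = 0; j < R; ++j) atm(i, j) /= used;
    }
  }
  return List::create(_["atm"] = atm, _["n_avalanches"] = used);
}
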