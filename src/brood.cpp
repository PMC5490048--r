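// Poisson brood production with per-offspring gamete formation and
// mutation.  Uses R's RNG throughout, so runs are reproducible under
// set.seed() from the R side.

#include <Rcpp.h>
using namespace Rcpp;

static inline double mutate1(double v, double mu, double sigma) {
  if (mu > 0.0 && unif_rand() < mu) {
    v += norm_rand() * sigma;
    if (v < 0.0) v = 0.0;
    else if (v > 1.0) v = 1.0;
  }
  return v;
}

// one gamete locus from a diploid genome row (columns 2l, 2l+1)
static inline double gamete_dip(const NumericMatrix &G, int row, int locus) {
  int col = 2 * locus + (unif_rand() < 0.5 ? 0 : 1);
  return G(row, col);
}

// [[Rcpp::export(name = ".brood_cpp")]]
List brood_cpp(NumericMatrix Gm, List sperm, NumericVector shares,
               NumericVector fec, NumericVector z, bool haplo,
               double mu, double sigma, double mu_h) {
  const int nm = Gm.nrow();
  const int k = sperm.size();
  const double mus[3] = {mu, mu, mu_h};
  std::vector<NumericMatrix> S(k);
  for (int s = 0; s < k; s++) S[s] = as<NumericMatrix>(sperm[s]);
  const bool dip_father = (k > 0) && (S[0].ncol() == 6);
  const int son_cols = haplo ? 3 : 6;

  std::vector<double> Gd;   // daughter genomes, row-major 6 cols
  std::vector<double> Gs;   // son genomes, row-major son_cols
  std::vector<int> md, ms;  // 1-based mother index per offspring

  for (int i = 0; i < nm; i++) {
    int n = (int) R::rpois(fec[i]);
    for (int j = 0; j < n; j++) {
      bool son = unif_rand() < z[i];
      double matg[3], patg[3];
      for (int l = 0; l < 3; l++)
        matg[l] = mutate1(gamete_dip(Gm, i, l), mus[l], sigma);
      bool need_father = !son || !haplo;
      if (need_father) {
        int slot = 0;
        if (k > 1) {
          double u = unif_rand(), acc = 0.0;
          for (slot = 0; slot < k - 1; slot++) {
            acc += shares[slot];
            if (u < acc) break;
          }
        }
        const NumericMatrix &F = S[slot];
        for (int l = 0; l < 3; l++) {
          double a = dip_father ? gamete_dip(F, i, l) : F(i, l);
          patg[l] = mutate1(a, mus[l], sigma);
        }
      }
      if (son) {
        if (haplo) {
          for (int l = 0; l < 3; l++) Gs.push_back(matg[l]);
        } else {
          for (int l = 0; l < 3; l++) {
            Gs.push_back(matg[l]);
            Gs.push_back(patg[l]);
          }
        }
        ms.push_back(i + 1);
      } else {
        for (int l = 0; l < 3; l++) {
          Gd.push_back(matg[l]);
          Gd.push_back(patg[l]);
        }
        md.push_back(i + 1);
      }
    }
  }

  const int nd = (int) md.size(), ns = (int) ms.size();
  NumericMatrix daughters(nd, 6), sons(ns, son_cols);
  for (int r = 0; r < nd; r++)
    for (int c = 0; c < 6; c++) daughters(r, c) = Gd[(size_t) r * 6 + c];
  for (int r = 0; r < ns; r++)
    for (int c = 0; c < son_cols; c++)
      sons(r, c) = Gs[(size_t) r * son_cols + c];
  return List::create(_["daughters"] = daughters,
                      _["d_mother"] = IntegerVector(md.begin(), md.end()),
                      _["sons"] = sons,
                      _["s_mother"] = IntegerVector(ms.begin(), ms.end()));
}
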