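// Desk-scale Li & Stephens haplotype-copying HMM kernels.
//
// States are (pairs of) conditioning haplotypes; per-interval switch
// probability theta mixes "stay" with a uniform jump over the K states, so
// all transitions factorize and each forward/backward/Viterbi step is
// O(K) (haploid) or O(K^2) (diploid) per site.
//
// Emission model: the true allele is the copied haplotype allele flipped
// with probability err (mutation/copy error); observations are genotypes,
// with missing observations carrying no information.
//
// Haplotype matrices are passed states x sites (K x S, column-major), so
// per-site state scans are contiguous.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// per-site emission components: pAlt[k] = P(emitted allele 1 | state k)
static inline void alleleProbs(const int *hcol, int K, double err,
                               std::vector<double> &pAlt,
                               std::vector<double> &pRef) {
  for (int k = 0; k < K; ++k) {
    pAlt[k] = hcol[k] ? 1.0 - err : err;
    pRef[k] = 1.0 - pAlt[k];
  }
}

// Diploid forward-backward genotype posteriors.
// g: length-S genotype vector (0/1/2, -1 missing); H: K x S haplotype
// matrix; theta: length S-1 switch probabilities; err: copy error.
// Returns 3 x S posterior of the true genotype plus the log-likelihood.
// [[Rcpp::export]]
List cpp_diploid_posterior(IntegerVector g, IntegerMatrix H,
                           NumericVector theta, double err) {
  const int K = H.nrow(), S = H.ncol();
  const int *hp = INTEGER(H);
  std::vector<double> F((size_t)S * K * K), B((size_t)S * K * K);
  std::vector<double> e1(K), e0(K);
  double loglik = 0.0;

  // emission matrix applied in place: E[j,k] per genotype class
  auto emitInto = [&](int s, double *M, bool multiply) {
    const int gs = g[s];
    alleleProbs(hp + (size_t)s * K, K, err, e1, e0);
    for (int j = 0; j < K; ++j) {
      double a1 = e1[j], a0 = e0[j];
      double *row = M + (size_t)j * K;
      if (gs < 0) { if (!multiply) for (int k = 0; k < K; ++k) row[k] = 1.0; }
      else if (gs == 0)
        for (int k = 0; k < K; ++k) row[k] = (multiply ? row[k] : 1.0) * a0 * e0[k];
      else if (gs == 2)
        for (int k = 0; k < K; ++k) row[k] = (multiply ? row[k] : 1.0) * a1 * e1[k];
      else
        for (int k = 0; k < K; ++k)
          row[k] = (multiply ? row[k] : 1.0) * (a1 * e0[k] + a0 * e1[k]);
    }
  };

  { // forward
    for (int i = 0; i < K * K; ++i) F[i] = 1.0 / (K * K);
    emitInto(0, &F[0], true);
    double c = 0.0;
    for (int i = 0; i < K * K; ++i) c += F[i];
    if (c <= 0.0) stop("zero forward probability at site 1");
    for (int i = 0; i < K * K; ++i) F[i] /= c;
    loglik = std::log(c);
    std::vector<double> rsum(K), csum(K);
    for (int s = 1; s < S; ++s) {
      const double *Fp = &F[(size_t)(s - 1) * K * K];
      double *Fs = &F[(size_t)s * K * K];
      double th = theta[s - 1], a = 1.0 - th, b = th / K;
      std::fill(rsum.begin(), rsum.end(), 0.0);
      std::fill(csum.begin(), csum.end(), 0.0);
      double tot = 0.0;
      for (int j = 0; j < K; ++j) {
        const double *row = Fp + (size_t)j * K;
        double rs = 0.0;
        for (int k = 0; k < K; ++k) { rs += row[k]; csum[k] += row[k]; }
        rsum[j] = rs; tot += rs;
      }
      for (int j = 0; j < K; ++j) {
        const double *row = Fp + (size_t)j * K;
        double *out = Fs + (size_t)j * K;
        double rj = a * b * rsum[j] + b * b * tot;
        for (int k = 0; k < K; ++k)
          out[k] = a * a * row[k] + rj + a * b * csum[k];
      }
      emitInto(s, Fs, true);
      double cs = 0.0;
      for (int i = 0; i < K * K; ++i) cs += Fs[i];
      if (cs <= 0.0) stop("zero forward probability at site %d", s + 1);
      for (int i = 0; i < K * K; ++i) Fs[i] /= cs;
      loglik += std::log(cs);
    }
  }

  { // backward, rescaled per site
    double *Bl = &B[(size_t)(S - 1) * K * K];
    for (int i = 0; i < K * K; ++i) Bl[i] = 1.0;
    std::vector<double> tmp(K * K), rsum(K), csum(K);
    for (int s = S - 2; s >= 0; --s) {
      const double *Bn = &B[(size_t)(s + 1) * K * K];
      double *Bs = &B[(size_t)s * K * K];
      std::copy(Bn, Bn + (size_t)K * K, tmp.begin());
      emitInto(s + 1, &tmp[0], true);
      double th = theta[s], a = 1.0 - th, b = th / K;
      std::fill(rsum.begin(), rsum.end(), 0.0);
      std::fill(csum.begin(), csum.end(), 0.0);
      double tot = 0.0;
      for (int j = 0; j < K; ++j) {
        const double *row = &tmp[(size_t)j * K];
        double rs = 0.0;
        for (int k = 0; k < K; ++k) { rs += row[k]; csum[k] += row[k]; }
        rsum[j] = rs; tot += rs;
      }
      double c = 0.0;
      for (int j = 0; j < K; ++j) {
        const double *row = &tmp[(size_t)j * K];
        double *out = Bs + (size_t)j * K;
        double rj = a * b * rsum[j] + b * b * tot;
        for (int k = 0; k < K; ++k) {
          double v = a * a * row[k] + rj + a * b * csum[k];
          out[k] = v; c += v;
        }
      }
      for (int i = 0; i < K * K; ++i) Bs[i] /= c;
    }
  }

  NumericMatrix post(3, S);
  std::vector<double> m(K);
  for (int s = 0; s < S; ++s) {
    const double *Fs = &F[(size_t)s * K * K];
    const double *Bs = &B[(size_t)s * K * K];
    const int *hcol = hp + (size_t)s * K;
    for (int k = 0; k < K; ++k) m[k] = hcol[k] ? 1.0 - err : err;
    double p0 = 0, p1 = 0, p2 = 0, z = 0;
    for (int j = 0; j < K; ++j) {
      double mj = m[j];
      const double *fr = Fs + (size_t)j * K;
      const double *br = Bs + (size_t)j * K;
      for (int k = 0; k < K; ++k) {
        double w = fr[k] * br[k], mk = m[k];
        p0 += w * (1 - mj) * (1 - mk);
        p1 += w * (mj * (1 - mk) + (1 - mj) * mk);
        p2 += w * mj * mk;
        z += w;
      }
    }
    post(0, s) = p0 / z; post(1, s) = p1 / z; post(2, s) = p2 / z;
  }
  return List::create(_["posterior"] = post, _["loglik"] = loglik);
}

// Diploid Viterbi phase extraction.
// Returns the jointly most probable copying-state pair path and the
// implied diplotype: at het sites the orientation maximizing the
// path-conditional emission (ambiguous sites keep the previous
// orientation); at missing sites the copied alleles.
// [[Rcpp::export]]
List cpp_diploid_viterbi(IntegerVector g, IntegerMatrix H,
                         NumericVector theta, double err) {
  // single precision is ample for an argmax decode and halves the memory
  // traffic of the dominant loop
  const int K = H.nrow(), S = H.ncol();
  const int *hp = INTEGER(H);
  std::vector<float> V((size_t)S * K * K);
  std::vector<double> e1d(K), e0d(K);
  std::vector<float> e1(K), e0(K);

  std::vector<int> bestJ(S), bestK(S);   // argmax of the normalized V per
                                         // site (so its max is exactly 1)
  auto loadEmit = [&](int s) {
    alleleProbs(hp + (size_t)s * K, K, err, e1d, e0d);
    for (int k = 0; k < K; ++k) {
      e1[k] = (float)e1d[k]; e0[k] = (float)e0d[k];
    }
  };

  // site 0
  {
    float *V0 = &V[0];
    loadEmit(0);
    const int g0 = g[0];
    float best = 0.0f; int bj = 0, bk = 0;
    for (int j = 0; j < K; ++j) {
      float *row = V0 + (size_t)j * K;
      for (int k = 0; k < K; ++k) {
        float e = g0 < 0 ? 1.0f :
          (g0 == 0 ? e0[j] * e0[k] :
           (g0 == 2 ? e1[j] * e1[k] : e1[j] * e0[k] + e0[j] * e1[k]));
        row[k] = e;
        if (e > best) { best = e; bj = j; bk = k; }
      }
    }
    if (best <= 0.0f) stop("zero Viterbi probability at site 1");
    for (int i = 0; i < K * K; ++i) V0[i] /= best;
    bestJ[0] = bj; bestK[0] = bk;
  }

  std::vector<float> rmax(K), cmax(K);
  for (int s = 1; s < S; ++s) {
    const float *Vp = &V[(size_t)(s - 1) * K * K];
    float *Vs = &V[(size_t)s * K * K];
    double th = theta[s - 1], abD = 1.0 - th + th / K, bD = th / K;
    std::fill(rmax.begin(), rmax.end(), 0.0f);
    std::fill(cmax.begin(), cmax.end(), 0.0f);
    float gmax = 0.0f;
    for (int j = 0; j < K; ++j) {
      const float *row = Vp + (size_t)j * K;
      float rm = 0.0f;
      for (int k = 0; k < K; ++k) {
        float v = row[k];
        if (v > rm) rm = v;
        if (v > cmax[k]) cmax[k] = v;
      }
      rmax[j] = rm;
      if (rm > gmax) gmax = rm;
    }
    const float a2 = (float)(abD * abD), abb = (float)(abD * bD),
                b2 = (float)(bD * bD);
    const float t4 = b2 * gmax;
    loadEmit(s);
    const int gs = g[s];
    float best = 0.0f; int bj = 0, bk = 0;
    for (int j = 0; j < K; ++j) {
      const float *prow = Vp + (size_t)j * K;
      float *out = Vs + (size_t)j * K;
      const float t2 = abb * rmax[j];
      const float f1 = e1[j], f0 = e0[j];
      for (int k = 0; k < K; ++k) {
        float t = a2 * prow[k];
        float t3 = abb * cmax[k];
        if (t2 > t) t = t2;
        if (t3 > t) t = t3;
        if (t4 > t) t = t4;
        float e = gs < 0 ? 1.0f :
          (gs == 0 ? f0 * e0[k] :
           (gs == 2 ? f1 * e1[k] : f1 * e0[k] + f0 * e1[k]));
        float v = t * e;
        out[k] = v;
        if (v > best) { best = v; bj = j; bk = k; }
      }
    }
    if (best <= 0.0f) stop("zero Viterbi probability at site %d", s + 1);
    float inv = 1.0f / best;
    for (int i = 0; i < K * K; ++i) Vs[i] *= inv;
    bestJ[s] = bj; bestK[s] = bk;
  }

  // terminal state and traceback (each stored V is normalized to max 1 at
  // its recorded argmax, so the global-jump candidate needs no rescan)
  std::vector<int> pj(S), pk(S);
  pj[S - 1] = bestJ[S - 1]; pk[S - 1] = bestK[S - 1];
  for (int s = S - 1; s > 0; --s) {
    const float *Vp = &V[(size_t)(s - 1) * K * K];
    double th = theta[s - 1], ab = 1.0 - th + th / K, b = th / K;
    int j = pj[s], k = pk[s];
    int rj = 0, ck = 0;
    const int gj = bestJ[s - 1], gk = bestK[s - 1];
    const double gv = 1.0;
    double rv = -1, cv = -1;
    for (int x = 0; x < K; ++x) {
      double vr = Vp[(size_t)j * K + x];
      if (vr > rv) { rv = vr; rj = x; }
      double vc = Vp[(size_t)x * K + k];
      if (vc > cv) { cv = vc; ck = x; }
    }
    double cand1 = ab * ab * Vp[(size_t)j * K + k];
    double cand2 = ab * b * rv;
    double cand3 = b * ab * cv;
    double cand4 = b * b * gv;
    if (cand1 >= cand2 && cand1 >= cand3 && cand1 >= cand4) {
      pj[s - 1] = j; pk[s - 1] = k;
    } else if (cand2 >= cand3 && cand2 >= cand4) {
      pj[s - 1] = j; pk[s - 1] = rj;
    } else if (cand3 >= cand4) {
      pj[s - 1] = ck; pk[s - 1] = k;
    } else {
      pj[s - 1] = gj; pk[s - 1] = gk;
    }
  }

  IntegerVector h1(S), h2(S);
  NumericVector cert(S);
  LogicalVector imputed(S);
  int lastO = 1;  // orientation carried across emission-ambiguous het sites
  for (int s = 0; s < S; ++s) {
    const int *hcol = hp + (size_t)s * K;
    int hj = hcol[pj[s]], hk = hcol[pk[s]];
    if (g[s] == 0) { h1[s] = 0; h2[s] = 0; cert[s] = 1.0; }
    else if (g[s] == 2) { h1[s] = 1; h2[s] = 1; cert[s] = 1.0; }
    else if (g[s] == 1) {
      double a1j = hj ? 1.0 - err : err, a1k = hk ? 1.0 - err : err;
      double w10 = a1j * (1.0 - a1k);
      double w01 = (1.0 - a1j) * a1k;
      int o;
      if (w10 > w01) o = 1;
      else if (w01 > w10) o = 0;
      else o = lastO;   // both copied alleles equal: keep the previous
                        // orientation rather than breaking the segment
      h1[s] = o; h2[s] = 1 - o;
      lastO = o;
      cert[s] = std::max(w10, w01) / (w10 + w01);
    } else {            // missing: copy the path alleles
      h1[s] = hj; h2[s] = hk;
      cert[s] = (1.0 - err) * (1.0 - err);
      imputed[s] = true;
    }
  }
  return List::create(_["hap1"] = h1, _["hap2"] = h2,
                      _["certainty"] = cert, _["imputed"] = imputed,
                      _["stateJ"] = wrap(pj), _["stateK"] = wrap(pk));
}

// Haploid forward-backward allele posterior against a reference panel.
// obs: length-S allele vector (0/1, -1 = unobserved); H: K x S.
// Returns P(true allele = alt) at every site.
// [[Rcpp::export]]
NumericVector cpp_haploid_posterior(IntegerVector obs, IntegerMatrix H,
                                    NumericVector theta, double err) {
  const int K = H.nrow(), S = H.ncol();
  const int *hp = INTEGER(H);
  std::vector<double> F((size_t)S * K), B((size_t)S * K);

  for (int s = 0; s < S; ++s) {
    const int *hcol = hp + (size_t)s * K;
    double *Fs = &F[(size_t)s * K];
    double c = 0.0;
    if (s == 0) {
      for (int k = 0; k < K; ++k) {
        double e = obs[0] < 0 ? 1.0 :
          ((hcol[k] == obs[0]) ? 1.0 - err : err);
        Fs[k] = e / K; c += Fs[k];
      }
    } else {
      const double *Fp = &F[(size_t)(s - 1) * K];
      double th = theta[s - 1], a = 1.0 - th, bK = th / K;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) tot += Fp[k];
      double jump = bK * tot;
      for (int k = 0; k < K; ++k) {
        double e = obs[s] < 0 ? 1.0 :
          ((hcol[k] == obs[s]) ? 1.0 - err : err);
        double v = (a * Fp[k] + jump) * e;
        Fs[k] = v; c += v;
      }
    }
    if (c <= 0.0) stop("zero haploid forward probability at site %d", s + 1);
    for (int k = 0; k < K; ++k) Fs[k] /= c;
  }

  for (int k = 0; k < K; ++k) B[(size_t)(S - 1) * K + k] = 1.0;
  std::vector<double> tmp(K);
  for (int s = S - 2; s >= 0; --s) {
    const double *Bn = &B[(size_t)(s + 1) * K];
    double *Bs = &B[(size_t)s * K];
    const int *hcol = hp + (size_t)(s + 1) * K;
    double th = theta[s], a = 1.0 - th, bK = th / K;
    double tot = 0.0, c = 0.0;
    for (int k = 0; k < K; ++k) {
      double e = obs[s + 1] < 0 ? 1.0 :
        ((hcol[k] == obs[s + 1]) ? 1.0 - err : err);
      tmp[k] = Bn[k] * e;
      tot += tmp[k];
    }
    double jump = bK * tot;
    for (int k = 0; k < K; ++k) {
      double v = a * tmp[k] + jump;
      Bs[k] = v; c += v;
    }
    for (int k = 0; k < K; ++k) Bs[k] /= c;
  }

  NumericVector pAlt(S);
  for (int s = 0; s < S; ++s) {
    const double *Fs = &F[(size_t)s * K];
    const double *Bs = &B[(size_t)s * K];
    const int *hcol = hp + (size_t)s * K;
    double num = 0.0, z = 0.0;
    for (int k = 0; k < K; ++k) {
      double w = Fs[k] * Bs[k];
      num += w * (hcol[k] ? 1.0 - err : err);
      z += w;
    }
    pAlt[s] = num / z;
  }
  return pAlt;
}
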