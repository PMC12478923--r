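// Deep factorization model core: embedding lookup + multilayer perceptron,
// Adam training with validation-based model selection, and batched
// evaluation-mode forward passes. Single precision keeps the dense-layer
// products fast; validation error is accumulated in double precision.
// Embedding tables are held transposed (factors x entities) so that
// per-example gather/scatter touches contiguous memory.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cstdint>
#include <cstring>
#include <limits>

using namespace Rcpp;
using arma::fmat;
using arma::frowvec;
using arma::fvec;

namespace {

// Small deterministic RNG (xorshift128+ seeded via splitmix64) so that
// batch sampling and dropout masks are reproducible from a single integer
// seed and cheap enough to draw millions of masks per epoch.
struct Rng {
    uint64_t s0, s1;
    explicit Rng(uint64_t seed) {
        uint64_t x = seed;
        s0 = splitmix(x);
        s1 = splitmix(x);
        if (s0 == 0 && s1 == 0) s1 = 1;
    }
    static uint64_t splitmix(uint64_t &x) {
        x += 0x9E3779B97f4A7C15ULL;
        uint64_t z = x;
        z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
        z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
        return z ^ (z >> 31);
    }
    uint64_t next() {
        uint64_t x = s0, y = s1;
        s0 = y;
        x ^= x << 23;
        s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
        return s1 + y;
    }
    double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
    int below(int n) { return (int)(unif() * n) % n; }
};

struct Params {
    fmat EbT, EaT, EpT, EdT;      // embedding tables, transposed
    std::vector<fmat> W;          // dense layers, last maps to 1 unit
    std::vector<frowvec> b;
    int fB() const { return EbT.n_rows; }
    int fA() const { return EaT.n_rows; }
    int fP() const { return EpT.n_rows; }
    int fD() const { return EdT.n_rows; }
    int inDim() const { return fB() + fA() + 2 * fP() + fD(); }
};

Params paramsFromR(const List &emb, const List &layers) {
    Params p;
    p.EbT = arma::conv_to<fmat>::from(as<arma::mat>(emb["biosample"]).t());
    p.EaT = arma::conv_to<fmat>::from(as<arma::mat>(emb["assay"]).t());
    p.EpT = arma::conv_to<fmat>::from(as<arma::mat>(emb["position"]).t());
    p.EdT = arma::conv_to<fmat>::from(as<arma::mat>(emb["distance"]).t());
    for (int l = 0; l < layers.size(); ++l) {
        List layer = layers[l];
        p.W.push_back(arma::conv_to<fmat>::from(as<arma::mat>(layer["W"])));
        arma::vec bv = as<arma::vec>(layer["b"]);
        p.b.push_back(arma::conv_to<frowvec>::from(bv.t()));
    }
    return p;
}

List paramsToR(const Params &p) {
    List emb = List::create(
        _["biosample"] = wrap(arma::conv_to<arma::mat>::from(p.EbT.t())),
        _["assay"] = wrap(arma::conv_to<arma::mat>::from(p.EaT.t())),
        _["position"] = wrap(arma::conv_to<arma::mat>::from(p.EpT.t())),
        _["distance"] = wrap(arma::conv_to<arma::mat>::from(p.EdT.t())));
    List layers(p.W.size());
    for (size_t l = 0; l < p.W.size(); ++l) {
        layers[l] = List::create(
            _["W"] = wrap(arma::conv_to<arma::mat>::from(p.W[l])),
            _["b"] = wrap(arma::conv_to<arma::vec>::from(p.b[l].t())));
    }
    return List::create(_["embeddings"] = emb, _["layers"] = layers);
}

// Concatenated embedding columns for a block of (b, a, i, j) queries, one
// query per column. Queries are canonicalized so i <= j, which makes the
// prediction exactly symmetric in the two positions.
void gatherInputs(const Params &p, const int *bi, const int *ai,
                  const int *ii, const int *ji, int n, fmat &Xt) {
    const int fB = p.fB(), fA = p.fA(), fP = p.fP(), fD = p.fD();
    Xt.set_size(p.inDim(), n);
    for (int r = 0; r < n; ++r) {
        int i = ii[r], j = ji[r];
        if (i > j) std::swap(i, j);
        float *dst = Xt.colptr(r);
        std::memcpy(dst, p.EbT.colptr(bi[r]), fB * sizeof(float));
        dst += fB;
        std::memcpy(dst, p.EaT.colptr(ai[r]), fA * sizeof(float));
        dst += fA;
        std::memcpy(dst, p.EpT.colptr(i), fP * sizeof(float));
        dst += fP;
        std::memcpy(dst, p.EpT.colptr(j), fP * sizeof(float));
        dst += fP;
        std::memcpy(dst, p.EdT.colptr(j - i), fD * sizeof(float));
    }
}

// Evaluation-mode forward pass (no dropout).
fvec forwardEval(const Params &p, const fmat &Xt) {
    fmat A = Xt.t() * p.W[0];
    A.each_row() += p.b[0];
    A.transform([](float z) { return z > 0.0f ? z : 0.0f; });
    const size_t L = p.W.size();
    for (size_t l = 1; l + 1 < L; ++l) {
        fmat Z = A * p.W[l];
        Z.each_row() += p.b[l];
        Z.transform([](float z) { return z > 0.0f ? z : 0.0f; });
        A = std::move(Z);
    }
    fmat out = A * p.W[L - 1];
    out.each_row() += p.b[L - 1];
    return out.col(0);
}

struct Moments {
    fmat EbT, EaT, EpT, EdT;
    std::vector<fmat> W;
    std::vector<frowvec> b;
    explicit Moments(const Params &p) {
        EbT = arma::zeros<fmat>(arma::size(p.EbT));
        EaT = arma::zeros<fmat>(arma::size(p.EaT));
        EpT = arma::zeros<fmat>(arma::size(p.EpT));
        EdT = arma::zeros<fmat>(arma::size(p.EdT));
        for (size_t l = 0; l < p.W.size(); ++l) {
            W.push_back(arma::zeros<fmat>(arma::size(p.W[l])));
            b.push_back(arma::zeros<frowvec>(p.b[l].n_elem));
        }
    }
};

template <typename M>
inline void adamStep(M &p, const M &g, M &m, M &v, float lr, float c1,
                     float c2) {
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    m = b1 * m + (1.0f - b1) * g;
    v = b2 * v + (1.0f - b2) * (g % g);
    p -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_forward(List emb, List layers, IntegerMatrix queries) {
    Params p = paramsFromR(emb, layers);
    const int n = queries.nrow();
    NumericVector out(n);
    const int chunk = 8192;
    std::vector<int> bi(chunk), ai(chunk), ii(chunk), ji(chunk);
    fmat Xt;
    for (int start = 0; start < n; start += chunk) {
        const int m = std::min(chunk, n - start);
        for (int r = 0; r < m; ++r) {
            bi[r] = queries(start + r, 0);
            ai[r] = queries(start + r, 1);
            ii[r] = queries(start + r, 2);
            ji[r] = queries(start + r, 3);
        }
        gatherInputs(p, bi.data(), ai.data(), ii.data(), ji.data(), m, Xt);
        fvec y = forwardEval(p, Xt);
        for (int r = 0; r < m; ++r) out[start + r] = y[r];
    }
    return out;
}

// [[Rcpp::export]]
List cpp_train(List emb, List layers, List trainMaps, IntegerVector trainB,
               IntegerVector trainA, List valMaps, IntegerVector valB,
               IntegerVector valA, double learningRate, double dropout,
               int epochs, int batchSize, int batchesPerEpoch, int patience,
               bool valIncludeDiagonal, double rngSeed) {
    Params p = paramsFromR(emb, layers);
    const int nTrain = trainMaps.size();
    const int nBins = p.EpT.n_cols;
    const int L = (int)p.W.size();
    const float lr = (float)learningRate;
    const float keep = 1.0f - (float)dropout;
    const float dropScale = (dropout > 0) ? 1.0f / keep : 1.0f;
    const uint64_t keepU =
        (uint64_t)(keep * 18446744073709551616.0 /* 2^64 */);

    std::vector<fmat> tmaps(nTrain);
    for (int e = 0; e < nTrain; ++e) {
        tmaps[e] = arma::conv_to<fmat>::from(as<arma::mat>(trainMaps[e]));
    }

    // enumeration of unordered off-diagonal pairs for uniform sampling
    const long nPairs = (long)nBins * (nBins - 1) / 2;
    std::vector<int> pairI(nPairs), pairJ(nPairs);
    {
        long k = 0;
        for (int i = 0; i < nBins; ++i)
            for (int j = i + 1; j < nBins; ++j) {
                pairI[k] = i; pairJ[k] = j; ++k;
            }
    }

    // validation queries: upper-triangle entries of every validation map
    std::vector<int> vb, va, vi, vj;
    std::vector<double> vt;
    for (int e = 0; e < valMaps.size(); ++e) {
        arma::mat vm = as<arma::mat>(valMaps[e]);
        for (int i = 0; i < nBins; ++i) {
            for (int j = valIncludeDiagonal ? i : i + 1; j < nBins; ++j) {
                vb.push_back(valB[e]); va.push_back(valA[e]);
                vi.push_back(i); vj.push_back(j);
                vt.push_back(vm(i, j));
            }
        }
    }
    const long nVal = (long)vb.size();

    Rng rng((uint64_t)rngSeed);
    Moments m1(p), m2(p);
    long step = 0;

    fmat XtVal;
    auto validationMSE = [&](const Params &q) {
        double sse = 0.0;
        const int chunk = 8192;
        for (long start = 0; start < nVal; start += chunk) {
            const int mC = (int)std::min((long)chunk, nVal - start);
            gatherInputs(q, &vb[start], &va[start], &vi[start], &vj[start],
                         mC, XtVal);
            fvec y = forwardEval(q, XtVal);
            for (int r = 0; r < mC; ++r) {
                const double d = (double)y[r] - vt[start + r];
                sse += d * d;
            }
        }
        return sse / (double)nVal;
    };

    std::vector<double> trainLoss, valMSE;
    valMSE.push_back(validationMSE(p));  // epoch 0: random initialization
    Params best = p;
    double bestVal = valMSE[0] + 1.0;    // only trained epochs compete
    int bestEpoch = 0, sinceBest = 0;
    bool haveBest = false;

    std::vector<int> bi(batchSize), ai(batchSize), ii(batchSize),
        ji(batchSize);
    fvec target(batchSize);
    fmat Xt;
    std::vector<fmat> acts(L - 1), derivs(L - 1);

    for (int epoch = 1; epoch <= epochs; ++epoch) {
        double lossSum = 0.0;
        for (int batch = 0; batch < batchesPerEpoch; ++batch) {
            for (int r = 0; r < batchSize; ++r) {
                const int e = rng.below(nTrain);
                const long k = (long)(rng.unif() * (double)nPairs) % nPairs;
                bi[r] = trainB[e]; ai[r] = trainA[e];
                ii[r] = pairI[k]; ji[r] = pairJ[k];
                target[r] = tmaps[e](pairI[k], pairJ[k]);
            }
            gatherInputs(p, bi.data(), ai.data(), ii.data(), ji.data(),
                         batchSize, Xt);

            // forward, fusing relu and inverted dropout; derivs[l] holds
            // d(activation)/d(preactivation) including the dropout mask
            for (int l = 0; l < L - 1; ++l) {
                fmat Z = (l == 0) ? fmat(Xt.t() * p.W[0])
                                  : fmat(acts[l - 1] * p.W[l]);
                Z.each_row() += p.b[l];
                fmat D(arma::size(Z));
                float *z = Z.memptr();
                float *d = D.memptr();
                const arma::uword nel = Z.n_elem;
                if (dropout > 0) {
                    for (arma::uword q = 0; q < nel; ++q) {
                        if (z[q] > 0.0f && rng.next() < keepU) {
                            z[q] *= dropScale;
                            d[q] = dropScale;
                        } else {
                            z[q] = 0.0f;
                            d[q] = 0.0f;
                        }
                    }
                } else {
                    for (arma::uword q = 0; q < nel; ++q) {
                        if (z[q] > 0.0f) {
                            d[q] = 1.0f;
                        } else {
                            z[q] = 0.0f;
                            d[q] = 0.0f;
                        }
                    }
                }
                acts[l] = std::move(Z);
                derivs[l] = std::move(D);
            }
            fmat out = acts[L - 2] * p.W[L - 1];
            out.each_row() += p.b[L - 1];
            fvec resid = out.col(0) - target;
            lossSum += arma::dot(resid, resid) / batchSize;

            // backward with Adam updates
            ++step;
            const float c1 = 1.0f - std::pow(0.9f, (float)step);
            const float c2 = 1.0f - std::pow(0.999f, (float)step);
            fmat dA;
            {
                fmat dY(resid.n_elem, 1);
                dY.col(0) = resid * (2.0f / (float)batchSize);
                fmat gW = acts[L - 2].t() * dY;
                frowvec gb = arma::sum(dY, 0);
                dA = dY * p.W[L - 1].t();
                adamStep(p.W[L - 1], gW, m1.W[L - 1], m2.W[L - 1], lr, c1,
                         c2);
                adamStep(p.b[L - 1], gb, m1.b[L - 1], m2.b[L - 1], lr, c1,
                         c2);
            }
            fmat dXt;
            for (int l = L - 2; l >= 0; --l) {
                fmat dZ = dA % derivs[l];
                frowvec gb = arma::sum(dZ, 0);
                if (l == 0) {
                    fmat gW = Xt * dZ;
                    dXt = p.W[0] * dZ.t();
                    adamStep(p.W[0], gW, m1.W[0], m2.W[0], lr, c1, c2);
                } else {
                    fmat gW = acts[l - 1].t() * dZ;
                    dA = dZ * p.W[l].t();
                    adamStep(p.W[l], gW, m1.W[l], m2.W[l], lr, c1, c2);
                }
                adamStep(p.b[l], gb, m1.b[l], m2.b[l], lr, c1, c2);
            }

            // scatter the input gradient into the embedding tables
            fmat gEbT = arma::zeros<fmat>(arma::size(p.EbT));
            fmat gEaT = arma::zeros<fmat>(arma::size(p.EaT));
            fmat gEpT = arma::zeros<fmat>(arma::size(p.EpT));
            fmat gEdT = arma::zeros<fmat>(arma::size(p.EdT));
            const int fB = p.fB(), fA = p.fA(), fP = p.fP(), fD = p.fD();
            for (int r = 0; r < batchSize; ++r) {
                int i = ii[r], j = ji[r];
                if (i > j) std::swap(i, j);
                const float *src = dXt.colptr(r);
                float *g;
                g = gEbT.colptr(bi[r]);
                for (int q = 0; q < fB; ++q) g[q] += src[q];
                src += fB;
                g = gEaT.colptr(ai[r]);
                for (int q = 0; q < fA; ++q) g[q] += src[q];
                src += fA;
                g = gEpT.colptr(i);
                for (int q = 0; q < fP; ++q) g[q] += src[q];
                src += fP;
                g = gEpT.colptr(j);
                for (int q = 0; q < fP; ++q) g[q] += src[q];
                src += fP;
                g = gEdT.colptr(j - i);
                for (int q = 0; q < fD; ++q) g[q] += src[q];
            }
            adamStep(p.EbT, gEbT, m1.EbT, m2.EbT, lr, c1, c2);
            adamStep(p.EaT, gEaT, m1.EaT, m2.EaT, lr, c1, c2);
            adamStep(p.EpT, gEpT, m1.EpT, m2.EpT, lr, c1, c2);
            adamStep(p.EdT, gEdT, m1.EdT, m2.EdT, lr, c1, c2);
        }
        trainLoss.push_back(lossSum / batchesPerEpoch);
        const double v = validationMSE(p);
        valMSE.push_back(v);
        if (!haveBest || v < bestVal) {
            bestVal = v;
            best = p;
            bestEpoch = epoch;
            sinceBest = 0;
            haveBest = true;
        } else {
            ++sinceBest;
            if (patience > 0 && sinceBest >= patience) break;
        }
        Rcpp::checkUserInterrupt();
    }
    if (!haveBest) best = p;  // epochs == 0: untrained state

    List state = paramsToR(best);
    state["bestEpoch"] = bestEpoch;
    state["trainLoss"] = wrap(trainLoss);
    state["validationMSE"] = wrap(valMSE);
    return state;
}
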