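#include <Rcpp.h>
#include <sstream>
using namespace Rcpp;

// Scaled forward-backward over chromosome segments.
//
// logE:     L x S log emission densities (-Inf allowed)
// P:        list of G dense S x S transition matrices (one per distance group)
// group:    length L, 1-based index into P of the transition INTO locus l;
//           ignored where segStart[l] is true
// init:     length S initial distribution (used at every segment start)
// segStart: length L, true where a new independent segment (chromosome) begins
//
// Returns total log-likelihood, posteriors gamma (L x S) and the pairwise
// transition expectations aggregated per distance group (list of S x S).
// [[Rcpp::export(name = ".fbCpp")]]
List fbCpp(NumericMatrix logE, List P, IntegerVector group,
           NumericVector init, LogicalVector segStart) {
    const int L = logE.nrow(), S = logE.ncol(), G = P.size();
    if (group.size() != L || init.size() != S || segStart.size() != L)
        stop("forward_backward: dimension mismatch");
    if (L == 0) stop("forward_backward: empty data");
    if (!segStart[0]) stop("forward_backward: first locus must start a segment");

    std::vector<NumericMatrix> Pm;
    Pm.reserve(G);
    for (int g = 0; g < G; ++g) {
        NumericMatrix pg = P[g];
        if (pg.nrow() != S || pg.ncol() != S)
            stop("forward_backward: transition matrix dimension mismatch");
        Pm.push_back(pg);
    }

    NumericMatrix E(L, S);       // emissions scaled by exp(-rowmax)
    NumericVector rowmax(L);
    for (int l = 0; l < L; ++l) {
        double m = R_NegInf;
        for (int s = 0; s < S; ++s) m = std::max(m, logE(l, s));
        if (!R_finite(m)) {
            std::ostringstream msg;
            msg << "impossible datum at locus " << (l + 1)
                << ": emission is zero in every state";
            stop(msg.str());
        }
        rowmax[l] = m;
        for (int s = 0; s < S; ++s) E(l, s) = std::exp(logE(l, s) - m);
    }

    NumericMatrix alpha(L, S);   // scaled
    NumericVector cs(L);
    double loglik = 0.0;

    for (int l = 0; l < L; ++l) {
        double c = 0.0;
        if (segStart[l]) {
            for (int s = 0; s < S; ++s) {
                alpha(l, s) = init[s] * E(l, s);
                c += alpha(l, s);
            }
        } else {
            int g = group[l] - 1;
            if (g < 0 || g >= G) stop("forward_backward: bad group index");
            const NumericMatrix& Pg = Pm[g];
            for (int s2 = 0; s2 < S; ++s2) {
                double a = 0.0;
                for (int s1 = 0; s1 < S; ++s1)
                    a += alpha(l - 1, s1) * Pg(s1, s2);
                alpha(l, s2) = a * E(l, s2);
                c += alpha(l, s2);
            }
        }
        if (!(c > 0.0)) {
            std::ostringstream msg;
            msg << "impossible datum at locus " << (l + 1);
            stop(msg.str());
        }
        cs[l] = c;
        for (int s = 0; s < S; ++s) alpha(l, s) /= c;
        loglik += std::log(c) + rowmax[l];
    }

    NumericMatrix gamma(L, S);
    std::vector<NumericMatrix> xi;
    xi.reserve(G);
    for (int g = 0; g < G; ++g) xi.push_back(NumericMatrix(S, S));

    std::vector<double> beta(S), betaNext(S), tmp(S);
    for (int l = L - 1; l >= 0; --l) {
        bool lastOfSeg = (l == L - 1) || segStart[l + 1];
        if (lastOfSeg) {
            for (int s = 0; s < S; ++s) beta[s] = 1.0;
        } else {
            int g = group[l + 1] - 1;
            const NumericMatrix& Pg = Pm[g];
            for (int s = 0; s < S; ++s)
                tmp[s] = E(l + 1, s) * betaNext[s] / cs[l + 1];
            for (int s1 = 0; s1 < S; ++s1) {
                double b = 0.0;
                for (int s2 = 0; s2 < S; ++s2) b += Pg(s1, s2) * tmp[s2];
                beta[s1] = b;
            }
            // xi for the transition into locus l+1
            NumericMatrix& Xg = xi[g];
            for (int s1 = 0; s1 < S; ++s1) {
                double a1 = alpha(l, s1);
                if (a1 == 0.0) continue;
                for (int s2 = 0; s2 < S; ++s2)
                    Xg(s1, s2) += a1 * Pg(s1, s2) * tmp[s2];
            }
        }
        double norm = 0.0;
        for (int s = 0; s < S; ++s) {
            gamma(l, s) = alpha(l, s) * beta[s];
            norm += gamma(l, s);
        }
        for (int s = 0; s < S; ++s) gamma(l, s) /= norm;
        std::swap(beta, betaNext);
    }

    List xiOut(G);
    for (int g = 0; g < G; ++g) xiOut[g] = xi[g];
    return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                        _["xi"] = xiOut);
}
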