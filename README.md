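# mixscan

Locus-specific mixture proportions along the genome from population allele
counts.

## What problem this solves

Admixture-graph methods in population genetics (the TreeMix family) model
genome-wide allele frequencies as Brownian drift along a rooted graph whose
migration edges each carry a *single* genome-wide mixture proportion. When
selection favours or opposes introgressed material, the effective mixture
proportion varies along the genome — exactly the signal those methods
average away. `mixscan` takes the admixture graph as given (topology from
TreeMix or prior knowledge) and infers, for every locus, the posterior
mixture proportion of each migration edge, together with the branch lengths,
a root-frequency prior, and per-locus false-discovery scores for excess and
dearth of introgression. It is aimed at population geneticists scanning for
candidate regions of (adaptive) introgression in model or non-model species,
from nothing more than a VCF and a sample-to-population map.

## The model in brief

Transformed allele frequencies `d = arcsin(2f − 1)` at locus *l* are
marginally Gaussian,

    d_l | z_l = j  ~  N(mu·1, Sigma_l + W(c, w_j) + sigma²·11'),

where `Sigma_l = diag(1/N_lm)` is binomial sampling noise, `W(c, w)` is the
drift covariance of the graph — branch lengths `c`, per-edge migration rates
`w`, built from the open/closed-edge configuration average
`W = Σ_k c_k J_k`, `[J_k]_mn = p_mk p_nk` — and `(mu, sigma²)` is a normal
prior on the arcsine-scale root frequency. The hidden state `z_l` is the
vector of per-edge rates on a discrete grid (default 21 values in [0, 1]);
linkage enters through a continuous-time chain per edge,
`P = exp(delta·kappa·Lambda)` over inter-locus distance `delta`, with either
a ladder generator (neighbour moves only) or an attractor generator that
pulls toward a background rate `a` (rates `1+zeta` toward, `1−zeta` away,
escape rate `phi`). Parameters are learned by an empirical Bayes scheme:
Gaussian-mixture initialization of the covariance, least-squares coercion
onto the graph, SQUAREM-accelerated Baum–Welch, then a search over candidate
attractor states. Per-locus output: posterior mean rates
`w̄_il = Σ_j w_ij P(z_l = j | d)`, `q_e = 1 − P(z_l > a | d)` and
`q_d = 1 − P(z_l < a | d)`.

A model-faithful simulator (`simulateTrack`, `simulateDataset`) generates
allele counts under this generative process with constant, peak-block or
Markov migration tracks, so every stage is testable without external data.

## A worked example

Simulate 2,000 loci on a four-population graph with one migration edge
(background rate 0.1, peaks at 0.6), then re-infer the track:

```r
library(mixscan)
g <- readPopulationGraph(system.file("extdata", "fourpop_example.graph",
                                     package = "mixscan"))
g
#> PopulationGraph: 4 populations, 7 branches, 1 migration edge(s)
#> root: R
#> migration: m1: s -> P3
#> branch lengths: A=0.02, P1=0.04, s=0.015, P2=0.025, B=0.02, P3=0.03, P4=0.04

tr  <- simulateTrack(2000, "peaks", peakWidth = 20)
sim <- simulateDataset(g, track = tr, mu = -0.5, sigma2 = 0.3, N = 100,
                       seed = 7)
res <- mixScan(sim$counts, g,
               config = mixScanConfig(C = 100, J = 11, T = 3, seed = 1))
res$fit
#> MixScanFit
#>   logLik = -2851.8828 (34 EM steps, converged)
#>   mu = -0.4866, sigma2 = 0.2875
#>   edge 1: attractor kernel, a = 3, kappa = 0.286, phi = 0.858, zeta = 0.258
```

The fit recovers the generating root prior (`mu = −0.5`, `sigma² = 0.3`)
and places the attractor at grid state 3 — rate 0.2 on the 11-point grid,
one step above the true background 0.1. The per-locus posterior means
separate peak from background loci cleanly:

```r
w    <- meanMigrationRate(res$posterior)[, 1]
lab  <- trackLabels(tr)[, 1]
keep <- lab %in% c("peak", "background")
evaluateDetection(w[keep], lab[keep] == "peak")
#> [1] 0.982
mean(abs(w - trackRates(tr)[, 1]))
#> [1] 0.105
```

An AUC of 0.98 means peak loci are almost perfectly ranked above background
loci by `w̄`; the mean absolute error of ~0.1 on the rate itself reflects
posterior shrinkage toward the attractor at this modest locus count.
`excessFDR(res$posterior)` gives the per-locus `q_e` scores used to call
candidate regions, and `writeResults()` writes the per-locus table, a
reloadable parameter file and a run log.

Real data enter through `readVcfCounts(vcf, popmap, maf = 0.05)` or a plain
counts table; `inst/cli/mixscan.R` exposes `fit`, `simulate` and
`posteriors` subcommands for shell use.

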