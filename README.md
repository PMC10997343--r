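# ggmlrt

Corrected likelihood ratio tests for equality of two multivariate normal
distributions, with a factorized version for decomposable Gaussian graphical
models.

## The problem

Comparing two experimental conditions measured on the same set of continuous
variables — two patient groups with expression of the genes in a pathway,
two environments with the same panel of metabolites — often reduces to
testing whether the two multivariate normal distributions are equal:

    H0 : mu1 = mu2, Sigma1 = Sigma2

The likelihood ratio statistic

    Wn = -2 log Lambda_n
       = n log det(S_pooled) - n1 log det(S1) - n2 log det(S2)

(with maximum-likelihood covariance estimates) is asymptotically chi-square
with `f = p(p+3)/2` degrees of freedom. The catch is finite samples: as the
dimension `p` approaches the group sizes, the chi-square approximation
collapses and the nominal 5% test can reject almost always under the null.

This package implements a mean-based Bartlett-type correction

    Tn = delta_n * Wn,    delta_n = f / mu_wn(p, n1, n2)

where `mu_wn` is an analytic approximation of the null mean of `Wn` that
stays accurate when `p` grows with `n`. The corrected statistic keeps its
chi-square reference usable whenever `p/n -> 0` — a phase-transition
boundary of 1, against 1/2 for raw `Wn` and 2/3 for the classical
expansion-based `rho` correction (both included as comparators, alongside a
CLT standardization for the high-dimensional regime and exact finite-sample
null moments of `Wn` via `wn_null_moments()`).

The correction earns its keep in **decomposable Gaussian graphical models**:
when both distributions are Markov with respect to a chordal graph, the
global test factorizes over a running-intersection ordering of the cliques,

    Wn = Wn[C1] + sum_i ( Wn[Ci] - Wn[Si] ),

into independent local tests of dimension `|Ci|`, each corrected at its own
dimension. Local tests only require `nj > max |Ci| + 1`, so testing remains
feasible with `p` beyond the sample size, and a detected difference is
localized to cliques.

## Worked example

Two conditions on 14 variables tied to a known decomposable graph; in
condition 2 the means of nodes 1 and 2 are multiplied by 1.5 and their
variances halved, so only the first clique's hypothesis is false:

```r
library(ggmlrt)
set.seed(3)
g   <- four_clique_graph()               # cliques {1..8},{7..11},{11,12,13},{13,14}
sig <- graph_markov_sigma(g)             # precision zeros exactly at non-edges
mu1 <- rep(1, 14); mu2 <- mu1; mu2[1:2] <- 1.5 * mu2[1:2]
d   <- rep(1, 14); d[1:2] <- sqrt(0.5)
x1  <- matrix(rnorm(60 * 14), 60) %*% chol(sig) + rep(mu1, each = 60)
x2  <- matrix(rnorm(60 * 14), 60) %*% chol(sig * tcrossprod(d)) + rep(mu2, each = 60)

ggm_equality_test(two_sample_data(x1, x2, labels = as.character(1:14)),
                  graph = g, correction = "delta")
#> Decomposed two-sample equality test (correction: delta )
#>
#>   term clique_size statistic df   p.value
#>     C1           8   104.969 44 6.796e-07
#>  C2|S2           5    16.050 15 3.788e-01
#>  C3|S3           3     3.949  7 7.857e-01
#>  C4|S4           2     4.955  3 1.751e-01
#>
#> Global: statistic = 129.9 on 69 df, p-value = 1.291e-05 (summed local
#> corrected terms; finite-sample calibration of the sum is approximate)
```

The altered clique `C1` is flagged (p ≈ 7e-07) while the three conditional
tests, whose hypotheses are true, sit at unremarkable p-values — exactly the
localization the decomposition is for. Each local statistic was rescaled by
its own delta factor (for `C1` at `nj = 60`: `delta = 0.917`); without the
correction the 44-df test at small samples over-rejects badly.

Monte-Carlo drivers reproduce the calibration studies:

```r
clique_alteration_study(50, reps = 2000, seed = 1)   # size/power per local test
phase_transition_study(100, reps = 1000, seed = 1)   # rate vs eps, p = n^eps
approximation_study(p = c(2, 30, 40), nj = 50)       # null draws of all statistics
```

A thin command-line wrapper with `compare`, `decompose` and `simulate`
subcommands is installed at `system.file("cli", "ggmlrt", package = "ggmlrt")`.

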