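---
title: "Corrected likelihood ratio tests for equality of Gaussian graphical models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corrected likelihood ratio tests for equality of Gaussian graphical models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggmlrt)
```

## The testing problem

Given two independent samples of sizes $n_1$ and $n_2$ from $p$-variate
normal distributions $N_p(\mu_j, \Sigma_j)$, $j = 1, 2$, we test

$$H_0: \mu_1 = \mu_2,\ \Sigma_1 = \Sigma_2
  \qquad\text{vs.}\qquad H_a: \text{not } H_0 .$$

The likelihood ratio statistic is

$$W_n = -2\log\Lambda_n
  = n\log\det\hat\Sigma - n_1\log\det\hat\Sigma_1 - n_2\log\det\hat\Sigma_2 ,$$

where $\hat\Sigma_j$ are the maximum-likelihood (divide-by-$n_j$) covariance
estimates, $\hat\Sigma$ is the pooled MLE under $H_0$ (grand mean, divide by
$n = n_1 + n_2$), and under $H_0$, $W_n \rightsquigarrow \chi^2_f$ with
$f = p(p+3)/2$ ($p$ mean parameters plus $p(p+1)/2$ covariance parameters).
The statistic exists when $n_j > p + 1$ in both groups; `mle_summary()`
accepts the weaker $n_j \ge p + 1$ because the estimates themselves exist
there, but every test-statistic function enforces the strict bound.

$W_n$ is invariant under common affine maps $x \mapsto Ax + b$ of both
samples, so its null distribution is parameter-free ("pivotal").  This is
exploited throughout: null simulations can use a zero mean and identity
covariance without loss of generality, and Type-I results on graph-structured
generators do not depend on the particular covariance chosen.

## Why a correction, and which

The $\chi^2_f$ approximation degrades quickly as $p$ grows relative to
$n_j$: at $p = 40$, $n_j = 50$ the null mean of $W_n$ is about $1.9 f$, and
a nominal 5% test rejects essentially always.  The classical remedies each
have a limited range, conveniently summarized by the *phase transition
boundary* $d$: the chi-square approximation for a statistic holds if and
only if $p / n^d \to 0$.

* **Uncorrected $W_n$**: $d = 1/2$.
* **Expansion-based correction** $\rho\,W_n$ with
  $$\rho = 1 - \frac{2p^2 + 9p + 11}{6(p+3)\,n}
    \Big(\frac{n}{n_1} + \frac{n}{n_2} - 1\Big):$$
  $d = 2/3$ (`rho_factor()`).
* **CLT standardization** of $\log\Lambda_n$ referred to a standard normal:
  works with $p$ close to $n_j$, but fails for small $p$, where the LRT
  distribution is strongly skewed (`clt_zscore()`).
* **Mean-based correction** $T_n = \delta_n W_n$,
  $\delta_n = f / \mu_{w_n}$: $d = 1$, i.e. the chi-square reference is
  usable whenever $p/n \to 0$ (`delta_factor()`).

Here $\mu_{w_n} = -2\mu_n$ is an analytic approximation of
$E_{H_0}[W_n]$ that remains accurate when $p$ grows with $n$:

$$\mu_n = \tfrac14\Big[-4p - \sum_j \frac{p}{n_j}
  + n\,r_n^2\,(2p - 2n + 3)
  - \sum_j n_j\,r_{n_j'}^2\,(2p - 2n_j + 3)\Big],$$

with $n_j' = n_j - 1$ and $r_x^2 = -\log(1 - p/x)$ for $x > p$
(`mu_wn()`).  Because $\delta_n$ matches the first moment rather than a
fixed-$p$ expansion, it coincides with $\rho$ in the classical regime
(within 1% for $p/n < 0.05$) and keeps working where $\rho$ breaks down.

### Exact null moments as an internal anchor

Under $H_0$, $\Lambda_n$ factorizes into independent pieces: a matrix-beta
determinant pair coming from the two Wishart scatter matrices, and a
univariate beta (the mean comparison, a hypothesis of rank one).  The
log-moments of both are sums of digamma/trigamma values, so the *exact*
finite-sample mean and variance of $W_n$ have closed forms, implemented in
`wn_null_moments()`.  This plays three roles:

1. it is the dispersion term of the CLT comparator (the z-score divides by
   the exact standard deviation of $\log\Lambda_n$, while centering at the
   analytic $\mu_n$ above);
2. it arbitrates between two typographically plausible readings of the
   group term in $\mu_n$ — the $(2p - 2n_j + 3)$ reading tracks the exact
   mean to about 0.1% across the admissible range, while the
   $(2p - 2n_j' + 3)$ reading is off by more than 10%, so the former is the
   default and the latter is kept only behind the `last_factor` argument;
3. it gives the test suite a deterministic oracle, so Monte-Carlo checks
   can target the exact mean instead of the asymptotic one.

## Decomposable graphical models

When both distributions are Markov with respect to a decomposable
(chordal) undirected graph $G$, a running-intersection (RIP) ordering
$C_1, \dots, C_k$ of its cliques with separators
$S_i = C_i \cap (C_1 \cup \dots \cup C_{i-1})$ factorizes the global test
into independent local tests:

$$W_n = W_n^{C_1} + \sum_{i=2}^k W_n^{C_i|S_i},
  \qquad W_n^{C_i|S_i} = W_n^{C_i} - W_n^{S_i},$$

with local degrees of freedom $f_{C_1}$ and $f_{C_i} - f_{S_i}$.  Each
local test needs only $n_j > \max_i |C_i| + 1$, so the decomposition makes
testing feasible even when $p$ exceeds the sample size, and it *localizes*
a difference to the cliques whose hypotheses fail.

The correction extends to the conditional terms through the first moment:
since the null mean of a difference of nested LRTs is the difference of the
null means,

$$T_n^{C_i|S_i} = \frac{f_{C_i} - f_{S_i}}
  {\mu_{w_n}(|C_i|) - \mu_{w_n}(|S_i|)}\; W_n^{C_i|S_i}.$$

Each local term is thereby corrected *at its own dimension*, which matters
because a decomposition typically mixes regimes ($|C_i| \ll n$ next to
$|C_i| \approx n$).  A `"rho"` option on conditional terms is provided by
the same difference construction with the expansion-implied mean $f/\rho$;
this is an extension of ours — the published comparison uses only the
uncorrected and delta-corrected local statistics.

Two structural caveats, both verified in the test suite:

* only the *global* telescoping sum is invariant to which valid RIP
  ordering is used; the individual local statistics depend on which clique
  leads the recursion (the leader contributes a marginal, not a
  conditional, term);
* the sum of independently corrected local terms is referred to
  $\chi^2_{\sum f}$ only as a convenience — its finite-sample calibration
  is approximate, and the primary output is the set of local tests.

### Graph machinery

Decomposability is checked by maximum cardinality search followed by the
perfect-elimination test; maximal cliques are collected along the MCS order,
which automatically yields a RIP-compatible ordering, and every structural
invariant (clique maximality, RIP, residual partition) is re-verified on
each `rip_structure()` call.  MCS ties are broken toward the smallest label
(numerically when all labels parse as integers), so the reported ordering
is deterministic.  Triangulation of non-chordal graphs is out of scope; the
error message says so rather than silently altering the model.

## The simulation studies and their generators

`four_clique_graph()` fixes a 14-node decomposable graph with clique
cardinalities (8, 5, 3, 2) and separator cardinalities (2, 1, 1); the study
it supports published those cardinalities but not the edge set, so the
package fixes one concrete graph with nodes 1 and 2 inside $C_1$ and
outside every separator.  Under the null this choice is immaterial: by
affine invariance the local test distributions depend only on the
cardinalities.

`graph_markov_sigma()` builds the generating covariance: a precision matrix
with unit diagonal and $-0.3$ (the target partial correlation) at each
edge, shrunk by 10% steps until positive definite — for the 14-node graph
this lands at about $0.13$ — then inverted and rescaled to unit diagonal,
which preserves both the zero pattern and the partial correlations.  The
construction is deterministic.

`clique_alteration_study()` draws condition 1 with all means 1.0 and this
covariance; condition 2 multiplies the means of nodes 1 and 2 by 1.5 and
halves their variances (rescaling rows/columns by $\sqrt{0.5}$, preserving
correlations).  Only the $C_1$ hypothesis is false; because the alteration
touches coordinates 1 and 2 alone, the marginal laws over
$C_2, C_3, C_4$ and all separators are *identical* across conditions, so
the Type-I rows are exact null cells.  Power on $C_1$ is generator
dependent: with this generator it rises faster in $n_j$ than the published
intermediate cells (which used an unavailable generator) and saturates at 1
by $n_j = 100$; the package therefore validates the size rows, the
monotonicity of power, and its endpoint.

`phase_transition_study()` sets $p = \langle n_1^\varepsilon \rangle$ over
$\varepsilon \in \{6/24, \dots, 23/24, 23.5/24\}$ and records null
rejection rates of $W_n$, $\rho W_n$ and $T_n$ at $\alpha = 0.05$,
displaying the three boundaries $1/2$, $2/3$, $1$.  Cells with
$p \ge n_j - 1$ are flagged inadmissible, not computed.
`approximation_study()` retains raw null draws of all four statistics with
moments and Kolmogorov–Smirnov distances to their reference laws.

What the generators emulate — and what they do not: data are exactly
Gaussian, the graph is known and correct, samples are complete and
independent.  Passing tests therefore demonstrate calibration of the
correction under its stated assumptions; they say nothing about robustness
to non-normality, to a misspecified graph, or to dependent observations,
and the package deliberately offers no $p \ge n$ regularized estimator for
marginals larger than the sample.

## Numerical choices

* Log-determinants go through Cholesky factorization of the covariance
  (never determinant-then-log); a failed factorization *is* the definition
  of a singular estimate and produces an "LRT undefined" error naming the
  offending group.
* Every statistic is an LRT and hence nonnegative; values in
  $[-10^{-9}, 0)$ are clipped to zero as floating-point noise, anything
  more negative raises an internal-consistency error rather than being
  absorbed.
* Correction factors are pure deterministic functions of $(p, n_1, n_2)$
  and are precomputed once per Monte-Carlo scenario.
* Monte-Carlo drivers take an explicit `seed` and use a single stream per
  scenario, so reports are bit-reproducible; default replicate counts are
  2000 (standard errors of rates $\approx 0.005$), with the reproduction
  script using 10000, the published design.
* Sample files are aligned by variable label, never by column position, and
  missing values are rejected rather than imputed.

## Limitations

Two groups only; no missing data; no triangulation of non-chordal graphs;
no edge-level localization below clique resolution.  An exact-mean
rescaling ($f / E_{H_0}[W_n] \cdot W_n$, buildable from
`wn_null_moments()`) is not exposed as a correction option: the analytic
$\delta_n$ is the recommended correction, and the exact moments serve as
validation machinery rather than as a competing statistic.
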