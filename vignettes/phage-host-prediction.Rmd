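---
title: "Predicting phage-host associations from k-mer word frequencies"
author: "phagehost authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting phage-host associations from k-mer word frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagehost)
```

## The problem

Viral metagenomic studies produce large numbers of phage genomes and contigs
whose bacterial hosts are unknown. Because a phage depends on its host's
replication machinery, its genome tends to echo the host's oligonucleotide
("word") usage, and viruses infecting the same host genus tend to resemble
one another in word usage more than random virus pairs do. `phagehost` turns
that signal into a supervised prediction problem: given the word-frequency
profile of a viral sequence, does it infect a given bacterial host genus?

The package implements the full framework: the four word-frequency feature
representations, per-sequence Markov background models with exact word-count
moments, five supervised learners behind one score interface, the
cutting-year evaluation protocol with repeated negative resampling and rank
AUC, average-dissimilarity baselines (Manhattan and a d2*-type measure), a
contig fragmentation and sequencing-error simulator, and a beta-mixture
maximum-likelihood estimator of the fraction of truly infectious viruses in
high-throughput (viral-tagging) candidate sets.

## Features

For a sequence of length $L$ and word length $k$, let $N_w$ be the number of
(possibly overlapping) occurrences of each word $w \in \{A,C,G,T\}^k$ on the
forward strand. The four feature vectors are

$$
\mathcal{F}_1 = \frac{N_w}{L-k+1}, \quad
\mathcal{F}_2 = \frac{N_w - E(N_w)}{E(N_w)}, \quad
\mathcal{F}_3 = \frac{N_w - E(N_w)}{\sqrt{E(N_w)}}, \quad
\mathcal{F}_4 = \frac{N_w - E(N_w)}{\sigma(N_w)},
$$

where $E(N_w)$ and $\sigma(N_w)$ are the mean and standard deviation of the
count under a background model of the sequence itself: an i.i.d. model
(order 0) or a Markov chain of order 1-3, fitted by maximum likelihood to
each sequence individually (`fit_markov()`, pseudocount 0 by default).
Windows containing IUPAC ambiguity codes are skipped both in counting and in
the window total, so $\mathcal{F}_1$ always sums to 1; entries with zero
expectation (or zero $\sigma$) are set to 0 rather than propagating
infinities, which matters in sparse high-$k$ regimes. Words are indexed
lexicographically over $A<C<G<T$ so feature matrices are portable. Counting
is forward-strand only; a `canonical` switch adds reverse-complement counts
for users who want strand-symmetric profiles.

### Exact word-count moments

The variance of an overlapping word count under a Markov background has no
simple closed form, so `count_sd()` computes it exactly from the indicator
decomposition $N_w = \sum_i I_i$:

* the chain is started from the empirical initial context distribution of
  the source sequence, and the marginal context distribution at every
  position is propagated explicitly, so $P(I_i)$ is exact even where the
  empirical initial distribution is not perfectly stationary;
* covariances at lags $d < k$ use the word's self-overlap structure: the
  joint probability is the transition product along the overlapped
  extension of the word (zero when the shifted word is incompatible with
  itself);
* covariances at lags $d \ge k$ use $d$-step context transition powers;
  the geometric convergence of those powers is detected and the tail is
  truncated only at machine precision ($10^{-15}$ in the row supremum), so
  the summation is exact to floating-point resolution.

The $k=1$ i.i.d. case collapses to the binomial $\sqrt{Lp(1-p)}$ exactly,
which the tests assert to $10^{-12}$. For everything else the
implementation target is defined by simulation: the exact moments must sit
within 3 standard errors of the empirical mean and SD of counts simulated
from the same background (the suite uses $10^6$ simulated sequences of
length 100 per grid cell, over self-overlapping and non-overlapping words,
$k \in \{2,4,6\}$ and orders 0-2; the SE of the sample SD uses the
delta-method form with the empirical fourth moment, since rare-word counts
are strongly skewed). A `method = "poisson"` fallback
($\sigma \approx \sqrt{E}$) is provided for cross-checks.

## Learners and the evaluation protocol

Five learners sit behind one contract — a real-valued score per sequence,
higher meaning more likely to infect:

* **logistic_l1** — logistic regression with LASSO penalty. The penalty
  weight applies to the *summed* log-likelihood (default $\lambda = 1$);
  glmnet penalizes the mean, so the value is divided by the number of
  observations internally.
* **svm_rbf** — SVM with RBF kernel, $\gamma$ defaulting to the reciprocal
  of the feature dimension; the score is the signed margin.
* **random_forest** — 100 fully grown trees by default ($\sqrt{p}$ features
  per split); the score is the class-1 vote fraction. The original tree
  count is not stated in the protocol, so comparisons to published AUCs
  carry that caveat.
* **gaussian_nb / bernoulli_nb** — naive Bayes with Gaussian
  class-conditionals, or Bernoulli after binarizing each feature at its
  training-set mean (the binarization rule is a documented choice; Laplace
  smoothing 1 avoids zero cell probabilities). Gaussian class-conditional
  SDs are floored at $10^{-9}$ so constant features cannot produce
  non-finite scores.

The protocol (`evaluate_host()`) mirrors a realistic discovery timeline
rather than cross-validation: positives found up to the cutting year train,
positives found after it test. "Identified before the cutting year" is
implemented inclusively (`year <= cutting_year`); the printed partition
counts of the original genome snapshot cannot be re-derived without that
snapshot, so the inclusive convention is a documented, configurable choice.
Negatives — every virus not known to infect the host, including viruses
with unknown hosts — are drawn uniformly without replacement at the same
sizes as the positive sets, independently 50 times, and performance is the
mean rank AUC over the repeats. The rank (Mann-Whitney) AUC uses midranks,
so ties count 1/2, and equals trapezoidal ROC integration exactly. One
master seed expands deterministically into per-repeat sampler and learner
seeds, making every repeat individually reproducible.

The dissimilarity baselines score a query by its average Manhattan (on
$\mathcal{F}_1$) or d2*-type (on $\mathcal{F}_3$) dissimilarity to the
positive training set, and sweep a threshold to trace the ROC; since only
the score ordering matters, `dissimilarity_auc()` computes the identical
rank AUC on the negated scores. The d2* statistic is an uncentered (cosine)
correlation; it is mapped to $[0,1]$ by $(1-\cos)/2$, and the raw
correlation is also exposed since any strictly monotone transform leaves
the AUC unchanged.

## Contigs

`fragment()` cuts genomes into non-overlapping contigs of exactly 1, 3 or
5 kb (coordinates 0-based half-open, ids `parent|start-end`); the trailing
remainder is discarded so all contigs have the advertised length.
`inject_errors()` substitutes each base independently at the protocol rate
of 0.05%, choosing uniformly among the other three bases; errors are
applied after fragmentation, including to the whole-genome length class.
`cross_length_evaluation()` runs the full train-length x test-length grid.
Two design points matter: negatives are sampled at the *genome* level
before fragmentation, so contigs of one genome never straddle the
train/test boundary, and all contigs of a genome are used (rather than one
per genome) — the grid cell with whole/whole lengths and error rate 0
reproduces `evaluate_host()` bit-exactly under a shared seed, which the
tests assert.

## Infectious-fraction estimation

Viral tagging yields candidate — not confirmed — virus-host associations.
Modeling candidate scores as a two-component mixture
$P_{\mathrm{obs}} = (1-\gamma)\,\Phi_0(\alpha_0,\beta_0) +
\gamma\,\Phi_1(\alpha_1,\beta_1)$ of beta distributions, the package
estimates $\gamma$, the fraction of truly infectious candidates, in two
stages exactly as the protocol prescribes: the component shapes are fitted
once by moments ($\alpha = m(m(1-m)/v - 1)$, $\beta = (1-m)(m(1-m)/v-1)$,
population-variance denominator) from held-out positive and negative
reference scores and then frozen; $\gamma$ alone is estimated by maximum
likelihood. The mixture log-likelihood is concave in $\gamma$, so
golden-section search on $[0,1]$ (tolerance $10^{-8}$, endpoints checked
explicitly) suffices without multistart, and the tests verify agreement
with an exhaustive 0.001-grid search.

Numerical choices: probability scores can hit 0 or 1 exactly (a forest
voting unanimously), where beta densities are undefined, so scores are
clamped to $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 1/(2n)$ and
the clamp count is reported. A useful by-product: after clamping, the
sample variance is strictly below $m(1-m)$, so the moment estimator is
always well defined for non-constant scores. The confidence interval is
profile-likelihood based ($\{\gamma: 2(\ell(\hat\gamma)-\ell(\gamma)) \le
\chi^2_1(0.95)\}$, truncated to $[0,1]$): the original analysis does not
state its interval construction, and the profile interval behaves sensibly
when $\hat\gamma$ sits near a boundary, where a Wald interval (also
available) degenerates. Simulation at the fitted component shapes
$\Phi_1(3.35, 1.10)$ and $\Phi_0(3.54, 8.78)$ with $n = 1661$ — the scale
of the contig analysis — recovers $\gamma = 0.3$ within $\pm 0.05$ in at
least 95% of replicates, and the profile interval holds near-nominal
coverage over 500 simulated datasets. SVM margins are not probabilities;
if they are fed into the mixture they must be squashed first, which is why
the protocol's forest probabilities are the recommended input.

## The synthetic benchmark

Real genome snapshots are large and external, so the package ships a
generator (`make_benchmark()`) that emulates the statistical premise the
classifier relies on — viruses of one host share word usage. Each
pseudo-host receives a random Markov chain (Dirichlet rows, stationary
initial distribution); a single `divergence` knob blends each host's
transition rows with a shared random chain, from 0 (all hosts identical:
no signal, AUC near 1/2) to 1 (fully host-specific: near-perfect
separation). Defaults are 3 hosts x 40 genomes x 20 kb with an order-1
chain — genome lengths long enough for stable $k=4$ and $k=6$ frequencies
yet small enough for seconds-scale runs — with discovery years uniform on
2005-2015 and cycling family labels. All randomness flows from one seed;
the benchmark is bit-reproducible.

What passing on this benchmark does and does not show: it validates the
machinery (features, resampling, learners, AUC, fragmentation) end to end
under a controlled signal, and the null case guards against leakage. It
does not reproduce published per-genus AUCs, which depend on a specific
curated genome snapshot; and real phage genomes have architecture (genes,
GC skew, repeats, shared modules between hosts) that an order-1 chain does
not imitate, so absolute AUCs here are not forecasts of field performance.

## Reference tables and worked correlations

The package bundles the nine-genus benchmark summary tables (per-genus AUC
of the forest + $\mathcal{F}_1$ classifier at $k = 4, 6, 8$; average
within-genus Manhattan distances; Caudovirales family compositions with
the reported entropy column). From them, `entropy_base2()` and
`spearman()` reproduce the reported associations — within-genus distance
vs AUC: $\rho = -0.450, -0.800, -0.683$ for $k = 4, 6, 8$; composition
entropy vs AUC: $\rho = -0.600, -0.750, -0.783$ — i.e. genera whose
viruses are more homogeneous (smaller distances, lower entropy) are the
easier prediction targets. The entropy base is not stated in the source
table; base 2 reproduces seven of the nine printed values to 3 decimals
(the Lactococcus and Mycobacterium rows match no consistent parse of their
printed counts and are treated as probable typos, excluded from the exact
checks — the reported column is still used for the rank correlations,
whose ranks are unaffected).

```{r tables}
tabs <- host_benchmark_tables()
entropy_base2(as.numeric(tabs$family_counts[1, 2:5])) # Bacillus
spearman(tabs$auc$k6, tabs$manhattan$k6)
```

## Problem sizes used by the test suite

The suite exercises the full protocol at sizes chosen to keep a complete
run in the minutes range while leaving the statistical checks sharp: the
separability and null benchmarks at the generator defaults (3 x 40 x 20 kb,
5-10 repeats); word-count moment checks at $10^6$ simulated sequences per
grid cell; mixture recovery at $n = 1661$ with 200 replicates and interval
coverage over 500 datasets; and smaller fixtures (2 hosts x 12 x 4 kb) for
pipeline identities. The acceptance script (`scripts/acceptance.R`)
recomputes the same quantities from scratch at the same scales under a
user-supplied seed.

## Known limitations

* Forward-strand counting and per-sequence (not per-host) backgrounds are
  fixed conventions of the protocol; both are configurable but untested
  against published results.
* No gapped or mismatch-tolerant words, no protein alphabet, no read-level
  simulation (indels, quality scores) and no assembly.
* Hyperparameters beyond those stated by the protocol (forest size, naive
  Bayes binarization) are documented defaults, not recovered originals.
* The mixture model assumes exactly two beta components with shapes fixed
  by reference score sets; no joint EM over shapes and $\gamma$.
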