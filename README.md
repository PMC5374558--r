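# phagehost

Alignment-free prediction of phage-host infectious associations from k-mer
word frequencies.

## What it does, and for whom

Viral metagenomics routinely yields phage genomes and contigs with no host
information. Because phages depend on their host's replication machinery,
their genomes tend to echo the host's oligonucleotide usage, so viruses
infecting the same bacterial genus resemble one another in word-frequency
space. `phagehost` is for microbial ecologists and bioinformaticians who
want to exploit that signal: it predicts whether a viral sequence infects a
given host genus, evaluates predictors the way hosts are actually
discovered (by date, not by cross-validation), and quantifies how many
candidates from high-throughput screens are truly infectious.

The core components:

* **Features.** For word length *k*, the count *N<sub>w</sub>* of each word
  *w* over the L−k+1 windows of a sequence yields four representations:
  relative frequency F1 = N<sub>w</sub>/(L−k+1), and three normalized forms
  F2 = (N<sub>w</sub>−E)/E, F3 = (N<sub>w</sub>−E)/√E,
  F4 = (N<sub>w</sub>−E)/σ, with E(N<sub>w</sub>) and σ(N<sub>w</sub>)
  computed **exactly** under an i.i.d. or order 1-3 Markov background
  fitted to each sequence itself (overlapping-occurrence covariances
  included, validated against large-scale simulation).
* **Classifiers.** Logistic regression with LASSO, SVM-RBF, random forest,
  Gaussian and Bernoulli naive Bayes behind one score interface, plus the
  average Manhattan / d2*-dissimilarity baselines.
* **Protocol.** Cutting-year train/test partitions, 50 random negative
  resamples at equal class sizes, midrank (Mann-Whitney) AUC — fully
  seeded and bit-reproducible.
* **Contigs.** Non-overlapping 1/3/5-kb fragmentation with 0.05%
  substitution errors and the cross-length training/testing AUC grid.
* **Infectious fraction.** A two-component beta-mixture maximum-likelihood
  estimator of the fraction γ of truly infectious viruses in a candidate
  score set, with profile-likelihood confidence intervals.
* **Synthetic benchmark.** A seeded generator of pseudo-host genomes with a
  single class-separation knob, so the whole pipeline is testable without
  downloads.

## Worked example

Generate a divergent synthetic benchmark, evaluate a random-forest
classifier for one pseudo-host under the cutting-year protocol, and
estimate an infectious fraction from simulated tagging scores:

```r
library(phagehost)

bench <- make_benchmark(n_hosts = 3, genomes_per_host = 40,
                        genome_length = 20000, divergence = 1, seed = 11)
part <- partition_by_cutting_year(bench$records, "Host01", cutting_year = 2010)
part
#> Host partition for genus 'Host01' (cutting year 2010)
#>   positive train: 30 viruses
#>   positive test:  10 viruses
#>   negative pool:  80 viruses

evaluate_host(bench$records, part, kind = "F1", k = 4,
              learner = learner_spec("random_forest"), repeats = 5, seed = 5)
#> Evaluation for host 'Host01': mean AUC 1.000 (SD 0.000) over 5 negative resample(s)

# fraction of truly infectious candidates in a score set
c1 <- beta_component(3.35, 1.10)   # infectious score component
c0 <- beta_component(3.54, 8.78)   # non-infectious score component
scores <- simulate_mixture_scores(1661, gamma = 0.3, c0, c1, seed = 2)
estimate_gamma(scores, c0, c1)
#> beta mixture fit (n = 1661): gamma_hat = 0.299, 95% CI [0.274, 0.324]
#>   comp0 (non-infectious): Beta(3.54, 8.78)
#>   comp1 (infectious):     Beta(3.35, 1.10)
```

The mean AUC of 1.000 reflects fully divergent pseudo-hosts (the
`divergence = 0` null sits near 0.5); `gamma_hat` recovers the true mixing
fraction 0.3 with its 95% profile-likelihood interval.

The bundled nine-genus summary tables reproduce the published rank
correlations between classifier performance and within-genus homogeneity:

```r
tabs <- host_benchmark_tables()
spearman(tabs$auc$k6, tabs$manhattan$k6)
#> [1] -0.8
entropy_base2(c(21, 8, 27, 3))   # Bacillus family composition
#> [1] 1.655886
```

A thin command-line front end over the same functions ships in
`inst/cli/phk.R` (`Rscript phk.R <command> --help`), with subcommands for
partitioning, feature extraction, simulation, fragmentation, baseline
scoring, protocol evaluation, the cross-length grid, fraction estimation
and the summary statistics.

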