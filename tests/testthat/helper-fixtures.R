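# Shared fixtures, built in code. The larger benchmark objects are created
# once per test run and reused across files.

toy_records <- function() {
  data.frame(
    id = paste0("v", 1:6),
    sequence = c("ACGTACGTACGTACGT", "ACGTACGAACGTACGA", "ACGTTCGTACGTTCGT",
                 "GGGGCCCCGGGGCCCC", "TTTTAAAATTTTAAAA", "GCGCGCGCATATATAT"),
    host_genus = c("hostX", "hostX", "hostX", "hostY", "hostY", NA),
    year = c(2009L, 2011L, 2013L, 2010L, 2012L, 2011L),
    family = c("Myoviridae", "Siphoviridae", NA, "Podoviridae", "other", NA),
    stringsAsFactors = FALSE)
}

write_toy_fasta <- function(records = toy_records(), path = tempfile(fileext = ".fa")) {
  write_fasta(records, path)
  path
}

# brute-force k-mer counter: sliding window + dictionary
brute_count_kmers <- function(sequence, k) {
  sequence <- toupper(sequence)
  words <- phagehost:::all_words(k)
  counts <- setNames(integer(length(words)), words)
  for (i in seq_len(nchar(sequence) - k + 1)) {
    w <- substr(sequence, i, i + k - 1)
    if (w %in% words) counts[w] <- counts[w] + 1L
  }
  counts
}

# trapezoidal integration of the empirical ROC curve (threshold sweep)
trapezoid_auc <- function(pos, neg) {
  thr <- sort(unique(c(pos, neg, -Inf, Inf)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# divergent and null synthetic benchmarks at the study scale, built once
divergent_bench <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- make_benchmark(n_hosts = 3, genomes_per_host = 40,
                             genome_length = 20000, order = 1,
                             divergence = 1, seed = 101)
    }
    val
  }
})

null_bench <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- make_benchmark(n_hosts = 3, genomes_per_host = 40,
                             genome_length = 20000, order = 1,
                             divergence = 0, seed = 101)
    }
    val
  }
})

# small benchmark for fast pipeline tests (short genomes, fewer records)
small_bench <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- make_benchmark(n_hosts = 2, genomes_per_host = 12,
                             genome_length = 4000, order = 1,
                             divergence = 1, seed = 77)
    }
    val
  }
})

# Monte-Carlo oracle: empirical mean/SD of N_w over sequences simulated
# from a background (compiled path, seeded)
mc_word_moments <- function(bg, word, L, nsim, seed = 1) {
  sims <- withr::with_seed(seed, phagehost:::mc_simulate_word_counts(
    cumsum(unname(bg$initial_distribution)),
    t(apply(bg$transitions, 1, cumsum)),
    bg$order, as.integer(L),
    phagehost:::word_to_bases(word) - 1L, as.integer(nsim)))
  mu <- mean(sims)
  v <- mean((sims - mu)^2)
  m4 <- mean((sims - mu)^4)
  list(mean = mu, sd = sd(sims), n = nsim,
       se_mean = sd(sims) / sqrt(nsim),
       # delta-method SE of the sample SD: Var(s^2) = (m4 - v^2)/n,
       # valid for the skewed distributions of rare-word counts
       se_sd = sqrt(max(m4 - v^2, 0) / (4 * v * nsim)))
}
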