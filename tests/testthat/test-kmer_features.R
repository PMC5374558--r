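test_that("k-mer counting matches hand examples and the ambiguity rule", {
  x <- count_kmers("ACGT", 2)
  expect_equal(unname(x$counts[c("AC", "CG", "GT")]), c(1L, 1L, 1L))
  expect_equal(sum(x$counts), 3L)
  expect_equal(x$n_windows, 3L)

  # overlapping occurrences
  expect_equal(unname(count_kmers("AAAA", 2)$counts["AA"]), 3L)

  # windows containing ambiguity codes are skipped and not in n_windows
  y <- count_kmers("ACNGT", 2)
  expect_equal(unname(y$counts[c("AC", "GT")]), c(1L, 1L))
  expect_equal(y$n_windows, 2L)

  expect_error(count_kmers("ACG", 4), "exceeds")
})

test_that("k-mer counting equals the brute-force sliding-window oracle", {
  set.seed(5)
  for (i in 1:4) {
    L <- sample(200:2000, 1)
    s <- paste(sample(c("A", "C", "G", "T", "N"), L, replace = TRUE,
                      prob = c(.24, .24, .24, .24, .04)), collapse = "")
    for (k in c(1, 3, 5)) {
      expect_equal(count_kmers(s, k)$counts, brute_count_kmers(s, k))
    }
  }
})

test_that("Markov fitting reproduces hand-counted transitions", {
  bg0 <- fit_markov("AACC", 0)
  expect_equal(unname(bg0$transitions[1, ]), c(0.5, 0.5, 0, 0))

  bg1 <- fit_markov("AAAT", 1)
  expect_equal(unname(bg1$transitions["A", c("A", "T")]), c(2/3, 1/3))

  bg <- fit_markov("ACACAC", 1)
  expect_equal(unname(bg$transitions["A", "C"]), 1)
  expect_equal(unname(bg$transitions["C", "A"]), 1)
  # pseudocount: p(C|A) = (3 + 0.5) / (3 + 4 * 0.5) = 0.7
  bgp <- fit_markov("ACACAC", 1, pseudocount = 0.5)
  expect_equal(unname(bgp$transitions["A", "C"]), 0.7)

  expect_error(fit_markov("AC", 3), "too short")
  # rows are stochastic for all orders
  for (ord in 0:3) {
    b <- fit_markov(strrep("ACGTTGCA", 40), ord, pseudocount = 0.1)
    expect_equal(unname(rowSums(b$transitions)), rep(1, 4^ord),
                 tolerance = 1e-12)
  }
})

test_that("word probabilities chain transitions and sum to one", {
  bg <- fit_markov("ACACAC", 1)
  # p(AC) = p_hat(A) * p(C|A) = 0.5 * 1
  expect_equal(word_probability(bg, "AC"), 0.5)
  expect_equal(word_probability(bg, "AA"), 0)

  src <- generate_genome(make_host_generator(3, order = 2), 2000, seed = 9)
  for (ord in 0:3) {
    b <- fit_markov(src, ord)
    for (k in c(1, 2, 5)) {
      expect_equal(sum(phagehost:::all_word_probabilities(b, k)), 1,
                   tolerance = 1e-12)
    }
  }
  # uniform iid: every k=2 word has probability 1/16
  u <- fit_markov(strrep("ACGT", 100), 0)
  expect_equal(unname(phagehost:::all_word_probabilities(u, 2)),
               rep(1/16, 16), tolerance = 1e-12)
  expect_error(word_probability(bg, "ANC"), "non-ACGT")
})

test_that("expected counts satisfy the normalization identity", {
  u <- fit_markov(strrep("ACGT", 100), 0)
  expect_equal(expected_count(u, "AC", 5), 4 / 16)
  src <- generate_genome(make_host_generator(21, order = 1), 3000, seed = 2)
  for (ord in 0:3) {
    b <- fit_markov(src, ord)
    for (k in c(2, 5, 8)) {
      expect_equal(sum(expected_counts_all(b, k, 300)), 300 - k + 1,
                   tolerance = 1e-9)
    }
  }
  # degenerate background: p(A) = 1 makes E(N_AA) = L - 1
  dg <- fit_markov(strrep("A", 50), 0)
  expect_equal(expected_count(dg, "AA", 30), 29)
})

test_that("feature vectors obey their defining identities", {
  cts <- count_kmers("ACGT", 2)
  f1 <- compute_feature(cts, kind = "F1")
  expect_equal(unname(f1$values[c("AC", "CG", "GT")]), rep(1/3, 3))
  expect_equal(sum(f1$values), 1)

  src <- generate_genome(make_host_generator(13, order = 1), 2500, seed = 4)
  cts <- count_kmers(src, 3)
  bg <- fit_markov(src, 1)
  f2 <- compute_feature(cts, bg, "F2")
  f3 <- compute_feature(cts, bg, "F3")
  f4 <- compute_feature(cts, bg, "F4")
  expect_equal(sum(compute_feature(cts, kind = "F1")$values), 1)
  # F2 * sqrt(E) == F3 wherever E > 0
  E <- expected_counts_all(bg, 3, cts$L)
  pos <- E > 0
  expect_equal(unname(f2$values[pos] * sqrt(E[pos])), unname(f3$values[pos]),
               tolerance = 1e-9)
  expect_true(all(is.finite(f2$values)))
  expect_true(all(is.finite(f4$values)))
  expect_equal(f4$background_order, 1L)
  expect_error(compute_feature(cts, kind = "F3"), "background")

  # N_w == E for all w under an exactly uniform sequence: F2 = F3 = 0
  useq <- strrep("ACGT", 64)
  ubg <- fit_markov(useq, 0)
  ucts <- count_kmers(useq, 1)
  uf2 <- compute_feature(ucts, ubg, "F2")
  expect_equal(unname(uf2$values), rep(0, 4), tolerance = 1e-12)
})

test_that("features are invariant to FASTA line wrapping", {
  rec <- small_bench()$records[1:2, ]
  f1 <- tempfile(fileext = ".fa")
  f2 <- tempfile(fileext = ".fa")
  write_fasta(rec, f1, width = 60)
  write_fasta(rec, f2, width = 7)
  m1 <- feature_matrix(read_fasta(f1), "F1", k = 3)
  m2 <- feature_matrix(read_fasta(f2), "F1", k = 3)
  expect_identical(m1, m2)
})

test_that("feature matrices carry recipes and write to TSV", {
  rec <- small_bench()$records[1:3, ]
  m <- feature_matrix(rec, "F2", k = 2, order = 1)
  expect_equal(attr(m, "recipe"), list(kind = "F2", k = 2L, order = 1L))
  expect_equal(rownames(m), rec$id)
  # matrix path agrees with the single-sequence path
  one <- compute_feature(count_kmers(rec$sequence[2], 2),
                         fit_markov(rec$sequence[2], 1), "F2")
  expect_equal(unname(m[2, ]), unname(one$values), tolerance = 1e-12)

  tsv <- tempfile(fileext = ".tsv")
  write_feature_tsv(m, tsv)
  back <- read.delim(tsv, check.names = FALSE)
  expect_equal(back$id, rec$id)
  expect_equal(as.numeric(back[1, -1]), unname(m[1, ]), tolerance = 1e-9)
})
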