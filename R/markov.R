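#' Fit a Markov background model to a sequence
#'
#' Fits an order-m Markov chain (m = 0 is the i.i.d. model) to a single DNA
#' sequence: maximum-likelihood transition probabilities from observed
#' (m+1)-mer counts, plus the empirical m-mer frequencies of the sequence as
#' the initial context distribution. Windows containing ambiguity codes are
#' skipped, consistently with k-mer counting. Contexts never observed get a
#' uniform transition row (they carry zero probability mass anyway).
#'
#' @param sequence DNA string (A/C/G/T plus IUPAC ambiguity codes).
#' @param order Markov order, one of 0, 1, 2, 3.
#' @param pseudocount Added to every transition count; default 0 (pure ML fit
#'   from the sequence itself). Use a small positive value for short contigs
#'   with unseen contexts.
#' @return An object of class `markov_background`: list with `order`,
#'   `initial_distribution` (length 4^order, lexicographic contexts),
#'   `transitions` (4^order x 4 row-stochastic matrix), `source_length`.
#' @examples
#' bg <- fit_markov("ACACAC", order = 1)
#' bg$transitions["A", "C"] # == 1
#' @export
fit_markov <- function(sequence, order, pseudocount = 0) {
  stopifnot(length(sequence) == 1L, order %in% 0:3, pseudocount >= 0)
  L <- nchar(sequence)
  if (L <= order) stop("sequence of length ", L,
                       " too short for Markov order ", order)
  dna <- Biostrings::BString(toupper(sequence))
  m <- as.integer(order)
  if (m == 0L) {
    base_counts <- word_frequency(dna, 1L)
    tot <- sum(base_counts) + 4 * pseudocount
    if (tot == 0) stop("sequence has no unambiguous bases")
    trans <- matrix((base_counts + pseudocount) / tot, nrow = 1,
                    dimnames = list("", BASES))
    init <- setNames(1, "")
  } else {
    pair_counts <- word_frequency(dna, m + 1L)
    trans_counts <- matrix(pair_counts, ncol = 4, byrow = TRUE,
                           dimnames = list(all_words(m), BASES))
    denom <- rowSums(trans_counts) + 4 * pseudocount
    trans <- (trans_counts + pseudocount) / ifelse(denom > 0, denom, 1)
    trans[denom == 0, ] <- 0.25 # unseen contexts: uninformative row
    ctx_counts <- word_frequency(dna, m)
    if (sum(ctx_counts) == 0) stop("no unambiguous length-", m, " windows")
    init <- ctx_counts / sum(ctx_counts)
  }
  structure(list(order = m, initial_distribution = init, transitions = trans,
                 source_length = L),
            class = "markov_background")
}

#' @export
print.markov_background <- function(x, ...) {
  cat("Markov background, order", x$order, "fitted on a length-",
      x$source_length, "sequence\n")
  invisible(x)
}

# overlapping k-mer counts over the ACGT alphabet; ambiguity windows are
# implicitly skipped because they match no ACGT word
word_frequency <- function(dna, k) {
  Biostrings::oligonucleotideFrequency(Biostrings::DNAString(as.character(dna)),
                                       width = k)
}

all_words <- function(k) {
  if (k == 0L) return("")
  do.call(paste0, rev(lapply(seq_len(k) - 1L, function(j)
    rep(rep(BASES, each = 4^j), length.out = 4^k))))
}

word_to_bases <- function(word) {
  idx <- match(strsplit(toupper(word), "")[[1]], BASES)
  if (anyNA(idx)) stop("word '", word, "' contains non-ACGT symbols")
  idx
}

# lexicographic index (1-based) of the sub-word bases[from..to]
word_index <- function(bases, from, to) {
  if (to < from) return(1L)
  sum((bases[from:to] - 1L) * 4^((to - from):0)) + 1L
}

#' Probability of a word under a Markov background
#'
#' For a word longer than the model order m, the probability is the initial
#' m-mer probability of its prefix times the chained transition
#' probabilities; for a word of length k < m it is the marginal of the
#' initial distribution over all m-mers starting with the word. Over all 4^k
#' words the probabilities sum to 1.
#'
#' @param bg A `markov_background`.
#' @param word A word over A/C/G/T.
#' @return The probability of observing `word` at a position in equilibrium
#'   with the empirical initial distribution.
#' @export
word_probability <- function(bg, word) {
  b <- word_to_bases(word)
  k <- length(b)
  m <- bg$order
  if (k <= m) {
    p <- all_word_probabilities(bg, k)
    return(unname(p[word_index(b, 1L, k)]))
  }
  p <- if (m == 0L) 1 else unname(bg$initial_distribution[word_index(b, 1L, m)])
  for (i in seq(m + 1L, k)) {
    ctx <- if (m == 0L) 1L else word_index(b, i - m, i - 1L)
    p <- p * bg$transitions[ctx, b[i]]
  }
  unname(p)
}

# vector of probabilities for all 4^k words, lexicographic order
all_word_probabilities <- function(bg, k) {
  m <- bg$order
  if (k < m) {
    marg <- rowSums(matrix(bg$initial_distribution, nrow = 4^k, byrow = TRUE))
    return(setNames(marg, all_words(k)))
  }
  p <- unname(bg$initial_distribution) # length 4^m (or 1 for m = 0)
  if (k > m) {
    for (i in seq(m + 1L, k)) {
      nprefix <- length(p)
      ctx <- if (m == 0L) rep(1L, nprefix) else
        ((seq_len(nprefix) - 1L) %% 4^m) + 1L
      p <- rep(p, each = 4) *
        bg$transitions[cbind(rep(ctx, each = 4), rep(1:4, nprefix))]
    }
  }
  setNames(p, all_words(k))
}

#' Expected count of a word in a background-generated sequence
#'
#' `E(N_w) = (L - k + 1) * p(w)`: every one of the L-k+1 windows carries the
#' same marginal word probability because the chain starts from the empirical
#' context distribution of the source sequence (see the methods vignette for
#' the position-marginal subtlety that enters the variance, not the mean).
#' The variant `expected_counts_all` returns the full 4^k vector.
#'
#' @param bg A `markov_background`.
#' @param word A word over A/C/G/T (or `k` for the vectorized variant).
#' @param L Length of the hypothetical sequence.
#' @return Expected occurrence count (possibly overlapping occurrences).
#' @export
expected_count <- function(bg, word, L) {
  k <- nchar(word)
  if (L < k) stop("L < word length")
  # marginal at position i uses the position-i context distribution; summing
  # the exact position marginals equals (L-k+1)*p(w) only when the initial
  # distribution is the chain's own empirical one, which is stationary to
  # first order -- we use the exact per-position form for consistency with
  # count_sd
  mom <- word_count_moments(bg, word, L)
  mom$expectation
}

#' @rdname expected_count
#' @param k Word length for the vectorized form.
#' @export
expected_counts_all <- function(bg, k, L) {
  if (L < k) stop("L < k")
  (L - k + 1) * all_word_probabilities(bg, k)
}

#' Standard deviation of a word count under a Markov background
#'
#' Exact standard deviation of the number of (possibly overlapping)
#' occurrences of `word` in a length-`L` sequence generated by `bg`, started
#' from its empirical initial context distribution. The variance is the full
#' indicator-sum expansion: per-position Bernoulli variances, lag-d < k
#' covariances through the word's self-overlap structure (joint probability =
#' transition product along the overlapped extension), and lag-d >= k
#' covariances through d-step context transition powers. The geometric tail
#' of the transition powers is truncated only at machine precision.
#'
#' @inheritParams expected_count
#' @param method `"exact"` (default) or `"poisson"` (returns `sqrt(E(N_w))`,
#'   a cross-check approximation).
#' @return The standard deviation of `N_w`.
#' @examples
#' bg <- fit_markov(paste(rep("ACGT", 50), collapse = ""), order = 0)
#' count_sd(bg, "A", 100) # binomial special case: sqrt(L p (1-p))
#' @export
count_sd <- function(bg, word, L, method = c("exact", "poisson")) {
  method <- match.arg(method)
  if (method == "poisson") {
    return(sqrt((L - nchar(word) + 1) * word_probability(bg, word)))
  }
  word_count_moments(bg, word, L)$sd
}

# Exact first two moments of N_w for one word. Returns list(expectation, sd).
# shared: optional precomputation from moment_context(bg, L) reused across
# words of the same length grid.
word_count_moments <- function(bg, word, L, shared = NULL) {
  b <- word_to_bases(word)
  k <- length(b)
  m <- bg$order
  if (L < k) stop("L < word length")
  if (k < max(m, 1L)) stop("count_sd requires word length >= max(order, 1)")
  n <- L - k + 1L
  tw <- trans_product(bg, b)

  if (m == 0L) {
    p <- tw
    E <- n * p
    V <- n * p * (1 - p)
    for (d in seq_len(min(k - 1L, n - 1L))) {
      joint <- if (self_overlap(b, d))
        trans_product(bg, c(b[seq_len(d)], b)) else 0
      V <- V + 2 * (n - d) * (joint - p^2)
    }
    return(list(expectation = E, sd = sqrt(max(V, 0))))
  }

  if (is.null(shared)) shared <- moment_context(bg, L)
  cs <- word_index(b, 1L, m)
  ce <- word_index(b, k - m + 1L, k)
  q <- shared$Q[seq_len(n), cs] # P(context at i == word prefix)
  p <- q * tw
  E <- sum(p)
  V <- sum(p * (1 - p))
  for (d in seq_len(min(k - 1L, n - 1L))) {
    i1 <- seq_len(n - d)
    cross <- tw^2 * sum(q[i1] * q[i1 + d])
    joint <- if (self_overlap(b, d))
      trans_product(bg, c(b[seq_len(d)], b)) * sum(q[i1]) else 0
    V <- V + 2 * (joint - cross)
  }
  if (n > k) {
    nf <- n - k # number of start positions with at least one far partner
    a <- power_entries(shared, ce, cs, m, nf) # a[r] = [P^(m+r-1)]_{ce,cs}
    cumA <- cumsum(a)
    i1 <- seq_len(nf)
    S1 <- sum(q[i1] * cumA[nf - i1 + 1L])
    qtail <- rev(cumsum(rev(q))) # qtail[j] = sum_{j' >= j} q[j']
    S2 <- sum(q[i1] * qtail[i1 + k])
    V <- V + 2 * tw^2 * (S1 - S2)
  }
  list(expectation = E, sd = sqrt(max(V, 0)))
}

# product of transition probabilities along bases b (positions m+1..len)
trans_product <- function(bg, b) {
  m <- bg$order
  len <- length(b)
  if (len <= m) return(1)
  t <- 1
  for (i in seq(m + 1L, len)) {
    ctx <- if (m == 0L) 1L else word_index(b, i - m, i - 1L)
    t <- t * bg$transitions[ctx, b[i]]
  }
  t
}

self_overlap <- function(b, d) {
  k <- length(b)
  identical(b[seq(d + 1L, k)], b[seq_len(k - d)])
}

# Precomputation shared across words for one (bg, L):
#   Q: (L - m + 1) x 4^m matrix of per-position context marginals
#   P: 4^m x 4^m one-step context transition matrix
#   pow: environment caching powers of P until numerical convergence
moment_context <- function(bg, L) {
  m <- bg$order
  nctx <- 4^m
  P <- matrix(0, nctx, nctx)
  for (c0 in seq_len(nctx)) {
    for (bb in 1:4) {
      c1 <- ((c0 - 1L) %% 4^(m - 1L)) * 4L + bb
      P[c0, c1] <- P[c0, c1] + bg$transitions[c0, bb]
    }
  }
  npos <- L - m + 1L
  Q <- matrix(0, npos, nctx)
  Q[1L, ] <- unname(bg$initial_distribution)
  if (npos > 1L) {
    for (i in seq(2L, npos)) Q[i, ] <- Q[i - 1L, , drop = FALSE] %*% P
  }
  env <- new.env(parent = emptyenv())
  env$powers <- list(P) # powers[[g]] = P^g
  env$converged_at <- NA_integer_
  list(Q = Q, P = P, pow = env, nctx = nctx)
}

# a[r] = [P^(m + r - 1)]_{ce, cs} for r = 1..nf, using cached powers and
# stopping power computation once successive powers agree to machine
# precision (fast-mixing chains converge in a few dozen steps)
power_entries <- function(shared, ce, cs, m, nf) {
  env <- shared$pow
  gmax <- m + nf - 1L
  have <- length(env$powers)
  while (have < gmax && is.na(env$converged_at)) {
    nxt <- env$powers[[have]] %*% shared$P
    if (max(abs(nxt - env$powers[[have]])) < 1e-15) {
      env$converged_at <- have
      break
    }
    env$powers[[have + 1L]] <- nxt
    have <- have + 1L
  }
  lim <- if (is.na(env$converged_at)) gmax else min(env$converged_at, gmax)
  gs <- pmin(seq(m, gmax), lim)
  vapply(gs, function(g) env$powers[[g]][ce, cs], numeric(1))
}
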