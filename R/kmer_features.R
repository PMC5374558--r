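#' Count overlapping k-mers in a DNA sequence
#'
#' Counts forward-strand occurrences of every word of length `k` over the
#' A/C/G/T alphabet, in lexicographic order (A < C < G < T). Windows that
#' contain any non-ACGT symbol (ambiguity codes) are skipped and excluded
#' from `n_windows`. With `canonical = TRUE` reverse-complement counts are
#' added (off by default: forward-only is the documented convention).
#'
#' @param sequence DNA string.
#' @param k Word length, >= 1.
#' @param canonical Also count reverse-complement occurrences.
#' @return An object of class `kmer_counts`: list with `k`, `counts` (named
#'   integer vector of length 4^k), `n_windows` (valid windows), `L`
#'   (sequence length).
#' @examples
#' count_kmers("ACGT", 2)$counts[c("AC", "CG", "GT")]
#' @export
count_kmers <- function(sequence, k, canonical = FALSE) {
  stopifnot(length(sequence) == 1L, k >= 1L)
  L <- nchar(sequence)
  if (k > L) stop("k = ", k, " exceeds sequence length ", L)
  dna <- Biostrings::DNAString(toupper(sequence))
  counts <- Biostrings::oligonucleotideFrequency(dna, width = k)
  if (canonical) {
    counts <- counts +
      Biostrings::oligonucleotideFrequency(Biostrings::reverseComplement(dna),
                                           width = k)
  }
  structure(list(k = as.integer(k), counts = counts,
                 n_windows = sum(counts), L = L),
            class = "kmer_counts")
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat("k-mer counts: k =", x$k, ", L =", x$L, ",", x$n_windows,
      "valid windows,", sum(x$counts > 0), "distinct words\n")
  invisible(x)
}

#' Compute one of the four word-frequency feature vectors
#'
#' The four representations of a sequence's word usage:
#' \describe{
#'   \item{F1}{relative frequency `N_w / n_windows` (no background needed);}
#'   \item{F2}{`(N_w - E) / E`, the CVtree-style normalization;}
#'   \item{F3}{`(N_w - E) / sqrt(E)`, the d2*-style normalization;}
#'   \item{F4}{`(N_w - E) / sigma(N_w)`, exact-variance normalization.}
#' }
#' `E(N_w)` and `sigma(N_w)` come from the per-sequence Markov background
#' `bg`. Entries with `E = 0` (F2, F3) or `sigma = 0` (F4) are set to 0: under
#' the background the observed count is then almost surely 0 as well, and the
#' convention avoids infinities in sparse high-k regimes.
#'
#' @param counts A `kmer_counts` object.
#' @param bg A `markov_background` (required for F2-F4; ignored for F1).
#' @param kind One of `"F1"`, `"F2"`, `"F3"`, `"F4"`.
#' @return An object of class `feature_vector`: list with `kind`, `k`,
#'   `values` (named numeric, length 4^k), `background_order` (NULL for F1).
#' @export
compute_feature <- function(counts, bg = NULL, kind = c("F1", "F2", "F3", "F4")) {
  kind <- match.arg(kind)
  stopifnot(inherits(counts, "kmer_counts"))
  N <- as.numeric(counts$counts)
  if (kind == "F1") {
    vals <- if (counts$n_windows > 0) N / counts$n_windows else N
    return(new_feature_vector(kind, counts$k, setNames(vals, names(counts$counts)),
                              NULL))
  }
  if (is.null(bg)) stop(kind, " requires a Markov background model")
  stopifnot(inherits(bg, "markov_background"))
  E <- unname(expected_counts_all(bg, counts$k, counts$L))
  vals <- switch(kind,
    F2 = ifelse(E > 0, (N - E) / E, 0),
    F3 = ifelse(E > 0, (N - E) / sqrt(E), 0),
    F4 = {
      sds <- all_count_sds(bg, counts$k, counts$L)
      ifelse(sds > 0, (N - E) / sds, 0)
    })
  new_feature_vector(kind, counts$k, setNames(vals, names(counts$counts)),
                     bg$order)
}

new_feature_vector <- function(kind, k, values, background_order) {
  structure(list(kind = kind, k = as.integer(k), values = values,
                 background_order = background_order),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("feature vector", x$kind, ": k =", x$k,
      if (!is.null(x$background_order))
        paste0("(background order ", x$background_order, ")"), "\n")
  invisible(x)
}

# sigma(N_w) for all 4^k words, sharing the per-position context marginals
# and transition powers across words
all_count_sds <- function(bg, k, L) {
  shared <- if (bg$order > 0) moment_context(bg, L) else NULL
  vapply(all_words(k),
         function(w) word_count_moments(bg, w, L, shared = shared)$sd,
         numeric(1), USE.NAMES = FALSE)
}

#' Feature matrix for a set of genome records
#'
#' Computes the chosen feature vector for every record and stacks them into a
#' numeric matrix (rows = records, columns = the 4^k words). For F2-F4 a
#' background of order `order` is fitted to each sequence individually.
#' The feature recipe is attached as the `"recipe"` attribute so that models
#' trained on one recipe refuse to score another.
#'
#' @param records Data frame with `id` and `sequence` columns.
#' @param kind Feature kind, `"F1"` to `"F4"`.
#' @param k Word length.
#' @param order Background Markov order (F2-F4 only).
#' @param pseudocount Pseudocount for the per-sequence background fits.
#' @return Numeric matrix with row names = record ids.
#' @export
feature_matrix <- function(records, kind = "F1", k = 6, order = NULL,
                           pseudocount = 0) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  kind <- match.arg(kind, c("F1", "F2", "F3", "F4"))
  if (kind == "F1") {
    set <- Biostrings::DNAStringSet(toupper(records$sequence))
    counts <- Biostrings::oligonucleotideFrequency(set, width = k)
    nw <- rowSums(counts)
    mat <- counts / ifelse(nw > 0, nw, 1)
  } else {
    if (is.null(order)) stop("feature ", kind, " requires a background order")
    mat <- t(vapply(records$sequence, function(s) {
      bg <- fit_markov(s, order = order, pseudocount = pseudocount)
      compute_feature(count_kmers(s, k), bg, kind)$values
    }, numeric(4^k), USE.NAMES = FALSE))
    colnames(mat) <- all_words(k)
  }
  rownames(mat) <- records$id
  attr(mat, "recipe") <- feature_recipe(kind, k, order)
  mat
}

feature_recipe <- function(kind, k, order = NULL) {
  list(kind = kind, k = as.integer(k),
       order = if (kind == "F1") NULL else as.integer(order))
}

#' Write a feature matrix to TSV
#'
#' One row per record: id then the 4^k values, with a header row of words.
#'
#' @param mat Matrix from [feature_matrix()].
#' @param path Output path.
#' @export
write_feature_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
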