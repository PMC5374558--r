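#' Manhattan distance between feature vectors
#'
#' L1 distance between two word-frequency vectors of the same word length:
#' the classical alignment-free baseline for phage-host matching.
#'
#' @param u,v `feature_vector` objects or plain numeric vectors of equal
#'   length.
#' @return Non-negative distance.
#' @export
manhattan <- function(u, v) {
  u <- feature_values(u)
  v <- feature_values(v)
  if (length(u) != length(v)) stop("feature vectors differ in length (",
                                   length(u), " vs ", length(v), ")")
  sum(abs(u - v))
}

#' d2*-type dissimilarity between background-normalized feature vectors
#'
#' The uncentered (cosine) correlation of two F3-type vectors, mapped to a
#' dissimilarity in \[0, 1\] via `(1 - cos) / 2`: 0 for identical direction,
#' 0.5 for orthogonal vectors, 1 for anti-correlated ones. Both vectors must
#' share word length and background order. Set `value = "correlation"` for
#' the raw cosine.
#'
#' @param a,b `feature_vector` objects (kind F3) or numeric vectors.
#' @param value `"dissimilarity"` (default) or `"correlation"`.
#' @return Dissimilarity in \[0, 1\] (or raw correlation in \[-1, 1\]).
#' @export
d2star_dissimilarity <- function(a, b, value = c("dissimilarity", "correlation")) {
  value <- match.arg(value)
  if (inherits(a, "feature_vector") && inherits(b, "feature_vector")) {
    if (a$k != b$k) stop("word lengths differ")
    if (!identical(a$background_order, b$background_order))
      stop("background orders differ")
  }
  a <- feature_values(a)
  b <- feature_values(b)
  if (length(a) != length(b)) stop("feature vectors differ in length")
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("uncentered correlation undefined for a zero vector")
  cosab <- sum(a * b) / (na * nb)
  cosab <- max(-1, min(1, cosab))
  if (value == "correlation") cosab else (1 - cosab) / 2
}

feature_values <- function(x) {
  if (inherits(x, "feature_vector")) unname(x$values) else as.numeric(x)
}

#' Average dissimilarity of a query to a reference set
#'
#' The baseline classifier score: the mean (or minimum) dissimilarity between
#' a query sequence's feature vector and those of the known infectious
#' viruses of a host. Lower scores mean the query looks more like the
#' positives, i.e. is predicted infectious at smaller thresholds.
#'
#' @param query A `feature_vector` or numeric vector.
#' @param references Non-empty list of feature vectors, or a numeric matrix
#'   with one reference per row.
#' @param measure `"manhattan"` or `"d2star"`.
#' @param agg Aggregation over references: `"mean"` (default) or `"min"`.
#' @return The aggregated dissimilarity.
#' @export
avg_distance_score <- function(query, references,
                               measure = c("manhattan", "d2star"),
                               agg = c("mean", "min")) {
  measure <- match.arg(measure)
  agg <- match.arg(agg)
  refs <- as_reference_list(references)
  if (length(refs) == 0L) stop("reference set is empty")
  f <- if (measure == "manhattan") manhattan else d2star_dissimilarity
  d <- vapply(refs, function(r) f(query, r), numeric(1))
  if (agg == "mean") mean(d) else min(d)
}

as_reference_list <- function(references) {
  if (is.matrix(references)) {
    lapply(seq_len(nrow(references)), function(i) references[i, ])
  } else if (inherits(references, "feature_vector")) {
    list(references)
  } else {
    as.list(references)
  }
}

#' AUC of the average-dissimilarity baseline
#'
#' Scores every positive and negative query by minus its average
#' dissimilarity to the reference (positive-training) set, so that higher
#' scores mean "more infectious", then computes the rank AUC. Sweeping a
#' dissimilarity threshold traces the same ROC, so this equals the
#' threshold-sweep AUC exactly.
#'
#' @param pos_queries,neg_queries Lists of feature vectors or matrices (one
#'   query per row).
#' @param references Reference feature vectors (list or matrix).
#' @param measure `"manhattan"` or `"d2star"`.
#' @param agg Aggregation passed to [avg_distance_score()].
#' @return AUC in \[0, 1\].
#' @export
dissimilarity_auc <- function(pos_queries, neg_queries, references,
                              measure = c("manhattan", "d2star"),
                              agg = c("mean", "min")) {
  measure <- match.arg(measure)
  agg <- match.arg(agg)
  pos <- as_reference_list(pos_queries)
  neg <- as_reference_list(neg_queries)
  if (length(pos) == 0L || length(neg) == 0L) stop("empty query set")
  score <- function(qs) -vapply(qs, avg_distance_score, numeric(1),
                                references = references, measure = measure,
                                agg = agg)
  auc(score(pos), score(neg))
}

#' Pairwise dissimilarity matrix
#'
#' Square symmetric matrix of Manhattan or d2* dissimilarities between all
#' rows of a feature matrix.
#'
#' @param mat Feature matrix (rows = sequences).
#' @param measure `"manhattan"` or `"d2star"`.
#' @return Symmetric matrix with the row names of `mat`.
#' @export
pairwise_dissimilarity <- function(mat, measure = c("manhattan", "d2star")) {
  measure <- match.arg(measure)
  if (measure == "manhattan") {
    d <- as.matrix(dist(mat, method = "manhattan"))
  } else {
    n <- nrow(mat)
    d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j > i) d[i, j] <- d2star_dissimilarity(mat[i, ], mat[j, ])
      }
    }
    d <- d + t(d)
  }
  d
}

#' @importFrom stats dist
NULL
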