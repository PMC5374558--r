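#' Base-2 entropy of a composition
#'
#' Shannon entropy `H = -sum p_i log2 p_i` of a vector of category counts
#' (with `0 log 0 := 0`), e.g. the distribution of a host's viruses over the
#' Caudovirales families. Bounded by `log2(#nonzero categories)`, attained at
#' uniformity.
#'
#' @param counts Non-negative counts, at least one positive.
#' @return Entropy in bits.
#' @examples
#' entropy_base2(c(21, 8, 27, 3))
#' @export
entropy_base2 <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("all counts are zero")
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

#' Spearman rank correlation
#'
#' Classical Spearman rho: the Pearson correlation of midranks (equal to
#' `1 - 6 sum(d^2) / (n (n^2 - 1))` when there are no ties). Optionally
#' returns a p-value via `stats::cor.test` (exact for small tie-free
#' samples).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param p_value If `TRUE`, return a list with `rho` and `p_value`.
#' @return The correlation, or a list when `p_value = TRUE`.
#' @export
spearman <- function(x, y, p_value = FALSE) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector: rank correlation undefined")
  rho <- cor(x, y, method = "spearman")
  if (!p_value) return(rho)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = rho, p_value = ct$p.value)
}

#' Average pairwise distance within a group
#'
#' Mean dissimilarity over all `n (n - 1) / 2` unordered pairs of feature
#' vectors — the within-host spread statistic that explains part of the
#' cross-genus variation in classifier performance.
#'
#' @param features Numeric matrix (rows = sequences) or list of
#'   `feature_vector`s.
#' @param measure `"manhattan"` or `"d2star"`.
#' @return The mean pairwise dissimilarity.
#' @export
avg_within_group_distance <- function(features,
                                      measure = c("manhattan", "d2star")) {
  measure <- match.arg(measure)
  if (!is.matrix(features)) {
    features <- do.call(rbind, lapply(as_reference_list(features),
                                      feature_values))
  }
  if (nrow(features) < 2L) stop("need at least 2 feature vectors")
  if (measure == "manhattan") {
    mean(dist(features, method = "manhattan"))
  } else {
    d <- pairwise_dissimilarity(features, "d2star")
    mean(d[lower.tri(d)])
  }
}

#' Bundled benchmark summary tables for nine bacterial host genera
#'
#' Loads the package's reference tables for the nine host genera with at
#' least 45 known infecting viruses: per-genus AUC of the random forest +
#' relative-frequency classifier at word lengths 4/6/8, average within-genus
#' Manhattan distances at the same word lengths, and the composition of each
#' genus's viruses over the major Caudovirales families with the reported
#' entropy column. These drive the worked examples correlating classifier
#' performance with within-genus sequence spread and family-composition
#' entropy.
#'
#' @return List of data frames `auc`, `manhattan`, `family_counts`.
#' @export
host_benchmark_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "phagehost",
                                  mustWork = TRUE)
  list(auc = read.delim(path("host_genus_auc.tsv"), stringsAsFactors = FALSE),
       manhattan = read.delim(path("host_genus_manhattan.tsv"),
                              stringsAsFactors = FALSE),
       family_counts = read.delim(path("host_genus_family_counts.tsv"),
                                  stringsAsFactors = FALSE))
}
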