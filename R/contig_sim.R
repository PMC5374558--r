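#' Fragment a sequence into fixed-length non-overlapping contigs
#'
#' Cuts a genome into `floor(L / length)` consecutive contigs of exactly
#' `length` bases, covering positions `[0, length)`, `[length, 2*length)`,
#' ...; the trailing remainder shorter than `length` is discarded, so every
#' returned contig has the advertised length. Coordinates are 0-based
#' half-open. A genome shorter than `length` yields zero contigs.
#'
#' @param sequence DNA string.
#' @param length Contig length in bases, or `"whole"` for the intact
#'   sequence.
#' @return Data frame with columns `start`, `end`, `sequence`.
#' @export
fragment <- function(sequence, length) {
  L <- nchar(sequence)
  if (identical(length, "whole")) {
    return(data.frame(start = 0L, end = L, sequence = sequence,
                      stringsAsFactors = FALSE))
  }
  length <- as.integer(length)
  stopifnot(length >= 1L)
  n <- L %/% length
  if (n == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  start <- (seq_len(n) - 1L) * length
  data.frame(start = start, end = start + length,
             sequence = substring(sequence, start + 1L, start + length),
             stringsAsFactors = FALSE)
}

#' Inject uniform substitution errors into a sequence
#'
#' Each A/C/G/T position independently mutates with probability `rate` to one
#' of the other three bases with equal probability (the sequencing-error
#' model used in the contig experiments; the protocol default is 0.05%).
#' Ambiguity codes are left untouched; length is preserved.
#'
#' @param sequence DNA string.
#' @param rate Per-base substitution probability in \[0, 1\].
#' @param seed Optional seed for reproducible error patterns.
#' @return The mutated sequence.
#' @export
inject_errors <- function(sequence, rate = 5e-4, seed = NULL) {
  if (rate < 0 || rate > 1) stop("error rate must be in [0, 1]")
  if (rate == 0) return(sequence)
  run <- function() {
    chars <- strsplit(sequence, "")[[1]]
    base_idx <- match(chars, BASES)
    hit <- which(!is.na(base_idx) & runif(length(chars)) < rate)
    if (length(hit)) {
      shift <- sample.int(3L, length(hit), replace = TRUE)
      chars[hit] <- BASES[((base_idx[hit] - 1L + shift) %% 4L) + 1L]
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else with_preserved_seed({ set.seed(seed); run() })
}

#' Fragment a set of records into labeled contigs
#'
#' Applies [fragment()] to every record and optionally [inject_errors()] to
#' every contig. Contigs inherit their parent's metadata (host genus, year,
#' family); contig ids are `{parent}|{start}-{end}` and a `parent` column
#' records the lineage. With `length = "whole"` and `error_rate = 0` the
#' records pass through unchanged apart from the added `parent` column.
#'
#' @param records Data frame of genome records.
#' @param length Contig length or `"whole"`.
#' @param error_rate Substitution rate applied to each contig.
#' @param seed Seed for the error injection.
#' @return Data frame of contig records with a `parent` column.
#' @export
fragment_records <- function(records, length = "whole", error_rate = 0,
                             seed = NULL) {
  seeds <- if (error_rate > 0)
    derive_seeds(seed %||% 1L, nrow(records)) else NULL
  pieces <- lapply(seq_len(nrow(records)), function(i) {
    fr <- fragment(records$sequence[i], length)
    if (nrow(fr) == 0L) return(NULL)
    seqs <- fr$sequence
    if (error_rate > 0) {
      sub_seeds <- with_preserved_seed({
        set.seed(seeds[i])
        sample.int(2147483646L, nrow(fr))
      })
      seqs <- vapply(seq_len(nrow(fr)), function(j)
        inject_errors(seqs[j], error_rate, seed = sub_seeds[j]), character(1))
    }
    out <- data.frame(
      id = if (identical(length, "whole")) records$id[i] else
        paste0(records$id[i], "|", fr$start, "-", fr$end),
      sequence = seqs, parent = records$id[i], stringsAsFactors = FALSE)
    for (col in intersect(c("host_genus", "year", "family"), names(records)))
      out[[col]] <- records[[col]][i]
    out
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) stop("no contigs produced: all sequences shorter than ",
                         length)
  rownames(out) <- NULL
  out
}

#' Cross-length training/testing AUC grid
#'
#' The contig-length robustness experiment: for every (training length,
#' testing length) pair, both the training and testing halves of the
#' partition are fragmented at their respective lengths (with substitution
#' errors applied to the contigs, including the whole-genome class), a model
#' is trained on the training contigs and evaluated on the testing contigs,
#' and the mean AUC over negative resamples fills the cell. Negatives are
#' drawn at the genome level before fragmentation, so no genome's contigs
#' leak between training and testing. With `train_lengths = test_lengths =
#' "whole"` and `error_rate = 0` the single cell reproduces
#' [evaluate_host()] exactly under the same seed.
#'
#' @param records Data frame of genome records.
#' @param partition A `host_partition`.
#' @param train_lengths,test_lengths Vectors over `{1000, 3000, 5000,
#'   "whole"}` (any integer lengths are accepted).
#' @param kind,k,order Feature recipe.
#' @param learner A [learner_spec()].
#' @param repeats Negative resamples per cell.
#' @param seed Master seed (shared across cells for paired comparison).
#' @param error_rate Per-base substitution rate (protocol default 0.05%).
#' @return List with `auc` (matrix train_lengths x test_lengths of mean
#'   AUCs) and `results` (the full `evaluation_result` per cell).
#' @export
cross_length_evaluation <- function(records, partition,
                                    train_lengths = c(1000, 3000, 5000, "whole"),
                                    test_lengths = train_lengths,
                                    kind = "F1", k = 6, order = NULL,
                                    learner = learner_spec("random_forest"),
                                    repeats = 50, seed = 1,
                                    error_rate = 5e-4) {
  lab <- function(x) ifelse(x == "whole", "whole", paste0(x, "bp"))
  frag_seeds <- derive_seeds(seed + 2L, length(unique(c(train_lengths,
                                                        test_lengths))))
  lengths_all <- unique(c(train_lengths, test_lengths))
  frag_sets <- lapply(seq_along(lengths_all), function(i) {
    contigs <- fragment_records(records, lengths_all[i],
                                error_rate = error_rate,
                                seed = frag_seeds[i])
    feats <- feature_matrix(contigs, kind = kind, k = k, order = order)
    list(features = feats, parent = contigs$parent)
  })
  names(frag_sets) <- as.character(lengths_all)
  aucmat <- matrix(NA_real_, length(train_lengths), length(test_lengths),
                   dimnames = list(paste0("train_", lab(train_lengths)),
                                   paste0("test_", lab(test_lengths))))
  results <- list()
  for (i in seq_along(train_lengths)) {
    for (j in seq_along(test_lengths)) {
      tr <- frag_sets[[as.character(train_lengths[i])]]
      te <- frag_sets[[as.character(test_lengths[j])]]
      res <- evaluate_core(tr$features, tr$parent, te$features, te$parent,
                           partition, learner, repeats, seed,
                           recipe = attr(tr$features, "recipe"))
      aucmat[i, j] <- res$mean_auc
      results[[paste(rownames(aucmat)[i], colnames(aucmat)[j], sep = "/")]] <- res
    }
  }
  list(auc = aucmat, results = results)
}
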