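#' Draw a random Markov background model
#'
#' Generates a random but valid order-m chain: each transition row is
#' Dirichlet-distributed (independent gammas, normalized), and the initial
#' context distribution is the chain's stationary distribution (by power
#' iteration), so generated sequences are homogeneous from the first base.
#' Used as a pseudo-host "genome style" for the synthetic benchmark.
#'
#' @param seed Seed making the model reproducible.
#' @param order Markov order in 0..3.
#' @param concentration Dirichlet concentration of the rows (1 = uniform
#'   simplex; smaller = spikier, more distinctive word usage).
#' @return A `markov_background`.
#' @export
make_host_generator <- function(seed, order = 1, concentration = 1) {
  stopifnot(order %in% 0:3)
  trans <- with_preserved_seed({
    set.seed(seed)
    nctx <- 4^order
    g <- matrix(stats::rgamma(nctx * 4, shape = concentration), nrow = nctx)
    g / rowSums(g)
  })
  rownames(trans) <- all_words(order)
  colnames(trans) <- BASES
  background_from_transitions(trans, order)
}

# assemble a markov_background with stationary initial distribution
background_from_transitions <- function(trans, order) {
  if (order == 0L) {
    init <- setNames(1, "")
    rownames(trans) <- ""
  } else {
    bg_tmp <- structure(list(order = order, transitions = trans,
                             initial_distribution = NULL),
                        class = "markov_background")
    P <- context_step_matrix(trans, order)
    v <- rep(1 / nrow(P), nrow(P))
    for (i in 1:500) {
      v2 <- as.numeric(v %*% P)
      if (max(abs(v2 - v)) < 1e-14) { v <- v2; break }
      v <- v2
    }
    init <- setNames(v / sum(v), all_words(order))
  }
  structure(list(order = as.integer(order), initial_distribution = init,
                 transitions = trans, source_length = NA_integer_),
            class = "markov_background")
}

context_step_matrix <- function(trans, order) {
  nctx <- 4^order
  P <- matrix(0, nctx, nctx)
  for (c0 in seq_len(nctx)) {
    for (b in 1:4) {
      c1 <- ((c0 - 1L) %% 4^(order - 1L)) * 4L + b
      P[c0, c1] <- P[c0, c1] + trans[c0, b]
    }
  }
  P
}

#' Generate a sequence from a Markov background
#'
#' Samples the initial context from the model's initial distribution, then
#' extends base by base with the transition matrix (compiled code; draws from
#' R's RNG, so `seed` / `set.seed()` govern it).
#'
#' @param bg A `markov_background`.
#' @param length Sequence length (> order).
#' @param seed Optional seed.
#' @return A DNA string.
#' @export
generate_genome <- function(bg, length, seed = NULL) {
  stopifnot(inherits(bg, "markov_background"), length > bg$order)
  run <- function() {
    b <- mc_simulate_bases(cumsum(unname(bg$initial_distribution)),
                           t(apply(bg$transitions, 1, cumsum)),
                           bg$order, as.integer(length))
    paste(BASES[b + 1L], collapse = "")
  }
  if (is.null(seed)) run() else with_preserved_seed({ set.seed(seed); run() })
}

#' Generate a labeled synthetic phage-host benchmark
#'
#' Builds a fully reproducible dataset with controllable class separation:
#' each pseudo-host gets its own random Markov model, blended row-wise with a
#' shared model by the `divergence` weight (`0` = every host shares one
#' generator, so hosts are statistically indistinguishable; `1` = fully
#' host-specific word usage). Genomes are sampled from the blended models;
#' metadata assigns the host genus, a uniform random discovery year in
#' `year_range`, and cycling family labels. This emulates the premise that
#' viruses of one host share word-pattern usage; it does not mimic real phage
#' genome architecture.
#'
#' @param n_hosts Number of pseudo-hosts.
#' @param genomes_per_host Genomes per host.
#' @param genome_length Genome length in bases (default 20 kb).
#' @param order Markov order of the generators.
#' @param divergence Class-separation knob in \[0, 1\].
#' @param year_range Integer `c(min, max)` for discovery years.
#' @param seed Master seed; all randomness flows from it.
#' @param dir If non-NULL, write `benchmark.fa` and `benchmark.tsv` there.
#' @param concentration Dirichlet concentration of generator rows.
#' @return List with `records` (data frame with sequence + metadata),
#'   `fasta`, `metadata` (paths or NULL).
#' @export
make_benchmark <- function(n_hosts = 3, genomes_per_host = 40,
                           genome_length = 20000, order = 1, divergence = 1,
                           year_range = c(2005, 2015), seed = 1, dir = NULL,
                           concentration = 1) {
  stopifnot(n_hosts >= 1, genomes_per_host >= 1, divergence >= 0,
            divergence <= 1)
  seeds <- derive_seeds(seed, n_hosts + 2L)
  shared <- make_host_generator(seeds[n_hosts + 1L], order = order,
                                concentration = concentration)
  families <- c("Myoviridae", "Podoviridae", "Siphoviridae", "other")
  hosts <- sprintf("Host%02d", seq_len(n_hosts))
  records <- with_preserved_seed({
    set.seed(seeds[n_hosts + 2L])
    pieces <- lapply(seq_len(n_hosts), function(h) {
      own <- make_host_generator(seeds[h], order = order,
                                 concentration = concentration)
      blended <- background_from_transitions(
        divergence * own$transitions + (1 - divergence) * shared$transitions,
        order)
      data.frame(
        id = sprintf("%s_v%03d", hosts[h], seq_len(genomes_per_host)),
        sequence = vapply(seq_len(genomes_per_host), function(i)
          generate_genome(blended, genome_length), character(1)),
        host_genus = hosts[h],
        year = sample(seq(year_range[1], year_range[2]), genomes_per_host,
                      replace = TRUE),
        family = rep(families, length.out = genomes_per_host),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, pieces)
  })
  rownames(records) <- NULL
  fasta <- meta <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fasta <- file.path(dir, "benchmark.fa")
    meta <- file.path(dir, "benchmark.tsv")
    write_fasta(records, fasta)
    write.table(records[, c("id", "host_genus", "year", "family")], meta,
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(records = records, fasta = fasta, metadata = meta)
}
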