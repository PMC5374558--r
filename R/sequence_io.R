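#' Read viral sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file into a data frame
#' of genome records. The record id is the header token before the first
#' whitespace; the full header is kept as the description. Sequences are
#' upper-cased on ingest and validated against the IUPAC nucleotide alphabet;
#' ambiguity codes (N, R, Y, ...) are retained and handled downstream by the
#' k-mer counters.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `sequence`, `description`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">v1 a phage", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (any(ids == "")) stop("FASTA entry with empty id in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  bad <- regexpr(sprintf("[^%s]", IUPAC_CHARS), seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid character '%s' in record '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for record '", ids[which(nchar(seqs) == 0L)[1L]], "'")
  }
  data.frame(id = ids, sequence = unname(seqs), description = headers,
             stringsAsFactors = FALSE, row.names = NULL)
}

IUPAC_CHARS <- "ACGTNRYSWKMBDHV"

#' Write genome records to a FASTA file
#'
#' Round-trips with [read_fasta()]: ids and sequences are preserved exactly.
#'
#' @param records Data frame with columns `id` and `sequence` (and optionally
#'   `description`, used as the header).
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  headers <- if ("description" %in% names(records) &&
                 !anyNA(records$description)) records$description else records$id
  set <- Biostrings::BStringSet(setNames(records$sequence, headers))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a virus metadata table
#'
#' Reads a tab-separated table with header columns `id`, `host_genus`, `year`
#' and `family`. Empty cells become `NA` ("absent"). `year`, when present,
#' must be a 4-digit integer (the discovery year driving the cutting-year
#' partition).
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `id`, `host_genus`, `year` (integer),
#'   `family`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = NULL)
  required <- c("id", "host_genus", "year", "family")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$id)) {
    stop("duplicate metadata ids: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  blank <- function(x) ifelse(trimws(x) == "", NA_character_, x)
  year_chr <- blank(tab$year)
  bad_year <- !is.na(year_chr) & !grepl("^[0-9]{4}$", year_chr)
  if (any(bad_year)) {
    stop("non-integer year for id(s): ",
         paste(tab$id[bad_year], collapse = ", "))
  }
  data.frame(id = tab$id,
             host_genus = blank(tab$host_genus),
             year = as.integer(year_chr),
             family = blank(tab$family),
             stringsAsFactors = FALSE)
}

#' Attach metadata to genome records
#'
#' Left-joins a metadata table (see [read_metadata()]) onto FASTA records by
#' `id`; records without metadata get `NA` fields.
#'
#' @param records Data frame from [read_fasta()].
#' @param metadata Data frame from [read_metadata()].
#' @return The records with `host_genus`, `year`, `family` columns added.
#' @export
add_metadata <- function(records, metadata) {
  idx <- match(records$id, metadata$id)
  records$host_genus <- metadata$host_genus[idx]
  records$year <- metadata$year[idx]
  records$family <- metadata$family[idx]
  records
}

#' Partition records by host genus and cutting year
#'
#' Splits a dated dataset for one host genus into the three pools used by the
#' evaluation protocol: positives discovered up to the cutting year (training),
#' positives discovered after it (testing), and all viruses not identified to
#' infect the host (negative pool, including viruses with unknown hosts).
#' "Identified before the cutting year" is implemented inclusively
#' (`year <= cutting_year`); set `inclusive = FALSE` for the strict reading.
#'
#' @param records Data frame with `id`, `host_genus`, `year` columns.
#' @param host Host genus name.
#' @param cutting_year Integer year splitting positives into train/test.
#' @param allow_empty_train If `FALSE` (default), an empty positive training
#'   set is an error; if `TRUE`, it is a warning.
#' @param inclusive Whether positives with `year == cutting_year` train.
#' @return An object of class `host_partition` with elements `host_genus`,
#'   `cutting_year`, `positive_train`, `positive_test`, `negative_pool`
#'   (character vectors of ids).
#' @export
partition_by_cutting_year <- function(records, host, cutting_year,
                                      allow_empty_train = FALSE,
                                      inclusive = TRUE) {
  stopifnot(is.data.frame(records), all(c("id", "host_genus", "year") %in%
                                          names(records)))
  is_pos_host <- !is.na(records$host_genus) & records$host_genus == host
  if (!any(is_pos_host)) stop("no viruses with host genus '", host, "'")
  undated <- is_pos_host & is.na(records$year)
  if (any(undated)) {
    warning(sum(undated), " record(s) for host '", host,
            "' lack a discovery year and are excluded from the partition")
  }
  pos <- records[is_pos_host & !is.na(records$year), , drop = FALSE]
  in_train <- if (inclusive) pos$year <= cutting_year else pos$year < cutting_year
  positive_train <- pos$id[in_train]
  positive_test <- pos$id[!in_train]
  if (length(positive_train) == 0L) {
    msg <- paste0("no positive training viruses for host '", host,
                  "' at cutting year ", cutting_year)
    if (allow_empty_train) warning(msg) else stop(msg)
  }
  structure(list(host_genus = host,
                 cutting_year = as.integer(cutting_year),
                 positive_train = positive_train,
                 positive_test = positive_test,
                 negative_pool = records$id[!is_pos_host]),
            class = "host_partition")
}

#' @export
print.host_partition <- function(x, ...) {
  cat("Host partition for genus '", x$host_genus, "' (cutting year ",
      x$cutting_year, ")\n", sep = "")
  cat("  positive train:", length(x$positive_train), "viruses\n")
  cat("  positive test: ", length(x$positive_test), "viruses\n")
  cat("  negative pool: ", length(x$negative_pool), "viruses\n")
  invisible(x)
}

#' Save or load a host partition as JSON
#'
#' @param partition A `host_partition`.
#' @param path Output / input path.
#' @return `write_partition_json` returns `path` invisibly;
#'   `read_partition_json` returns a `host_partition`.
#' @export
write_partition_json <- function(partition, path) {
  jsonlite::write_json(unclass(partition), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_partition_json
#' @export
read_partition_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$positive_train <- as.character(obj$positive_train)
  obj$positive_test <- as.character(obj$positive_test)
  obj$negative_pool <- as.character(obj$negative_pool)
  structure(obj, class = "host_partition")
}
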