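test_that("FASTA reading normalizes case, keeps order, and round-trips", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">v1 first phage", "acgt", ">v2", "AACC", "GGTT"), fa)
  rec <- read_fasta(fa)
  expect_equal(rec$id, c("v1", "v2"))
  expect_equal(rec$sequence, c("ACGT", "AACCGGTT"))
  expect_equal(rec$description[1], "v1 first phage")

  # round trip is bit-exact on ids and sequences, wrapped or not
  out <- tempfile(fileext = ".fa")
  write_fasta(rec, out, width = 5)
  rec2 <- read_fasta(out)
  expect_identical(rec2$id, rec$id)
  expect_identical(rec2$sequence, rec$sequence)
})

test_that("FASTA errors name the offending record and position", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">v1", "ACGX"), fa)
  expect_error(read_fasta(fa), "v1.*position 4|'X'")

  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">v1", "ACGT", ">v1", "AAAA"), fa2)
  expect_error(read_fasta(fa2), "duplicate")

  fa3 <- tempfile(fileext = ".fa")
  file.create(fa3)
  expect_error(read_fasta(fa3), "empty")

  # ambiguity codes are legal and retained
  fa4 <- tempfile(fileext = ".fa")
  writeLines(c(">v1", "ACNRT"), fa4)
  expect_equal(read_fasta(fa4)$sequence, "ACNRT")
})

test_that("metadata parsing handles absent fields and rejects bad input", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("id\thost_genus\tyear\tfamily",
               "v1\tBacillus\t2010\tSiphoviridae",
               "v2\t\t\t"), tsv)
  meta <- read_metadata(tsv)
  expect_equal(meta$host_genus, c("Bacillus", NA))
  expect_equal(meta$year, c(2010L, NA))
  expect_equal(meta$family, c("Siphoviridae", NA))

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("id\thost_genus\tyear\tfamily",
               "v1\tA\t2010\t", "v1\tB\t2011\t"), dup)
  expect_error(read_metadata(dup), "duplicate")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("id\thost_genus\tyear\tfamily", "v1\tA\t20x0\t"), bad)
  expect_error(read_metadata(bad), "year")

  mis <- tempfile(fileext = ".tsv")
  writeLines(c("id\thost_genus", "v1\tA"), mis)
  expect_error(read_metadata(mis), "year")
})

test_that("cutting-year partition implements the inclusive boundary", {
  rec <- data.frame(id = c("a", "b", "c"), host_genus = "hostX",
                    year = c(2010L, 2012L, 2014L),
                    stringsAsFactors = FALSE)
  p <- partition_by_cutting_year(rec, "hostX", 2012)
  expect_setequal(p$positive_train, c("a", "b"))
  expect_equal(p$positive_test, "c")
  p2 <- partition_by_cutting_year(rec, "hostX", 2012, inclusive = FALSE)
  expect_equal(p2$positive_train, "a")
})

test_that("six-record partition puts every record in exactly one bucket", {
  rec <- toy_records()
  rec$host_genus[6] <- "hostZ" # fully resolvable metadata
  p <- partition_by_cutting_year(rec, "hostX", 2011)
  expect_setequal(p$positive_train, c("v1", "v2"))
  expect_equal(p$positive_test, "v3")
  expect_setequal(p$negative_pool, c("v4", "v5", "v6"))
  expect_length(intersect(p$negative_pool,
                          c(p$positive_train, p$positive_test)), 0)
  expect_equal(length(p$positive_train) + length(p$positive_test) +
                 length(p$negative_pool), nrow(rec))
  # deterministic
  expect_identical(p, partition_by_cutting_year(rec, "hostX", 2011))
})

test_that("degenerate partitions error or warn as configured", {
  rec <- data.frame(id = c("a", "b"), host_genus = "hostX",
                    year = c(2015L, 2016L), stringsAsFactors = FALSE)
  expect_error(partition_by_cutting_year(rec, "hostX", 2010),
               "no positive training")
  expect_warning(partition_by_cutting_year(rec, "hostX", 2010,
                                           allow_empty_train = TRUE),
                 "no positive training")
  expect_error(partition_by_cutting_year(rec, "hostQ", 2010), "hostQ")
  # same-host record without a year is dropped with a warning
  rec2 <- rbind(rec, data.frame(id = "c", host_genus = "hostX", year = NA))
  expect_warning(partition_by_cutting_year(rec2, "hostX", 2015),
                 "lack a discovery year")
})

test_that("partition JSON round-trips through files", {
  rec <- toy_records()
  p <- partition_by_cutting_year(rec, "hostX", 2011)
  f <- tempfile(fileext = ".json")
  write_partition_json(p, f)
  p2 <- read_partition_json(f)
  expect_equal(p2$positive_train, p$positive_train)
  expect_equal(p2$negative_pool, p$negative_pool)
  expect_equal(p2$cutting_year, p$cutting_year)
})
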