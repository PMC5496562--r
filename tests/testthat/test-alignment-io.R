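test_that("a minimal well-formed FASTA is read as an aligned set", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp1 some description", "ACGT", ">sp2", "ACGA"), f)
  a <- read_aligned_fasta(f)
  expect_s3_class(a, "aligned_set")
  expect_equal(dim(a), c(2L, 4L))
  expect_equal(a$labels, c("sp1", "sp2"))
  expect_equal(unname(a$matrix[1, ]), c("A", "C", "G", "T"))
})

test_that("symbols are upper-cased and U is mapped to T on read", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acgu", ">b", "ACGT"), f)
  a <- read_aligned_fasta(f)
  expect_equal(unname(a$matrix[1, ]), c("A", "C", "G", "T"))
})

test_that("malformed input is rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGTA"), f)
  expect_error(read_aligned_fasta(f), "not aligned")
  writeLines(c(">a", "ACGT", ">a", "ACGA"), f)
  expect_error(read_aligned_fasta(f), "[Dd]uplicate")
  writeLines(character(0), f)
  expect_error(read_aligned_fasta(f))
  expect_error(read_aligned_fasta(file.path(tempdir(), "nope.fa")),
               "not found")
  expect_error(aligned_set("only_one", matrix("A", 1, 4)), "at least 2")
  expect_error(aligned_set(c("a", "b"), c("AXGT", "ACGT")), "symbols")
})

test_that("write then read round-trips labels and matrix", {
  a <- figure3_fixture()
  f <- withr::local_tempfile(fileext = ".fasta")
  write_aligned_fasta(a, f)
  b <- read_aligned_fasta(f)
  expect_equal(b$labels, a$labels)
  expect_equal(b$matrix, a$matrix)
})

test_that("long sequences are wrapped at 60 columns on write", {
  set.seed(1)
  a <- random_panel(3, 150, seed = 5)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_aligned_fasta(a, f)
  lines <- readLines(f)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  expect_equal(read_aligned_fasta(f)$matrix, a$matrix)
})

test_that("trimming removes exactly the terminal-gap columns", {
  a <- aligned_set(c("x", "y"), c("--ACG", "TTACG"))
  t <- trim_common_region(a)
  expect_equal(dim(t), c(2L, 3L))
  expect_equal(unname(t$matrix[1, ]), c("A", "C", "G"))
  expect_equal(t$origin_offset, 2L)
})

test_that("disjoint sequence spans have no common region", {
  a <- aligned_set(c("x", "y"), c("AA---", "---TT"))
  expect_error(trim_common_region(a), "no common region")
})

test_that("trimming the staggered-ends fixture yields the known inner block", {
  a <- protruding_ends_fixture()
  t <- trim_common_region(a)
  expect_equal(t$origin_offset, 3L)
  expect_equal(ncol(t$matrix), 8L)
  expect_equal(apply(t$matrix, 1, paste, collapse = ""),
               c(S1 = "CAGTACGA", S2 = "CAGCACGA",
                 S3 = "CAGAACGT", S4 = "CAGTTCGT"))
  # no row begins or ends with a gap after trimming
  expect_false(any(t$matrix[, 1] == "-" | t$matrix[, ncol(t$matrix)] == "-"))
})

test_that("trimming is idempotent and bounded by the shortest span", {
  a <- protruding_ends_fixture()
  t1 <- trim_common_region(a)
  t2 <- trim_common_region(t1)
  expect_equal(t2$matrix, t1$matrix)
  expect_equal(t2$origin_offset, t1$origin_offset)
  spans <- apply(a$matrix != "-", 1, sum)
  expect_lte(ncol(t1$matrix), min(spans))
})

test_that("internal gaps survive trimming and only exclude their column", {
  a <- aligned_set(c("x", "y", "z"), c("-ACG-TA-", "GAC-GTAT", "GACGGTAC"))
  t <- trim_common_region(a)
  expect_equal(t$origin_offset, 1L)
  expect_equal(ncol(t$matrix), 6L)          # columns 2..7
  expect_true("-" %in% t$matrix)            # internal gap kept
  d <- nucleotide_distribution(t)
  expect_equal(d$excluded, c(3L, 4L))       # the internally gapped columns
})
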