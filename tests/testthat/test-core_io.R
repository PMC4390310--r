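test_that("sample table validation catches duplicates and label errors", {
  expect_s3_class(
    sample_table(c("a", "b", "c"), c("A1", "A2", "A3"),
                 c("OL", "RL", "DMM")),
    "sample_table")
  expect_error(
    sample_table(c("a", "a"), c("A1", "A2"), c("OL", "OL")),
    "duplicate individual")
  expect_error(
    sample_table(c("a", "b"), c("A1", "A2"), c("OL", "XX")),
    "unknown population")
  expect_error(
    sample_table(c("a", "b"), c("A1", "A1"), c("OL", "RL")),
    "more than one population")
})

test_that("sample metadata round-trips through TSV", {
  s <- sample_table(c("a", "b", "c"), c("A1", "A1", "A2"),
                    c("RL", "RL", "DMM"), control = c(FALSE, FALSE, TRUE))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_samples(s, f)
  s2 <- read_samples(f)
  expect_equal(s2$individual, s$individual)
  expect_equal(s2$accession, s$accession)
  expect_equal(s2$control, s$control)
})

test_that("dominant matrix rejects out-of-alphabet cells with coordinates", {
  m <- matrix(c(1L, 0L, -9L, 1L), 2, 2,
              dimnames = list(c("a", "b"), c("L1", "L2")))
  dm <- dominant_matrix(m)
  expect_identical(unclass(dm)[1, ], c(L1 = 1L, L2 = -9L))
  m[2, 1] <- 2L
  expect_error(dominant_matrix(m), "row 2.*col 1")
})

test_that("dominant matrix round-trips and realigns to the sample table", {
  set.seed(1)
  m <- matrix(sample(c(0L, 1L, -9L), 200, replace = TRUE,
                     prob = c(.45, .45, .1)), 10, 20)
  rownames(m) <- sprintf("I%02d", 1:10)
  colnames(m) <- sprintf("L%02d", 1:20)
  samp <- sample_table(rev(rownames(m)), rev(rownames(m)),
                       rep("OL", 10))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dominant_matrix(dominant_matrix(m), f)
  dm <- read_dominant_matrix(f, samp)
  expect_identical(rownames(dm), samp$individual)  # realigned
  expect_identical(unclass(dm)[rownames(m), ], m)  # values intact
  # unknown / missing individuals are rejected
  expect_error(read_dominant_matrix(f, samp[1:5, ]), "not in sample table")
})

test_that("codominant genotypes are stored unordered and both dialects agree", {
  samp <- sample_table(c("i1", "i2"), c("a1", "a2"), c("OL", "OL"))
  two_row <- withr::local_tempfile(fileext = ".str")
  writeLines(c("S1\tS2",
               "i1\t101\t-9", "i1\t103\t-9",
               "i2\t103\t101", "i2\t101\t101"), two_row)
  m <- read_codominant_matrix(two_row, samp, "two-row-structure")
  expect_equal(unname(m$a1["i1", ]), c(101L, -9L))
  expect_equal(unname(m$a2["i1", ]), c(103L, -9L))
  # (a,b) and (b,a) are the same stored value
  expect_equal(unname(m$a1["i2", "S1"]), 101L)
  expect_equal(unname(m$a2["i2", "S1"]), 103L)

  one_row <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("S1\tS2", "i1\t101/103\t-9", "i2\t103/101\t101/101"),
             one_row)
  m2 <- read_codominant_matrix(one_row, samp, "one-row-paired")
  expect_identical(m$a1, m2$a1)
  expect_identical(m$a2, m2$a2)
})

test_that("two-row dialect rejects an odd number of rows per individual", {
  samp <- sample_table("i1", "a1", "OL")
  f <- withr::local_tempfile()
  writeLines(c("S1", "i1\t101"), f)
  expect_error(read_codominant_matrix(f, samp), "odd number of rows")
})

test_that("codominant write/read round-trips in both dialects", {
  set.seed(7)
  n <- 10; L <- 20
  a1 <- matrix(sample(100:110, n * L, TRUE), n, L)
  a2 <- matrix(sample(100:110, n * L, TRUE), n, L)
  miss <- matrix(runif(n * L) < 0.1, n, L)
  a1[miss] <- a2[miss] <- -9L
  rownames(a1) <- rownames(a2) <- sprintf("I%02d", 1:n)
  samp <- sample_table(rownames(a1), rownames(a1), rep("RL", n))
  m <- codominant_matrix(a1, a2)
  for (dialect in c("two-row-structure", "one-row-paired")) {
    f <- withr::local_tempfile()
    write_codominant_matrix(m, f, dialect)
    m2 <- read_codominant_matrix(f, samp, dialect)
    expect_identical(m$a1, m2$a1, info = dialect)
    expect_identical(m$a2, m2$a2, info = dialect)
  }
})

test_that("half-missing genotype cells are rejected", {
  expect_error(codominant_matrix(matrix(-9L), matrix(5L)), "half-missing")
})

test_that("genotype_dataset enforces aligned rows and one matrix minimum", {
  samp <- sample_table(c("a", "b"), c("A", "B"), c("OL", "OL"))
  expect_error(genotype_dataset(samp), "at least one marker matrix")
  m <- dominant_matrix(matrix(c(1L, 0L), 2, 1,
                              dimnames = list(c("b", "a"), "L1")))
  expect_error(genotype_dataset(samp, dominant = m), "do not match")
})
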