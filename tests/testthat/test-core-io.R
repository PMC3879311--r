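test_that("plain expression tables parse into validated matrices", {
  v <- matrix(c(1, 0, 3.5, 2, 9, 0, 4, 7, 0, 1, 2, 3), nrow = 3,
              dimnames = list(c("l1", "l2", "l3"),
                              c("lung", "brain", "liver", "heart")))
  f <- writeExprFixture(v)
  suppressMessages(m <- readExpressionTable(f))
  expect_s4_class(m, "ExpressionMatrix")
  expect_equal(entityIds(m), c("l1", "l2", "l3"))
  expect_equal(conditionLabels(m), c("lung", "brain", "liver", "heart"))
  expect_equal(unname(expressionValues(m)), unname(v))
})

test_that("expression table validation produces named hard errors", {
  v <- matrix(1:8, 2, 4, dimnames = list(c("dup", "dup"), letters[1:4]))
  f <- writeExprFixture(v)
  expect_error(suppressMessages(readExpressionTable(f)), "dup")

  neg <- matrix(c(1, -2, 3, 4), 2, 2,
                dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(suppressMessages(readExpressionTable(writeExprFixture(neg))),
               "negative.*'b'.*'x'")

  bad <- data.frame(entity_id = "a", x = "oops", y = 1)
  fb <- tempfile(fileext = ".tsv")
  write.table(bad, fb, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(suppressMessages(readExpressionTable(fb)), "non-numeric")

  empty <- tempfile(fileext = ".tsv")
  writeLines("entity_id\tc1\tc2", empty)
  expect_error(suppressMessages(readExpressionTable(empty)), "empty")
})

test_that("bedlike layout is keyed by name and carries position annotation", {
  scores <- matrix(round(runif(3 * 22, 0, 1000)), 3, 22,
                   dimnames = list(NULL, sprintf("tissue%02d", 1:22)))
  df <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                   start = c(100L, 500L, 40L), end = c(300L, 900L, 90L),
                   name = c("TCONS_1", "TCONS_2", "TCONS_3"),
                   scores, check.names = FALSE)
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  suppressMessages(m <- readExpressionTable(f, layout = "bedlike",
                                            saturationValue = 1000))
  expect_equal(entityIds(m), c("TCONS_1", "TCONS_2", "TCONS_3"))
  expect_length(conditionLabels(m), 22L)
  rd <- as.data.frame(SummarizedExperiment::rowData(m))
  expect_equal(rd$start, c(100L, 500L, 40L))
  expect_equal(S4Vectors::metadata(m)$saturation_value, 1000)
  # a file without the BED columns cannot claim the bedlike layout
  v <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(suppressMessages(
    readExpressionTable(writeExprFixture(v), layout = "bedlike")),
    "chrom")
})

test_that("condition label normalization happens at read time and is idempotent", {
  v <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c(" Lung ", "BRAIN")))
  f <- writeExprFixture(v)
  suppressMessages(m <- readExpressionTable(f))
  expect_equal(conditionLabels(m), c("lung", "brain"))
  expect_equal(normalizeConditionLabels(normalizeConditionLabels(c(" Lung ", "BRAIN"))),
               normalizeConditionLabels(c(" Lung ", "BRAIN")))
})

test_that("expression write/read round-trip is identity on content", {
  v <- matrix(c(0, 5, 1000, 2, 7, 3), 2, 3,
              dimnames = list(c("l1", "l2"), c("t1", "t2", "t3")))
  m <- ExpressionMatrix(v)
  f <- tempfile(fileext = ".tsv")
  writeExpressionTable(m, f)
  suppressMessages(m2 <- readExpressionTable(f))
  expect_identical(expressionValues(m2), expressionValues(m))
  expect_identical(entityIds(m2), entityIds(m))
  expect_identical(conditionLabels(m2), conditionLabels(m))
})

test_that("gene-disease tables deduplicate and index by disease", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("g1\tD1", "g2\tD1", "g1\tD2", "g3\tD2", "g1\tD2"), f)
  expect_message(gd <- readGeneDiseaseTable(f), "deduplicated 1")
  expect_equal(nrow(associationPairs(gd)), 4L)
  expect_setequal(diseaseGenes(gd)[["D1"]], c("g1", "g2"))
  expect_setequal(diseaseGenes(gd)[["D2"]], c("g1", "g3"))

  fh <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tdisease_id", "g1\tD1"), fh)
  suppressMessages(gdh <- readGeneDiseaseTable(fh))
  expect_equal(associationPairs(gdh)$gene_id, "g1")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("g1\tD1", "justonecolumn"), bad)
  expect_error(suppressMessages(readGeneDiseaseTable(bad)),
               "fewer than 2 columns")
  emptyf <- tempfile(fileext = ".tsv")
  writeLines(character(0), emptyf)
  expect_error(suppressMessages(readGeneDiseaseTable(emptyf)), "empty")
})

test_that("association sets load, deduplicate and round-trip", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("L1\tD1", "L2\tD1", "L1\tD2", "L1\tD2"), f)
  expect_message(as1 <- readAssociationSet(f), "deduplicated 1")
  expect_equal(nrow(associationPairs(as1)), 3L)
  f2 <- tempfile(fileext = ".tsv")
  writeAssociationSet(as1, f2)
  suppressMessages(as2 <- readAssociationSet(f2))
  expect_identical(associationPairs(as2), associationPairs(as1))
})

test_that("prediction tables write with the documented schema and round-trip", {
  res <- data.frame(lncrna_id = c("L1", "L2"), disease_id = c("D2", "D1"),
                    n = c(10L, 3L), x = c(4L, 7L), y = c(2L, 1L),
                    p_raw = c(0.001, 0.2), p_bonferroni = c(0.01, 1),
                    q_fdr = c(0.005, 0.04), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  writePredictions(res, f)
  header <- strsplit(readLines(f, n = 1L), "\t")[[1L]]
  expect_identical(header, c("lncRNA", "disease", "n", "x", "y",
                             "p_raw", "p_bonferroni", "q_fdr"))
  back <- readPredictions(f)
  expect_equal(back, res)

  fe <- tempfile(fileext = ".tsv")
  writePredictions(res[0, ], fe)
  expect_identical(length(readLines(fe)), 1L)
  expect_equal(nrow(readPredictions(fe)), 0L)
})
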