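toy_matrix <- function() {
  v <- matrix(c(1.5, 2.25, NA,
                0.125, -3.5, 4,
                NA, NA, 7.75), nrow = 3, byrow = TRUE,
              dimnames = list(c("TP53", "BRCA1", "EGFR"),
                              c("S1", "S2", "S3")))
  expression_matrix(v, c("tumor", "tumor", "healthy"))
}

test_that("matrix TSV reading counts missing cells and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pGene\tS1\tS2", "TP53\t1.5\tNA", "BRCA1\t2\t3"), path)
  m <- read_expression_matrix(path)
  expect_equal(sum(is.na(m$values)), 1)
  expect_equal(dim(m$values), c(2, 2))

  # write(read(x)) == x bit-exactly, including awkward floating values
  m0 <- toy_matrix()
  m0$values[1, 1] <- 1 / 3
  m0$values[2, 2] <- exp(1) * 1e-7
  out <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m0, out)
  m1 <- read_expression_matrix(out)
  expect_identical(m1$values, m0$values)
})

test_that("malformed matrices are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pGene\tS1", "TP53\t1", "TP53\t2"), path)
  expect_error(read_expression_matrix(path), "TP53")
  writeLines(c("pGene\tS1\tS2", "TP53\t1\tx17"), path)
  expect_error(read_expression_matrix(path), "S2")
  expect_error(expression_matrix(matrix(1, 1, 1)), "rownames")
})

test_that("missingness filter applies the sample-count rule literally", {
  # proteins with missing counts {0, 60, 61} in 111 samples, cap 60
  v <- matrix(rnorm(3 * 111), 3, 111,
              dimnames = list(c("A", "B", "C"), sprintf("S%03d", 1:111)))
  v["B", 1:60] <- NA
  v["C", 1:61] <- NA
  m <- expression_matrix(v)
  kept <- filter_pgenes_by_missingness(m, max_missing = 60)
  expect_identical(rownames(kept$values), c("A", "B"))
  # vacuous threshold is the identity
  all_kept <- filter_pgenes_by_missingness(m, max_missing = 111)
  expect_identical(all_kept$values, m$values)
  # fraction-based alternative
  frac <- filter_pgenes_by_missingness(m, max_missing_frac = 60 / 111)
  expect_identical(rownames(frac$values), c("A", "B"))
  # idempotent
  expect_identical(filter_pgenes_by_missingness(kept, 60)$values, kept$values)
})

test_that("flagged-sample removal drops exactly the named samples", {
  v <- matrix(rnorm(2 * 111), 2, 111,
              dimnames = list(c("A", "B"), sprintf("S%03d", 1:111)))
  m <- expression_matrix(v)
  expect_identical(drop_flagged_samples(m, character(0))$values, m$values)
  # a 111-sample study with 28 decay-flagged samples keeps 83
  m2 <- drop_flagged_samples(m, sprintf("S%03d", 1:28))
  expect_equal(ncol(m2$values), 83)
  expect_error(drop_flagged_samples(m, "sampleX"), "sampleX")
})

test_that("control-group completeness removes partially measured proteins", {
  v <- matrix(rnorm(4 * 6), 4, 6,
              dimnames = list(c("A", "B", "C", "D"), sprintf("S%d", 1:6)))
  grp <- c(rep("tumor", 3), rep("healthy", 3))
  # healthy-missing counts {0, 0, 1, 3}
  v["C", 4] <- NA
  v["D", 4:6] <- NA
  m <- expression_matrix(v, grp)
  kept <- require_complete_in_group(m, "healthy")
  expect_identical(rownames(kept$values), c("A", "B"))
  # complete matrix is untouched
  m0 <- expression_matrix(matrix(1:12, 2, 6,
                                 dimnames = list(c("X", "Y"),
                                                 sprintf("S%d", 1:6))) * 1.0,
                          grp)
  expect_identical(require_complete_in_group(m0, "healthy")$values, m0$values)
})

test_that("median imputation fills gaps without touching observed values", {
  v <- matrix(c(1, NA, 3,
                5, NA, NA,
                2, 2, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("S1", "S2", "S3")))
  v <- cbind(v, S4 = c(9, 5, 2))
  m <- impute_missing(expression_matrix(v))
  expect_equal(unname(m$values["A", ]), c(1, 3, 3, 9))  # median of {1,3,9}
  expect_equal(unname(m$values["B", ]), c(5, 5, 5, 5))
  expect_false(anyNA(m$values))
  # observed cells unchanged
  expect_identical(m$values[!is.na(v)], v[!is.na(v)])
  # all-missing row is an error
  v["A", ] <- NA
  expect_error(impute_missing(expression_matrix(v)), "A")
})

test_that("chromosome map keeps the first conflicting entry with a warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("TP53\t17", "G1\t1", "G1\t2", "brca1\t17"), path)
  expect_warning(cm <- read_chromosome_map(path), "G1")
  expect_identical(unname(cm["TP53"]), "17")
  expect_identical(unname(cm["G1"]), "1")
  expect_identical(unname(cm["BRCA1"]), "17")  # case-normalized
})

test_that("GMT parsing deduplicates members and flags malformed lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg2", "setB\tdesc\tg3\tg4"), path)
  sets <- read_gmt(path)
  expect_equal(length(sets$setA), 2)
  expect_setequal(sets$setA, c("G1", "G2"))
  writeLines(c("setA\tdesc\tg1", "broken\tonly-two-fields"), path)
  expect_error(read_gmt(path), "line 2")
  # round trip through the writer
  write_gmt(list(s1 = c("A", "B"), s2 = c("C", "D", "E")), path)
  expect_equal(lengths(read_gmt(path)), c(s1 = 2L, s2 = 3L))
})
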