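test_that("replicate aggregation: normalisation and combine rules", {
  m <- matrix(c(10, 20, 30), nrow = 1, dimnames = list("g1", NULL))
  expect_equal(aggregate_expression(m, normalization = "none"),
               c(g1 = 20))
  # CPM is the identity on a library of exactly one million reads
  lib <- matrix(c(10, 1e6 - 10), ncol = 1,
                dimnames = list(c("g1", "g2"), NULL))
  expect_equal(aggregate_expression(lib, normalization = "cpm")[["g1"]], 10)
  # mean and median coincide on two replicates
  two <- matrix(c(1, 100), nrow = 1, dimnames = list("g1", NULL))
  expect_equal(aggregate_expression(two, normalization = "none",
                                    combine = "mean")[["g1"]], 50.5)
  expect_equal(aggregate_expression(two, normalization = "none",
                                    combine = "median")[["g1"]], 50.5)
})

test_that("aggregation rejects bad input and strips gene versions", {
  expect_error(aggregate_expression(matrix(numeric(0), 0, 0)), "non-empty")
  neg <- matrix(-1, 1, 1, dimnames = list("g1", NULL))
  expect_error(aggregate_expression(neg), "negative")

  v <- matrix(c(5, 7), ncol = 1,
              dimnames = list(c("ENSG01.4", "ENSG01.7"), NULL))
  # two versioned rows of one gene collapse by summation
  expect_equal(aggregate_expression(v, normalization = "none"),
               c(ENSG01 = 12))
  expect_equal(names(aggregate_expression(v, normalization = "none",
                                          strip_versions = FALSE)),
               c("ENSG01.4", "ENSG01.7"))
})

test_that("featureCounts-style tables are read with annotation columns dropped", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# Program:featureCounts v2.0; Command: ...",
    paste("Geneid", "Chr", "Start", "End", "Strand", "Length",
          "s1.bam", "s2.bam", sep = "\t"),
    paste("gA", "1", "100", "200", "+", "101", "10", "14", sep = "\t"),
    paste("gB", "1", "300", "400", "-", "101", "0", "2", sep = "\t")
  ), f)
  m <- read_expression_table(f)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(rownames(m), c("gA", "gB"))
  expect_equal(unname(m["gA", ]), c(10, 14))
})

test_that("RAS profiles cover exactly the defined GPR reactions", {
  g <- toy_two_nutrient_gem()  # 3 GPR reactions
  em <- c(gT1 = 10, gT2 = 5, gT3 = 8, gG1 = 3, gG2 = 9)
  p <- compute_ras_profile(g, em, condition = "full")
  expect_s3_class(p, "ras_profile")
  expect_length(p$ras, 3L)
  expect_equal(p$coverage, 1)
  expect_equal(p$ras[["T_glc"]], 15)   # or -> sum
  expect_equal(p$ras[["GLYC"]], 3)     # and -> min

  # a reaction with no measured gene drops out under skip and counts
  # against coverage
  p2 <- compute_ras_profile(g, c(gT3 = 8), condition = "sparse")
  expect_length(p2$ras, 1L)
  expect_equal(p2$coverage, 1 / 3)

  # RAS 0 is a value, not an absence
  p3 <- compute_ras_profile(g, c(gT1 = 0, gT2 = 0, gT3 = 0, gG1 = 0,
                                 gG2 = 0))
  expect_equal(unname(p3$ras[c("T_glc", "T_gln")]), c(0, 0))
  expect_length(p3$ras, 3L)
})

test_that("a malformed GPR surfaces as an error naming the reaction", {
  g <- toy_chain_gem()
  g$reactions$gpr[2] <- "gA and or gB"
  expect_error(compute_ras_profile(g, c(gA = 1)), "R1")
})

test_that("RAS profiles survive a TSV round trip", {
  g <- toy_two_nutrient_gem()
  p <- compute_ras_profile(g, c(gT1 = 10, gT2 = 5, gT3 = 8, gG1 = 3,
                                gG2 = 9), condition = "c1")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ras_profile(p, f)
  p2 <- read_ras_profile(f, condition = "c1")
  expect_equal(p2$ras, p$ras)
})
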