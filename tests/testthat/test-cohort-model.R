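test_that("cohort round-trips through TSV files bit-for-bit", {
  set.seed(3)
  b <- toy_bundle()
  # perturb with irrational values to make exact round-trip non-trivial
  b$expression[1, ] <- b$expression[1, ] + pi * 1e-7
  b <- cohort_bundle(b$cancer_code, b$expression, b$annotations, b$clinical,
                     b$methylation)
  dir <- withr::local_tempdir()
  paths <- write_cohort(b, dir)
  b2 <- read_cohort(paths[["expression"]], paths[["annotations"]],
                    paths[["clinical"]], paths[["methylation"]])
  expect_identical(b2$expression, b$expression)
  expect_identical(b2$clinical$os_time, b$clinical$os_time)
  expect_identical(b2$methylation$beta, b$methylation$beta)
  expect_equal(b2$annotations, b$annotations)
  expect_identical(b2$cancer_code, b$cancer_code)
})

test_that("bundle without methylation writes no methylation file", {
  b <- toy_bundle(with_methylation = FALSE)
  dir <- withr::local_tempdir()
  paths <- write_cohort(b, dir)
  expect_false("methylation" %in% names(paths))
  expect_false(file.exists(file.path(dir, "methylation.tsv")))
  b2 <- read_cohort(paths[["expression"]], paths[["annotations"]],
                    paths[["clinical"]])
  expect_null(b2$methylation)
})

test_that("validation rejects malformed cohorts with informative errors", {
  b <- toy_bundle()
  bad_cl <- b$clinical; bad_cl$os_time[1] <- -1
  expect_error(cohort_bundle("TOY", b$expression, b$annotations, bad_cl),
               "os_time")
  bad_expr <- rbind(b$expression, GENEA = 1)
  expect_error(validate_expression_matrix(bad_expr), "GENEA")
  bad_beta <- b$methylation$beta; bad_beta[1, 1] <- 1.5
  expect_error(methylation_matrix(bad_beta, b$methylation$probe_info),
               "\\[0, 1\\]")
  bad_cl2 <- b$clinical; bad_cl2$sample_id[1] <- "UNKNOWN"
  expect_error(cohort_bundle("TOY", b$expression, b$annotations, bad_cl2),
               "UNKNOWN")
  bad_ann <- b$annotations; bad_ann$tissue_type[1] <- "organoid"
  expect_error(validate_annotations(bad_ann), "organoid")
  # duplicated gene symbol inside an expression file is named in the error
  dir <- withr::local_tempdir()
  paths <- write_cohort(b, dir)
  lines <- readLines(paths[["expression"]])
  writeLines(c(lines, lines[2]), paths[["expression"]])
  expect_error(read_cohort(paths[["expression"]], paths[["annotations"]],
                           paths[["clinical"]]), "GENEA")
})

test_that("empty expression matrix is refused on write", {
  b <- toy_bundle(with_methylation = FALSE)
  b$expression <- b$expression[, 0, drop = FALSE]
  expect_error(write_cohort(b, withr::local_tempdir()), "empty")
})

test_that("GMT parsing collapses duplicates and reports malformed lines", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SETA\tdesc\tG1\tG2\tG2", "SETB\tother\tG3"), f)
  gsc <- read_gmt(f)
  expect_identical(gsc$sets$SETA, c("G1", "G2"))
  expect_identical(gsc$sets$SETB, "G3")
  expect_identical(unname(gsc$descriptions["SETA"]), "desc")

  writeLines(character(), f)
  expect_length(read_gmt(f)$sets, 0L)

  writeLines(c("SETA\tdesc\tG1", "SETB\tdesc"), f)
  expect_error(read_gmt(f), "line 2")
  writeLines(c("SETA\tdesc\tG1", "SETA\tdesc\tG2"), f)
  expect_error(read_gmt(f), "duplicate")
})

test_that("reference-gene normalization divides per sample and drops zeros", {
  expr <- matrix(c(10, 6, 2,
                   5, 3, 0),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(c("G1", "REF"), c("A", "B", "C")))
  out <- normalize_to_reference_gene(expr, "REF")
  expect_equal(out["G1", "A"], 2)
  expect_equal(unname(out["REF", ]), c(1, 1))
  expect_identical(attr(out, "dropped_samples"), "C")
  expect_error(normalize_to_reference_gene(expr, "MISSING"), "MISSING")
  all_zero <- expr; all_zero["REF", ] <- 0
  expect_error(normalize_to_reference_gene(all_zero, "REF"), "all samples")
  # multiplying the reference row back restores the original on kept samples
  restored <- sweep(out, 2, expr["REF", colnames(out)], "*")
  expect_equal(restored, expr[, colnames(out)], ignore_attr = TRUE)
})

test_that("log2_plus_one matches its definition and rejects negatives", {
  expect_equal(log2_plus_one(0), 0)
  expect_equal(log2_plus_one(7), 3)
  expect_equal(log2_plus_one(c(1, 3)), c(1, 2))
  expect_error(log2_plus_one(-0.5), "non-negative")
})

test_that("correlation wrappers reproduce hand-derived values", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(6, 4, 2)), -1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_true(is.na(pearson_correlation(c(1, 1, 1), c(1, 2, 3))))
  # rho = 1 - 6*sum(d^2)/(n(n^2-1)) with d = (-2, 1, 1)
  expect_equal(spearman_correlation(c(1, 2, 3), c(3, 1, 2)), -0.5)
  expect_equal(spearman_correlation(c(1, 2, 3), c(10, 100, 1000)), 1)
  expect_error(pearson_correlation(c(1, 2), c(3, 4)), "3")
})

test_that("correlations agree with textbook oracles on random vectors", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(4:15, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(pearson_correlation(x, y), pearson_oracle(x, y),
                 tolerance = 1e-12)
    expect_equal(spearman_correlation(x, y), spearman_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(5)
  x <- rnorm(30); y <- rnorm(30)
  base <- spearman_correlation(x, y)
  for (f in list(exp, function(v) v^3, function(v) 10 * v + 2))
    expect_equal(spearman_correlation(x, f(y)), base)
})

test_that("correlations use pairwise-complete observations", {
  x <- c(1, 2, 3, 4, NA)
  y <- c(2, 4, 6, NA, 10)
  expect_equal(pearson_correlation(x, y), 1)
  expect_error(pearson_correlation(c(1, NA, NA, 4), c(1, 2, 3, NA)), "pairs")
})
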