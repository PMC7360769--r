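test_that("abundance_table validates entries and ids", {
  m <- matrix(c(1, 2, 3, 4), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  tab <- abundance_table(m)
  expect_s3_class(tab, "abundance_table")
  expect_identical(library_sizes(tab), c(s1 = 3, s2 = 7))

  m_neg <- m; m_neg[2, 1] <- -1
  expect_error(abundance_table(m_neg), "negative count.*'b'.*'s1'")

  expect_error(abundance_table(m, taxon_ids = c("OTU1", "OTU1")),
               "duplicate taxon id.*OTU1")
  expect_error(abundance_table(m, sample_ids = c("s", "s")),
               "duplicate sample id")
  m_na <- m; m_na[1, 1] <- NA
  expect_error(abundance_table(m_na), "missing or non-finite")
})

test_that("count tables round-trip through write+read bit-exactly", {
  tab <- toy_table(matrix(c(0L, 5L, 123L, 7L, 1L, 0L), nrow = 3))
  for (ext in c("tsv", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_counts(tab, path)
    back <- read_counts(path)
    expect_identical(unclass(back), unclass(tab))
  }
})

test_that("read_counts rejects malformed cells with locations", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\ts1\ts2", "OTU1\t3\t-1", "OTU2\t0\t2"), path)
  expect_error(read_counts(path), "negative count")

  writeLines(c("taxon\ts1\ts2", "OTU1\t3\t1.5", "OTU2\t0\t2"), path)
  expect_error(read_counts(path), "non-integer count.*'OTU1'.*'s2'")

  writeLines(c("taxon\ts1\ts2", "OTU1\t3\tx", "OTU2\t0\t2"), path)
  expect_error(read_counts(path), "non-numeric")

  writeLines(c("taxon\ts1\ts2", "OTU1\t3\t1", "OTU1\t0\t2"), path)
  expect_error(read_counts(path), "duplicate taxon id.*OTU1")
})

test_that("group_design and read_metadata parse groups and catch degeneracy", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tcountry", "s1\tMW", "s2\tMW", "s3\tMW",
               "s4\tVE", "s5\tVE"), path)
  gd <- read_metadata(path, "country")
  expect_identical(gd$group_labels, c("MW", "VE"))
  expect_identical(unname(gd$sizes), c(3L, 2L))
  expect_identical(gd$reference, "MW")

  expect_error(read_metadata(path, "nation"),
               "column 'nation' not found.*country")

  writeLines(c("sample\tcountry", "s1\tMW", "s2\tMW", "s3\tVE"), path)
  expect_error(read_metadata(path, "country"),
               "fewer than 2 samples.*variance")

  writeLines(c("sample\tcountry", "s1\tMW", "s2\tMW", "s3\tNA",
               "s4\tVE", "s5\tVE"), path)
  expect_warning(gd <- read_metadata(path, "country"), "dropping 1 sample")
  expect_identical(length(gd$assignment), 4L)
  expect_error(read_metadata(path, "country", na_action = "error"),
               "missing metadata.*s3")
})

test_that("align_samples intersects, errors on mismatch, and is idempotent", {
  tab <- toy_table(matrix(1:12, nrow = 3, dimnames = NULL),
                   samples = paste0("s", 1:4))
  gd <- toy_design(2, 2)
  al <- align_samples(tab, gd)
  expect_identical(colnames(al$table), names(al$design$assignment))

  # one extra table sample dropped under intersect, error under strict
  tab5 <- toy_table(matrix(1:15, nrow = 3), samples = paste0("s", 1:5))
  expect_message(al5 <- align_samples(tab5, gd), "dropping 1 table-only")
  expect_identical(ncol(al5$table), 4L)
  expect_error(align_samples(tab5, gd, policy = "strict"),
               "mismatch.*s5")

  # idempotence
  al2 <- align_samples(al5$table, al5$design)
  expect_identical(unclass(al2$table), unclass(al5$table))
  expect_identical(al2$design$assignment, al5$design$assignment)

  # disjoint ids
  tabx <- toy_table(matrix(1:6, nrow = 3), samples = c("x1", "x2"))
  expect_error(align_samples(tabx, gd), "no shared sample ids")
})

test_that("results round-trip through write+read to 12 significant digits", {
  set.seed(42)
  n <- 10
  res <- data.frame(
    taxon_id = paste0("t", 1:n),
    effect = rnorm(n), se = rexp(n), W = rnorm(n),
    p = runif(n), p_adj = runif(n), ci_lo = rnorm(n), ci_hi = rnorm(n),
    structural_zero_A = rep(FALSE, n), structural_zero_B = rep(FALSE, n),
    decided_by_structural_zero = rep(FALSE, n))
  res$W[3] <- NA  # structural-zero-decided convention
  res$decided_by_structural_zero[3] <- TRUE
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(res, path)
  back <- read_results(path)
  expect_identical(back$taxon_id, res$taxon_id)
  expect_true(is.na(back$W[3]))
  expect_true(back$decided_by_structural_zero[3])
  for (col in c("effect", "se", "p", "p_adj", "ci_lo", "ci_hi")) {
    expect_equal(back[[col]], res[[col]], tolerance = 1e-12)
  }

  # empty result set gives a header-only file
  write_results(res[0, ], path)
  expect_identical(length(readLines(path)), 1L)
  expect_identical(nrow(read_results(path)), 0L)
})

test_that("toy two-taxon specimens give the expected sampling fractions", {
  eco <- matrix(c(12, 6, 18, 9), nrow = 2,
                dimnames = list(c("red", "green"), c("A", "B")))
  obs <- matrix(c(4, 2, 4, 2), nrow = 2, dimnames = dimnames(eco))
  expect_identical(microbial_load(eco), c(A = 18, B = 27))
  expect_equal(sampling_fractions(obs, eco), c(A = 3 / 9, B = 2 / 9))
})
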