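test_that("CSV parsing respects descriptor kinds and the missing token", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,age,FVC,smoking_now,exercise",
               "a,61.5,3.20,no,often",
               "b,58.0,NA,yes,none",
               "c,not_a_number,4.1,no,daily"),
             path)
  tab <- read_cohort_table(path, demo_schema())
  expect_s3_class(tab, "cohort_table")
  expect_equal(nrow(tab$data), 3)
  expect_equal(tab$data$age, c(61.5, 58.0, NA))
  expect_true(is.na(tab$data$FVC[2]))      # missing token
  expect_true(is.na(tab$data$age[3]))      # unparseable continuous
  expect_equal(tab$data$exercise, c("often", "none", "daily"))
})

test_that("duplicate subject IDs and undeclared levels are hard errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,age,FVC,smoking_now,exercise",
               "a,61,3.2,no,often",
               "a,58,3.0,yes,none"),
             path)
  expect_error(read_cohort_table(path, demo_schema()), "duplicate subject ID: a")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,age,FVC,smoking_now,exercise",
               "a,61,3.2,no,often",
               "b,58,3.0,maybe,none"),
             path2)
  expect_error(read_cohort_table(path2, demo_schema()),
               "undeclared level 'maybe' in column 'smoking_now', row 2")

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,age", "a,61", "b,58"), path3)
  expect_error(read_cohort_table(path3, demo_schema()), "absent")
})

test_that("read-write-read round trip is the identity", {
  tab <- demo_table(8)
  tab$data$FVC[3] <- NA
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_table(tab, p1)
  r1 <- read_cohort_table(p1, demo_schema(), timepoint = "2018")
  write_cohort_table(r1, p2)
  r2 <- read_cohort_table(p2, demo_schema(), timepoint = "2018")
  expect_identical(r1$data, r2$data)
  expect_identical(readBin(p1, "raw", 1e6), readBin(p2, "raw", 1e6))
  expect_equal(r1$data$age, tab$data$age)
  expect_equal(r1$data$exercise, tab$data$exercise)
})

test_that("longitudinal pairing intersects IDs and filters required vars", {
  schema <- demo_schema()
  mk <- function(ids, tp, fvc = 3.5) {
    cohort_table(data.frame(subject_id = ids, age = 60, FVC = fvc,
                            smoking_now = "no", exercise = "none",
                            stringsAsFactors = FALSE),
                 schema, timepoint = tp)
  }
  base <- mk(c("a", "b", "c"), "2013")
  fol <- mk(c("b", "c", "d"), "2018")
  paired <- align_longitudinal_pairs(base, fol)
  expect_equal(paired$paired_ids, c("b", "c"))
  expect_equal(unname(paired$exclusions[["not_in_both"]]), 2)

  # same timepoint label is rejected
  expect_error(align_longitudinal_pairs(base, mk(c("a", "b"), "2013")),
               "distinct timepoint")
  # empty intersection is an error
  expect_error(align_longitudinal_pairs(base, mk(c("x", "y"), "2018")),
               "no subjects shared")
})

test_that("flow-chart accounting: 1848 shared subjects minus 83 with missing spirometry leaves 1765", {
  schema <- list(variable_descriptor("FVC", "continuous", units = "L"),
                 variable_descriptor("FEV1", "continuous", units = "L"))
  ids <- sprintf("K%04d", 1:1848)
  set.seed(5)
  mk <- function(tp) {
    cohort_table(data.frame(subject_id = ids,
                            FVC = stats::rnorm(1848, 3.58, 0.86),
                            FEV1 = stats::rnorm(1848, 2.71, 0.69),
                            stringsAsFactors = FALSE),
                 schema, timepoint = tp)
  }
  base <- mk("2013"); fol <- mk("2018")
  drop_ids <- sample(ids, 83)
  half <- sample(c(TRUE, FALSE), 83, replace = TRUE)
  base$data$FVC[match(drop_ids[half], ids)] <- NA
  fol$data$FEV1[match(drop_ids[!half], ids)] <- NA
  paired <- align_longitudinal_pairs(base, fol,
                                     required_vars = c("FVC", "FEV1"))
  expect_equal(length(paired$paired_ids), 1765)
  expect_equal(unname(paired$exclusions[["missing_required"]]), 83)
  # conservation: intersection size = retained + missing-required
  expect_equal(length(paired$paired_ids) +
                 paired$exclusions[["missing_required"]],
               1848, ignore_attr = TRUE)
  # empty required_vars degenerates to plain intersection
  expect_equal(length(align_longitudinal_pairs(base, fol)$paired_ids), 1848)
})

test_that("edge lists serialise deterministically and round trip", {
  edges <- data.frame(
    var1 = c("b", "a", "c"), var2 = c("x", "y", "z"),
    value = c(0.5, 0.5, -0.3), rank = c(1L, 1L, 2L),
    significance = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(edges, path)
  back <- read_edge_list(path)
  # equal rank resolves lexicographically
  expect_equal(back$var1, c("a", "b", "c"))
  expect_equal(back$value, c(0.5, 0.5, -0.3))
  # round trip reproduces the set exactly
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(back, path2)
  expect_identical(readBin(path, "raw", 1e6), readBin(path2, "raw", 1e6))
  # empty set gives a header-only file
  write_edge_list(edges[0, ], path)
  expect_equal(readLines(path), "var1\tvar2\tvalue\trank\tsignificance")
})

test_that("schema YAML round trips descriptors", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_schema(demo_schema(), path)
  back <- read_schema(path)
  expect_equal(names(back), c("age", "FVC", "smoking_now", "exercise"))
  expect_equal(back$exercise$levels,
               c("none", "sometimes", "often", "daily"))
  expect_equal(back$age$kind, "continuous")
})
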