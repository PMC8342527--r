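make_numeric_table <- function(df) {
  schema <- lapply(setdiff(names(df), "subject_id"), function(nm)
    variable_descriptor(nm, "continuous"))
  cohort_table(df, schema)
}

test_that("pairwise correlations match hand values and flag degeneracy", {
  df <- data.frame(subject_id = letters[1:4],
                   x = c(1, 2, 3, 4), y = c(2, 4, 6, 8),
                   z = c(1, 3, 2, 4), k = c(7, 7, 7, 7))
  cm <- pairwise_correlation_matrix(make_numeric_table(df), min_pair_n = 3)
  expect_equal(cm$r["x", "y"], 1)
  expect_equal(cm$r["x", "z"], 0.8)  # cov 4 over sqrt(5*5) on n-1 scale
  expect_true(is.na(cm$r["x", "k"])) # constant column: unavailable, no error
  expect_true(isSymmetric(cm$r))
  expect_equal(cm$n_pair["x", "y"], 4, ignore_attr = TRUE)
})

test_that("entries below the pairwise-n floor are unavailable", {
  df <- data.frame(subject_id = sprintf("s%02d", 1:10),
                   a = rnorm(10), b = c(rnorm(4), rep(NA, 6)))
  cm <- pairwise_correlation_matrix(make_numeric_table(df), min_pair_n = 5)
  expect_true(is.na(cm$r["a", "b"]))
  expect_equal(cm$n_pair["a", "b"], 4, ignore_attr = TRUE)
  expect_equal(cm$r["a", "a"], 1, ignore_attr = TRUE)
})

test_that("correlations are invariant to positive affine maps and flip under negation", {
  set.seed(21)
  df <- data.frame(subject_id = sprintf("s%03d", 1:50),
                   x = rnorm(50), y = rnorm(50))
  base <- pairwise_correlation_matrix(make_numeric_table(df),
                                      min_pair_n = 3)$r["x", "y"]
  df2 <- df; df2$x <- 3.2 * df2$x + 17
  r2 <- pairwise_correlation_matrix(make_numeric_table(df2),
                                    min_pair_n = 3)$r["x", "y"]
  expect_equal(r2, base, tolerance = 1e-12)
  df3 <- df; df3$x <- -df3$x
  r3 <- pairwise_correlation_matrix(make_numeric_table(df3),
                                    min_pair_n = 3)$r["x", "y"]
  expect_equal(r3, -base, tolerance = 1e-12)
})

test_that("matrix entries match a naive two-pass per-pair oracle", {
  set.seed(31)
  n <- 40
  df <- data.frame(subject_id = sprintf("s%03d", 1:n),
                   a = rnorm(n), b = rnorm(n), c = rnorm(n))
  df$a[sample(n, 6)] <- NA
  df$b[sample(n, 5)] <- NA
  cm <- pairwise_correlation_matrix(make_numeric_table(df), min_pair_n = 3)
  naive <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  for (p in list(c("a", "b"), c("a", "c"), c("b", "c")))
    expect_equal(cm$r[p[1], p[2]], naive(df[[p[1]]], df[[p[2]]]),
                 tolerance = 1e-12)
})

test_that("correlation ratio matches hand sums of squares", {
  # groups {1,2} vs {3,4}: SSB 4, SST 5
  expect_equal(correlation_ratio(c(1, 2, 3, 4), c("g1", "g1", "g2", "g2")),
               sqrt(4 / 5))
  # equal group means: no between-group variance
  expect_equal(correlation_ratio(c(1, 3, 1, 3), c("a", "a", "b", "b")), 0)
  # all variance between groups
  expect_equal(correlation_ratio(c(0, 0, 1, 1), c("a", "a", "b", "b")), 1)
  expect_error(correlation_ratio(1:4, rep("only", 4)), "2 non-empty groups")
  # zero total sum of squares is defined as 0
  expect_equal(correlation_ratio(c(2, 2, 2, 2), c("a", "a", "b", "b")), 0)
})

test_that("eta equals |r| for a binary grouping", {
  set.seed(41)
  for (i in 1:10) {
    g <- sample(c(0, 1), 30, replace = TRUE)
    if (length(unique(g)) < 2) next
    y <- rnorm(30) + g
    expect_equal(correlation_ratio(y, g), abs(cor(y, g)), tolerance = 1e-12)
  }
})

test_that("pair_screen reports r and eta sorted by |r|", {
  set.seed(51)
  n <- 400
  ex <- sample(c("none", "low", "high"), n, replace = TRUE)
  exn <- match(ex, c("none", "low", "high"))
  df <- data.frame(subject_id = sprintf("s%04d", 1:n),
                   exposure = ex,
                   strong = exn + rnorm(n, 0, 0.5),
                   weak = rnorm(n),
                   stringsAsFactors = FALSE)
  schema <- list(
    variable_descriptor("exposure", "ordinal",
                        levels = c("none", "low", "high")),
    variable_descriptor("strong", "continuous"),
    variable_descriptor("weak", "continuous"))
  tab <- cohort_table(df, schema)
  scr <- pair_screen(tab, "exposure", c("strong", "weak"))
  expect_equal(scr$var2[1], "strong")   # sorted by |r| descending
  expect_true(abs(scr$r[1]) > abs(scr$r[2]))
  expect_false(anyNA(scr$eta))          # ordinal exposure: eta reported
  expect_true(all(scr$eta >= 0 & scr$eta <= 1))
  # self pairs are excluded by default but reported first when included
  scr2 <- pair_screen(tab, "strong", c("strong", "weak"),
                      include_self = TRUE)
  expect_equal(scr2$var2[1], "strong")
  expect_equal(scr2$r[1], 1)
})

test_that("a planted association is recovered at cohort scale", {
  gen <- generate_cross_sectional(synthetic_config(n = 6036, seed = 13))
  scr <- pair_screen(gen$table, "alcohol_weekly_g", c("FVC", "weak" = "crp"))
  r_fvc <- scr$r[scr$var2 == "FVC"]
  expect_true(abs(r_fvc - 0.35) < 0.03)
})
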