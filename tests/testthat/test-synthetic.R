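test_that("identical configs generate identical cohorts", {
  cfg <- synthetic_config(n = 300, seed = 4)
  a <- generate_cross_sectional(cfg)
  b <- generate_cross_sectional(cfg)
  expect_identical(a$table$data, b$table$data)
  la <- generate_longitudinal(cfg)
  lb <- generate_longitudinal(cfg)
  expect_identical(la$paired$followup$data, lb$paired$followup$data)
  # different seed, different draw
  c2 <- generate_cross_sectional(synthetic_config(n = 300, seed = 5))
  expect_false(identical(a$table$data, c2$table$data))
})

test_that("category mixtures and demographics match the configured moments", {
  gen <- generate_cross_sectional(synthetic_config(n = 20000, seed = 23))
  d <- gen$table$data
  mix <- table(factor(d$drinking_category,
                      c("never", "light", "moderate", "heavy"))) / nrow(d)
  target <- c(0.264, 0.285, 0.360, 0.087) / sum(c(0.264, 0.285, 0.360, 0.087))
  expect_true(all(abs(as.numeric(mix) - target) < 0.02))
  expect_true(abs(mean(d$sex == "male") - 0.612) < 0.02)
  expect_true(abs(mean(d$age) - 60) < 0.5)
  expect_true(abs(sd(d$age) - 13) < 0.5)
  # grams are consistent with the sampled questionnaire answers
  expect_equal(d$alcohol_weekly_g,
               quantify_weekly_alcohol(d$drink_volume, d$drink_freq))
  # and with the category column
  expect_equal(d$drinking_category,
               assign_drinking_category(d$alcohol_weekly_g))
})

test_that("planted edges reach their observed-scale targets", {
  gen <- generate_cross_sectional(synthetic_config(n = 20000, seed = 29))
  x <- encode_cohort_numeric(gen$table)
  r <- cor(x, use = "pairwise.complete.obs")
  for (i in seq_len(nrow(gen$truth$edges))) {
    e <- gen$truth$edges[i, ]
    expect_true(abs(r[e$var1, e$var2] - e$target_r) < 0.02,
                label = paste0(e$var1, "-", e$var2, " r=",
                               round(r[e$var1, e$var2], 3),
                               " target=", e$target_r))
  }
})

test_that("a confounder induces only the product correlation", {
  cfg <- synthetic_config(
    n = 20000, seed = 31, core = FALSE, extra_vars = c("x", "y", "z"),
    planted_edges = list(),
    confounders = list(list(source = "z", targets = c("x", "y"),
                            strengths = c(0.6, 0.4))))
  gen <- generate_cross_sectional(cfg)
  x <- encode_cohort_numeric(gen$table)
  r <- cor(x)
  expect_true(abs(r["x", "z"] - 0.6) < 0.02)
  expect_true(abs(r["y", "z"] - 0.4) < 0.02)
  expect_true(abs(r["x", "y"] - 0.24) < 0.02)   # a * b, no direct term
  expect_equal(gen$truth$confounded$implied_observed_r, 0.24)
  expect_equal(nrow(gen$truth$edges), 0)
})

test_that("empty structure leaves variables independent", {
  cfg <- synthetic_config(n = 5000, seed = 37, core = FALSE,
                          extra_vars = sprintf("v%02d", 1:6),
                          planted_edges = list(), confounders = list())
  r <- cor(encode_cohort_numeric(generate_cross_sectional(cfg)$table))
  off <- abs(r[upper.tri(r)])
  expect_true(all(off < 0.05))
})

test_that("infeasible correlation structures fail before sampling", {
  cfg <- synthetic_config(
    n = 100, seed = 1, core = FALSE, extra_vars = c("a", "b", "c"),
    planted_edges = list(c("a", "b", 0.9), c("a", "c", 0.9),
                         c("b", "c", -0.9)),
    confounders = list())
  expect_error(generate_cross_sectional(cfg), "not positive definite")
  # a target unreachable after discretization is also rejected
  cfg2 <- synthetic_config(n = 100, seed = 1,
                           planted_edges = list(c("smoking", "FVC", 0.95)),
                           confounders = list())
  expect_error(generate_cross_sectional(cfg2), "infeasible")
  # a confounded pair may not coincide with a planted edge
  cfg3 <- synthetic_config(
    n = 100, seed = 1, core = FALSE, extra_vars = c("x", "y", "z"),
    planted_edges = list(c("x", "y", 0.3)),
    confounders = list(list(source = "z", targets = c("x", "y"),
                            strengths = c(0.5, 0.5))))
  expect_error(generate_cross_sectional(cfg3), "coincides")
})

test_that("five-year decline and alcohol change follow the configuration", {
  cfg <- synthetic_config(n = 1765, seed = 41, fvc_mean = 3.58,
                          fvc_sd = 0.86)
  gen <- generate_longitudinal(cfg)
  p <- gen$paired
  dfvc <- compute_change_scores(p, "FVC")$delta
  dalc <- compute_change_scores(p, "alcohol_weekly_g")$delta
  dage <- compute_change_scores(p, "age")$delta
  expect_true(abs(mean(dfvc) + 0.10) < 0.03)
  expect_equal(dage, rep(5, 1765))
  expect_true(abs(mean(dalc == 0) - 0.533) < 0.03)
  # small/large split among changers respects the 100 g/week threshold
  bins <- bin_alcohol_change(dalc)
  expect_true(abs(mean(bins == "large") - 0.119) < 0.03)
  # with the attenuation switched off the deltas decorrelate
  cfg0 <- synthetic_config(n = 1765, seed = 41, attenuation_beta = 0)
  gen0 <- generate_longitudinal(cfg0)
  r0 <- cor(compute_change_scores(gen0$paired, "alcohol_weekly_g")$delta,
            compute_change_scores(gen0$paired, "FVC")$delta)
  expect_true(abs(r0) < 0.05)
})

test_that("the attenuation solver hits a requested delta-correlation", {
  cfg <- synthetic_config(n = 1765, seed = 43)
  beta <- attenuation_for_delta_correlation(0.10, cfg)
  rs <- vapply(1:20, function(s) {
    g <- generate_longitudinal(synthetic_config(n = 1765, seed = 43 + s,
                                                attenuation_beta = beta))
    cor(compute_change_scores(g$paired, "alcohol_weekly_g")$delta,
        compute_change_scores(g$paired, "FVC")$delta)
  }, numeric(1))
  expect_true(abs(mean(rs) - 0.10) < 0.02)
})

test_that("truth tables flatten edges, confounders and parameters", {
  cfg <- synthetic_config(n = 100, seed = 3)
  gen <- generate_cross_sectional(cfg)
  tt <- truth_table(gen$truth)
  expect_equal(sum(tt$type == "direct"), nrow(gen$truth$edges))
  expect_equal(sum(tt$type == "indirect"), 1)
  expect_true("attenuation_beta" %in% tt$var1[tt$type == "parameter"])
  # pair rows survive an edge-list round trip
  pairs <- tt[tt$type != "parameter", ]
  edges <- data.frame(var1 = pairs$var1, var2 = pairs$var2,
                      value = pairs$value, rank = seq_len(nrow(pairs)),
                      significance = pairs$type == "direct")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(edges, path)
  back <- read_edge_list(path)
  expect_equal(back$value, edges$value)
  expect_equal(back$var1, edges$var1)
})
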