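# In-code fixtures shared across test files.

demo_schema <- function() {
  list(
    variable_descriptor("age", "continuous", units = "years"),
    variable_descriptor("FVC", "continuous", units = "L"),
    variable_descriptor("smoking_now", "binary", levels = c("no", "yes")),
    variable_descriptor("exercise", "ordinal",
                        levels = c("none", "sometimes", "often", "daily"))
  )
}

demo_table <- function(n = 6) {
  set.seed(99)
  cohort_table(
    data.frame(
      subject_id = sprintf("P%02d", seq_len(n)),
      age = round(stats::rnorm(n, 60, 10), 1),
      FVC = round(stats::rnorm(n, 3.6, 0.9), 2),
      smoking_now = sample(c("no", "yes"), n, replace = TRUE),
      exercise = sample(c("none", "sometimes", "often", "daily"), n,
                        replace = TRUE),
      stringsAsFactors = FALSE),
    demo_schema(), timepoint = "2018")
}

# sample correlation matrix of p standard normal variables
random_corr <- function(n, p, seed) {
  set.seed(seed)
  stats::cor(matrix(stats::rnorm(n * p), n, p,
                    dimnames = list(NULL, sprintf("v%02d", seq_len(p)))))
}

# seeded end-to-end run of the shell pipeline into `dir`
run_pipeline <- function(dir, seed = 11, n = 400) {
  old <- setwd(dir)
  on.exit(setwd(old))
  quiet <- function(...) utils::capture.output(cohort_cli(c(...)))
  quiet("simulate", "--n", n, "--seed", seed,
        "--out-base", "base.csv", "--out-follow", "follow.csv",
        "--schema", "schema.yaml", "--truth", "truth.tsv")
  quiet("quantify-alcohol", "base.csv", "--schema", "schema.yaml",
        "--out", "baseq.csv")
  quiet("screen", "baseq.csv", "--schema", "schema.yaml",
        "--matrix", "matrix.tsv", "--out", "screen.tsv")
  quiet("pcit", "matrix.tsv", "--out", "decisions.tsv")
  quiet("network", "decisions.tsv", "--top", "250",
        "--dot", "network.dot", "--out", "edges.tsv")
  quiet("longitudinal", "base.csv", "follow.csv", "--schema", "schema.yaml",
        "--exposure", "alcohol_weekly_g", "--outcome", "FVC",
        "--out", "assoc.tsv")
  invisible(dir)
}

# paired vectors whose sample correlation is exactly r
exact_corr_pair <- function(r, n, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  e <- stats::rnorm(n)
  e <- stats::residuals(stats::lm(e ~ x))
  x <- as.numeric(scale(x))
  e <- as.numeric(scale(e))
  list(x = x, y = r * x + sqrt(1 - r^2) * e)
}
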