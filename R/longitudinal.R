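#' Per-subject change scores between two timepoints
#'
#' `delta = followup - baseline` for each paired subject, on the numeric
#' encoding of the variable. Subjects missing the value at either timepoint
#' are dropped and counted.
#'
#' @param paired A [align_longitudinal_pairs()] result.
#' @param variable Variable name present at both timepoints.
#' @return A data.frame `subject_id`, `baseline`, `followup`, `delta` with
#'   attribute `n_excluded` (subjects dropped for missingness).
#' @export
compute_change_scores <- function(paired, variable) {
  stopifnot(inherits(paired, "paired_cohort"))
  if (!variable %in% names(paired$baseline$variables) ||
      !variable %in% names(paired$followup$variables))
    stop("variable '", variable, "' absent at one of the timepoints",
         call. = FALSE)
  b <- encode_answer_numeric(paired$baseline$data[[variable]],
                             paired$baseline$variables[[variable]])
  f <- encode_answer_numeric(paired$followup$data[[variable]],
                             paired$followup$variables[[variable]])
  ok <- !is.na(b) & !is.na(f)
  out <- data.frame(subject_id = paired$paired_ids[ok],
                    baseline = b[ok], followup = f[ok],
                    delta = f[ok] - b[ok], stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Correlate two change scores with the compound significance rule
#'
#' Pearson correlation R of paired deltas, with `df = n - 2`,
#' `t = |R| sqrt(df) / sqrt(1 - R^2)`, and the two-tailed p-value from the
#' t distribution with `df` degrees of freedom. The association is declared
#' significant only when `p < p_threshold` **and** `|R| > r_threshold`
#' (defaults 0.05 and 0.05): at cohort-scale n, the magnitude floor keeps
#' vanishingly small correlations from reaching significance on sample size
#' alone. A least-squares trend line of `y` on `x` is attached.
#'
#' @param x_deltas,y_deltas Paired numeric delta vectors (same length,
#'   pairs with a missing member are dropped); at least 4 complete pairs and
#'   nonzero variance in both are required.
#' @param p_threshold,r_threshold The compound rule's thresholds.
#' @param x_name,y_name Labels carried into the result.
#' @return An object of class `"longitudinal_association"`: `exposure_delta`,
#'   `outcome_delta`, `n`, `R`, `df`, `t`, `p`, `slope`, `intercept`,
#'   `significant`.
#' @export
change_correlation_test <- function(x_deltas, y_deltas,
                                    p_threshold = 0.05, r_threshold = 0.05,
                                    x_name = "x", y_name = "y") {
  x <- as.numeric(x_deltas); y <- as.numeric(y_deltas)
  if (length(x) != length(y))
    stop("delta vectors must have equal length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete delta pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in a delta vector", call. = FALSE)
  R <- stats::cor(x, y)
  df <- n - 2L
  t <- abs(R) * sqrt(df) / sqrt(max(1 - R^2, .Machine$double.xmin))
  p <- 2 * stats::pt(t, df = df, lower.tail = FALSE)
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  structure(list(exposure_delta = x_name, outcome_delta = y_name,
                 n = n, R = R, df = df, t = t, p = p,
                 slope = slope, intercept = intercept,
                 significant = (p < p_threshold) & (abs(R) > r_threshold),
                 p_threshold = p_threshold, r_threshold = r_threshold),
            class = "longitudinal_association")
}

#' @export
print.longitudinal_association <- function(x, ...) {
  cat("<longitudinal_association> d", x$exposure_delta, " ~ d",
      x$outcome_delta, "\n", sep = "")
  cat(sprintf("  n = %d, R = %.4f, t = %.4f (df = %d), p = %.4g, %s\n",
              x$n, x$R, x$t, x$df, x$p,
              if (x$significant) "significant" else "not significant"))
  cat(sprintf("  trend line: slope = %.6g, intercept = %.6g\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Define a stratum of paired subjects
#'
#' A stratum is a named deterministic predicate over the paired tables.
#' `predicate` receives the aligned baseline and followup data.frames and
#' returns one logical per subject.
#'
#' @param name Stratum label.
#' @param predicate `function(baseline_data, followup_data) -> logical`.
#' @return An object of class `"stratum_spec"`.
#' @export
stratum_spec <- function(name, predicate) {
  stopifnot(is.character(name), length(name) == 1L, is.function(predicate))
  structure(list(name = name, predicate = predicate), class = "stratum_spec")
}

#' @describeIn stratum_spec subjects whose baseline `variable` equals
#'   `value` (e.g. sex = male).
#' @param variable Variable name; @param value level it must equal.
#' @export
stratum_equal <- function(variable, value) {
  force(variable); force(value)
  stratum_spec(paste0(variable, "=", value),
               function(b, f) !is.na(b[[variable]]) & b[[variable]] == value)
}

#' @describeIn stratum_spec subjects whose `variable` is identical (and
#'   non-missing) at both timepoints — e.g. drinking category unchanged.
#' @export
stratum_stable <- function(variable) {
  force(variable)
  stratum_spec(paste0(variable, " stable"),
               function(b, f) !is.na(b[[variable]]) & !is.na(f[[variable]]) &
                 b[[variable]] == f[[variable]])
}

#' Change-change association within a stratum
#'
#' Applies the stratum predicate to the paired cohort, then correlates the
#' exposure and outcome change scores of the surviving subjects. With
#' `stratum = NULL` this is the unstratified analysis.
#'
#' @param paired A [align_longitudinal_pairs()] result.
#' @param exposure,outcome Variable names (deltas are followup - baseline).
#' @param stratum Optional [stratum_spec()].
#' @param p_threshold,r_threshold Passed to [change_correlation_test()].
#' @return A [change_correlation_test()] result with an extra `stratum`
#'   element and `n` reflecting the stratum.
#' @export
stratified_association <- function(paired, exposure, outcome, stratum = NULL,
                                   p_threshold = 0.05, r_threshold = 0.05) {
  stopifnot(inherits(paired, "paired_cohort"))
  name <- "all subjects"
  if (!is.null(stratum)) {
    stopifnot(inherits(stratum, "stratum_spec"))
    keep <- stratum$predicate(paired$baseline$data, paired$followup$data)
    if (!is.logical(keep) || length(keep) != length(paired$paired_ids))
      stop("stratum predicate must return one logical per paired subject",
           call. = FALSE)
    keep[is.na(keep)] <- FALSE
    if (sum(keep) < 4L)
      stop("stratum '", stratum$name, "' leaves fewer than 4 subjects",
           call. = FALSE)
    idx <- which(keep)
    paired$baseline$data <- paired$baseline$data[idx, , drop = FALSE]
    paired$followup$data <- paired$followup$data[idx, , drop = FALSE]
    paired$paired_ids <- paired$paired_ids[idx]
    name <- stratum$name
  }
  dx <- compute_change_scores(paired, exposure)
  dy <- compute_change_scores(paired, outcome)
  common <- intersect(dx$subject_id, dy$subject_id)
  res <- change_correlation_test(dx$delta[match(common, dx$subject_id)],
                                 dy$delta[match(common, dy$subject_id)],
                                 p_threshold = p_threshold,
                                 r_threshold = r_threshold,
                                 x_name = exposure, y_name = outcome)
  res$stratum <- name
  res
}

#' Bin alcohol-change deltas for descriptive tables
#'
#' Reproduces the descriptive grouping of weekly-alcohol change: exactly no
#' change, a change of less than 100 g/week in magnitude, and a change of
#' 100 g/week or more.
#'
#' @param deltas Numeric change-score vector (g/week).
#' @param threshold Magnitude split between small and large change
#'   (default 100 g/week).
#' @return Character vector over `{"none","small","large"}`.
#' @export
bin_alcohol_change <- function(deltas, threshold = 100) {
  d <- abs(as.numeric(deltas))
  out <- rep(NA_character_, length(d))
  ok <- !is.na(d)
  out[ok & d == 0] <- "none"
  out[ok & d > 0 & d < threshold] <- "small"
  out[ok & d >= threshold] <- "large"
  out
}
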