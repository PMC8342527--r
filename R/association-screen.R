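#' Pairwise-complete correlation matrix over a cohort
#'
#' Product-moment correlations over all encodable variables, each entry
#' computed on the subjects non-missing in both variables of the pair.
#' Entries whose pairwise-complete count falls below `min_pair_n`, or whose
#' pairwise-complete subset leaves a variable with zero variance, are
#' flagged unavailable (`NA`) rather than raising an error.
#'
#' @param table A [cohort_table()].
#' @param min_pair_n Minimum pairwise-complete sample size for an entry to
#'   be reported (default 30; must be >= 3).
#' @param variables Variables to include (default: every schema variable).
#'
#' @return An object of class `"correlation_matrix"`: `variable_names`, the
#'   symmetric matrix `r` (unit diagonal, `NA` = unavailable), the
#'   pairwise-complete count matrix `n_pair`, and `method = "pearson"`.
#' @export
pairwise_correlation_matrix <- function(table, min_pair_n = 30,
                                        variables = NULL) {
  stopifnot(min_pair_n >= 3)
  x <- if (is.matrix(table)) table else encode_cohort_numeric(table, variables)
  p <- ncol(x)
  obs <- !is.na(x)
  n_pair <- crossprod(obs)
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs",
                                   method = "pearson"))
  unavailable <- n_pair < min_pair_n
  if (any(unavailable & upper.tri(unavailable, diag = TRUE)))
    .log_note("correlation entries with n < ", min_pair_n,
              " flagged unavailable: ",
              sum(unavailable[upper.tri(unavailable)]))
  r[unavailable] <- NA_real_
  # cor() already returns NA for zero-variance pairs; keep a unit diagonal
  # wherever the variable has any variance at all
  dvar <- apply(x, 2, function(col) {
    col <- col[!is.na(col)]
    length(col) >= 2 && stats::var(col) > 0
  })
  diag(r) <- ifelse(dvar & diag(n_pair) >= min_pair_n, 1, NA_real_)
  structure(list(variable_names = colnames(x), r = r,
                 n_pair = n_pair, method = "pearson",
                 min_pair_n = min_pair_n),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  p <- length(x$variable_names)
  cat("<correlation_matrix> ", p, " variables (", x$method, "), ",
      sum(is.na(x$r[upper.tri(x$r)])), " unavailable entries\n", sep = "")
  invisible(x)
}

#' Correlation ratio (eta) of an outcome across categories
#'
#' The ANOVA-scale effect size for a categorical-continuous pair:
#' `eta = sqrt(SS_between / SS_total)`. It is 0 when all group means
#' coincide and 1 when every group is internally constant but group means
#' differ. For a binary 0/1 grouping it equals `|r|` of the outcome on the
#' group indicator.
#'
#' @param values Numeric outcome vector.
#' @param groups Grouping vector (factor or character), same length.
#' @return `eta` in `[0, 1]`. A zero total sum of squares yields 0.
#' @export
correlation_ratio <- function(values, groups) {
  values <- as.numeric(values)
  groups <- as.character(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  if (length(unique(groups)) < 2L)
    stop("correlation_ratio needs at least 2 non-empty groups", call. = FALSE)
  if (length(values) < 3L)
    stop("correlation_ratio needs at least 3 observations", call. = FALSE)
  grand <- mean(values)
  sst <- sum((values - grand)^2)
  if (sst == 0) {
    .log_note("correlation_ratio: zero total sum of squares, eta set to 0")
    return(0)
  }
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ssb <- sum(ns * (means - grand)^2)
  sqrt(max(0, min(1, ssb / sst)))
}

#' Screen exposure-outcome pairs by correlation and effect size
#'
#' For every exposure x outcome pair, reports the pairwise-complete Pearson
#' correlation and, when the exposure is level-based (ordinal, binary or
#' categorical), the correlation ratio of the outcome across the exposure's
#' answer categories. Rows are sorted by `|r|` descending.
#'
#' @param table A [cohort_table()].
#' @param exposures,outcomes Character vectors of variable names.
#' @param min_pair_n Passed to [pairwise_correlation_matrix()].
#' @param include_self Keep exposure==outcome pairs (default `FALSE`).
#' @return A data.frame with columns `var1` (exposure), `var2` (outcome),
#'   `r`, `n_pair`, `eta`.
#' @export
pair_screen <- function(table, exposures, outcomes, min_pair_n = 30,
                        include_self = FALSE) {
  stopifnot(inherits(table, "cohort_table"))
  vars <- union(exposures, outcomes)
  absent <- setdiff(vars, names(table$variables))
  if (length(absent))
    stop("variables not in table: ", paste(absent, collapse = ", "),
         call. = FALSE)
  cm <- pairwise_correlation_matrix(table, min_pair_n = min_pair_n,
                                    variables = vars)
  grid <- expand.grid(var1 = exposures, var2 = outcomes,
                      stringsAsFactors = FALSE)
  if (!include_self) grid <- grid[grid$var1 != grid$var2, , drop = FALSE]
  res <- lapply(seq_len(nrow(grid)), function(i) {
    e <- grid$var1[i]; o <- grid$var2[i]
    eta <- NA_real_
    ed <- table$variables[[e]]
    if (ed$kind != "continuous" && table$variables[[o]]$kind == "continuous") {
      ok <- !is.na(table$data[[e]]) & !is.na(table$data[[o]])
      if (sum(ok) >= 3 && length(unique(table$data[[e]][ok])) >= 2)
        eta <- correlation_ratio(table$data[[o]][ok], table$data[[e]][ok])
    }
    data.frame(var1 = e, var2 = o, r = cm$r[e, o],
               n_pair = cm$n_pair[e, o], eta = eta,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res <- res[order(-abs(res$r), res$var1, res$var2, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

.log_note <- function(...) {
  if (isTRUE(getOption("checkupnet.quiet", TRUE))) return(invisible())
  message("checkupnet: ", ...)
}
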