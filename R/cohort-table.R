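#' Construct a cohort table
#'
#' A cohort table holds one row per subject at a single timepoint, with a
#' typed column per variable. Missingness is cell-level (`NA`): subjects are
#' retained and excluded per-analysis, mirroring how periodic-checkup data
#' report per-item missing counts rather than dropping whole records.
#'
#' @param data A data.frame with a `subject_id` column plus one column per
#'   descriptor in `schema`. Continuous columns numeric; level-based columns
#'   character.
#' @param schema List of [variable_descriptor()] objects (order defines
#'   variable order).
#' @param timepoint Opaque timepoint label (e.g. `"2018"`); never parsed.
#'
#' @return An object of class `"cohort_table"` with elements `data`,
#'   `variables`, `timepoint`.
#' @export
cohort_table <- function(data, schema, timepoint = "t0") {
  schema <- .check_schema(schema)
  if (!is.data.frame(data) || !"subject_id" %in% names(data))
    stop("data must be a data.frame with a 'subject_id' column", call. = FALSE)
  ids <- as.character(data$subject_id)
  if (anyDuplicated(ids))
    stop("duplicate subject ID: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (nrow(data) < 2L)
    stop("a cohort table needs at least 2 subjects", call. = FALSE)
  missing_cols <- setdiff(names(schema), names(data))
  if (length(missing_cols))
    stop("schema variables absent from data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  data <- data[, c("subject_id", names(schema)), drop = FALSE]
  data$subject_id <- ids
  for (nm in names(schema)) {
    d <- schema[[nm]]
    if (d$kind == "continuous") {
      data[[nm]] <- as.numeric(data[[nm]])
    } else {
      v <- as.character(data[[nm]])
      bad <- !is.na(v) & !(v %in% d$levels)
      if (any(bad)) {
        i <- which(bad)[1L]
        stop("undeclared level '", v[i], "' in column '", nm,
             "', row ", i, " (subject ", ids[i], ")", call. = FALSE)
      }
      data[[nm]] <- v
    }
  }
  rownames(data) <- NULL
  structure(list(data = data, variables = schema,
                 timepoint = as.character(timepoint)),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x$data), " subjects x ", length(x$variables),
      " variables, timepoint '", x$timepoint, "'\n", sep = "")
  cat("  variables:", paste(names(x$variables), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) c(nrow(x$data), length(x$variables))

#' Read a cohort table from delimited text
#'
#' Parses a comma-separated UTF-8 file with a header row. Continuous cells
#' that equal `missing_token` or fail numeric parsing become missing; cells
#' of level-based variables must be declared levels or `missing_token`.
#'
#' @param path CSV file path. Must contain a `subject_id` column and every
#'   schema variable.
#' @param schema List of [variable_descriptor()] objects.
#' @param missing_token Text marking a missing cell (default `"NA"`).
#' @param timepoint Timepoint label to attach.
#'
#' @return A [cohort_table()].
#' @export
read_cohort_table <- function(path, schema, missing_token = "NA",
                              timepoint = "t0") {
  schema <- .check_schema(schema)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (!"subject_id" %in% names(raw))
    stop("file '", path, "' lacks a 'subject_id' column", call. = FALSE)
  absent <- setdiff(names(schema), names(raw))
  if (length(absent))
    stop("schema columns absent from '", path, "': ",
         paste(absent, collapse = ", "), call. = FALSE)
  for (nm in names(schema)) {
    v <- raw[[nm]]
    v[v == missing_token | v == ""] <- NA_character_
    if (schema[[nm]]$kind == "continuous") {
      raw[[nm]] <- suppressWarnings(as.numeric(v))
    } else {
      raw[[nm]] <- v
    }
  }
  cohort_table(raw, schema, timepoint = timepoint)
}

#' Write a cohort table to CSV
#'
#' Continuous values are written with up to 15 significant digits so that a
#' read-write-read cycle is the identity; declared levels round-trip as
#' exact text.
#'
#' @param table A [cohort_table()].
#' @param path Output CSV path.
#' @param missing_token Text to write for missing cells.
#' @export
write_cohort_table <- function(table, path, missing_token = "NA") {
  stopifnot(inherits(table, "cohort_table"))
  out <- table$data
  for (nm in names(table$variables)) {
    if (table$variables[[nm]]$kind == "continuous") {
      x <- out[[nm]]
      s <- vapply(x, function(v)
        if (is.na(v)) missing_token else format(v, digits = 15,
                                               scientific = FALSE),
        character(1))
      out[[nm]] <- s
    } else {
      v <- out[[nm]]
      v[is.na(v)] <- missing_token
      out[[nm]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Pair subjects across two timepoints
#'
#' Retains subjects present in both tables whose `required_vars` are
#' non-missing at both timepoints — the flow-chart style exclusion used when
#' subjects with missing lung-function records are dropped from a
#' longitudinal analysis. Exclusion counts are recorded by reason.
#'
#' @param baseline,followup [cohort_table()] objects with distinct timepoint
#'   labels, sharing `required_vars` in their schemas.
#' @param required_vars Character vector of variables that must be
#'   non-missing at both timepoints (may be empty).
#'
#' @return An object of class `"paired_cohort"`: `baseline` and `followup`
#'   restricted to the paired subjects (sorted by subject ID), `paired_ids`,
#'   and `exclusions` (counts `not_in_both`, `missing_required`).
#' @export
align_longitudinal_pairs <- function(baseline, followup,
                                     required_vars = character()) {
  stopifnot(inherits(baseline, "cohort_table"),
            inherits(followup, "cohort_table"))
  if (identical(baseline$timepoint, followup$timepoint))
    stop("baseline and followup must carry distinct timepoint labels",
         call. = FALSE)
  for (v in required_vars) {
    if (!v %in% names(baseline$variables) || !v %in% names(followup$variables))
      stop("required variable '", v, "' absent from one of the tables",
           call. = FALSE)
  }
  b_ids <- baseline$data$subject_id
  f_ids <- followup$data$subject_id
  both <- sort(intersect(b_ids, f_ids))
  if (!length(both))
    stop("no subjects shared between the two timepoints", call. = FALSE)
  n_union <- length(union(b_ids, f_ids))
  keep <- rep(TRUE, length(both))
  bi <- match(both, b_ids)
  fi <- match(both, f_ids)
  for (v in required_vars) {
    keep <- keep & !is.na(baseline$data[[v]][bi]) &
      !is.na(followup$data[[v]][fi])
  }
  paired_ids <- both[keep]
  if (length(paired_ids) < 2L)
    stop("fewer than 2 subjects survive pairing", call. = FALSE)
  sub <- function(tab, idx) {
    tab$data <- tab$data[idx, , drop = FALSE]
    rownames(tab$data) <- NULL
    tab
  }
  structure(
    list(baseline = sub(baseline, match(paired_ids, b_ids)),
         followup = sub(followup, match(paired_ids, f_ids)),
         paired_ids = paired_ids,
         exclusions = c(not_in_both = n_union - length(both),
                        missing_required = sum(!keep))),
    class = "paired_cohort"
  )
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat("<paired_cohort> ", length(x$paired_ids), " paired subjects (",
      x$baseline$timepoint, " -> ", x$followup$timepoint, ")\n", sep = "")
  cat("  excluded: ", x$exclusions[["not_in_both"]], " not in both, ",
      x$exclusions[["missing_required"]], " missing required variables\n",
      sep = "")
  invisible(x)
}
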