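#' Describe a cohort variable
#'
#' A variable descriptor records how a column of a cohort table is typed and,
#' for questionnaire items, how its answer categories map onto numbers. The
#' descriptor is what allows clinical measurements (litres, kilograms) and
#' ordinal questionnaire answers ("3-4 days/week") to enter one correlation
#' matrix on a common numeric footing.
#'
#' @param name Column name; must be unique within a table.
#' @param kind One of `"continuous"`, `"ordinal"`, `"binary"`, `"categorical"`.
#' @param units Free-text units (e.g. `"L"`, `"g/week"`); informational only.
#' @param levels Ordered character vector of declared answer labels. Required
#'   (length >= 2) for ordinal, binary and categorical kinds.
#' @param numeric_map Optional named numeric vector mapping answer labels to
#'   numeric levels (e.g. band means). Names must be a subset of `levels`;
#'   when present it must cover every level.
#'
#' @return An object of class `"variable_descriptor"`.
#' @seealso [encode_answer_numeric()], [read_cohort_table()]
#' @export
variable_descriptor <- function(name, kind, units = "", levels = character(),
                                numeric_map = NULL) {
  kind <- match.arg(kind, c("continuous", "ordinal", "binary", "categorical"))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (kind %in% c("ordinal", "binary", "categorical")) {
    if (length(levels) < 2L)
      stop("variable '", name, "' of kind '", kind,
           "' needs at least 2 declared levels", call. = FALSE)
    if (kind == "binary" && length(levels) != 2L)
      stop("binary variable '", name, "' must have exactly 2 levels",
           call. = FALSE)
    if (anyDuplicated(levels))
      stop("duplicated levels in variable '", name, "'", call. = FALSE)
  }
  if (!is.null(numeric_map)) {
    if (is.null(names(numeric_map)) || !all(names(numeric_map) %in% levels))
      stop("numeric_map keys of '", name,
           "' must be a subset of the declared levels", call. = FALSE)
    if (!all(levels %in% names(numeric_map)))
      stop("numeric_map of '", name, "' must cover every declared level",
           call. = FALSE)
    numeric_map <- stats::setNames(as.numeric(numeric_map), names(numeric_map))
  }
  structure(
    list(name = name, kind = kind, units = units,
         levels = levels, numeric_map = numeric_map),
    class = "variable_descriptor"
  )
}

#' @export
print.variable_descriptor <- function(x, ...) {
  cat("<variable_descriptor> ", x$name, " (", x$kind,
      if (nzchar(x$units)) paste0(", ", x$units) else "", ")\n", sep = "")
  if (length(x$levels))
    cat("  levels: ", paste(x$levels, collapse = " | "), "\n", sep = "")
  invisible(x)
}

.check_schema <- function(schema) {
  if (inherits(schema, "variable_descriptor")) schema <- list(schema)
  ok <- vapply(schema, inherits, logical(1), "variable_descriptor")
  if (!length(schema) || !all(ok))
    stop("schema must be a list of variable_descriptor objects", call. = FALSE)
  nms <- vapply(schema, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicated variable names in schema: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(schema) <- nms
  schema
}

#' Read or write a variable schema as YAML
#'
#' The on-disk schema is a YAML mapping `name -> {kind, units, levels,
#' numeric_map}`, mirroring [variable_descriptor()].
#'
#' @param path File path of the YAML schema.
#' @return `read_schema()` returns a named list of descriptors.
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stop("schema file '", path, "' is empty", call. = FALSE)
  .check_schema(lapply(names(raw), function(nm) {
    spec <- raw[[nm]]
    nmap <- spec$numeric_map
    if (!is.null(nmap)) nmap <- unlist(nmap)
    variable_descriptor(
      name = nm,
      kind = spec$kind %||% "continuous",
      units = spec$units %||% "",
      levels = as.character(spec$levels %||% character()),
      numeric_map = nmap
    )
  }))
}

#' @rdname read_schema
#' @param schema List of [variable_descriptor()] objects to serialise.
#' @export
write_schema <- function(schema, path) {
  schema <- .check_schema(schema)
  out <- lapply(schema, function(d) {
    spec <- list(kind = d$kind)
    if (nzchar(d$units)) spec$units <- d$units
    if (length(d$levels)) spec$levels <- as.list(d$levels)
    if (!is.null(d$numeric_map)) spec$numeric_map <- as.list(d$numeric_map)
    spec
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
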