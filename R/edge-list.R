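#' Write a ranked edge list to TSV
#'
#' Serialises association records deterministically: one edge per line,
#' ordered by rank then lexicographically by the (var1, var2) pair, so equal
#' inputs always produce byte-identical files.
#'
#' @param edges A data.frame with columns `var1`, `var2`, `value`, `rank`,
#'   `significance` (zero rows allowed; a header-only file is written).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @seealso [read_edge_list()]
#' @export
write_edge_list <- function(edges, path) {
  required <- c("var1", "var2", "value", "rank", "significance")
  if (!is.data.frame(edges) || !all(required %in% names(edges)))
    stop("edges must carry columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  edges <- edges[, required, drop = FALSE]
  if (nrow(edges)) {
    o <- order(edges$rank, edges$var1, edges$var2, method = "radix")
    edges <- edges[o, , drop = FALSE]
  }
  con <- try(file(path, open = "wb"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop("cannot open '", path, "' for writing", call. = FALSE)
  on.exit(close(con))
  lines <- paste(required, collapse = "\t")
  if (nrow(edges)) {
    lines <- c(lines, paste(
      edges$var1, edges$var2,
      vapply(edges$value, function(v) format(v, digits = 15,
                                             scientific = FALSE),
             character(1)),
      edges$rank,
      tolower(as.character(edges$significance)),
      sep = "\t"))
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read an edge list written by [write_edge_list()]
#'
#' @param path TSV path.
#' @return A data.frame with columns `var1`, `var2`, `value`, `rank`,
#'   `significance`.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE)
  required <- c("var1", "var2", "value", "rank", "significance")
  if (!all(required %in% names(df)))
    stop("'", path, "' is not an edge list file", call. = FALSE)
  df$value <- as.numeric(df$value)
  df$rank <- as.integer(df$rank)
  df$significance <- df$significance == "true"
  df
}
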