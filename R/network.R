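#' Rank significant edges and build the correlation network
#'
#' Orders the PCIT-significant associations by absolute correlation, drops a
#' user-supplied exclusion list of well-established correlations (an
#' editorial, not algorithmic, notion — e.g. alcohol with gamma-GTP), and
#' keeps the top `k`. Exclusion happens before truncation, so a dropped
#' well-known pair frees a slot for the next-ranked novel one.
#'
#' @param decisions A [pcit_edge_decisions()] result (or any data.frame with
#'   `var1`, `var2`, `r`, `significant`).
#' @param exclusion Optional two-column data.frame / matrix / list of
#'   character pairs naming edges to drop. Pairs are matched irrespective of
#'   order; pairs naming unknown variables raise a warning and are ignored.
#' @param k Number of edges to retain (default 250).
#'
#' @return An object of class `"network_graph"`: `nodes` (variables incident
#'   to a retained edge), `edges` (data.frame `var1`, `var2`, `r`, `rank`,
#'   sorted by `|r|` descending, ties broken lexicographically on the
#'   canonical pair), `k`, and `excluded` (data.frame of dropped pairs with
#'   a `reason` column).
#' @export
rank_and_filter_edges <- function(decisions, exclusion = NULL, k = 250) {
  stopifnot(is.data.frame(decisions), k >= 0)
  need <- c("var1", "var2", "r", "significant")
  if (!all(need %in% names(decisions)))
    stop("decisions must carry columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  sig <- decisions[decisions$significant & !is.na(decisions$r), , drop = FALSE]
  # canonical (sorted) name order within each pair
  swap <- sig$var1 > sig$var2
  tmp <- sig$var1[swap]; sig$var1[swap] <- sig$var2[swap]; sig$var2[swap] <- tmp
  known <- unique(c(decisions$var1, decisions$var2))
  excl_keys <- character()
  if (!is.null(exclusion)) {
    pairs <- .as_pair_list(exclusion)
    for (pr in pairs) {
      if (!all(pr %in% known)) {
        warning("exclusion pair (", pr[1], ", ", pr[2],
                ") names unknown variables; ignored", call. = FALSE)
        next
      }
      excl_keys <- c(excl_keys, paste(sort(pr), collapse = "\r"))
    }
  }
  key <- paste(sig$var1, sig$var2, sep = "\r")
  drop <- key %in% excl_keys
  excluded <- if (any(drop)) {
    data.frame(var1 = sig$var1[drop], var2 = sig$var2[drop],
               r = sig$r[drop], reason = "exclusion_list",
               stringsAsFactors = FALSE)
  } else {
    data.frame(var1 = character(), var2 = character(), r = numeric(),
               reason = character(), stringsAsFactors = FALSE)
  }
  kept <- sig[!drop, , drop = FALSE]
  o <- order(-abs(kept$r), kept$var1, kept$var2, method = "radix")
  kept <- kept[o, , drop = FALSE]
  if (nrow(kept) > k) kept <- kept[seq_len(k), , drop = FALSE]
  edges <- data.frame(var1 = kept$var1, var2 = kept$var2, r = kept$r,
                      rank = seq_len(nrow(kept)), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(edges$var1, edges$var2))),
                 edges = edges, k = k, excluded = excluded),
            class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  cat("<network_graph> ", nrow(x$edges), " edges (top ", x$k, ") over ",
      length(x$nodes), " nodes; ", nrow(x$excluded), " excluded\n", sep = "")
  invisible(x)
}

#' Export a correlation network as a DOT diagram
#'
#' Emits an undirected `graph` in the DOT language: one node statement per
#' variable incident to a retained edge (sorted by name), then one edge
#' statement per retained edge in rank order, each carrying the absolute
#' correlation to four decimals as `weight` and `label` and the sign as a
#' separate `sign` attribute. Output is byte-identical across runs for equal
#' input, so downstream Graphviz renderings are reproducible.
#'
#' @param graph A [rank_and_filter_edges()] result.
#' @param path Output `.dot` path.
#' @return `path`, invisibly.
#' @export
export_dot <- function(graph, path) {
  stopifnot(inherits(graph, "network_graph"))
  con <- try(file(path, open = "wb"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop("cannot open '", path, "' for writing", call. = FALSE)
  on.exit(close(con))
  q <- function(s) paste0('"', gsub('"', '\\\\"', s), '"')
  lines <- c("graph correlation_network {", "  node [shape=ellipse];")
  for (nd in graph$nodes) lines <- c(lines, paste0("  ", q(nd), ";"))
  e <- graph$edges
  if (nrow(e)) {
    lines <- c(lines, paste0(
      "  ", q(e$var1), " -- ", q(e$var2),
      " [weight=\"", sprintf("%.4f", abs(e$r)),
      "\", sign=\"", ifelse(e$r < 0, "-", "+"),
      "\", label=\"", sprintf("%.4f", abs(e$r)), "\"];"))
  }
  lines <- c(lines, "}")
  writeLines(lines, con)
  invisible(path)
}

.as_pair_list <- function(exclusion) {
  if (is.data.frame(exclusion) || is.matrix(exclusion)) {
    if (ncol(exclusion) < 2L)
      stop("exclusion needs two columns of variable names", call. = FALSE)
    lapply(seq_len(nrow(exclusion)), function(i)
      as.character(unlist(exclusion[i, 1:2])))
  } else if (is.list(exclusion)) {
    lapply(exclusion, function(pr) {
      if (length(pr) != 2L)
        stop("each exclusion pair must have exactly 2 names", call. = FALSE)
      as.character(pr)
    })
  } else {
    stop("exclusion must be a two-column table or a list of pairs",
         call. = FALSE)
  }
}
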