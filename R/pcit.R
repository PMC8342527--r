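#' First-order partial correlation
#'
#' Correlation of x and y with the linear effect of a third variable z
#' removed:
#' `r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))`.
#' Symmetric under exchanging x and y. When a flanking correlation magnitude
#' is within 1e-12 of 1 the denominator term `1 - r^2` is clamped to 1e-12,
#' keeping the value finite; such trios are degenerate and flagged by the
#' callers.
#'
#' @param r_xy,r_xz,r_yz Direct product-moment correlations (vectorised).
#' @return The first-order partial correlation `r_xy.z`.
#' @export
partial_correlation <- function(r_xy, r_xz, r_yz) {
  (r_xy - r_xz * r_yz) / sqrt(.clamp_one_minus_r2(r_xz) *
                                .clamp_one_minus_r2(r_yz))
}

#' Trio tolerance level
#'
#' The local elimination threshold of the PCIT procedure: the average ratio
#' of partial to direct correlation over the three rotations of a trio,
#' `eps = (r_xy.z/r_xy + r_xz.y/r_xz + r_yz.x/r_yz) / 3`.
#' Direct correlations with magnitude below 1e-12 are clamped to 1e-12 with
#' sign preserved so the ratios stay finite; because the discard rule
#' compares `|r_xy|` against `|eps * r|`, a true-zero flanking correlation
#' still cannot discard a nonzero edge.
#'
#' @param r_xy,r_xz,r_yz Direct correlations of the trio (vectorised).
#' @return The tolerance `eps`. For a trio with all three correlations equal
#'   to `r`, `eps = 1 / (1 + r)`.
#' @export
trio_tolerance <- function(r_xy, r_xz, r_yz) {
  p_xy_z <- partial_correlation(r_xy, r_xz, r_yz)
  p_xz_y <- partial_correlation(r_xz, r_xy, r_yz)
  p_yz_x <- partial_correlation(r_yz, r_xy, r_xz)
  (p_xy_z / .clamp_r(r_xy) + p_xz_y / .clamp_r(r_xz) +
      p_yz_x / .clamp_r(r_yz)) / 3
}

#' PCIT edge significance decisions
#'
#' Applies the partial-correlation-and-information-theory elimination rule
#' to every unordered variable pair of a correlation matrix. For a pair
#' (x, y) and each third variable z, the trio's tolerance `eps` is computed
#' and the connection is discarded if
#' `|r_xy| <= |eps * r_xz|` **and** `|r_xy| <= |eps * r_yz|`;
#' the association is significant iff no z among the remaining p - 2
#' variables discards it. Comparisons use `<=` at double precision with no
#' tolerance, so verdicts are deterministic.
#'
#' Variables with unavailable matrix entries cannot enter trios; they are
#' removed (most-missing first) before the scan and noted.
#'
#' @param x A [pairwise_correlation_matrix()] result, or a symmetric numeric
#'   correlation matrix with dimnames.
#' @return An object of class `"pcit_decisions"`: a data.frame with one row
#'   per unordered pair — `var1`, `var2`, `r`, `significant`,
#'   `eliminating_z` (first discarding third variable in variable order, NA
#'   if significant) and `trios_evaluated`.
#' @seealso [pcit_brute_oracle()] for the reference implementation.
#' @export
pcit_edge_decisions <- function(x) {
  R <- .as_complete_corr(x)
  p <- ncol(R)
  vars <- colnames(R)
  rows <- vector("list", p * (p - 1L) / 2L)
  k <- 0L
  for (i in seq_len(p - 1L)) {
    for (j in seq.int(i + 1L, p)) {
      zs <- setdiff(seq_len(p), c(i, j))
      r_xy <- R[i, j]
      r_xz <- R[i, zs]
      r_yz <- R[j, zs]
      eps <- trio_tolerance(r_xy, r_xz, r_yz)
      disc <- abs(r_xy) <= abs(eps * r_xz) & abs(r_xy) <= abs(eps * r_yz)
      k <- k + 1L
      rows[[k]] <- data.frame(
        var1 = vars[i], var2 = vars[j], r = r_xy,
        significant = !any(disc),
        eliminating_z = if (any(disc)) vars[zs[which(disc)[1L]]]
                        else NA_character_,
        trios_evaluated = length(zs),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("pcit_decisions", "data.frame"),
            variable_names = vars)
}

#' Brute-force PCIT reference
#'
#' A literal, unoptimised transcription of the elimination procedure —
#' scalar triple loop over (x, y, z), recomputing the three partials and the
#' tolerance for every trio. Exists solely as an independent reference for
#' equivalence testing against [pcit_edge_decisions()]; the two share only
#' the degenerate-value clamping policy.
#'
#' @inheritParams pcit_edge_decisions
#' @return Same structure as [pcit_edge_decisions()].
#' @export
pcit_brute_oracle <- function(x) {
  R <- .as_complete_corr(x)
  p <- ncol(R)
  vars <- colnames(R)
  rows <- vector("list", p * (p - 1L) / 2L)
  k <- 0L
  for (i in seq_len(p - 1L)) {
    for (j in seq.int(i + 1L, p)) {
      r_xy <- R[i, j]
      eliminating <- NA_character_
      trios <- 0L
      for (z in seq_len(p)) {
        if (z == i || z == j) next
        trios <- trios + 1L
        r_xz <- R[i, z]
        r_yz <- R[j, z]
        p_xy_z <- (r_xy - r_xz * r_yz) /
          sqrt(.clamp_one_minus_r2(r_xz) * .clamp_one_minus_r2(r_yz))
        p_xz_y <- (r_xz - r_xy * r_yz) /
          sqrt(.clamp_one_minus_r2(r_xy) * .clamp_one_minus_r2(r_yz))
        p_yz_x <- (r_yz - r_xy * r_xz) /
          sqrt(.clamp_one_minus_r2(r_xy) * .clamp_one_minus_r2(r_xz))
        eps <- (p_xy_z / .clamp_r(r_xy) + p_xz_y / .clamp_r(r_xz) +
                  p_yz_x / .clamp_r(r_yz)) / 3
        if (abs(r_xy) <= abs(eps * r_xz) && abs(r_xy) <= abs(eps * r_yz) &&
            is.na(eliminating))
          eliminating <- vars[z]
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        var1 = vars[i], var2 = vars[j], r = r_xy,
        significant = is.na(eliminating),
        eliminating_z = eliminating,
        trios_evaluated = trios,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("pcit_decisions", "data.frame"),
            variable_names = vars)
}

#' @export
print.pcit_decisions <- function(x, ...) {
  cat("<pcit_decisions> ", nrow(x), " pairs over ",
      length(attr(x, "variable_names")), " variables; ",
      sum(x$significant), " significant\n", sep = "")
  invisible(NextMethod())
}

# Accept a correlation_matrix or plain matrix; drop variables carrying
# unavailable entries (most-missing first) until the matrix is complete.
.as_complete_corr <- function(x) {
  if (inherits(x, "correlation_matrix")) {
    R <- x$r
  } else if (is.matrix(x)) {
    R <- x
    if (is.null(colnames(R)))
      colnames(R) <- rownames(R) <- paste0("V", seq_len(ncol(R)))
  } else {
    stop("expected a correlation_matrix or a numeric matrix", call. = FALSE)
  }
  if (nrow(R) != ncol(R)) stop("correlation matrix must be square",
                               call. = FALSE)
  dropped <- character()
  while (anyNA(R) && ncol(R) > 0L) {
    na_count <- rowSums(is.na(R))
    worst <- which.max(na_count)
    dropped <- c(dropped, colnames(R)[worst])
    R <- R[-worst, -worst, drop = FALSE]
  }
  if (length(dropped))
    .log_note("variables with unavailable entries excluded from PCIT: ",
              paste(dropped, collapse = ", "))
  if (ncol(R) < 3L)
    stop("PCIT needs at least 3 variables with complete correlations",
         call. = FALSE)
  R
}

# Degenerate-value policy shared by both implementations: direct
# correlations below 1e-12 in magnitude keep their sign at magnitude 1e-12;
# 1 - r^2 is floored at 1e-12.
.clamp_r <- function(r, tol = 1e-12) {
  s <- ifelse(r < 0, -1, 1)
  ifelse(abs(r) < tol, s * tol, r)
}

.clamp_one_minus_r2 <- function(r, tol = 1e-12) {
  pmax(1 - r^2, tol)
}
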