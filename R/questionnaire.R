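#' Configuration for quantifying drinking answers
#'
#' Weekly ethanol intake is reconstructed from two questionnaire items — a
#' daily-volume band ("how much do you drink?") and a frequency band ("how
#' often do you drink?") — by multiplying the mean level of each answer
#' category. The mean of a closed band is its midpoint; an open-ended top
#' band is assigned its lower bound plus half the preceding band's width.
#' Subjects are then split into never / light / moderate / heavy drinkers by
#' two grams-per-week cutoffs; heavy means more than `cutoffs[2]` g/week.
#'
#' @param volume_means Named numeric vector: volume answer label ->
#'   grams/day (band mean).
#' @param frequency_means Named numeric vector: frequency answer label ->
#'   days/week (band mean).
#' @param cutoffs Two strictly increasing thresholds in grams/week: the
#'   light/moderate and moderate/heavy boundaries. Defaults to
#'   `c(100, 350)`; 350 anchors "heavy" at more than 350 g/week.
#'
#' @return An object of class `"quantification_config"`.
#' @export
quantification_config <- function(volume_means, frequency_means,
                                  cutoffs = c(100, 350)) {
  stopifnot(is.numeric(volume_means), !is.null(names(volume_means)),
            is.numeric(frequency_means), !is.null(names(frequency_means)),
            length(cutoffs) == 2L)
  if (any(volume_means < 0) || any(frequency_means < 0))
    stop("band means must be non-negative", call. = FALSE)
  if (!(cutoffs[1] > 0 && cutoffs[2] > cutoffs[1]))
    stop("cutoffs must be strictly increasing and positive", call. = FALSE)
  structure(list(volume_means = volume_means,
                 frequency_means = frequency_means,
                 cutoffs = as.numeric(cutoffs)),
            class = "quantification_config")
}

#' Default drinking-band configuration
#'
#' Volume bands (grams ethanol/day): none = 0, "<20 g/day" = 10,
#' "21-40 g/day" = 30.5, "41-60 g/day" = 50.5, ">60 g/day" = 70.5 (open top
#' band: 60 plus half the preceding 20-g width). Frequency bands (days/week):
#' never = 0, "few times/month" = 0.5, "1-2 days/week" = 1.5,
#' "3-4 days/week" = 3.5, "5-6 days/week" = 5.5, "every day" = 7.
#'
#' @return A [quantification_config()].
#' @export
default_drinking_config <- function() {
  quantification_config(
    volume_means = c("none" = 0, "<20 g/day" = 10, "21-40 g/day" = 30.5,
                     "41-60 g/day" = 50.5, ">60 g/day" = 70.5),
    frequency_means = c("never" = 0, "few times/month" = 0.5,
                        "1-2 days/week" = 1.5, "3-4 days/week" = 3.5,
                        "5-6 days/week" = 5.5, "every day" = 7),
    cutoffs = c(100, 350)
  )
}

#' Weekly alcohol grams from questionnaire answers
#'
#' `weekly_grams = volume_means[volume] * frequency_means[frequency]`. A
#' frequency answer of zero days/week ("never") annihilates the product
#' regardless of the volume answer. Vectorised over answers.
#'
#' @param volume Character vector of volume answer labels.
#' @param frequency Character vector of frequency answer labels (recycled
#'   against `volume` if scalar).
#' @param config A [quantification_config()].
#' @return Numeric vector of grams ethanol per week; `NA` answers propagate.
#' @export
quantify_weekly_alcohol <- function(volume, frequency,
                                    config = default_drinking_config()) {
  stopifnot(inherits(config, "quantification_config"))
  volume <- as.character(volume)
  frequency <- as.character(frequency)
  n <- max(length(volume), length(frequency))
  volume <- rep_len(volume, n)
  frequency <- rep_len(frequency, n)
  bad_v <- !is.na(volume) & !(volume %in% names(config$volume_means))
  if (any(bad_v))
    stop("unknown volume answer label: '", volume[which(bad_v)[1]], "'",
         call. = FALSE)
  bad_f <- !is.na(frequency) & !(frequency %in% names(config$frequency_means))
  if (any(bad_f))
    stop("unknown frequency answer label: '", frequency[which(bad_f)[1]], "'",
         call. = FALSE)
  unname(config$volume_means[volume] * config$frequency_means[frequency])
}

#' Drinking category from weekly grams
#'
#' Partition of the non-negative line: 0 -> never; (0, cutoff1] -> light;
#' (cutoff1, cutoff2] -> moderate; above cutoff2 -> heavy. Bands are
#' lower-open/upper-closed so that "more than 350 g per week" is heavy.
#'
#' @param weekly_grams Non-negative numeric vector (NA propagates).
#' @param config A [quantification_config()] supplying the cutoffs.
#' @return Character vector over `{"never","light","moderate","heavy"}`.
#' @export
assign_drinking_category <- function(weekly_grams,
                                     config = default_drinking_config()) {
  stopifnot(inherits(config, "quantification_config"))
  g <- as.numeric(weekly_grams)
  if (any(!is.na(g) & g < 0))
    stop("weekly_grams must be non-negative", call. = FALSE)
  cut1 <- config$cutoffs[1]; cut2 <- config$cutoffs[2]
  out <- rep(NA_character_, length(g))
  ok <- !is.na(g)
  out[ok & g == 0] <- "never"
  out[ok & g > 0 & g <= cut1] <- "light"
  out[ok & g > cut1 & g <= cut2] <- "moderate"
  out[ok & g > cut2] <- "heavy"
  out
}

#' Encode an answer column as numeric
#'
#' Continuous values pass through; binary levels map to 0/1 in declared
#' level order; ordinals map through their `numeric_map` when present, else
#' to the 1-based level rank. Nominal categoricals with more than two levels
#' and no numeric map cannot enter a product-moment correlation and are
#' rejected.
#'
#' @param values Vector of raw answers (character levels or numerics).
#' @param descriptor The column's [variable_descriptor()].
#' @return Numeric vector; missing answers stay `NA`.
#' @export
encode_answer_numeric <- function(values, descriptor) {
  stopifnot(inherits(descriptor, "variable_descriptor"))
  if (descriptor$kind == "continuous") return(as.numeric(values))
  v <- as.character(values)
  bad <- !is.na(v) & !(v %in% descriptor$levels)
  if (any(bad))
    stop("undeclared level '", v[which(bad)[1]], "' for variable '",
         descriptor$name, "'", call. = FALSE)
  if (!is.null(descriptor$numeric_map))
    return(unname(descriptor$numeric_map[v]))
  if (descriptor$kind == "binary")
    return(match(v, descriptor$levels) - 1)
  if (descriptor$kind == "ordinal")
    return(as.numeric(match(v, descriptor$levels)))
  stop("nominal variable '", descriptor$name, "' has ",
       length(descriptor$levels), " levels and no numeric_map; supply a ",
       "numeric_map or exclude it from the correlation screen",
       call. = FALSE)
}

#' Numeric encoding of a whole cohort table
#'
#' Applies [encode_answer_numeric()] column-wise and returns the
#' subjects-by-variables numeric matrix fed to the correlation screen.
#'
#' @param table A [cohort_table()].
#' @param variables Variables to encode (default: all in the schema).
#' @return Numeric matrix with subject IDs as row names.
#' @export
encode_cohort_numeric <- function(table, variables = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  if (is.null(variables)) variables <- names(table$variables)
  absent <- setdiff(variables, names(table$variables))
  if (length(absent))
    stop("variables not in table: ", paste(absent, collapse = ", "),
         call. = FALSE)
  cols <- lapply(variables, function(nm)
    encode_answer_numeric(table$data[[nm]], table$variables[[nm]]))
  m <- do.call(cbind, cols)
  dimnames(m) <- list(table$data$subject_id, variables)
  m
}
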