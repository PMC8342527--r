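#' Configuration for the synthetic checkup cohort
#'
#' Defines the study conditions the generator emulates: cohort moments of a
#' periodic health-checkup population (age 60.0 (SD 13.0) years, 61.2% male,
#' drinking-category mix 26.4/28.5/36.0/8.7%, FVC 3.60 (0.90) L), planted
#' direct associations (alcohol with FVC at r = 0.35, with skeletal muscle
#' mass 0.39 and grip 0.30), a smoking confounder loading positively on
#' alcohol and negatively on FEV1, five-year decline of lung function
#' (FVC -0.10 L, FEV1 -0.16 L), and a dose-dependent attenuation of FVC
#' decline by alcohol-intake change.
#'
#' All planted structure lives in a joint Gaussian latent space; marginals
#' are transformed afterwards (category bands, lognormal CRP, binary sex).
#' Planted-edge targets are observed-scale: each is divided by the
#' attenuation factors of the transformed marginals before entering the
#' latent correlation matrix, so the sampled, observed-scale correlation
#' converges to the stated target.
#'
#' @param n Number of subjects (>= 10).
#' @param seed Integer seed; identical configs generate identical cohorts.
#' @param male_fraction Proportion of males.
#' @param age_mean,age_sd Age moments (years).
#' @param height_mean,height_sd Height moments (cm).
#' @param bmi_mean,bmi_sd BMI moments (kg/m^2).
#' @param smoking_mix Never/previous/current smoking proportions
#'   (normalised internally).
#' @param drinking_mix Never/light/moderate/heavy proportions (normalised).
#' @param fvc_mean,fvc_sd,fev1_mean,fev1_sd Spirometry moments (L).
#' @param muscle_mean,muscle_sd Appendicular skeletal muscle mass (kg).
#' @param grip_mean,grip_sd Grip strength (kg).
#' @param crp_meanlog,crp_sdlog Log-scale moments of C-reactive protein
#'   (mg/dL, lognormal).
#' @param planted_edges Data.frame or list of `(var1, var2, r)` triples:
#'   direct associations at the stated observed-scale correlation. `NULL`
#'   keeps the defaults; use `list()` for none.
#' @param confounders List of `list(source, targets, strengths)`: the source
#'   loads on the two targets with the given latent-scale strengths `(a, b)`,
#'   inducing an indirect target-target correlation of `a * b` (latent) with
#'   no direct dependence. `NULL` keeps the default smoking confounder; use
#'   `list()` for none.
#' @param extra_vars Names of additional standard-normal continuous
#'   variables (usable in `planted_edges` / `confounders`).
#' @param core Include the core checkup variables (`FALSE` generates only
#'   `extra_vars`).
#' @param timepoints Two opaque labels for the longitudinal tables.
#' @param years_between Years between the timepoints (added to age).
#' @param decline Named mean five-year change of continuous variables.
#' @param delta_noise_sd Named SD of the subject-level change noise.
#' @param attenuation_beta FVC-decline change (L) per +100 g/week alcohol
#'   change; see [attenuation_for_delta_correlation()] to target a
#'   population delta-correlation.
#' @param change_mix Proportions of subjects with zero / under-100 g/week /
#'   over-100 g/week alcohol change over the follow-up interval.
#' @param drinking_config A [quantification_config()] defining answer bands.
#'
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n = 6036, seed = 1L,
                             male_fraction = 0.612,
                             age_mean = 60.0, age_sd = 13.0,
                             height_mean = 165.2, height_sd = 8.8,
                             bmi_mean = 23.3, bmi_sd = 3.2,
                             smoking_mix = c(never = 0.495, previous = 0.391,
                                             current = 0.106),
                             drinking_mix = c(never = 0.264, light = 0.285,
                                              moderate = 0.360,
                                              heavy = 0.087),
                             fvc_mean = 3.60, fvc_sd = 0.90,
                             fev1_mean = 2.71, fev1_sd = 0.72,
                             muscle_mean = 21.0, muscle_sd = 4.5,
                             grip_mean = 33.0, grip_sd = 9.0,
                             crp_meanlog = log(0.05), crp_sdlog = 1.0,
                             planted_edges = NULL,
                             confounders = NULL,
                             extra_vars = character(),
                             core = TRUE,
                             timepoints = c("2013", "2018"),
                             years_between = 5,
                             decline = c(FVC = -0.10, FEV1 = -0.16),
                             delta_noise_sd = c(FVC = 0.30, FEV1 = 0.25),
                             attenuation_beta = 0.025,
                             change_mix = c(none = 0.533, small = 0.348,
                                            large = 0.119),
                             drinking_config = default_drinking_config()) {
  stopifnot(n >= 10, length(timepoints) == 2L,
            timepoints[1] != timepoints[2],
            inherits(drinking_config, "quantification_config"))
  .check_mix <- function(m, k, what) {
    if (length(m) != k || any(m < 0) || sum(m) <= 0)
      stop(what, " must be ", k, " non-negative proportions", call. = FALSE)
    m / sum(m)
  }
  smoking_mix <- .check_mix(smoking_mix, 3L, "smoking_mix")
  drinking_mix <- .check_mix(drinking_mix, 4L, "drinking_mix")
  change_mix <- .check_mix(change_mix, 3L, "change_mix")
  if (male_fraction < 0 || male_fraction > 1)
    stop("male_fraction must be in [0, 1]", call. = FALSE)
  if (is.null(planted_edges) && core) {
    planted_edges <- list(
      c("alcohol_weekly_g", "FVC", 0.35),
      c("FVC", "FEV1", 0.85),
      c("alcohol_weekly_g", "muscle_mass", 0.39),
      c("alcohol_weekly_g", "grip", 0.30),
      c("muscle_mass", "grip", 0.60))
  } else if (is.null(planted_edges)) {
    planted_edges <- list()
  }
  if (is.null(confounders) && core) {
    confounders <- list(list(source = "smoking",
                             targets = c("alcohol_weekly_g", "FEV1"),
                             strengths = c(0.20, -0.25)))
  } else if (is.null(confounders)) {
    confounders <- list()
  }
  planted_edges <- .normalize_edges(planted_edges)
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         male_fraction = male_fraction,
         age_mean = age_mean, age_sd = age_sd,
         height_mean = height_mean, height_sd = height_sd,
         bmi_mean = bmi_mean, bmi_sd = bmi_sd,
         smoking_mix = smoking_mix, drinking_mix = drinking_mix,
         fvc_mean = fvc_mean, fvc_sd = fvc_sd,
         fev1_mean = fev1_mean, fev1_sd = fev1_sd,
         muscle_mean = muscle_mean, muscle_sd = muscle_sd,
         grip_mean = grip_mean, grip_sd = grip_sd,
         crp_meanlog = crp_meanlog, crp_sdlog = crp_sdlog,
         planted_edges = planted_edges, confounders = confounders,
         extra_vars = as.character(extra_vars), core = core,
         timepoints = as.character(timepoints),
         years_between = years_between,
         decline = decline, delta_noise_sd = delta_noise_sd,
         attenuation_beta = attenuation_beta, change_mix = change_mix,
         drinking_config = drinking_config),
    class = "synthetic_config")
}

.normalize_edges <- function(edges) {
  if (is.data.frame(edges)) {
    edges <- lapply(seq_len(nrow(edges)), function(i)
      c(as.character(edges[i, 1]), as.character(edges[i, 2]),
        as.numeric(edges[i, 3])))
  }
  lapply(edges, function(e) {
    if (length(e) != 3L)
      stop("each planted edge must be (var1, var2, r)", call. = FALSE)
    r <- as.numeric(e[[3]])
    if (is.na(r) || abs(r) >= 1)
      stop("planted edge target correlations must lie in (-1, 1)",
           call. = FALSE)
    list(var1 = as.character(e[[1]]), var2 = as.character(e[[2]]), r = r)
  })
}

# All (volume, frequency) answer combinations consistent with each drinking
# category: never is the single zero combo; within a category the mass is
# split equally over its combos, ordered by grams, and assigned by the
# latent quantile position (a monotone step map from latent to grams).
.drinking_combos <- function(drinking_config, drinking_mix) {
  vm <- drinking_config$volume_means
  fm <- drinking_config$frequency_means
  grid <- expand.grid(volume = names(vm), frequency = names(fm),
                      stringsAsFactors = FALSE)
  grid$grams <- unname(vm[grid$volume] * fm[grid$frequency])
  grid$category <- assign_drinking_category(grid$grams, drinking_config)
  nonzero <- grid[grid$grams > 0, , drop = FALSE]
  nonzero <- nonzero[order(nonzero$grams, nonzero$volume, nonzero$frequency,
                           method = "radix"), , drop = FALSE]
  zero <- data.frame(volume = names(vm)[which.min(vm)],
                     frequency = names(fm)[which.min(fm)],
                     grams = 0, category = "never",
                     stringsAsFactors = FALSE)
  combos <- rbind(zero, nonzero)
  cats <- c("never", "light", "moderate", "heavy")
  per_cat <- table(factor(combos$category, levels = cats))
  if (any(per_cat == 0))
    stop("drinking bands leave a category with no answer combination",
         call. = FALSE)
  combos$mass <- unname(drinking_mix[combos$category] /
                          per_cat[combos$category])
  rownames(combos) <- NULL
  combos
}

# Attenuation factor lambda = cor(g(Z), Z) of a monotone step transform of
# a standard normal, computed exactly from the step masses:
# E[Z g(Z)] = sum_k g_k * (phi(z_{k-1}) - phi(z_k)).
.lambda_discrete <- function(masses, values) {
  stopifnot(length(masses) == length(values), all(masses >= 0))
  masses <- masses / sum(masses)
  breaks <- stats::qnorm(cumsum(masses))
  lo <- c(-Inf, breaks[-length(breaks)])
  ezg <- sum(values * (stats::dnorm(lo) - stats::dnorm(breaks)))
  mu <- sum(masses * values)
  v <- sum(masses * values^2) - mu^2
  if (v <= 0) return(0)
  ezg / sqrt(v)
}

# lambda for a continuous monotone transform, by quantile-grid quadrature.
.lambda_grid <- function(transform, n_grid = 200000L) {
  z <- stats::qnorm((seq_len(n_grid) - 0.5) / n_grid)
  g <- transform(z)
  if (stats::var(g) <= 0) return(0)
  stats::cor(z, g)
}

# Latent model shared by both generators: variable order, marginal
# transforms, attenuation factors, latent correlation matrix and ground
# truth. Raises an error if the implied latent matrix is not positive
# definite (infeasible correlation structure) before any sampling happens.
.build_latent_model <- function(config) {
  transforms <- list()
  lambda <- c()
  combos <- NULL
  if (config$core) {
    combos <- .drinking_combos(config$drinking_config, config$drinking_mix)
    lin <- function(m, s) { force(m); force(s); function(z) m + s * z }
    transforms$age <- lin(config$age_mean, config$age_sd)
    transforms$height <- lin(config$height_mean, config$height_sd)
    transforms$bmi <- lin(config$bmi_mean, config$bmi_sd)
    transforms$smoking <- local({
      mix <- config$smoking_mix
      function(z) findInterval(stats::pnorm(z), cumsum(mix),
                               rightmost.closed = TRUE) + 1L
    })
    transforms$alcohol_weekly_g <- local({
      cb <- combos
      function(z) {
        idx <- findInterval(stats::pnorm(z), c(0, cumsum(cb$mass)),
                            rightmost.closed = TRUE, all.inside = TRUE)
        cb$grams[idx]
      }
    })
    transforms$FVC <- lin(config$fvc_mean, config$fvc_sd)
    transforms$FEV1 <- lin(config$fev1_mean, config$fev1_sd)
    transforms$muscle_mass <- lin(config$muscle_mean, config$muscle_sd)
    transforms$grip <- lin(config$grip_mean, config$grip_sd)
    transforms$crp <- local({
      ml <- config$crp_meanlog; sl <- config$crp_sdlog
      function(z) exp(ml + sl * z)
    })
    transforms$sex <- local({
      mf <- config$male_fraction
      function(z) as.integer(stats::pnorm(z) <= mf)  # 1 = male
    })
    lambda <- c(
      age = 1, height = 1, bmi = 1,
      smoking = .lambda_discrete(config$smoking_mix, 0:2),
      alcohol_weekly_g = .lambda_discrete(combos$mass, combos$grams),
      FVC = 1, FEV1 = 1, muscle_mass = 1, grip = 1,
      crp = .lambda_grid(transforms$crp),
      sex = .lambda_discrete(c(config$male_fraction,
                               1 - config$male_fraction), c(1, 0)))
  }
  for (v in config$extra_vars) {
    if (v %in% names(transforms))
      stop("extra variable '", v, "' clashes with a core variable name",
           call. = FALSE)
    transforms[[v]] <- identity
    lambda[v] <- 1
  }
  vars <- names(transforms)
  p <- length(vars)
  if (p < 1L) stop("no variables to generate", call. = FALSE)
  Sigma <- diag(p)
  dimnames(Sigma) <- list(vars, vars)
  set_entry <- function(S, a, b, val, what) {
    if (!a %in% vars || !b %in% vars)
      stop(what, " references unknown variable: ",
           paste(setdiff(c(a, b), vars), collapse = ", "), call. = FALSE)
    if (a == b) stop(what, " links a variable to itself", call. = FALSE)
    if (S[a, b] != 0 && abs(S[a, b] - val) > 1e-12)
      stop("conflicting latent correlations requested for (", a, ", ", b,
           ")", call. = FALSE)
    S[a, b] <- S[b, a] <- val
    S
  }
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  planted_keys <- vapply(config$planted_edges, function(e)
    pair_key(e$var1, e$var2), character(1))
  conf_keys <- vapply(config$confounders, function(cf)
    if (length(cf$targets) == 2L) pair_key(cf$targets[1], cf$targets[2])
    else NA_character_, character(1))
  overlap <- intersect(planted_keys, conf_keys)
  if (length(overlap))
    stop("a confounded pair coincides with a planted direct edge: ",
         paste(overlap, collapse = "; "), call. = FALSE)
  conf_rows <- NULL
  for (cf in config$confounders) {
    if (!all(c("source", "targets", "strengths") %in% names(cf)) ||
        length(cf$targets) != 2L || length(cf$strengths) != 2L)
      stop("each confounder needs source, 2 targets and 2 strengths",
           call. = FALSE)
    a <- cf$strengths[1]; b <- cf$strengths[2]
    Sigma <- set_entry(Sigma, cf$source, cf$targets[1], a, "confounder")
    Sigma <- set_entry(Sigma, cf$source, cf$targets[2], b, "confounder")
    Sigma <- set_entry(Sigma, cf$targets[1], cf$targets[2], a * b,
                       "confounder")
    t1 <- sort(cf$targets)
    conf_rows <- rbind(conf_rows, data.frame(
      source = cf$source, var1 = t1[1], var2 = t1[2],
      strength1 = a, strength2 = b,
      implied_latent_r = a * b,
      implied_observed_r = a * b * lambda[[cf$targets[1]]] *
        lambda[[cf$targets[2]]],
      stringsAsFactors = FALSE))
  }
  edge_rows <- NULL
  for (e in config$planted_edges) {
    if (!e$var1 %in% vars || !e$var2 %in% vars)
      stop("planted edge references unknown variable: ",
           paste(setdiff(c(e$var1, e$var2), vars), collapse = ", "),
           call. = FALSE)
    latent <- e$r / (lambda[[e$var1]] * lambda[[e$var2]])
    if (!is.finite(latent) || abs(latent) >= 1)
      stop("target correlation ", e$r, " for (", e$var1, ", ", e$var2,
           ") is infeasible after marginal discretization", call. = FALSE)
    Sigma <- set_entry(Sigma, e$var1, e$var2, latent, "planted edge")
    v <- sort(c(e$var1, e$var2))
    edge_rows <- rbind(edge_rows, data.frame(
      var1 = v[1], var2 = v[2], latent_r = latent, target_r = e$r,
      stringsAsFactors = FALSE))
  }
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8)
    stop("infeasible correlation structure: implied latent matrix is not ",
         "positive definite (min eigenvalue ", format(min(ev), digits = 3),
         ")", call. = FALSE)
  truth <- structure(
    list(edges = edge_rows %||% data.frame(var1 = character(),
                                           var2 = character(),
                                           latent_r = numeric(),
                                           target_r = numeric()),
         confounded = conf_rows %||% data.frame(source = character(),
                                                var1 = character(),
                                                var2 = character(),
                                                strength1 = numeric(),
                                                strength2 = numeric(),
                                                implied_latent_r = numeric(),
                                                implied_observed_r =
                                                  numeric()),
         decline = config$decline,
         attenuation_beta = config$attenuation_beta,
         change_mix = config$change_mix,
         drinking_mix = config$drinking_mix,
         lambda = lambda),
    class = "ground_truth")
  list(vars = vars, transforms = transforms, lambda = lambda,
       Sigma = Sigma, combos = combos, truth = truth)
}

#' Generate a cross-sectional synthetic cohort
#'
#' Draws a joint Gaussian latent sample with the configured planted and
#' confounded structure, transforms marginals (category bands for drinking
#' answers, ordinal smoking, binary sex, lognormal CRP), derives weekly
#' alcohol grams from the sampled volume/frequency answers, and returns the
#' cohort together with its ground truth. Deterministic given the config
#' (including its seed).
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `table` (a [cohort_table()]) and `truth`
#'   (a `"ground_truth"` object).
#' @export
generate_cross_sectional <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  model <- .build_latent_model(config)
  set.seed(config$seed)
  Z <- .sample_latent(config$n, model$Sigma)
  build <- .latent_to_table(Z, model, config, config$timepoints[2])
  list(table = build, truth = model$truth)
}

.sample_latent <- function(n, Sigma) {
  E <- matrix(stats::rnorm(n * ncol(Sigma)), nrow = n)
  Z <- E %*% chol(Sigma)
  colnames(Z) <- colnames(Sigma)
  Z
}

.latent_to_table <- function(Z, model, config, timepoint) {
  n <- nrow(Z)
  cols <- list(subject_id = sprintf("S%06d", seq_len(n)))
  schema <- list()
  for (v in model$vars) {
    g <- model$transforms[[v]](Z[, v])
    if (config$core && v == "smoking") {
      lv <- c("never", "previous", "current")
      cols$smoking <- lv[g]
      schema$smoking <- variable_descriptor(
        "smoking", "ordinal", levels = lv,
        numeric_map = stats::setNames(0:2, lv))
    } else if (config$core && v == "sex") {
      cols$sex <- c("female", "male")[g + 1L]
      schema$sex <- variable_descriptor("sex", "binary",
                                        levels = c("female", "male"))
    } else if (config$core && v == "alcohol_weekly_g") {
      idx <- findInterval(stats::pnorm(Z[, v]),
                          c(0, cumsum(model$combos$mass)),
                          rightmost.closed = TRUE, all.inside = TRUE)
      cols$drink_volume <- model$combos$volume[idx]
      cols$drink_freq <- model$combos$frequency[idx]
      cols$alcohol_weekly_g <- model$combos$grams[idx]
      dc <- config$drinking_config
      schema$drink_volume <- variable_descriptor(
        "drink_volume", "ordinal", units = "g/day band",
        levels = names(dc$volume_means), numeric_map = dc$volume_means)
      schema$drink_freq <- variable_descriptor(
        "drink_freq", "ordinal", units = "days/week band",
        levels = names(dc$frequency_means), numeric_map = dc$frequency_means)
      schema$alcohol_weekly_g <- variable_descriptor(
        "alcohol_weekly_g", "continuous", units = "g/week")
    } else {
      units <- switch(v, age = "years", height = "cm",
                      bmi = "kg/m2", FVC = "L", FEV1 = "L",
                      muscle_mass = "kg", grip = "kg", crp = "mg/dL", "")
      if (v %in% c("FVC", "FEV1")) g <- pmax(g, 0.3)
      cols[[v]] <- g
      schema[[v]] <- variable_descriptor(v, "continuous", units = units)
    }
  }
  if (config$core) {
    cols$fev1_fvc_ratio <- 100 * cols$FEV1 / cols$FVC
    schema$fev1_fvc_ratio <- variable_descriptor("fev1_fvc_ratio",
                                                 "continuous", units = "%")
    cats <- c("never", "light", "moderate", "heavy")
    cols$drinking_category <- assign_drinking_category(
      cols$alcohol_weekly_g, config$drinking_config)
    schema$drinking_category <- variable_descriptor(
      "drinking_category", "ordinal", levels = cats,
      numeric_map = stats::setNames(0:3, cats))
  }
  cohort_table(as.data.frame(cols, stringsAsFactors = FALSE), schema,
               timepoint = timepoint)
}

#' Generate a paired longitudinal synthetic cohort
#'
#' The baseline table is a [generate_cross_sectional()] draw; the follow-up
#' applies the configured mean decline plus subject-level noise to FVC and
#' FEV1, ages subjects by `years_between`, and draws each subject's
#' weekly-alcohol change from `change_mix` (exactly zero for the "none"
#' group, magnitude uniform on (10, 100) g/week for "small" and (100, 300)
#' for "large", random sign, decreases floored at zero grams). The FVC
#' change mean is shifted by `attenuation_beta * (alcohol change / 100)`,
#' planting the dose-dependent attenuation of decline. Follow-up drinking
#' answers are re-labelled to the nearest achievable answer combination
#' (reporting coarseness only; analyses use the grams column).
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `paired` (a `"paired_cohort"`) and `truth`.
#' @export
generate_longitudinal <- function(config = synthetic_config(n = 1765,
                                                            fvc_mean = 3.58,
                                                            fvc_sd = 0.86)) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!config$core)
    stop("longitudinal generation needs the core checkup variables",
         call. = FALSE)
  cs <- generate_cross_sectional(config)
  base <- cs$table
  base$timepoint <- config$timepoints[1]
  n <- nrow(base$data)
  # follow-up draws continue the stream seeded inside the baseline draw
  grp <- sample(c("none", "small", "large"), n, replace = TRUE,
                prob = config$change_mix)
  mag_small <- stats::runif(n, 10, 100)
  mag_large <- stats::runif(n, 100, 300)
  sign_u <- stats::runif(n)
  g1 <- base$data$alcohol_weekly_g
  sgn <- ifelse(g1 == 0, 1, ifelse(sign_u < 0.5, -1, 1))
  mag <- ifelse(grp == "none", 0,
                ifelse(grp == "small", mag_small, mag_large))
  g2 <- pmax(0, g1 + sgn * mag)
  d_alc <- g2 - g1
  fu <- base$data
  fu$alcohol_weekly_g <- g2
  combos <- .drinking_combos(config$drinking_config, config$drinking_mix)
  nearest <- vapply(g2, function(g) which.min(abs(combos$grams - g)),
                    integer(1))
  fu$drink_volume <- combos$volume[nearest]
  fu$drink_freq <- combos$frequency[nearest]
  fu$drinking_category <- assign_drinking_category(g2,
                                                   config$drinking_config)
  fu$age <- fu$age + config$years_between
  dn <- config$delta_noise_sd
  dFVC <- (config$decline[["FVC"]] %||% 0) +
    config$attenuation_beta * d_alc / 100 +
    stats::rnorm(n, 0, dn[["FVC"]] %||% 0)
  fu$FVC <- pmax(fu$FVC + dFVC, 0.3)
  dFEV1 <- (config$decline[["FEV1"]] %||% 0) +
    stats::rnorm(n, 0, dn[["FEV1"]] %||% 0)
  fu$FEV1 <- pmax(fu$FEV1 + dFEV1, 0.3)
  fu$fev1_fvc_ratio <- 100 * fu$FEV1 / fu$FVC
  followup <- cohort_table(fu, base$variables,
                           timepoint = config$timepoints[2])
  paired <- structure(
    list(baseline = base, followup = followup,
         paired_ids = base$data$subject_id,
         exclusions = c(not_in_both = 0L, missing_required = 0L)),
    class = "paired_cohort")
  truth <- cs$truth
  truth$change_groups <- grp
  list(paired = paired, truth = truth)
}

#' Flatten a ground-truth object into a table
#'
#' One row per planted direct edge (`type = "direct"`), per confounded pair
#' (`type = "indirect"`) and per scalar generator parameter
#' (`type = "parameter"`), for test assertions and reports.
#'
#' @param truth A `"ground_truth"` object from a generator call.
#' @return A data.frame with columns `var1`, `var2`, `value`, `type`.
#' @export
truth_table <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  rows <- list()
  if (nrow(truth$edges))
    rows$direct <- data.frame(var1 = truth$edges$var1,
                              var2 = truth$edges$var2,
                              value = truth$edges$target_r,
                              type = "direct", stringsAsFactors = FALSE)
  if (nrow(truth$confounded))
    rows$indirect <- data.frame(var1 = truth$confounded$var1,
                                var2 = truth$confounded$var2,
                                value = truth$confounded$implied_observed_r,
                                type = "indirect", stringsAsFactors = FALSE)
  params <- c(attenuation_beta = truth$attenuation_beta,
              stats::setNames(truth$decline,
                              paste0("decline_", names(truth$decline))),
              stats::setNames(truth$change_mix,
                              paste0("change_mix_",
                                     names(truth$change_mix))))
  rows$params <- data.frame(var1 = names(params), var2 = "",
                            value = unname(params), type = "parameter",
                            stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", nrow(x$edges), " planted edges, ",
      nrow(x$confounded), " confounded pairs\n", sep = "")
  invisible(x)
}

# Moments of the realized weekly-alcohol change under a config, accounting
# for the flooring of decreases at zero grams and the forced-increase rule
# for never drinkers. Closed-form over the discrete baseline grams
# distribution and the uniform change-magnitude bands.
.alcohol_change_moments <- function(config) {
  combos <- .drinking_combos(config$drinking_config, config$drinking_mix)
  mix <- config$change_mix
  unif_mom <- function(a, b) c(m1 = (a + b) / 2, m2 = (a^2 + a * b + b^2) / 3)
  # E[min(m, g)^k] for m ~ U(a, b)
  min_mom <- function(g, a, b) {
    if (g <= a) return(c(m1 = g, m2 = g^2))
    if (g >= b) return(unif_mom(a, b))
    c(m1 = ((g^2 - a^2) / 2 + g * (b - g)) / (b - a),
      m2 = ((g^3 - a^3) / 3 + g^2 * (b - g)) / (b - a))
  }
  bands <- list(small = c(10, 100), large = c(100, 300))
  e1 <- 0; e2 <- 0
  for (i in seq_len(nrow(combos))) {
    g <- combos$grams[i]; w <- combos$mass[i]
    for (bn in names(bands)) {
      a <- bands[[bn]][1]; b <- bands[[bn]][2]
      up <- unif_mom(a, b)
      if (g == 0) {        # forced increase
        e1 <- e1 + w * mix[[bn]] * up[["m1"]]
        e2 <- e2 + w * mix[[bn]] * up[["m2"]]
      } else {             # half increase, half floored decrease
        dn <- min_mom(g, a, b)
        e1 <- e1 + w * mix[[bn]] * 0.5 * (up[["m1"]] - dn[["m1"]])
        e2 <- e2 + w * mix[[bn]] * 0.5 * (up[["m2"]] + dn[["m2"]])
      }
    }
  }
  c(mean = e1, var = e2 - e1^2)
}

#' Attenuation coefficient for a target delta-correlation
#'
#' Solves for the `attenuation_beta` that makes the population correlation
#' between weekly-alcohol change and FVC change equal `target_r` under the
#' config's change mixture and FVC change-noise SD:
#' `beta = R * sigma / (sd(d_alc)/100 * sqrt(1 - R^2))`, with `sd(d_alc)`
#' the closed-form SD of the realized alcohol change (floored decreases
#' included).
#'
#' @param target_r Desired population correlation of the two change scores.
#' @param config A [synthetic_config()].
#' @return The `attenuation_beta` value (L per +100 g/week).
#' @export
attenuation_for_delta_correlation <- function(target_r,
                                              config = synthetic_config()) {
  stopifnot(abs(target_r) < 1)
  mom <- .alcohol_change_moments(config)
  sdd <- sqrt(mom[["var"]]) / 100
  sigma <- config$delta_noise_sd[["FVC"]]
  target_r * sigma / (sdd * sqrt(1 - target_r^2))
}
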