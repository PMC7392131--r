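#' Configuration for the synthetic loyalty-card cohort generator
#'
#' The generator emulates the structure a consumer-panel bias analysis needs:
#' a reference adult population with realistic sociodemographic margins, a
#' consent mechanism that over-represents women, higher-educated and employed
#' people and under-represents the youngest and oldest age groups,
#' questionnaire nonresponse, right-skewed zero-inflated grocery purchase
#' amounts, and a 5-category self-assessed degree of loyalty correlated with
#' purchase volume.
#'
#' The joint covariate distribution is built sequentially
#' (sex, age | sex, then education / occupation / marital status given age,
#' children given age and marital status) from conditional probability
#' tables, which reproduces the two-way structure raking calibrates against
#' without requiring a full joint specification.
#'
#' @param population_size Number of reference-population individuals.
#' @param seed Integer seed; mandatory, every run is deterministic given it.
#' @param sex_probs Named probabilities for the sex categories.
#' @param age_probs Named probabilities for the six age groups, or a
#'   sex-by-age matrix of conditional probabilities.
#' @param education_probs,occupation_probs,marital_probs Age-by-category
#'   conditional probability matrices (rows = age groups, rows sum to 1).
#' @param children_probs Age-by-marital matrix of probabilities that a
#'   household includes children under 18.
#' @param selection_coefs Logistic consent model: list with `intercept`
#'   (log-odds) and optional named vectors per variable of category log-odds
#'   offsets, e.g. `list(intercept = qlogis(0.04), sex = c(women = 0.45))`.
#' @param nonresponse_rate Probability a consenter skips the questionnaire.
#' @param nonresponse_mechanism `"mcar"` (completely at random, default) or
#'   `"covariate"` (depends on covariates via `nonresponse_coefs`).
#' @param nonresponse_coefs Logistic coefficients for covariate-dependent
#'   nonresponse (same structure as `selection_coefs`); the intercept is
#'   calibrated so the marginal rate stays near `nonresponse_rate`.
#' @param sexage_missing_rate Small probability that the register variables
#'   sex/age are themselves missing (such units can receive no weight).
#' @param loyalty_probs Probabilities of the five latent loyalty propensity
#'   classes, lowest share of purchases first.
#' @param loyalty_multipliers Multiplier applied to purchase totals per
#'   loyalty class; strictly increasing by default.
#' @param purchase_model Data.frame with one row per food/product group:
#'   `group`, `zero_inflation` (probability of no purchases in 2 years),
#'   `meanlog_eur`, `sdlog_eur`, `meanlog_kg`, `sdlog_kg` (log-normal
#'   parameters of the 2-year totals), `events_rate` (mean number of purchase
#'   events beyond the first).
#' @param never_purchase_rate Probability a consenter records no purchases at
#'   all over the period (about half a percent of participants buy nothing).
#' @param margin_pairs List of variable-name vectors defining the raking
#'   margins the pipeline uses; defaults to [default_margin_pairs()]. Small
#'   cohorts should use fewer/coarser margins so no sample cell is empty.
#' @param period_start,period_end Observation period (ISO dates).
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(population_size = 200000L,
                             seed = 1L,
                             sex_probs = c(women = 0.5112, men = 0.4888),
                             age_probs = default_age_probs(),
                             education_probs = default_education_probs(),
                             occupation_probs = default_occupation_probs(),
                             marital_probs = default_marital_probs(),
                             children_probs = default_children_probs(),
                             selection_coefs = default_selection_coefs(),
                             nonresponse_rate = 0.22,
                             nonresponse_mechanism = c("mcar", "covariate"),
                             nonresponse_coefs = NULL,
                             sexage_missing_rate = 21 / 47066,
                             loyalty_probs = c(0.0625, 0.1279, 0.1685,
                                               0.2525, 0.3886),
                             loyalty_multipliers = c(0.30, 0.64, 1.00,
                                                     1.46, 1.92),
                             purchase_model = default_purchase_model(),
                             never_purchase_rate = 0.005,
                             margin_pairs = default_margin_pairs(),
                             period_start = "2017-01-01",
                             period_end = "2018-12-31") {
  nonresponse_mechanism <- match.arg(nonresponse_mechanism)
  cfg <- list(population_size = as.integer(population_size),
              seed = as.integer(seed),
              sex_probs = sex_probs, age_probs = age_probs,
              education_probs = education_probs,
              occupation_probs = occupation_probs,
              marital_probs = marital_probs,
              children_probs = children_probs,
              selection_coefs = selection_coefs,
              nonresponse_rate = nonresponse_rate,
              nonresponse_mechanism = nonresponse_mechanism,
              nonresponse_coefs = nonresponse_coefs,
              sexage_missing_rate = sexage_missing_rate,
              loyalty_probs = loyalty_probs,
              loyalty_multipliers = loyalty_multipliers,
              purchase_model = purchase_model,
              never_purchase_rate = never_purchase_rate,
              margin_pairs = margin_pairs,
              period_start = as.Date(period_start),
              period_end = as.Date(period_end))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$population_size < 1L) stop("population_size must be >= 1")
  if (is.na(cfg$seed)) stop("seed is mandatory")
  check_probs <- function(p, field) {
    if (anyNA(p) || any(p < 0) || any(p > 1))
      stop("probabilities outside [0,1] in '", field, "'")
    sums <- if (is.matrix(p)) rowSums(p) else sum(p)
    if (any(abs(sums - 1) > 1e-9))
      stop("probabilities in '", field, "' must sum to 1 (off by ",
           signif(max(abs(sums - 1)), 3), ")")
  }
  check_probs(cfg$sex_probs, "sex_probs")
  check_probs(cfg$age_probs, "age_probs")
  check_probs(cfg$education_probs, "education_probs")
  check_probs(cfg$occupation_probs, "occupation_probs")
  check_probs(cfg$marital_probs, "marital_probs")
  check_probs(cfg$loyalty_probs, "loyalty_probs")
  if (anyNA(cfg$children_probs) || any(cfg$children_probs < 0) ||
      any(cfg$children_probs > 1))
    stop("probabilities outside [0,1] in 'children_probs'")
  if (cfg$nonresponse_rate < 0 || cfg$nonresponse_rate > 1)
    stop("nonresponse_rate outside [0,1]")
  if (cfg$sexage_missing_rate < 0 || cfg$sexage_missing_rate > 1)
    stop("sexage_missing_rate outside [0,1]")
  if (cfg$never_purchase_rate < 0 || cfg$never_purchase_rate > 1)
    stop("never_purchase_rate outside [0,1]")
  pm <- cfg$purchase_model
  need <- c("group", "zero_inflation", "meanlog_eur", "sdlog_eur",
            "meanlog_kg", "sdlog_kg", "events_rate")
  if (!all(need %in% names(pm)))
    stop("purchase_model must have columns: ", paste(need, collapse = ", "))
  if (any(pm$zero_inflation < 0 | pm$zero_inflation > 1))
    stop("probabilities outside [0,1] in 'purchase_model$zero_inflation'")
  if (any(pm$sdlog_eur <= 0) || any(pm$sdlog_kg <= 0))
    stop("non-positive scale parameter in 'purchase_model'")
  if (any(diff(cfg$loyalty_multipliers) < 0))
    warning("loyalty_multipliers are not non-decreasing")
  if (cfg$period_start >= cfg$period_end)
    stop("period_start must precede period_end")
  invisible(cfg)
}

age_levels <- function() c("<=29", "30-39", "40-49", "50-59", "60-69", ">=70")

default_age_probs <- function() {
  c("<=29" = 0.1804, "30-39" = 0.1580, "40-49" = 0.1486,
    "50-59" = 0.1652, "60-69" = 0.1658, ">=70" = 0.1820)
}

cond_matrix <- function(rows, cols, values) {
  matrix(values, nrow = length(rows), ncol = length(cols), byrow = TRUE,
         dimnames = list(rows, cols))
}

default_education_probs <- function() {
  cond_matrix(age_levels(),
              c("basic", "upper_secondary", "bachelor", "master"),
              c(0.20, 0.55, 0.18, 0.07,
                0.12, 0.42, 0.28, 0.18,
                0.14, 0.42, 0.26, 0.18,
                0.20, 0.45, 0.22, 0.13,
                0.30, 0.40, 0.20, 0.10,
                0.50, 0.30, 0.13, 0.07))
}

default_occupation_probs <- function() {
  cond_matrix(age_levels(),
              c("employed", "unemployed", "student", "retired", "other"),
              c(0.545, 0.080, 0.250, 0.015, 0.110,
                0.820, 0.080, 0.040, 0.010, 0.050,
                0.850, 0.070, 0.010, 0.030, 0.040,
                0.795, 0.080, 0.010, 0.100, 0.015,
                0.400, 0.050, 0.010, 0.520, 0.020,
                0.030, 0.010, 0.020, 0.920, 0.020))
}

default_marital_probs <- function() {
  cond_matrix(age_levels(),
              c("married", "single", "divorced", "widowed"),
              c(0.120, 0.840, 0.025, 0.015,
                0.450, 0.465, 0.070, 0.015,
                0.550, 0.305, 0.130, 0.015,
                0.550, 0.250, 0.180, 0.020,
                0.550, 0.200, 0.190, 0.060,
                0.480, 0.150, 0.150, 0.220))
}

default_children_probs <- function() {
  cond_matrix(age_levels(),
              c("married", "single", "divorced", "widowed"),
              c(0.55, 0.15, 0.25, 0.10,
                0.75, 0.25, 0.45, 0.30,
                0.70, 0.20, 0.45, 0.30,
                0.25, 0.08, 0.15, 0.08,
                0.03, 0.02, 0.03, 0.02,
                0.01, 0.01, 0.01, 0.01))
}

default_selection_coefs <- function() {
  list(intercept = stats::qlogis(0.04),
       sex = c(women = 0.45),
       age_group = c("<=29" = -0.45, ">=70" = -0.95),
       education = c(basic = -0.90, bachelor = 0.35, master = 0.55),
       occupation = c(employed = 0.30, retired = -0.30))
}

#' @rdname generator_config
#' @export
default_purchase_model <- function() {
  data.frame(
    group = c("vegetables", "skimmed_milk_sour_milk",
              "sugar_sweetened_beverages", "rye_bread",
              "red_meat_processed_meat", "fat_spreads",
              "sweets_chocolate", "other_groceries"),
    zero_inflation = c(0.03, 0.26, 0.04, 0.04, 0.03, 0.04, 0.03, 0.005),
    meanlog_eur = log(c(284.3, 23.0, 45.3, 50.7, 386.5, 53.1, 119.2, 2500)),
    sdlog_eur = c(1.05, 1.60, 1.30, 1.20, 1.20, 1.10, 1.20, 0.90),
    meanlog_kg = log(c(76.6, 23.5, 23.5, 12.9, 47.5, 10.1, 10.3, 600)),
    sdlog_kg = c(1.10, 1.70, 1.40, 1.30, 1.20, 1.20, 1.20, 1.00),
    events_rate = c(8, 4, 6, 6, 8, 5, 6, 20),
    stringsAsFactors = FALSE)
}

#' Implied one-way marginal distributions of a generator configuration
#'
#' For variables generated conditionally on age, the implied marginal is the
#' age-weighted mixture of the conditional rows. These are the targets the
#' generated population's empirical margins converge to.
#'
#' @param config A [generator_config].
#' @return Named list of named probability vectors, one per variable.
#' @export
implied_margins <- function(config) {
  p_age <- if (is.matrix(config$age_probs)) {
    drop(config$sex_probs %*% config$age_probs)
  } else config$age_probs
  mix <- function(m) drop(p_age %*% m)
  ch <- config$children_probs
  p_children <- 0
  for (a in seq_along(p_age))
    p_children <- p_children +
      p_age[a] * sum(config$marital_probs[a, ] * ch[a, ])
  list(sex = config$sex_probs,
       age_group = p_age,
       education = mix(config$education_probs),
       occupation = mix(config$occupation_probs),
       marital = mix(config$marital_probs),
       children = c(yes = unname(p_children), no = unname(1 - p_children)))
}

sample_cat <- function(n, probs) {
  names(probs)[1L + findInterval(stats::runif(n), cumsum(probs)[-length(probs)])]
}

#' Generate a synthetic reference population
#'
#' Draws `population_size` individuals with the sequential covariate scheme
#' described in [generator_config()]. Every field is non-missing; ids are
#' unique integers.
#'
#' @param config A [generator_config].
#' @return Data.frame with columns `id`, `sex`, `age_group`, `marital`,
#'   `education`, `occupation`, `children` ("yes"/"no").
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$population_size
  sex <- sample_cat(n, config$sex_probs)
  if (is.matrix(config$age_probs)) {
    age <- character(n)
    for (s in rownames(config$age_probs)) {
      k <- sex == s
      age[k] <- sample_cat(sum(k), config$age_probs[s, ])
    }
  } else {
    age <- sample_cat(n, config$age_probs)
  }
  draw_given_age <- function(m) {
    out <- character(n)
    for (a in rownames(m)) {
      k <- age == a
      if (any(k)) out[k] <- sample_cat(sum(k), m[a, ])
    }
    out
  }
  education <- draw_given_age(config$education_probs)
  occupation <- draw_given_age(config$occupation_probs)
  marital <- draw_given_age(config$marital_probs)
  p_child <- config$children_probs[cbind(match(age, rownames(config$children_probs)),
                                         match(marital, colnames(config$children_probs)))]
  children <- ifelse(stats::runif(n) < p_child, "yes", "no")
  data.frame(id = seq_len(n), sex = sex, age_group = age, marital = marital,
             education = education, occupation = occupation,
             children = children, stringsAsFactors = FALSE)
}

linear_predictor <- function(data, coefs) {
  lp <- rep(coefs$intercept %||% 0, nrow(data))
  for (v in setdiff(names(coefs), "intercept")) {
    if (!v %in% names(data))
      stop("selection coefficient references unknown variable: ", v)
    unknown <- setdiff(names(coefs[[v]]), unique(data[[v]]))
    if (length(unknown))
      stop("selection coefficient references unknown category '",
           unknown[1], "' of variable '", v, "'")
    offs <- coefs[[v]][data[[v]]]
    offs[is.na(offs)] <- 0
    lp <- lp + offs
  }
  lp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw a biased consent sample from a population
#'
#' Each individual consents independently with probability
#' `plogis(linear predictor)` of the logistic selection model, emulating
#' volunteer bias. The true inclusion probability is carried in the
#' oracle-only column `.oracle_p_consent`, which analysis functions must
#' never read (it exists so tests can check bias-correction against truth).
#'
#' @param population Output of [generate_population()].
#' @param selection_coefs See [generator_config()].
#' @param seed Integer seed.
#' @return The consenting subset, with `.oracle_p_consent` appended.
#' @export
sample_consenters <- function(population, selection_coefs, seed) {
  set.seed(seed)
  p <- stats::plogis(linear_predictor(population, selection_coefs))
  keep <- stats::runif(nrow(population)) < p
  out <- population[keep, , drop = FALSE]
  out$.oracle_p_consent <- p[keep]
  rownames(out) <- NULL
  out
}

#' Apply questionnaire nonresponse
#'
#' Nonresponders have every questionnaire field (`marital`, `education`,
#' `occupation`, `children`, and `loyalty` if present) set to missing.
#' `sex` and `age_group` come from the retailer register and are left intact
#' (a small independent `sexage_missing_rate` can blank those too, emulating
#' units that can receive no weight at all).
#'
#' @param participants Consenter table.
#' @param rate Marginal nonresponse probability in `[0, 1]`.
#' @param mechanism `"mcar"` or `"covariate"`.
#' @param seed Integer seed.
#' @param coefs Logistic coefficients (without meaningful intercept) for the
#'   covariate-dependent mechanism; the intercept is set so the average
#'   nonresponse probability equals `rate`.
#' @param sexage_missing_rate Probability of missing register sex/age.
#' @return `participants` with missingness applied and a logical column
#'   `responded`.
#' @export
apply_nonresponse <- function(participants, rate, mechanism = c("mcar", "covariate"),
                              seed, coefs = NULL, sexage_missing_rate = 0) {
  mechanism <- match.arg(mechanism)
  stopifnot(rate >= 0, rate <= 1)
  set.seed(seed)
  n <- nrow(participants)
  if (mechanism == "mcar" || is.null(coefs)) {
    p_nr <- rep(rate, n)
  } else {
    lp <- linear_predictor(participants, c(list(intercept = 0), coefs))
    # calibrate the intercept so the mean nonresponse probability hits `rate`
    f <- function(a) mean(stats::plogis(a + lp)) - rate
    a <- if (rate %in% c(0, 1)) stats::qlogis(rate) else
      stats::uniroot(f, c(-20, 20))$root
    p_nr <- stats::plogis(a + lp)
  }
  nonresp <- stats::runif(n) < p_nr
  qfields <- intersect(c("marital", "education", "occupation", "children",
                         "loyalty"), names(participants))
  participants[nonresp, qfields] <- NA
  if (sexage_missing_rate > 0) {
    blank <- stats::runif(n) < sexage_missing_rate
    participants[blank, c("sex", "age_group")] <- NA
  }
  participants$responded <- !nonresp
  participants
}

#' Assign the self-reported degree-of-loyalty category
#'
#' Bins the share `100 * focal_spend / total_spend` into the five ordinal
#' categories `0%-20%`, `21%-40%`, `41%-60%`, `61%-80%`, `81%-100%`.
#' A share falling exactly on 20/40/60/80 goes to the lower-labelled bin
#' (the printed labels are closed intervals). Zero `total_spend` yields a
#' missing category.
#'
#' @param focal_spend,total_spend Non-negative vectors,
#'   `focal_spend <= total_spend`.
#' @return Ordered factor with the five loyalty levels (NA where undefined).
#' @export
assign_loyalty <- function(focal_spend, total_spend) {
  if (any(focal_spend < 0, na.rm = TRUE) ||
      any(focal_spend > total_spend, na.rm = TRUE))
    stop("need 0 <= focal_spend <= total_spend")
  share <- ifelse(total_spend > 0, 100 * focal_spend / total_spend, NA_real_)
  cut(share, breaks = c(-Inf, 20, 40, 60, 80, Inf),
      labels = loyalty_levels(), right = TRUE, ordered_result = TRUE)
}

loyalty_levels <- function() {
  c("0%-20%", "21%-40%", "41%-60%", "61%-80%", "81%-100%")
}

#' Draw latent loyalty classes and self-reported categories
#'
#' Each participant receives a latent loyalty propensity class (1-5) with the
#' configured probabilities; their share of spending at the focal retailer is
#' drawn uniformly within that class's 20-point band, and the self-reported
#' category is recovered through [assign_loyalty()]. Purchase totals later
#' scale with the class's multiplier, which is what links the self-report to
#' observed purchase volume.
#'
#' @param participants Consenter table.
#' @param loyalty_probs Probabilities of the five classes.
#' @param seed Integer seed.
#' @return `participants` with integer `loyalty_class` and factor `loyalty`.
#' @export
draw_loyalty <- function(participants, loyalty_probs, seed) {
  stopifnot(length(loyalty_probs) == 5L)
  set.seed(seed)
  n <- nrow(participants)
  cls <- 1L + findInterval(stats::runif(n),
                           cumsum(loyalty_probs)[-5])
  lo <- c(0, 20, 40, 60, 80)[cls]
  hi <- c(20, 40, 60, 80, 100)[cls]
  share <- stats::runif(n, lo + 1e-9, hi)  # open at the lower edge
  participants$loyalty_class <- cls
  participants$loyalty <- assign_loyalty(share, rep(100, n))
  participants
}

#' Generate a synthetic transaction table
#'
#' For each participant and product group, a Bernoulli draw with the group's
#' zero-inflation probability decides whether anything was bought over the
#' observation period; conditional 2-year totals of expenditure (EUR) and
#' weight (kg) are log-normal, scaled by the participant's loyalty
#' multiplier. Totals are split over `1 + Poisson(events_rate)` purchase
#' events with uniform random timestamps in the period.
#'
#' @param participants Table with `id` and (optionally) `loyalty_class`.
#' @param purchase_model See [generator_config()].
#' @param period_start,period_end Observation period (Dates or ISO strings).
#' @param seed Integer seed.
#' @param loyalty_multipliers Per-class multipliers (ignored without
#'   `loyalty_class`).
#' @param never_purchase_rate Probability a participant records no purchases
#'   at all.
#' @return Data.frame `id`, `timestamp` (Date), `product_group`, `eur`, `kg`,
#'   sorted by id, timestamp.
#' @export
generate_transactions <- function(participants, purchase_model,
                                  period_start = "2017-01-01",
                                  period_end = "2018-12-31", seed = 1L,
                                  loyalty_multipliers = rep(1, 5),
                                  never_purchase_rate = 0) {
  period_start <- as.Date(period_start)
  period_end <- as.Date(period_end)
  if (period_start >= period_end) stop("period_start must precede period_end")
  if (any(purchase_model$sdlog_eur <= 0) || any(purchase_model$sdlog_kg <= 0))
    stop("non-positive scale parameter in purchase_model")
  set.seed(seed)
  n <- nrow(participants)
  mult <- if ("loyalty_class" %in% names(participants))
    loyalty_multipliers[participants$loyalty_class] else rep(1, n)
  days <- as.integer(period_end - period_start)
  ever_buys <- stats::runif(n) >= never_purchase_rate
  pieces <- vector("list", nrow(purchase_model))
  for (g in seq_len(nrow(purchase_model))) {
    pm <- purchase_model[g, ]
    buys <- ever_buys & stats::runif(n) >= pm$zero_inflation
    nb <- sum(buys)
    if (nb == 0L) next
    tot_eur <- stats::rlnorm(nb, pm$meanlog_eur, pm$sdlog_eur) * mult[buys]
    tot_kg <- stats::rlnorm(nb, pm$meanlog_kg, pm$sdlog_kg) * mult[buys]
    nev <- 1L + stats::rpois(nb, pm$events_rate * mult[buys])
    idx <- rep.int(seq_len(nb), nev)
    # split totals over events with uniform spacings (normalized within id)
    u <- stats::runif(length(idx))
    usum <- rowsum_by_index(u, idx, nb)
    frac <- u / usum[idx]
    pieces[[g]] <- data.frame(
      id = rep.int(participants$id[buys], nev),
      timestamp = period_start + floor(stats::runif(length(idx)) * (days + 1)),
      product_group = pm$group,
      eur = tot_eur[idx] * frac,
      kg = tot_kg[idx] * frac,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(id = integer(), timestamp = as.Date(character()),
                      product_group = character(), eur = numeric(),
                      kg = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$id, out$timestamp, out$product_group,
                   out$eur, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
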