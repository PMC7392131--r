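#' Recruitment-flow percentages
#'
#' Recomputes each recruitment stage's share of its denominator the way a
#' participant flow chart prints them: contacted as an integer percentage of
#' card owners, consented as an integer percentage of contacted, questionnaire
#' responders as an integer percentage of consenters, and purchasers (at
#' least one grocery item) to one decimal, also of consenters.
#'
#' @param owners Number of loyalty-card owners assessed for eligibility.
#' @param contacted Number contacted.
#' @param consented Number who consented.
#' @param responded Number who answered the background questionnaire.
#' @param purchasers Number with at least one purchase.
#' @return Data.frame `stage`, `count`, `denominator`, `pct` (printed
#'   precision) and `pct_exact`.
#' @examples
#' recruitment_flow(2400000, 1214663, 47066, 36621, 46825)
#' @export
recruitment_flow <- function(owners, contacted, consented, responded,
                             purchasers) {
  counts <- c(owners = owners, contacted = contacted, consented = consented,
              responded = responded, purchasers = purchasers)
  if (any(counts < 0)) stop("negative count")
  if (contacted > owners || consented > contacted || responded > consented ||
      purchasers > consented)
    stop("inconsistent flow counts: each stage must not exceed its denominator")
  denom <- c(NA, owners, contacted, consented, consented)
  exact <- ifelse(!is.na(denom) & denom > 0, 100 * counts / denom,
                  c(NA, 0, 0, 0, 0))
  printed <- c(NA, round(exact[2]), round(exact[3]), round(exact[4]),
               round(exact[5], 1))
  data.frame(stage = names(counts), count = as.numeric(counts),
             denominator = denom, pct = unname(printed),
             pct_exact = unname(exact), row.names = NULL)
}

#' Default raking margin variable pairs
#'
#' The margin set used when nothing else is configured: eight two-way tables
#' (sex by age, sex by education, sex by marital status, sex by occupation,
#' age by education, age by marital status, age by occupation, education by
#' occupation) plus the one-way children-in-household table, the combination
#' for which reference two-way tables are typically available.
#'
#' @return List of character vectors of variable names.
#' @export
default_margin_pairs <- function() {
  list(c("sex", "age_group"), c("sex", "education"), c("sex", "marital"),
       c("sex", "occupation"), c("age_group", "education"),
       c("age_group", "marital"), c("age_group", "occupation"),
       c("education", "occupation"), "children")
}

#' Build margin specs from a reference population table
#'
#' Tabulates the requested one-/two-way margins directly from a unit-level
#' population table (the synthetic truth, or any census extract).
#'
#' @param population Data.frame of reference-population units.
#' @param pairs List of variable-name vectors (length 1 or 2); defaults to
#'   [default_margin_pairs()].
#' @return List of [margin_spec] objects.
#' @export
population_margins <- function(population, pairs = default_margin_pairs()) {
  lapply(pairs, function(v) {
    tab <- tabulate_sample(population, v)
    margin_spec(tab, v, source = "population tabulation")
  })
}

#' Unweighted vs weighted sample shares against population shares
#'
#' The bias-characterization table: for each variable, the population share
#' of each category, the unweighted sample share, the weighted share, and
#' absolute errors of both against the population. Shares in percent,
#' rounded to two decimals.
#'
#' @param population,sample Data.frames with the variables as columns.
#' @param weights Data.frame `id`, `weight` aligned to `sample$id`.
#' @param variables Variables to compare.
#' @return Data.frame `variable`, `category`, `population_pct`,
#'   `sample_pct`, `weighted_pct`, `abs_err_unweighted`, `abs_err_weighted`.
#' @export
bias_comparison <- function(population, sample, weights,
                            variables = c("sex", "age_group", "marital",
                                          "education", "occupation",
                                          "children")) {
  w <- weights$weight[match(sample$id, weights$id)]
  rows <- list()
  for (v in variables) {
    ptab <- tabulate_sample(population, v)
    ppct <- 100 * ptab / sum(ptab)
    stab <- tabulate_sample(sample, v, levels = stats::setNames(
      list(dimnames(ptab)[[1]]), v))
    spct <- 100 * stab / sum(stab)
    ok <- !is.na(w)
    wtab <- tabulate_sample(sample[ok, , drop = FALSE], v, weights = w[ok],
                            levels = stats::setNames(list(dimnames(ptab)[[1]]), v))
    wpct <- 100 * wtab / sum(wtab)
    rows[[v]] <- data.frame(
      variable = v, category = dimnames(ptab)[[1]],
      population_pct = round(as.numeric(ppct), 2),
      sample_pct = round(as.numeric(spct), 2),
      weighted_pct = round(as.numeric(wpct), 2),
      abs_err_unweighted = abs(as.numeric(spct) - as.numeric(ppct)),
      abs_err_weighted = abs(as.numeric(wpct) - as.numeric(ppct)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full synthetic bias-correction pipeline
#'
#' Generates (or accepts) a population, draws the biased consent sample,
#' applies questionnaire nonresponse, simulates transactions, builds
#' two-phase raking weights, scores RFM, summarizes food groups weighted and
#' unweighted, and profiles the loyalty groups. All outputs are written as
#' CSV under `out_dir` together with a plain-text run log; a rerun with the
#' same config writes byte-identical tables.
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @param mapping Product-to-food-group mapping passed to [map_products()];
#'   defaults to the identity mapping of the generator's product groups.
#' @return List of class `pipeline_result`: `population` margins table,
#'   `participants`, `weights` (a `weight_result`), `comparison`
#'   (bias-comparison table), `rfm`, `food_summary`, `profile`, `flow`,
#'   `coverage`.
#' @export
run_pipeline <- function(config, out_dir = NULL, mapping = NULL) {
  stopifnot(inherits(config, "generator_config"))
  pop <- generate_population(config)
  consent <- sample_consenters(pop, config$selection_coefs,
                               seed = config$seed + 1L)
  consent <- draw_loyalty(consent, config$loyalty_probs,
                          seed = config$seed + 2L)
  tx <- generate_transactions(consent, config$purchase_model,
                              config$period_start, config$period_end,
                              seed = config$seed + 3L,
                              loyalty_multipliers = config$loyalty_multipliers,
                              never_purchase_rate = config$never_purchase_rate)
  participants <- apply_nonresponse(consent, config$nonresponse_rate,
                                    config$nonresponse_mechanism,
                                    seed = config$seed + 4L,
                                    coefs = config$nonresponse_coefs,
                                    sexage_missing_rate = config$sexage_missing_rate)
  analysis_cols <- !startsWith(names(participants), ".oracle_")
  participants_analysis <- participants[, analysis_cols, drop = FALSE]

  margins <- population_margins(pop, config$margin_pairs)
  reduced <- population_margins(pop, list(c("sex", "age_group")))
  wr <- two_phase_weights(participants_analysis, margins, reduced)

  comparison <- bias_comparison(pop, participants_analysis, wr$weights)

  if (is.null(mapping))
    mapping <- data.frame(product_group_code = config$purchase_model$group,
                          food_group = ifelse(
                            config$purchase_model$group %in% food_group_levels(),
                            config$purchase_model$group, "unassigned"))
  tx <- map_products(tx, mapping)
  coverage <- attr(tx, "coverage")
  scores <- rfm_scores(tx, reference_date = config$period_end)
  fs <- participant_food_summary(tx)
  # never-purchasers carry a weight but no purchase rows; drop them here
  w_purch <- wr$weights[wr$weights$id %in% fs$id, , drop = FALSE]
  food_summary <- summarize_food_groups(fs, weights = w_purch)
  profile <- loyalty_profile(participants_analysis, scores = scores,
                             summaries = fs, weights = wr$weights)
  flow <- recruitment_flow(owners = config$population_size,
                           contacted = config$population_size,
                           consented = nrow(consent),
                           responded = sum(participants$responded),
                           purchasers = length(unique(tx$id)))

  result <- structure(list(config = config, participants = participants,
                           weights = wr, comparison = comparison,
                           rfm = scores, food_summary = food_summary,
                           profile = profile, flow = flow,
                           coverage = coverage),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                          row.names = FALSE)
  wcsv(result$weights$weights, "weights.csv")
  wcsv(result$comparison, "bias_comparison.csv")
  wcsv(result$rfm, "rfm_scores.csv")
  wcsv(result$food_summary, "food_summary.csv")
  wcsv(result$flow, "recruitment_flow.csv")
  wcsv(result$profile$demographics, "loyalty_demographics.csv")
  wcsv(result$profile$demographic_tests, "loyalty_demographic_tests.csv")
  if (!is.null(result$profile$food)) {
    wcsv(result$profile$food$summary, "loyalty_food_summary.csv")
    wcsv(result$profile$food$totals, "loyalty_food_totals.csv")
  }
  log <- c(
    "cartrake pipeline run",
    paste0("package version: ",
           as.character(utils::packageVersion("cartrake"))),
    paste0("seed: ", result$config$seed),
    paste0("population_size: ", result$config$population_size),
    paste0("consenters: ", nrow(result$participants)),
    paste0("weighted units: ", nrow(result$weights$weights)),
    paste0("excluded (missing sex/age): ",
           length(result$weights$excluded_ids)),
    sprintf("raking converged: %s (max discrepancy %.3g)",
            all(result$weights$converged), result$weights$max_discrepancy),
    sprintf("trimmed: %d at lower, %d at upper bound",
            result$weights$trimmed["lower"], result$weights$trimmed["upper"]),
    sprintf("weight sum: %.6f", sum(result$weights$weights$weight)),
    sprintf("food-mapping coverage: %.1f%%", result$coverage$coverage_pct),
    "config echo:",
    utils::capture.output(utils::str(unclass(result$config), digits.d = 6)))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("cartrake pipeline result\n")
  cat("  consenters:", nrow(x$participants), "of",
      x$config$population_size, "population units\n")
  print(x$weights)
  cat("  mean |share error| unweighted: ",
      sprintf("%.3f", mean(x$comparison$abs_err_unweighted)),
      "pp, weighted: ",
      sprintf("%.3f", mean(x$comparison$abs_err_weighted)), "pp\n")
  invisible(x)
}
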