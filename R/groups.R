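#' Pearson chi-square test of independence
#'
#' Classical Pearson statistic `sum((O - E)^2 / E)` on an r-by-c contingency
#' table with expected counts from the product of the margins,
#' `df = (r-1)(c-1)`, asymptotic p-value, no continuity correction. Used to
#' compare sociodemographic distributions across loyalty groups.
#'
#' @param contingency Numeric matrix or table of observed counts.
#' @return List `statistic`, `df`, `p_value`, `expected`.
#' @examples
#' chi_square_test(matrix(c(10, 20, 20, 10), 2))$statistic  # 6.667
#' @export
chi_square_test <- function(contingency) {
  x <- as.matrix(contingency)
  if (any(x < 0) || anyNA(x)) stop("counts must be non-negative, non-missing")
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need at least a 2x2 table")
  n <- sum(x)
  expected <- outer(rowSums(x), colSums(x)) / n
  if (any(expected == 0))
    stop("zero expected count; collapse empty categories before testing")
  stat <- sum((x - expected)^2 / expected)
  df <- (nrow(x) - 1L) * (ncol(x) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

#' Kruskal-Wallis rank test
#'
#' Rank-based one-way test for differences in location across k groups, with
#' the standard tie correction: `H = [(12 / (n (n+1))) * sum(R_j^2 / n_j)
#' - 3 (n+1)] / (1 - sum(t^3 - t) / (n^3 - n))` where `R_j` are group rank
#' sums and `t` the tie multiplicities. `df = k - 1`, asymptotic chi-square
#' p-value. The appropriate test for the strongly right-skewed purchase
#' variables.
#'
#' @param values Numeric vector.
#' @param groups Group label per value; at least 2 non-empty groups.
#' @return List `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis_test <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  groups <- droplevels(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 non-empty groups")
  n <- length(values)
  if (n < 3L) stop("need at least 3 observations in total")
  r <- rank(values, ties.method = "average")
  rsum <- tapply(r, groups, sum)
  sizes <- tapply(r, groups, length)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / sizes) - 3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction == 0) {          # all values identical
    h <- 0
  } else {
    h <- h / correction
  }
  h <- max(h, 0)                  # guard tiny negative rounding
  df <- k - 1L
  list(statistic = unname(h), df = df,
       p_value = stats::pchisq(h, df, lower.tail = FALSE))
}

#' Stratified loyalty-group profile
#'
#' Builds the combined comparison across the five degree-of-loyalty groups:
#' per-group sociodemographic distributions (counts and column percentages,
#' chi-square test per variable), RFM score medians with ANOVA and
#' Kruskal-Wallis, food-group purchase medians and shares with
#' Kruskal-Wallis, and, when weights are supplied, the per-group median
#' poststratification weight. Participants with a missing loyalty category
#' are excluded and counted.
#'
#' @param participants Data.frame with `id`, a `loyalty` column, and the
#'   sociodemographic variables.
#' @param scores Optional [rfm_scores()] output.
#' @param summaries Optional [participant_food_summary()] output.
#' @param weights Optional data.frame `id`, `weight`.
#' @param demo_vars Sociodemographic variables to profile.
#' @return List of class `loyalty_profile`: `demographics` (long data.frame
#'   of counts/percentages), `demographic_tests`, `rfm`, `food`,
#'   `n_missing_loyalty`.
#' @export
loyalty_profile <- function(participants, scores = NULL, summaries = NULL,
                            weights = NULL,
                            demo_vars = c("sex", "age_group", "marital",
                                          "education", "occupation",
                                          "children")) {
  if (!"loyalty" %in% names(participants))
    stop("participants must carry a 'loyalty' column")
  miss <- is.na(participants$loyalty)
  n_missing <- sum(miss)
  part <- participants[!miss, , drop = FALSE]
  part$loyalty <- droplevels(factor(part$loyalty))
  if (nlevels(part$loyalty) < 2L)
    warning("fewer than 2 non-empty loyalty groups")

  demo_vars <- intersect(demo_vars, names(part))
  demo_rows <- list()
  demo_tests <- list()
  for (v in demo_vars) {
    tab <- tabulate_sample(part, c(v, "loyalty"))
    cs <- colSums(tab)
    pct <- 100 * sweep(tab, 2L, pmax(cs, 1), "/")
    pct[, cs == 0] <- 0
    for (ci in colnames(tab)) for (ri in rownames(tab))
      demo_rows[[length(demo_rows) + 1L]] <- data.frame(
        variable = v, category = ri, loyalty = ci,
        n = tab[ri, ci], pct = round(pct[ri, ci], 2))
    nonempty <- colSums(tab) > 0
    if (sum(nonempty) >= 2L && nrow(tab) >= 2L) {
      ct <- chi_square_test(tab[, nonempty, drop = FALSE])
      demo_tests[[v]] <- data.frame(variable = v, test = "chi-square",
                                    statistic = ct$statistic, df = ct$df,
                                    p_value = ct$p_value)
    }
  }
  demographics <- do.call(rbind, demo_rows)
  demographic_tests <- do.call(rbind, demo_tests)
  rownames(demographic_tests) <- NULL

  rfm_part <- NULL
  if (!is.null(scores)) {
    m <- match(scores$id, part$id)
    ok <- !is.na(m)
    rfm_part <- compare_scores_by_group(scores$score[ok],
                                        part$loyalty[m[ok]])
  }

  weight_part <- NULL
  if (!is.null(weights)) {
    m <- match(weights$id, part$id)
    ok <- !is.na(m)
    weight_part <- compare_scores_by_group(weights$weight[ok],
                                           part$loyalty[m[ok]])
  }

  food_part <- NULL
  if (!is.null(summaries)) {
    by <- data.frame(id = part$id, group = as.character(part$loyalty))
    food_tbl <- summarize_food_groups(summaries, by = by)
    tests <- list()
    sums <- summaries[summaries$id %in% part$id, , drop = FALSE]
    gl <- as.character(part$loyalty[match(sums$id, part$id)])
    for (fg in unique(sums$food_group)) {
      sel <- sums$food_group == fg
      kw <- kruskal_wallis_test(sums$eur[sel], gl[sel])
      tests[[fg]] <- data.frame(food_group = fg, test = "kruskal-wallis",
                                statistic = kw$statistic, df = kw$df,
                                p_value = kw$p_value)
    }
    # total grocery purchases across loyalty groups (one row per participant)
    tot <- unique(sums[, c("id", "total_eur", "total_kg")])
    gt <- as.character(part$loyalty[match(tot$id, part$id)])
    total_summary <- data.frame(
      loyalty = sort(unique(gt)),
      median_total_eur = as.numeric(tapply(tot$total_eur, gt, stats::median)),
      median_total_kg = as.numeric(tapply(tot$total_kg, gt, stats::median)))
    kw_tot <- kruskal_wallis_test(tot$total_eur, gt)
    food_part <- list(summary = food_tbl,
                      tests = do.call(rbind, c(tests, make.row.names = FALSE)),
                      totals = total_summary, totals_test = kw_tot)
  }

  structure(list(demographics = demographics,
                 demographic_tests = demographic_tests,
                 rfm = rfm_part, weights = weight_part, food = food_part,
                 n_missing_loyalty = n_missing),
            class = "loyalty_profile")
}

#' @export
print.loyalty_profile <- function(x, ...) {
  cat("Degree-of-loyalty profile\n")
  cat("  participants with missing loyalty excluded:", x$n_missing_loyalty, "\n")
  if (!is.null(x$demographic_tests)) {
    cat("  sociodemographic chi-square tests:\n")
    print(x$demographic_tests, digits = 4)
  }
  if (!is.null(x$rfm)) {
    cat(sprintf("  RFM: F(%d,%d) = %.1f (p = %.3g); KW H(%d) = %.1f (p = %.3g)\n",
                x$rfm$anova$df1, x$rfm$anova$df2, x$rfm$anova$statistic,
                x$rfm$anova$p_value, x$rfm$kruskal$df,
                x$rfm$kruskal$statistic, x$rfm$kruskal$p_value))
    print(x$rfm$summary, digits = 4)
  }
  if (!is.null(x$food)) {
    cat("  food-group Kruskal-Wallis tests:\n")
    print(x$food$tests, digits = 4)
    cat("  total grocery purchases by loyalty group:\n")
    print(x$food$totals, digits = 5)
  }
  invisible(x)
}
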