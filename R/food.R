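#' The seven study food groups
#'
#' @return Character vector of the food-group labels used throughout.
#' @export
food_group_levels <- function() {
  c("vegetables", "skimmed_milk_sour_milk", "sugar_sweetened_beverages",
    "rye_bread", "red_meat_processed_meat", "fat_spreads",
    "sweets_chocolate")
}

#' Map product-group codes to food groups
#'
#' Retailer product taxonomies are far finer than the analysis needs; a
#' mapping table collapses product-group codes into the seven study food
#' groups, with everything else (mixed dishes, rare products, non-food)
#' left `unassigned`. The coverage report states how many codes of the
#' mapping were assigned to a food group, as a percentage to one decimal.
#'
#' @param transactions Data.frame with a `product_group` column.
#' @param mapping Data.frame with columns `product_group_code`, `food_group`,
#'   or a path to such a CSV. Codes absent from the mapping, and codes mapped
#'   to `"unassigned"`, count as unassigned.
#' @return `transactions` with a `food_group` column appended, plus attribute
#'   `coverage`: list with `codes_total`, `codes_assigned`, `coverage_pct`.
#' @examples
#' tx <- data.frame(id = 1, timestamp = "2017-05-01",
#'                  product_group = "P1", eur = 10, kg = 1)
#' mp <- data.frame(product_group_code = c("P1", "P2"),
#'                  food_group = c("vegetables", "unassigned"))
#' attr(map_products(tx, mp), "coverage")$coverage_pct
#' @export
map_products <- function(transactions, mapping) {
  if (is.character(mapping))
    mapping <- utils::read.csv(mapping, stringsAsFactors = FALSE,
                               colClasses = "character")
  need <- c("product_group_code", "food_group")
  if (!all(need %in% names(mapping)))
    stop("mapping must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(mapping$product_group_code))
    stop("product codes mapped more than once: ",
         mapping$product_group_code[duplicated(mapping$product_group_code)][1])
  bad <- setdiff(unique(mapping$food_group),
                 c(food_group_levels(), "unassigned"))
  if (length(bad))
    stop("unknown food group label(s) in mapping: ",
         paste(bad, collapse = ", "))
  fg <- mapping$food_group[match(transactions$product_group,
                                 mapping$product_group_code)]
  fg[is.na(fg)] <- "unassigned"
  transactions$food_group <- fg
  codes_total <- nrow(mapping)
  codes_assigned <- sum(mapping$food_group != "unassigned")
  attr(transactions, "coverage") <- list(
    codes_total = codes_total, codes_assigned = codes_assigned,
    coverage_pct = if (codes_total > 0)
      round(100 * codes_assigned / codes_total, 1) else NA_real_)
  transactions
}

#' Per-participant food-group purchase totals and shares
#'
#' Aggregates transactions over the observation period into per-participant,
#' per-food-group totals of expenditure (EUR) and weight (kg), plus each
#' group's share (%) of the participant's *all-grocery* totals (assigned and
#' unassigned purchases together). Participants with a zero all-grocery
#' total in a unit get missing shares in that unit.
#'
#' @param transactions Data.frame with `id`, `food_group`, `eur`, `kg`
#'   (see [map_products()]).
#' @return Data.frame in long-by-group layout: `id`, `food_group`, `eur`,
#'   `kg`, `eur_share`, `kg_share`, `total_eur`, `total_kg`; one row per
#'   participant and study food group (zeros filled in), `total_*` repeated
#'   within participant.
#' @export
participant_food_summary <- function(transactions) {
  need <- c("id", "food_group", "eur", "kg")
  if (!all(need %in% names(transactions)))
    stop("transactions must have columns: ", paste(need, collapse = ", "))
  if (any(transactions$eur < 0) || any(transactions$kg < 0))
    stop("negative expenditure or weight in transactions")
  dt <- data.table::as.data.table(transactions[need])
  totals <- dt[, list(total_eur = sum(eur), total_kg = sum(kg)), by = "id"]
  grp <- dt[food_group %in% food_group_levels(),
            list(eur = sum(eur), kg = sum(kg)), by = c("id", "food_group")]
  # complete the id x food-group grid with zeros
  grid <- data.table::CJ(id = totals$id, food_group = food_group_levels())
  out <- grp[grid, on = c("id", "food_group")]
  out[is.na(eur), eur := 0]
  out[is.na(kg), kg := 0]
  out <- totals[out, on = "id"]
  out[, eur_share := ifelse(total_eur > 0, 100 * eur / total_eur, NA_real_)]
  out[, kg_share := ifelse(total_kg > 0, 100 * kg / total_kg, NA_real_)]
  data.table::setcolorder(out, c("id", "food_group", "eur", "kg",
                                 "eur_share", "kg_share",
                                 "total_eur", "total_kg"))
  data.table::setorder(out, id, food_group)
  as.data.frame(out)
}

#' Weighted quantile (left-continuous cumulative-weight inverse)
#'
#' Returns the smallest value whose cumulative normalized weight reaches
#' `q`. With equal weights this reduces to the order statistic at
#' `ceiling(q * n)`. Used for weighted medians and IQRs of skewed purchase
#' distributions.
#'
#' @param values Numeric vector.
#' @param weights Non-negative weights, not all zero. Default: equal.
#' @param q Probabilities in `[0, 1]` (vectorized).
#' @return Numeric vector, one quantile per `q`.
#' @examples
#' weighted_quantile(c(1, 2, 3), c(1, 1, 8), 0.5)  # 3
#' @export
weighted_quantile <- function(values, weights = NULL, q = 0.5) {
  if (length(values) == 0L) stop("empty input")
  if (is.null(weights)) weights <- rep(1, length(values))
  stopifnot(length(weights) == length(values))
  keep <- !is.na(values) & !is.na(weights)
  values <- values[keep]; weights <- weights[keep]
  if (length(values) == 0L) stop("no non-missing value/weight pairs")
  if (any(weights < 0)) stop("negative weights")
  if (sum(weights) == 0) stop("weights must not all be zero")
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  o <- order(values)
  cw <- cumsum(weights[o]) / sum(weights)
  vapply(q, function(qi) values[o][which(cw >= qi - 1e-12)[1]], numeric(1))
}

#' Summarize food-group purchases, unweighted and weighted
#'
#' Produces the per-food-group `median [IQR]` of EUR totals, EUR shares, kg
#' totals and kg shares — unweighted, and, when poststratification weights
#' are supplied, also weighted together with the relative change of the
#' weighted vs unweighted median (`100 * (weighted/unweighted - 1)`, one
#' decimal). Optionally stratified by a grouping variable such as the degree
#' of loyalty. Both weighted and unweighted columns use the same
#' left-continuous [weighted_quantile()] estimator (unit weights for the
#' unweighted case), so supplying equal weights reproduces the unweighted
#' summary exactly.
#'
#' @param summaries Output of [participant_food_summary()].
#' @param weights Optional data.frame `id`, `weight`; participants of
#'   `summaries` without a weight are dropped from the weighted columns only.
#' @param by Optional data.frame `id`, `group` stratifying the summary.
#' @param mode `"all"` (default) summarizes over all participants with a
#'   positive all-grocery total; `"purchasers"` restricts each food-group row
#'   to participants with a positive total in that group.
#' @return Data.frame with one row per food group (and stratum), columns
#'   `<unit>_median`, `<unit>_q1`, `<unit>_q3` for units eur, eur_share, kg,
#'   kg_share; weighted counterparts `w_<...>` and `rel_change_<unit>_pct`
#'   when weights are given.
#' @export
summarize_food_groups <- function(summaries, weights = NULL, by = NULL,
                                  mode = c("all", "purchasers")) {
  mode <- match.arg(mode)
  dat <- summaries[!is.na(summaries$eur_share) | summaries$total_eur > 0, ,
                   drop = FALSE]
  dat <- dat[dat$total_eur > 0, , drop = FALSE]   # zero-total excluded
  if (!is.null(weights)) {
    if (!all(c("id", "weight") %in% names(weights)))
      stop("weights must have columns id, weight")
    if (!all(weights$id %in% summaries$id))
      stop("weights contain unknown participant ids")
    dat$.w <- weights$weight[match(dat$id, weights$id)]
  }
  strata <- if (!is.null(by)) {
    dat$.g <- by$group[match(dat$id, by$id)]
    split(dat, dat$.g, drop = TRUE)
  } else list(all = dat)

  units <- c("eur", "eur_share", "kg", "kg_share")
  rows <- list()
  for (s in names(strata)) {
    d <- strata[[s]]
    for (fg in food_group_levels()) {
      dg <- d[d$food_group == fg, , drop = FALSE]
      if (mode == "purchasers") dg <- dg[dg$eur > 0 | dg$kg > 0, , drop = FALSE]
      if (nrow(dg) == 0L) next
      row <- list(group = s, food_group = fg, n = nrow(dg))
      for (u in units) {
        v <- dg[[u]]
        qs <- weighted_quantile(v[!is.na(v)], q = c(0.25, 0.5, 0.75))
        row[[paste0(u, "_q1")]] <- unname(qs[1])
        row[[paste0(u, "_median")]] <- unname(qs[2])
        row[[paste0(u, "_q3")]] <- unname(qs[3])
        if (!is.null(weights)) {
          ok <- !is.na(dg$.w) & !is.na(v)
          wq <- weighted_quantile(v[ok], dg$.w[ok], c(0.25, 0.5, 0.75))
          row[[paste0("w_", u, "_q1")]] <- wq[1]
          row[[paste0("w_", u, "_median")]] <- wq[2]
          row[[paste0("w_", u, "_q3")]] <- wq[3]
          row[[paste0("rel_change_", u, "_pct")]] <-
            relative_median_change(unname(qs[2]), wq[2])
        }
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (is.null(by)) out$group <- NULL
  out
}

#' Relative change between unweighted and weighted medians
#'
#' `100 * (weighted / unweighted - 1)`, reported to one decimal, the scale on
#' which reweighting effects on purchase medians are stated.
#'
#' @param unweighted,weighted Medians (vectorized).
#' @return Percentage change, one decimal. `NA` where the unweighted median
#'   is zero.
#' @examples
#' relative_median_change(386.5, 416.8)  # 7.8
#' relative_median_change(47.5, 53.5)    # 12.6
#' @export
relative_median_change <- function(unweighted, weighted) {
  ifelse(unweighted != 0, round(100 * (weighted / unweighted - 1), 1),
         NA_real_)
}
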