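test_that("single one-way margin converges in one sweep to target/sample", {
  s <- data.frame(id = 1:100, sex = rep(c("w", "m"), c(60, 40)))
  m <- margin_spec(c(w = 500, m = 500), "sex")
  res <- rake(s, m)
  expect_true(res$converged)
  expect_equal(res$iterations, 1L)
  expect_equal(res$weights$weight[s$sex == "w"], rep(500 / 60, 60))
  expect_equal(res$weights$weight[s$sex == "m"], rep(500 / 40, 40))
})

test_that("a sample already at target margins is a fixed point", {
  s <- data.frame(id = 1:10, sex = rep(c("w", "m"), each = 5))
  m <- margin_spec(c(w = 5, m = 5), "sex")
  res <- rake(s, m)
  expect_equal(res$iterations, 1L)
  expect_equal(res$weights$weight, rep(1, 10))
})

test_that("unit-level raking equals classical cell-level IPF on the seed table", {
  set.seed(101)
  for (trial in 1:100) {
    nr <- sample(2:4, 1)
    nc <- sample(2:4, 1)
    seed_tab <- matrix(sample(1:6, nr * nc, replace = TRUE), nr, nc,
                       dimnames = list(paste0("r", 1:nr), paste0("c", 1:nc)))
    row_t <- as.numeric(seed_tab %*% rep(1, nc)) * stats::runif(nr, 0.5, 2)
    col_t <- colSums(seed_tab) * stats::runif(nc, 0.5, 2)
    col_t <- col_t * sum(row_t) / sum(col_t)  # consistent totals

    # expand the seed table into one unit per count
    idx <- which(seed_tab > 0, arr.ind = TRUE)
    units <- do.call(rbind, lapply(seq_len(nrow(idx)), function(k)
      data.frame(r = rownames(seed_tab)[idx[k, 1]],
                 c = colnames(seed_tab)[idx[k, 2]])[
                   rep(1, seed_tab[idx[k, , drop = FALSE]]), , drop = FALSE]))
    units$id <- seq_len(nrow(units))

    margins <- list(margin_spec(stats::setNames(row_t, rownames(seed_tab)), "r"),
                    margin_spec(stats::setNames(col_t, colnames(seed_tab)), "c"))
    res <- rake(units, margins, raking_control(tolerance = 1e-10))
    got <- tabulate_sample(units, c("r", "c"), weights = res$weights$weight,
                           levels = list(r = rownames(seed_tab),
                                         c = colnames(seed_tab)))
    want <- ipf_cells_oracle(seed_tab, row_t, col_t)
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-6)
  }
})

test_that("raking to one-way margins preserves the 2x2 sample odds ratio", {
  set.seed(7)
  for (trial in 1:25) {
    tab <- matrix(sample(2:30, 4), 2, 2,
                  dimnames = list(c("w", "m"), c("lo", "hi")))
    units <- expand.grid(sex = c("w", "m"), edu = c("lo", "hi"),
                         stringsAsFactors = FALSE)
    units <- units[rep(1:4, as.numeric(tab)), ]
    units$id <- seq_len(nrow(units))
    sex_t <- c(w = 100 * stats::runif(1, 0.5, 1.5), m = 100)
    edu_t <- c(lo = 80, hi = 80 * stats::runif(1, 0.5, 1.5))
    edu_t <- edu_t * sum(sex_t) / sum(edu_t)  # consistent totals
    margins <- list(margin_spec(sex_t, "sex"), margin_spec(edu_t, "edu"))
    res <- rake(units, margins, raking_control(tolerance = 1e-10))
    wt <- tabulate_sample(units, c("sex", "edu"),
                          weights = res$weights$weight,
                          levels = list(sex = c("w", "m"),
                                        edu = c("lo", "hi")))
    or_before <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    or_after <- (wt[1, 1] * wt[2, 2]) / (wt[1, 2] * wt[2, 1])
    expect_equal(or_after, or_before, tolerance = 1e-6)
  }
})

test_that("converged untrimmed weights reproduce every margin within tolerance", {
  cfg <- small_config(n = 20000, seed = 3)
  pop <- generate_population(cfg)
  sample_p <- sample_consenters(pop, cfg$selection_coefs, seed = 4)
  margins <- population_margins(pop, cfg$margin_pairs)
  ctl <- raking_control(tolerance = 1e-8)
  res <- rake(sample_p, margins, ctl)
  expect_true(res$converged)
  expect_lte(margin_discrepancy(sample_p, res$weights$weight, margins), 1e-8)
})

test_that("final weights do not depend on margin sweep order", {
  cfg <- small_config(n = 10000, seed = 5)
  pop <- generate_population(cfg)
  s <- sample_consenters(pop, cfg$selection_coefs, seed = 6)
  margins <- population_margins(pop, cfg$margin_pairs)
  ctl <- raking_control(tolerance = 1e-9)
  w1 <- rake(s, margins, ctl)$weights$weight
  w2 <- rake(s, rev(margins), ctl)$weights$weight
  expect_equal(w1, w2, tolerance = 1e-6)
})

test_that("zero weighted cell with positive target is a named hard error", {
  s <- data.frame(id = 1:4, sex = rep("w", 4))
  m <- margin_spec(c(w = 50, m = 50), "sex")
  expect_error(rake(s, m), "margin_category_not_in_sample|empty_sample_cell")
})

test_that("non-convergence returns converged = FALSE with a warning", {
  cfg <- small_config(n = 5000, seed = 9)
  pop <- generate_population(cfg)
  s <- sample_consenters(pop, cfg$selection_coefs, seed = 10)
  margins <- population_margins(pop, cfg$margin_pairs)
  expect_warning(
    res <- rake(s, margins, raking_control(max_iterations = 1,
                                           tolerance = 1e-12)),
    "did not converge")
  expect_false(res$converged)
  expect_gt(res$max_discrepancy, 1e-12)
})

test_that("trim_weights clamps, counts, and never reorders", {
  out <- trim_weights(c(0.04, 5, 82.4), 0.1, 10)
  expect_equal(as.numeric(out), c(0.1, 5, 10))
  expect_equal(attr(out, "trimmed"), c(lower = 1L, upper = 1L))

  w <- c(0.5, 2, 9.9)
  expect_equal(as.numeric(trim_weights(w)), w)

  out2 <- trim_weights(c(20, 30, 40), 9.999, 10)
  expect_equal(as.numeric(out2), rep(10, 3))

  set.seed(2)
  w <- exp(stats::rnorm(200, 0, 2))
  tw <- as.numeric(trim_weights(w))
  expect_true(all(diff(tw[order(w)]) >= 0))  # monotone in the original order
  expect_error(trim_weights(w, 5, 1))
})

test_that("rescale_weights preserves ratios and hits the total", {
  expect_equal(rescale_weights(c(1, 1, 2), 8), c(2, 2, 4))
  w <- c(0.3, 1.7, 2)
  expect_equal(rescale_weights(w, sum(w)), w)
  set.seed(3)
  for (i in 1:20) {
    w <- stats::runif(sample(2:50, 1), 0.01, 5)
    tot <- stats::runif(1, 1, 1e4)
    expect_lt(abs(sum(rescale_weights(w, tot)) - tot) / tot, 1e-8)
  }
  expect_error(rescale_weights(numeric(0), 10), "positive")
})

test_that("margin_discrepancy matches hand arithmetic on a 2x2 case", {
  s <- data.frame(id = 1:4, sex = c("w", "w", "m", "m"),
                  edu = c("lo", "hi", "lo", "hi"))
  m <- margin_spec(c(w = 3, m = 1), "sex")
  w <- rep(1, 4)
  # weighted totals (2, 2) vs targets (3, 1): rel dev = 1/3 and 1
  expect_equal(margin_discrepancy(s, w, m), 1)
  expect_gt(margin_discrepancy(s, w, m), 0)
})

test_that("two-phase weighting handles complete, partial and excluded units", {
  cfg <- small_config(n = 20000, seed = 12)
  pop <- generate_population(cfg)
  consent <- sample_consenters(pop, cfg$selection_coefs, seed = 13)
  part <- apply_nonresponse(consent, rate = 0.23, mechanism = "mcar",
                            seed = 14, sexage_missing_rate = 0.002)
  margins <- population_margins(pop, cfg$margin_pairs)
  reduced <- population_margins(pop, list(c("sex", "age_group")))
  res <- two_phase_weights(part, margins, reduced)

  n_missing_sexage <- sum(is.na(part$sex) | is.na(part$age_group))
  expect_equal(length(res$excluded_ids), n_missing_sexage)
  expect_equal(nrow(res$weights), nrow(part) - n_missing_sexage)
  expect_equal(sum(res$weights$weight), nrow(part) - n_missing_sexage,
               tolerance = 1e-8)
  # nonresponders (with sex/age known) must be phase 2
  nr_ids <- part$id[is.na(part$education) & !is.na(part$sex) &
                      !is.na(part$age_group)]
  expect_true(all(res$weights$phase[res$weights$id %in% nr_ids] == 2L))
  # complete cases phase 1
  cc_ids <- part$id[stats::complete.cases(
    part[, c("sex", "age_group", "marital", "education",
             "occupation", "children")])]
  expect_true(all(res$weights$phase[res$weights$id %in% cc_ids] == 1L))
  expect_true(all(res$weights$weight >= res$control$trim_lower -
                    1e-9 * res$total))
})

test_that("with no missing data two-phase equals rake + trim + rescale", {
  cfg <- small_config(n = 8000, seed = 15)
  pop <- generate_population(cfg)
  s <- sample_consenters(pop, cfg$selection_coefs, seed = 16)
  margins <- population_margins(pop, cfg$margin_pairs)
  reduced <- population_margins(pop, list(c("sex", "age_group")))
  ctl <- raking_control()
  res <- two_phase_weights(s, margins, reduced, ctl)
  expect_true(all(res$weights$phase == 1L))

  scaled <- lapply(margins, function(m) {
    m$table <- m$table * nrow(s) / sum(m$table); m })
  direct <- rake(s, scaled, ctl)$weights$weight
  direct <- rescale_weights(as.numeric(trim_weights(direct, ctl$trim_lower,
                                                    ctl$trim_upper)), nrow(s))
  expect_equal(res$weights$weight, direct)
})

test_that("all units missing a full-margin variable fall back to reduced margins", {
  cfg <- small_config(n = 8000, seed = 17)
  pop <- generate_population(cfg)
  s <- sample_consenters(pop, cfg$selection_coefs, seed = 18)
  s$education <- NA
  margins <- population_margins(pop, cfg$margin_pairs)
  reduced <- population_margins(pop, list(c("sex", "age_group")))
  res <- two_phase_weights(s, margins, reduced)
  expect_true(all(res$weights$phase == 2L))
  expect_equal(sum(res$weights$weight), nrow(s), tolerance = 1e-8)
})

test_that("oracle-only columns are never consumed by the analysis", {
  cfg <- small_config(n = 8000, seed = 19)
  pop <- generate_population(cfg)
  s <- sample_consenters(pop, cfg$selection_coefs, seed = 20)
  margins <- population_margins(pop, cfg$margin_pairs)
  reduced <- population_margins(pop, list(c("sex", "age_group")))
  r1 <- two_phase_weights(s, margins, reduced)
  s2 <- s
  s2$.oracle_p_consent <- rev(s2$.oracle_p_consent)  # scramble the oracle
  r2 <- two_phase_weights(s2, margins, reduced)
  expect_identical(r1$weights, r2$weights)
})
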