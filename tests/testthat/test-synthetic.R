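test_that("generator config validation names the offending field", {
  expect_error(generator_config(sex_probs = c(women = 0.6, men = 0.6)),
               "sex_probs")
  expect_error(generator_config(loyalty_probs = rep(0.25, 5)),
               "loyalty_probs")
  expect_error(generator_config(nonresponse_rate = 1.5), "nonresponse_rate")
  expect_error(generator_config(population_size = 0), "population_size")
  pm <- default_purchase_model()
  pm$sdlog_eur[1] <- -1
  expect_error(generator_config(purchase_model = pm), "scale parameter")
})

test_that("generation is deterministic given config + seed", {
  cfg <- small_config(n = 2000, seed = 77)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1, p2)
  c1 <- sample_consenters(p1, cfg$selection_coefs, seed = 78)
  c2 <- sample_consenters(p2, cfg$selection_coefs, seed = 78)
  expect_identical(c1, c2)
  c1 <- draw_loyalty(c1, cfg$loyalty_probs, seed = 79)
  t1 <- generate_transactions(c1, cfg$purchase_model, seed = 80,
                              loyalty_multipliers = cfg$loyalty_multipliers)
  t2 <- generate_transactions(c1, cfg$purchase_model, seed = 80,
                              loyalty_multipliers = cfg$loyalty_multipliers)
  expect_identical(t1, t2)
})

test_that("population margins converge to the configured/implied targets", {
  cfg <- generator_config(population_size = 50000, seed = 5)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop), 50000)
  expect_false(anyNA(pop))
  expect_equal(anyDuplicated(pop$id), 0L)

  targets <- implied_margins(cfg)
  n <- nrow(pop)
  for (v in c("sex", "age_group", "education", "occupation", "marital")) {
    col <- if (v == "age_group") pop$age_group else pop[[v]]
    for (cat in names(targets[[v]])) {
      p <- targets[[v]][[cat]]
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(mean(col == cat) - p), 3 * se + 1e-12)
    }
  }
  p_child <- targets$children[["yes"]]
  se <- sqrt(p_child * (1 - p_child) / n)
  expect_lt(abs(mean(pop$children == "yes") - p_child), 3 * se)
})

test_that("women share at n = 100,000 is within 3 binomial SEs of 0.5112", {
  cfg <- generator_config(population_size = 100000, seed = 1)
  pop <- generate_population(cfg)
  se <- sqrt(0.5112 * (1 - 0.5112) / 100000)
  expect_lt(abs(mean(pop$sex == "women") - 0.5112), 3 * se)
})

test_that("a single-category variable is degenerate", {
  cfg <- generator_config(population_size = 500, seed = 2,
                          sex_probs = c(women = 1))
  pop <- generate_population(cfg)
  expect_true(all(pop$sex == "women"))
})

test_that("consent with zero coefficients recovers the intercept rate", {
  cfg <- generator_config(population_size = 50000, seed = 31)
  pop <- generate_population(cfg)
  cons <- sample_consenters(pop, list(intercept = stats::qlogis(0.04)),
                            seed = 32)
  se <- sqrt(0.04 * 0.96 / 50000)
  expect_lt(abs(nrow(cons) / 50000 - 0.04), 3 * se)
  expect_equal(cons$.oracle_p_consent, rep(0.04, nrow(cons)))
})

test_that("an effectively minus-infinite intercept consents nobody", {
  cfg <- generator_config(population_size = 1000, seed = 33)
  pop <- generate_population(cfg)
  cons <- sample_consenters(pop, list(intercept = -50), seed = 34)
  expect_equal(nrow(cons), 0L)
})

test_that("selection-bias direction follows the coefficient signs", {
  cfg <- generator_config(population_size = 100000, seed = 35)
  pop <- generate_population(cfg)
  coefs <- list(intercept = stats::qlogis(0.05),
                sex = c(women = 0.6),
                education = c(master = 0.5, basic = -0.7),
                age_group = c(">=70" = -0.9))
  cons <- sample_consenters(pop, coefs, seed = 36)
  expect_gt(mean(cons$sex == "women"), mean(pop$sex == "women"))
  expect_gt(mean(cons$education == "master"), mean(pop$education == "master"))
  expect_lt(mean(cons$education == "basic"), mean(pop$education == "basic"))
  expect_lt(mean(cons$age_group == ">=70"), mean(pop$age_group == ">=70"))
})

test_that("unknown selection coefficient keys are configuration errors", {
  cfg <- generator_config(population_size = 100, seed = 37)
  pop <- generate_population(cfg)
  expect_error(sample_consenters(pop, list(intercept = 0,
                                           shoe_size = c(big = 1)), 38),
               "unknown variable")
  expect_error(sample_consenters(pop, list(intercept = 0,
                                           sex = c(woman = 1)), 38),
               "unknown category")
})

test_that("nonresponse blanks questionnaire fields only, at the right rate", {
  cfg <- generator_config(population_size = 60000, seed = 41)
  pop <- generate_population(cfg)
  pop$loyalty <- factor("41%-60%")
  part <- apply_nonresponse(pop, rate = 0.22, mechanism = "mcar", seed = 42)
  n <- nrow(part)
  # binomial oracle: mean responders n * 0.78, SE sqrt(n * .22 * .78)
  expect_lt(abs(sum(part$responded) - n * 0.78), 3 * sqrt(n * 0.22 * 0.78))
  nr <- !part$responded
  expect_true(all(is.na(part$education[nr])))
  expect_true(all(is.na(part$marital[nr])))
  expect_true(all(is.na(part$occupation[nr])))
  expect_true(all(is.na(part$children[nr])))
  expect_true(all(is.na(part$loyalty[nr])))
  expect_false(anyNA(part$sex))
  expect_false(anyNA(part$age_group))
  expect_false(anyNA(part$education[!nr]))
})

test_that("nonresponse rates 0 and 1 are the trivial extremes", {
  cfg <- generator_config(population_size = 300, seed = 43)
  pop <- generate_population(cfg)
  p0 <- apply_nonresponse(pop, rate = 0, seed = 44)
  expect_false(anyNA(p0))
  p1 <- apply_nonresponse(pop, rate = 1, seed = 45)
  expect_true(all(is.na(p1$education)))
  expect_false(anyNA(p1$sex))
  expect_false(anyNA(p1$age_group))
})

test_that("covariate-dependent nonresponse keeps the marginal rate and direction", {
  cfg <- generator_config(population_size = 40000, seed = 46)
  pop <- generate_population(cfg)
  part <- apply_nonresponse(pop, rate = 0.25, mechanism = "covariate",
                            seed = 47,
                            coefs = list(education = c(basic = 0.8)))
  expect_lt(abs(mean(!part$responded) - 0.25), 0.01)
  nr_basic <- mean(!part$responded[pop$education == "basic"])
  nr_rest <- mean(!part$responded[pop$education != "basic"])
  expect_gt(nr_basic, nr_rest)
})

test_that("transactions honour zero-inflation, positivity and the period", {
  cfg <- small_config(n = 3000, seed = 51)
  pop <- generate_population(cfg)
  cons <- sample_consenters(pop, cfg$selection_coefs, seed = 52)
  pm <- cfg$purchase_model
  pm$zero_inflation[pm$group == "rye_bread"] <- 1
  tx <- generate_transactions(cons, pm, seed = 53)
  expect_false(any(tx$product_group == "rye_bread"))
  expect_true(all(tx$eur > 0))
  expect_true(all(tx$kg > 0))
  expect_true(all(tx$timestamp >= as.Date("2017-01-01")))
  expect_true(all(tx$timestamp <= as.Date("2018-12-31")))
  expect_error(generate_transactions(cons, pm, period_start = "2018-01-01",
                                     period_end = "2017-01-01", seed = 1),
               "precede")
  pm$sdlog_eur[1] <- 0
  expect_error(generate_transactions(cons, pm, seed = 1), "scale")
})

test_that("median spend increases strictly across loyalty classes", {
  cfg <- generator_config(population_size = 10000, seed = 55)
  pop <- generate_population(cfg)
  pop <- draw_loyalty(pop, cfg$loyalty_probs, seed = 56)
  tx <- generate_transactions(pop, cfg$purchase_model, seed = 57,
                              loyalty_multipliers = cfg$loyalty_multipliers)
  tot <- tapply(tx$eur, tx$id, sum)
  med <- tapply(as.numeric(tot), pop$loyalty_class[match(names(tot), pop$id)],
                stats::median)
  expect_true(all(diff(med) > 0))
})

test_that("loyalty binning follows the printed closed-interval labels", {
  expect_equal(as.character(assign_loyalty(81, 100)), "81%-100%")
  expect_equal(as.character(assign_loyalty(0, 100)), "0%-20%")
  # boundary values fall in the lower-labelled bin
  expect_equal(as.character(assign_loyalty(c(20, 40, 60, 80), rep(100, 4))),
               c("0%-20%", "21%-40%", "41%-60%", "61%-80%"))
  # just above a boundary moves up
  expect_equal(as.character(assign_loyalty(c(20.01, 60.5), c(100, 100))),
               c("21%-40%", "61%-80%"))
  expect_true(is.na(assign_loyalty(0, 0)))
  expect_error(assign_loyalty(110, 100), "focal_spend")
  expect_error(assign_loyalty(-1, 100), "focal_spend")
})

test_that("drawn loyalty categories match their latent class and probabilities", {
  cfg <- generator_config(population_size = 50000, seed = 58)
  pop <- generate_population(cfg)
  pop <- draw_loyalty(pop, cfg$loyalty_probs, seed = 59)
  expect_equal(as.integer(pop$loyalty), pop$loyalty_class)
  for (k in 1:5) {
    p <- cfg$loyalty_probs[k]
    se <- sqrt(p * (1 - p) / 50000)
    expect_lt(abs(mean(pop$loyalty_class == k) - p), 3 * se)
  }
})
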