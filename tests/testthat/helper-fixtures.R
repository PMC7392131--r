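# Shared small fixtures; everything is built in code at test time.

# Small cohort config that keeps raking feasible: two-way sex x age plus
# one-way education margins only.
small_config <- function(n = 4000, seed = 42) {
  generator_config(
    population_size = n, seed = seed,
    selection_coefs = list(intercept = stats::qlogis(0.25),
                           sex = c(women = 0.5),
                           age_group = c("<=29" = -0.4, ">=70" = -0.8)),
    margin_pairs = list(c("sex", "age_group"), "education"))
}

# Transactions for `k` participants with strictly aligned recency, frequency
# and monetary ordering: participant i purchased on i distinct days ending
# i days before the reference date, spending 10*i in total.
aligned_rfm_transactions <- function(k = 5, ref = as.Date("2018-12-31")) {
  rows <- lapply(seq_len(k), function(i) {
    last <- ref - (k - i + 1)     # recency k-i+1 days: higher i = more recent
    dates <- last - seq_len(i) + 1  # i distinct purchase days
    data.frame(id = i, timestamp = dates, eur = 10 * i, kg = 1)
  })
  do.call(rbind, rows)
}

# Hand-built 3-participant transaction fixture with known sums.
hand_transactions <- function() {
  data.frame(
    id = c(1, 1, 1, 2, 2, 3),
    timestamp = as.Date(c("2017-02-01", "2017-06-15", "2018-11-30",
                          "2017-03-10", "2018-01-20", "2018-07-04")),
    food_group = c("vegetables", "vegetables", "rye_bread",
                   "vegetables", "unassigned", "unassigned"),
    eur = c(4, 6, 10, 5, 95, 7),
    kg = c(1, 2, 3, 2.5, 10, 0.5),
    stringsAsFactors = FALSE)
}
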