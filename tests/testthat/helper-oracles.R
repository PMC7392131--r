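# Independent oracles, deliberately written with different machinery than the
# package implementations they check.

# Classical cell-level IPF on a seed contingency table: scale rows to the row
# targets, columns to the column targets, repeat.
ipf_cells_oracle <- function(seed_tab, row_target, col_target,
                             tol = 1e-12, max_iter = 2000L) {
  x <- seed_tab
  for (i in seq_len(max_iter)) {
    x <- x * (row_target / rowSums(x))
    x <- sweep(x, 2L, col_target / colSums(x), "*")
    if (max(abs(rowSums(x) - row_target) / row_target,
            abs(colSums(x) - col_target) / col_target) < tol) break
  }
  x
}

# Rank computation by explicit counting (average ranks for ties).
oracle_ranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n))
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  r
}

# Kruskal-Wallis H from oracle ranks, tie correction included; a loop-based
# second route to the same statistic.
oracle_kw_H <- function(values, groups) {
  groups <- as.character(groups)
  r <- oracle_ranks(values)
  n <- length(values)
  h <- 0
  for (g in unique(groups)) {
    sel <- groups == g
    h <- h + sum(r[sel])^2 / sum(sel)
  }
  h <- 12 / (n * (n + 1)) * h - 3 * (n + 1)
  tie_term <- 0
  for (v in unique(values)) {
    t <- sum(values == v)
    tie_term <- tie_term + (t^3 - t)
  }
  denom <- 1 - tie_term / (n^3 - n)
  if (denom == 0) 0 else max(h / denom, 0)
}

# Pearson chi-square by explicit double loop.
oracle_chisq <- function(tab) {
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / n
    stat <- stat + (tab[i, j] - e)^2 / e
  }
  stat
}

# All distinct assignments of `sizes` group labels to n positions
# (multiset permutations via recursive combn); rows = assignments.
all_group_assignments <- function(sizes) {
  n <- sum(sizes)
  assign_rec <- function(positions, sizes_left, labels_left) {
    if (length(sizes_left) == 1L)
      return(list(stats::setNames(rep(labels_left[1], length(positions)),
                                  positions)))
    out <- list()
    picks <- utils::combn(positions, sizes_left[1], simplify = FALSE)
    for (p in picks) {
      rest <- assign_rec(setdiff(positions, p), sizes_left[-1],
                         labels_left[-1])
      for (r in rest) {
        v <- c(stats::setNames(rep(labels_left[1], length(p)), p), r)
        out[[length(out) + 1L]] <- v[as.character(seq_len(n))]
      }
    }
    out
  }
  assign_rec(as.character(seq_len(n)), sizes, seq_along(sizes))
}

# Left-continuous quantile by sort + cumulative count (unweighted oracle).
oracle_quantile_cumcount <- function(values, q) {
  v <- sort(values)
  n <- length(v)
  v[which((seq_len(n) / n) >= q - 1e-12)[1]]
}
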