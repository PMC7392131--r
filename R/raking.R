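#' Control parameters for raking
#'
#' @param max_iterations Maximum number of full sweeps over all margins.
#' @param tolerance Convergence threshold: the maximum relative discrepancy,
#'   over all margin cells, between the weighted sample total and the target.
#' @param trim_lower,trim_upper Weight trimming bounds. The defaults (0.1, 10)
#'   clamp extreme weights to limit variance inflation; trimming is applied
#'   after raking and is never followed by re-raking.
#' @param margin_order `"as-given"` (default) sweeps margins in list order;
#'   `"sorted"` sweeps in alphabetical order of their variable labels. The
#'   fixed point does not depend on the order; the option exists to test that.
#' @param rescale_before_trim Logical; if `TRUE` weights are rescaled to the
#'   target total before trimming instead of after (default `FALSE`:
#'   trim, then rescale).
#' @return A list of class `raking_control`.
#' @export
raking_control <- function(max_iterations = 200L, tolerance = 1e-7,
                           trim_lower = 0.1, trim_upper = 10,
                           margin_order = c("as-given", "sorted"),
                           rescale_before_trim = FALSE) {
  margin_order <- match.arg(margin_order)
  stopifnot(max_iterations >= 1, tolerance > 0,
            trim_lower > 0, trim_lower < trim_upper)
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, trim_lower = trim_lower,
                 trim_upper = trim_upper, margin_order = margin_order,
                 rescale_before_trim = rescale_before_trim),
            class = "raking_control")
}

# Map each sample row to its flat cell index within one margin's table.
# Rows must be non-missing on the margin variables (rake()'s precondition).
margin_cell_index <- function(sample, margin) {
  dn <- dimnames(margin$table)
  idx <- match(as.character(sample[[margin$variables[1]]]), dn[[1]])
  if (length(margin$variables) == 2L) {
    j <- match(as.character(sample[[margin$variables[2]]]), dn[[2]])
    idx <- idx + (j - 1L) * length(dn[[1]])
  }
  idx
}

#' Rake unit weights to population margins
#'
#' Unit-level iterative proportional fitting: starting from uniform weights
#' equal to (population total / sample size), each margin in turn multiplies
#' every unit's weight by `target cell total / current weighted cell total`
#' for the unit's cell. Sweeps over all margins repeat until the maximum
#' relative cell discrepancy falls below `control$tolerance` or
#' `control$max_iterations` is reached. Matching several two-way margins
#' simultaneously calibrates the sample to all those joint distributions at
#' once, which one-way matching alone cannot do.
#'
#' No trimming or rescaling is applied here; see [two_phase_weights()] for the
#' full weight-construction pipeline.
#'
#' @param sample Data.frame with an `id` column and every margin variable
#'   non-missing.
#' @param margins List of [margin_spec] objects (a single spec is accepted).
#'   All margins must carry the same population total.
#' @param control A [raking_control].
#' @return A `weight_result`: list with `weights` (data.frame `id`, `weight`),
#'   `iterations`, `converged`, `max_discrepancy`, and `control`.
#' @examples
#' s <- data.frame(id = 1:5, sex = c("w","w","w","m","m"))
#' m <- margin_spec(c(w = 500, m = 500), "sex")
#' rake(s, m)$weights
#' @export
rake <- function(sample, margins, control = raking_control()) {
  if (inherits(margins, "margin_spec")) margins <- list(margins)
  stopifnot(inherits(control, "raking_control"), nrow(sample) >= 1)
  if (!"id" %in% names(sample)) stop("sample must carry an 'id' column")
  val <- validate_margins(margins, sample)
  if (any(val$blocking))
    stop("margins fail validation; first blocking issue: ",
         val$issue[val$blocking][1], " [", val$cell[val$blocking][1], "]")
  totals <- vapply(margins, function(m) sum(m$table), numeric(1))
  if (max(totals) - min(totals) > 1e-6 * max(totals))
    warning("margins carry different population totals (",
            paste(signif(totals, 8), collapse = ", "),
            "); raking cannot match all of them exactly")
  if (control$margin_order == "sorted") {
    lab <- vapply(margins, function(m) paste(m$variables, collapse = "x"), "")
    margins <- margins[order(lab)]
  }
  n <- nrow(sample)
  cellidx <- lapply(margins, margin_cell_index, sample = sample)
  targets <- lapply(margins, function(m) as.numeric(m$table))
  w <- rep(totals[1] / n, n)

  iter <- 0L
  disc <- Inf
  while (iter < control$max_iterations) {
    iter <- iter + 1L
    for (k in seq_along(margins)) {
      cur <- rowsum_by_index(w, cellidx[[k]], length(targets[[k]]))
      dead <- cur == 0 & targets[[k]] > 0
      if (any(dead))
        stop("zero weighted sample cell with positive target in margin ",
             paste(margins[[k]]$variables, collapse = "x"), " [",
             paste(cell_names(margins[[k]]$table, which(dead)),
                   collapse = "; "), "]")
      fac <- ifelse(cur > 0, targets[[k]] / cur, 1)
      w <- w * fac[cellidx[[k]]]
    }
    disc <- raked_discrepancy(w, cellidx, targets)
    if (disc <= control$tolerance) break
  }
  converged <- disc <= control$tolerance
  if (!converged)
    warning(sprintf(
      "raking did not converge in %d iterations (max discrepancy %.3g)",
      iter, disc))
  structure(list(weights = data.frame(id = sample$id, weight = w),
                 iterations = iter, converged = converged,
                 max_discrepancy = disc, control = control),
            class = "weight_result")
}

rowsum_by_index <- function(w, idx, ncell) {
  out <- numeric(ncell)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

raked_discrepancy <- function(w, cellidx, targets) {
  m <- 0
  for (k in seq_along(targets)) {
    cur <- rowsum_by_index(w, cellidx[[k]], length(targets[[k]]))
    pos <- targets[[k]] > 0
    m <- max(m, abs(cur[pos] - targets[[k]][pos]) / targets[[k]][pos])
  }
  m
}

#' Maximum relative margin discrepancy of a weight vector
#'
#' Convergence diagnostic: the largest relative deviation, over all cells of
#' all margins, of the weighted sample total from the margin target. Zero
#' target cells are excluded (they are flagged by [validate_margins()]).
#'
#' @inheritParams rake
#' @param weights Numeric weight per sample row.
#' @return A single non-negative number.
#' @export
margin_discrepancy <- function(sample, weights, margins) {
  if (inherits(margins, "margin_spec")) margins <- list(margins)
  stopifnot(length(weights) == nrow(sample))
  cellidx <- lapply(margins, margin_cell_index, sample = sample)
  raked_discrepancy(weights, cellidx,
                    lapply(margins, function(m) as.numeric(m$table)))
}

#' Trim weights into fixed bounds
#'
#' Clamps each weight into `[lower, upper]`. Trimming guards against the
#' variance inflation caused by extreme weights; it is applied once, after
#' raking, with no re-raking (so trimmed margins match only approximately).
#'
#' @param weights Numeric vector.
#' @param lower,upper Bounds, `0 < lower < upper`.
#' @return The clamped vector, with attribute `trimmed` = named counts of
#'   units clamped at each bound.
#' @export
trim_weights <- function(weights, lower = 0.1, upper = 10) {
  stopifnot(lower < upper)
  n_lo <- sum(weights < lower, na.rm = TRUE)
  n_hi <- sum(weights > upper, na.rm = TRUE)
  out <- pmin(pmax(weights, lower), upper)
  attr(out, "trimmed") <- c(lower = n_lo, upper = n_hi)
  out
}

#' Rescale weights to a stated total
#'
#' Multiplies all weights by `total / sum(weights)`, preserving their ratios
#' exactly. Used as the final step so the weighted sample size equals the
#' number of weighted-eligible participants.
#'
#' @param weights Numeric vector with positive sum.
#' @param total Target sum.
#' @return Rescaled vector.
#' @export
rescale_weights <- function(weights, total) {
  s <- sum(weights)
  if (!is.finite(s) || s <= 0) stop("weight sum must be positive to rescale")
  weights * (total / s)
}

#' Two-phase poststratification weights with missing questionnaire data
#'
#' Questionnaire nonresponse leaves many units missing the education, marital,
#' occupation and children variables while register variables (sex, age) are
#' nearly complete. Weights are therefore built in two phases:
#'
#' 1. **Phase 1** rakes the complete cases (non-missing on every full-margin
#'    variable) to the full margin set.
#' 2. **Phase 2** rakes the *whole* eligible sample (non-missing on the
#'    reduced-margin variables) to the reduced margins — typically sex and age
#'    only — and its weights are assigned only to units that were incomplete
#'    on the full-margin variables.
#'
#' Within each phase the margin targets are rescaled to that phase's sample
#' size, so raked weights live on the mean-1 (relative) scale on which the
#' default trim bounds 0.1 and 10 are meaningful; only the weights' ratios
#' matter downstream. The concatenated weights are trimmed to
#' `control$trim_lower..trim_upper` and rescaled so they sum to the number
#' of eligible units (or `total`). Units missing a reduced-margin variable
#' receive no weight and are reported.
#'
#' @inheritParams rake
#' @param full_margins Margins over all sociodemographic variables (phase 1).
#' @param reduced_margins Margins over the near-complete variables (phase 2).
#' @param total Sum the final weights are rescaled to; defaults to the number
#'   of eligible units.
#' @return A `weight_result` with `weights` (`id`, `weight`, `phase`),
#'   per-phase convergence info, `trimmed` counts, `excluded_ids`, and `total`.
#' @export
two_phase_weights <- function(sample, full_margins, reduced_margins,
                              control = raking_control(), total = NULL) {
  if (inherits(full_margins, "margin_spec")) full_margins <- list(full_margins)
  if (inherits(reduced_margins, "margin_spec"))
    reduced_margins <- list(reduced_margins)
  full_vars <- unique(unlist(lapply(full_margins, `[[`, "variables")))
  red_vars <- unique(unlist(lapply(reduced_margins, `[[`, "variables")))

  miss_red <- Reduce(`|`, lapply(red_vars, function(v) is.na(sample[[v]])),
                     rep(FALSE, nrow(sample)))
  eligible <- sample[!miss_red, , drop = FALSE]
  excluded_ids <- sample$id[miss_red]
  if (nrow(eligible) == 0L) stop("no units are non-missing on the reduced margins")

  complete <- !Reduce(`|`, lapply(full_vars, function(v) is.na(eligible[[v]])),
                      rep(FALSE, nrow(eligible)))

  scale_margins <- function(margins, n) {
    tot <- sum(margins[[1]]$table)
    lapply(margins, function(m) {
      m$table <- m$table * (n / sum(m$table))
      m
    })
  }
  phase1 <- NULL
  if (any(complete))
    phase1 <- rake(eligible[complete, , drop = FALSE],
                   scale_margins(full_margins, sum(complete)), control)
  phase2 <- rake(eligible, scale_margins(reduced_margins, nrow(eligible)),
                 control)

  w <- phase2$weights$weight          # default: phase-2 weight
  phase <- rep(2L, nrow(eligible))
  if (!is.null(phase1)) {
    w[complete] <- phase1$weights$weight
    phase[complete] <- 1L
  }
  if (is.null(total)) total <- nrow(eligible)

  if (control$rescale_before_trim) w <- rescale_weights(w, total)
  w <- trim_weights(w, control$trim_lower, control$trim_upper)
  trimmed <- attr(w, "trimmed")
  w <- rescale_weights(as.numeric(w), total)

  structure(list(
    weights = data.frame(id = eligible$id, weight = w, phase = phase),
    iterations = c(phase1 = if (is.null(phase1)) NA_integer_ else
      phase1$iterations, phase2 = phase2$iterations),
    converged = all(c(if (!is.null(phase1)) phase1$converged, phase2$converged)),
    max_discrepancy = max(if (is.null(phase1)) 0 else phase1$max_discrepancy,
                          phase2$max_discrepancy),
    trimmed = trimmed, excluded_ids = excluded_ids, total = total,
    control = control), class = "weight_result")
}

#' @export
print.weight_result <- function(x, ...) {
  cat("Raking weight result:", nrow(x$weights), "weighted units\n")
  if ("phase" %in% names(x$weights)) {
    tb <- table(x$weights$phase)
    cat("  phases:", paste(sprintf("phase %s = %d", names(tb), tb),
                           collapse = ", "), "\n")
    cat("  excluded (missing reduced-margin variables):",
        length(x$excluded_ids), "\n")
    cat("  trimmed:", x$trimmed["lower"], "at lower,",
        x$trimmed["upper"], "at upper bound\n")
    cat(sprintf("  weight sum: %.6g\n", sum(x$weights$weight)))
  }
  cat(sprintf("  converged: %s (max margin discrepancy %.3g)\n",
              all(x$converged), x$max_discrepancy))
  cat("  weight range:",
      sprintf("[%.4g, %.4g]", min(x$weights$weight), max(x$weights$weight)),
      "\n")
  invisible(x)
}
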