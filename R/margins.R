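#' Construct a raking margin specification
#'
#' A margin is a one-way or two-way contingency table of reference-population
#' counts over sociodemographic categories. Margins are the unit the raking
#' loop iterates over: each sweep adjusts unit weights so the weighted sample
#' table matches the margin cell by cell.
#'
#' @param table A named numeric vector (one-way) or a numeric matrix with
#'   complete `dimnames` (two-way) of non-negative cell counts, or a `table`.
#' @param variables Character vector of one or two variable names, in the
#'   order of the table dimensions.
#' @param source Optional free-text label recording where the counts came from.
#' @param proportions Logical; if `TRUE` the cells are proportions and are
#'   scaled by `population_total` to counts.
#' @param population_total Population total used to scale proportions.
#'
#' @return An object of class `margin_spec`: a list with elements `variables`,
#'   `table` (an array with dimnames), and `source`.
#' @examples
#' margin_spec(c(women = 512, men = 488), "sex")
#' @export
margin_spec <- function(table, variables, source = NA_character_,
                        proportions = FALSE, population_total = NULL) {
  if (is.table(table)) table <- unclass(table)
  if (is.null(dim(table))) {
    if (is.null(names(table))) stop("one-way margin table must be named")
    table <- array(as.numeric(table), dim = length(table),
                   dimnames = list(names(table)))
  }
  nd <- length(dim(table))
  if (nd > 2L) stop("margins of dimension >= 3 are not supported")
  variables <- as.character(variables)
  if (length(variables) != nd)
    stop("'variables' must name each table dimension (", nd, " given ",
         length(variables), ")")
  if (anyNA(table) || any(table < 0))
    stop("margin cells must be non-negative and non-missing")
  if (any(vapply(dimnames(table), is.null, logical(1))))
    stop("margin table must carry complete dimnames")
  if (proportions) {
    if (is.null(population_total) || population_total <= 0)
      stop("'population_total' required to scale a proportion margin")
    if (abs(sum(table) - 1) > 1e-6)
      warning("proportion margin cells sum to ", signif(sum(table), 6),
              ", not 1; scaling anyway")
    table <- table / sum(table) * population_total
  }
  structure(list(variables = variables, table = table, source = source),
            class = "margin_spec")
}

#' @export
print.margin_spec <- function(x, ...) {
  cat("Raking margin:", paste(x$variables, collapse = " x "),
      sprintf("(total %.6g", sum(x$table)))
  if (!is.na(x$source)) cat(", source: ", x$source, sep = "")
  cat(")\n")
  print(x$table)
  invisible(x)
}

#' Read a margin table from CSV
#'
#' Expected layout: one or two leading category columns whose *headers* are the
#' variable names, and a final numeric `count` column. Example header for a
#' sex-by-age two-way margin: `sex,age_group,count`.
#'
#' @param path Path to a CSV file.
#' @param source Label stored on the margin; defaults to the file name.
#' @return A [margin_spec].
#' @export
read_margin_table <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop("margin file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2L || ncol(d) > 3L)
    stop("margin CSV must have 1 or 2 category columns plus 'count': ", path)
  if (names(d)[ncol(d)] != "count")
    stop("last column of a margin CSV must be named 'count': ", path)
  vars <- names(d)[-ncol(d)]
  cnt <- d[["count"]]
  if (!is.numeric(cnt)) stop("'count' column is not numeric: ", path)
  bad <- which(is.na(cnt) | cnt < 0)
  if (length(bad))
    stop("negative or missing count at data row ", bad[1], " of ", path)
  key <- do.call(paste, c(d[vars], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate category tuple at data row ", which(duplicated(key))[1],
         " of ", path)
  if (length(vars) == 1L) {
    tab <- array(cnt, dim = length(cnt), dimnames = list(d[[vars]]))
  } else {
    lv1 <- unique(d[[vars[1]]]); lv2 <- unique(d[[vars[2]]])
    tab <- matrix(NA_real_, length(lv1), length(lv2),
                  dimnames = list(lv1, lv2))
    tab[cbind(match(d[[vars[1]]], lv1), match(d[[vars[2]]], lv2))] <- cnt
    if (anyNA(tab))
      stop("margin CSV does not cover the full category cross: ", path)
  }
  margin_spec(tab, vars, source = source)
}

#' Write a margin table to CSV
#'
#' Inverse of [read_margin_table()]; `read_margin_table(write_margin_table(m))`
#' reproduces `m`'s variables and cells exactly.
#'
#' @param margin A [margin_spec].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_margin_table <- function(margin, path) {
  stopifnot(inherits(margin, "margin_spec"))
  tab <- margin$table
  if (length(dim(tab)) == 1L) {
    d <- data.frame(dimnames(tab)[[1]], as.numeric(tab))
  } else {
    idx <- expand.grid(seq_len(nrow(tab)), seq_len(ncol(tab)))
    d <- data.frame(rownames(tab)[idx[, 1]], colnames(tab)[idx[, 2]],
                    tab[as.matrix(idx)])
  }
  names(d) <- c(margin$variables, "count")
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-tabulate sample rows on harmonized categories
#'
#' Rows with a missing value in any of the requested variables are excluded
#' from the table and counted in the `excluded` attribute, mirroring how
#' questionnaire nonresponse removes rows from margin-variable tabulations.
#'
#' @param sample A data.frame of sample rows.
#' @param variables One or two column names to tabulate.
#' @param weights Optional non-negative per-row weights (default unit weights).
#' @param levels Optional named list of category levels per variable, so empty
#'   categories appear as zero cells (needed when comparing to a margin).
#' @return An array of weighted counts with attribute `excluded` (number of
#'   rows dropped for missingness).
#' @export
tabulate_sample <- function(sample, variables, weights = NULL, levels = NULL) {
  missing_vars <- setdiff(variables, names(sample))
  if (length(missing_vars))
    stop("unknown variable(s): ", paste(missing_vars, collapse = ", "))
  if (is.null(weights)) weights <- rep(1, nrow(sample))
  if (length(weights) != nrow(sample))
    stop("weights length must equal number of sample rows")
  cols <- lapply(variables, function(v) sample[[v]])
  keep <- !Reduce(`|`, lapply(cols, is.na), rep(FALSE, nrow(sample)))
  fac <- lapply(seq_along(variables), function(i) {
    lv <- if (!is.null(levels)) levels[[variables[i]]] else NULL
    if (is.null(lv)) lv <- unique(cols[[i]][keep])
    factor(cols[[i]][keep], levels = lv)
  })
  tab <- tapply(weights[keep], fac, sum, default = 0)
  tab <- array(tab, dim = dim(tab), dimnames = dimnames(tab))
  attr(tab, "excluded") <- sum(!keep)
  tab
}

#' Validate margins against a sample before raking
#'
#' Raking requires that margin and sample share identical category sets, that
#' no margin cell is zero, and that every positive-target cell contains at
#' least one sample unit to carry the mass. Violations are returned as a
#' report, not thrown; `blocking` issues make [rake()] refuse to run.
#'
#' @param margins A list of [margin_spec] objects (a single spec is accepted).
#' @param sample Sample data.frame with the margin variables as columns.
#' @return A data.frame of class `margin_validation` with columns `margin`,
#'   `issue`, `cell`, `blocking`. Zero rows means fully rakeable.
#' @export
validate_margins <- function(margins, sample) {
  if (inherits(margins, "margin_spec")) margins <- list(margins)
  issues <- list()
  push <- function(margin, issue, cell, blocking) {
    issues[[length(issues) + 1L]] <<-
      data.frame(margin = margin, issue = issue, cell = cell,
                 blocking = blocking, stringsAsFactors = FALSE)
  }
  for (m in margins) {
    lab <- paste(m$variables, collapse = "x")
    zc <- which(m$table == 0, arr.ind = TRUE)
    if (length(zc))
      push(lab, "zero_margin_cell", paste(cell_names(m$table, zc),
                                          collapse = "; "), TRUE)
    miss_v <- setdiff(m$variables, names(sample))
    if (length(miss_v)) {
      push(lab, "variable_absent", paste(miss_v, collapse = "; "), TRUE)
      next
    }
    ok <- TRUE
    for (i in seq_along(m$variables)) {
      mcats <- dimnames(m$table)[[i]]
      scats <- unique(stats::na.omit(sample[[m$variables[i]]]))
      extra_m <- setdiff(mcats, scats)
      extra_s <- setdiff(scats, mcats)
      if (length(extra_s)) {
        push(lab, "sample_category_not_in_margin",
             paste0(m$variables[i], ": ", paste(extra_s, collapse = ", ")),
             TRUE)
        ok <- FALSE
      }
      if (length(extra_m))
        # a margin category with no sample units at all surfaces below as an
        # empty cell; still name the mismatch explicitly
        push(lab, "margin_category_not_in_sample",
             paste0(m$variables[i], ": ", paste(extra_m, collapse = ", ")),
             TRUE)
    }
    if (!ok) next
    st <- tabulate_sample(sample, m$variables,
                          levels = stats::setNames(dimnames(m$table),
                                                   m$variables))
    empty <- which(st == 0 & m$table > 0, arr.ind = TRUE)
    if (length(empty))
      push(lab, "empty_sample_cell", paste(cell_names(m$table, empty),
                                           collapse = "; "), TRUE)
  }
  out <- if (length(issues)) do.call(rbind, issues) else
    data.frame(margin = character(), issue = character(),
               cell = character(), blocking = logical())
  class(out) <- c("margin_validation", "data.frame")
  out
}

cell_names <- function(tab, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 1L)
  dn <- dimnames(tab)
  apply(idx, 1L, function(i)
    paste(mapply(function(d, j) dn[[d]][j], seq_along(dn), i), collapse = ":"))
}

#' Collapse categories with a declarative harmonization map
#'
#' Reference tables and questionnaires rarely share category schemes (e.g. a
#' register may fold "Cohabiting" into "Single"). Harmonization is applied
#' explicitly from a mapping table, never silently.
#'
#' @param data A data.frame (sample) whose categories are recoded in place.
#' @param mapping A data.frame with columns `variable`, `from_category`,
#'   `to_category`, or a path to such a CSV.
#' @return `data` with the recodes applied.
#' @export
harmonize_categories <- function(data, mapping) {
  if (is.character(mapping)) mapping <- utils::read.csv(mapping,
                                                        stringsAsFactors = FALSE)
  need <- c("variable", "from_category", "to_category")
  if (!all(need %in% names(mapping)))
    stop("harmonization mapping needs columns: ", paste(need, collapse = ", "))
  for (i in seq_len(nrow(mapping))) {
    v <- mapping$variable[i]
    if (!v %in% names(data)) stop("harmonization variable not in data: ", v)
    col <- as.character(data[[v]])
    col[col == mapping$from_category[i]] <- mapping$to_category[i]
    data[[v]] <- col
  }
  data
}
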