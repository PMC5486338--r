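#' Classify hemoglobin into anemia severity categories
#'
#' Applies the standard under-five cut-offs for altitude-adjusted
#' hemoglobin: severe below 7, moderate 7 to below 10, mild 10 to below 11,
#' non-anemic 11 g/dL and above.  Intervals are half-open (closed on the
#' left) so the partition is exhaustive; hemoglobin is recorded to 0.1 g/dL
#' so this convention is observationally equivalent to the conventional
#' 7-9.9 / 10-10.9 category bounds.
#'
#' @param hb numeric vector of hemoglobin concentrations in g/dL
#'   (non-negative).
#' @return ordered factor with levels `severe < moderate < mild <
#'   non-anemic`.
#' @examples
#' classify_anemia(c(6.9, 10.0, 11.0))  # severe, mild, non-anemic
#' @export
classify_anemia <- function(hb) {
  if (!is.numeric(hb)) stop("'hb' must be numeric")
  if (any(hb < 0, na.rm = TRUE)) stop("hemoglobin cannot be negative")
  cut(hb, breaks = c(0, 7, 10, 11, Inf), right = FALSE,
      labels = c("severe", "moderate", "mild", "non-anemic"),
      include.lowest = TRUE, ordered_result = TRUE)
}

# round half away from zero, as display tables do (base round() is
# round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cross-tabulate a categorical covariate against anemia status
#'
#' Builds the levels x (anemic, non-anemic) contingency table with row
#' percentages (rounded half-up to 1 decimal) and the classical Pearson
#' chi-square test of association.  Rows with a missing covariate value are
#' dropped.  The anemic indicator is taken from an `anemic` column when
#' present (factor/logical, "yes"/TRUE = anemic), otherwise computed as
#' hemoglobin below 11 g/dL from the `hb` column.
#'
#' @param data data.frame of child records.
#' @param variable name of a categorical column of `data`.
#' @param weights optional per-row non-negative weights; counts become
#'   weighted sums and the chi-square is computed on the weighted table.
#' @return object of class `anemia_crosstab`: list with `variable`,
#'   `levels`, `counts` (levels x 2 matrix), `row_pct`, `chi2`, `df`
#'   (`levels - 1`), `p`, `n`.
#' @examples
#' anemia_crosstab(table1_fixture(), "sex")
#' @export
anemia_crosstab <- function(data, variable, weights = NULL) {
  if (!variable %in% names(data)) stop("unknown variable: ", variable)
  x <- data[[variable]]
  if (is.numeric(x) && length(unique(stats::na.omit(x))) > 12L) {
    stop("'", variable, "' does not look categorical")
  }
  x <- as.factor(x)
  anemic <- if ("anemic" %in% names(data)) {
    a <- data[["anemic"]]
    if (is.factor(a) || is.character(a)) as.character(a) %in% c("yes", "TRUE", "1")
    else as.logical(a)
  } else if ("hb" %in% names(data)) {
    data[["hb"]] < 11
  } else {
    stop("'data' needs an 'anemic' or 'hb' column")
  }
  if (is.null(weights)) weights <- rep(1, nrow(data))
  if (length(weights) != nrow(data) || any(weights < 0, na.rm = TRUE)) {
    stop("'weights' must be non-negative, one per row")
  }
  keep <- !is.na(x) & !is.na(anemic)
  x <- droplevels(x[keep]); anemic <- anemic[keep]; w <- weights[keep]
  lev <- levels(x)
  counts <- cbind(
    anemic = vapply(lev, function(l) sum(w[x == l & anemic]), 0),
    non_anemic = vapply(lev, function(l) sum(w[x == l & !anemic]), 0))
  rownames(counts) <- lev
  if (any(rowSums(counts) == 0)) stop("a level of '", variable,
                                      "' has zero total count")
  row_pct <- round_half_up(100 * counts / rowSums(counts), 1)
  test <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(variable = variable, levels = lev, counts = counts,
                 row_pct = row_pct, chi2 = unname(test$statistic),
                 df = unname(test$parameter), p = test$p.value,
                 n = sum(counts)),
            class = "anemia_crosstab")
}

#' @export
print.anemia_crosstab <- function(x, ...) {
  cat("Anemia cross-tabulation:", x$variable, "\n")
  tab <- cbind(
    anemic = sprintf("%g (%.1f%%)", x$counts[, 1], x$row_pct[, 1]),
    `non-anemic` = sprintf("%g (%.1f%%)", x$counts[, 2], x$row_pct[, 2]))
  rownames(tab) <- x$levels
  print(tab, quote = FALSE)
  cat(sprintf("Pearson chi-square = %.3f, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Screen covariates by chi-square p-value
#'
#' Keeps the variables whose cross-tabulation p-value falls below `alpha`
#' (default 0.2, the conventional liberal inclusion threshold used when
#' pre-selecting covariates for a multivariable model).
#'
#' @param tabs list of [anemia_crosstab()] results computed on one dataset.
#' @param alpha inclusion threshold on the p-value.
#' @return character vector of variable names with `p < alpha`, in the
#'   original order.
#' @export
screen_variables <- function(tabs, alpha = 0.2) {
  if (length(tabs) == 0L) stop("empty list of cross-tabulations")
  if (!all(vapply(tabs, inherits, TRUE, "anemia_crosstab"))) {
    stop("'tabs' must be a list of anemia_crosstab objects")
  }
  vars <- vapply(tabs, `[[`, "", "variable")
  ps <- vapply(tabs, `[[`, 0, "p")
  vars[ps < alpha]
}

#' Empirical quantile level of a hemoglobin cut-off
#'
#' Returns the proportion of observations strictly below `cutoff`, i.e. the
#' empirical distribution function of `hb` evaluated just below the
#' cut-off.  This is how an anemia prevalence is mapped to the quantile
#' level theta at which the quantile regression is fitted (e.g. a 37%
#' prevalence of Hb below 11 g/dL motivates theta = 0.37).
#'
#' @param hb non-empty numeric vector of hemoglobin values.
#' @param cutoff cut-off in g/dL.
#' @return a proportion in \[0, 1\].
#' @examples
#' prevalence_to_theta(c(6, 8, 10.5, 11.5), 11)  # 0.75
#' @export
prevalence_to_theta <- function(hb, cutoff) {
  if (length(hb) == 0L) stop("'hb' is empty")
  mean(hb < cutoff)
}

#' Write exploratory cross-tabulation tables to CSV
#'
#' Runs [anemia_crosstab()] on each requested variable, writes one CSV per
#' variable (levels, counts, row percentages, chi-square, df, p) plus a
#' `screened_variables.csv` with the `p < alpha` selection.
#'
#' @param data child-level data.frame with an anemia indicator (see
#'   [anemia_crosstab()]).
#' @param variables character vector of categorical columns; defaults to
#'   all factor/character columns except `anemic` and the district label.
#' @param out_dir output directory (created if needed).
#' @param alpha screening threshold passed to [screen_variables()].
#' @param weights optional per-row weights.
#' @return invisibly, the list of crosstab objects.
#' @export
eda_tables <- function(data, variables = NULL, out_dir, alpha = 0.2,
                       weights = NULL) {
  if (is.null(variables)) {
    is_cat <- vapply(data, function(c) is.factor(c) || is.character(c), TRUE)
    variables <- setdiff(names(data)[is_cat], c("anemic", "district"))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- lapply(variables, function(v) anemia_crosstab(data, v, weights))
  for (tab in tabs) {
    df <- data.frame(level = tab$levels,
                     anemic = tab$counts[, 1], non_anemic = tab$counts[, 2],
                     pct_anemic = tab$row_pct[, 1],
                     pct_non_anemic = tab$row_pct[, 2],
                     chi2 = tab$chi2, df = tab$df, p = tab$p)
    utils::write.csv(df, file.path(out_dir, paste0(tab$variable, ".csv")),
                     row.names = FALSE)
  }
  writeLines(screen_variables(tabs, alpha),
             file.path(out_dir, "screened_variables.csv"))
  invisible(tabs)
}
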