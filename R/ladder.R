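#' The five-model comparison ladder
#'
#' Builds the standard ladder of model specifications used to justify the
#' structured spatial additive quantile model:
#' \enumerate{
#'   \item Gaussian linear regression, every covariate as a linear fixed
#'     effect (the mean model);
#'   \item linear quantile regression, categorical fixed effects only;
#'   \item additive quantile regression, fixed effects plus RW2 smooths of
#'     the three continuous covariates;
#'   \item spatial quantile regression, fixed effects plus the ICAR
#'     district effect;
#'   \item structured spatial additive quantile regression, fixed effects
#'     plus smooths plus the spatial effect.
#' }
#'
#' @param level integer 1-5.
#' @param theta quantile level for the AL models (levels 2-5).
#' @param roles named list describing covariate roles: `response` (name of
#'   the hemoglobin column), `fixed` (character vector of categorical
#'   covariates), `smooth` (the continuous covariates, typically child
#'   age, mother's age at birth and breastfeeding duration), `spatial`
#'   (the district column).
#' @return a list of class `staqr_model_spec` with `level`, `formula`,
#'   `likelihood`, `theta` (absent/NA for level 1) and `description`.
#' @examples
#' roles <- list(response = "hb", fixed = c("sex", "fever"),
#'               smooth = c("child_age", "mother_age", "breastfeed"),
#'               spatial = "district")
#' build_model(5, theta = 0.37, roles)$formula
#' @export
build_model <- function(level, theta = 0.37, roles) {
  level <- as.integer(level)
  if (!level %in% 1:5) stop("'level' must be 1, 2, 3, 4 or 5")
  need <- c("response", "fixed", "smooth", "spatial")
  missing_roles <- setdiff(need, names(roles))
  if (length(missing_roles)) {
    stop("missing covariate role(s): ", paste(missing_roles, collapse = ", "))
  }
  if (length(roles$smooth) < 1L && level %in% c(1L, 3L, 5L)) {
    stop("levels 1, 3 and 5 need the smooth covariate role")
  }
  terms <- switch(level,
    `1` = c(roles$fixed, roles$smooth),                      # all linear
    `2` = roles$fixed,
    `3` = c(roles$fixed, sprintf("s(%s)", roles$smooth)),
    `4` = c(roles$fixed, sprintf("mrf(%s)", roles$spatial)),
    `5` = c(roles$fixed, sprintf("s(%s)", roles$smooth),
            sprintf("mrf(%s)", roles$spatial)))
  descriptions <- c("simple linear regression (Gaussian mean model)",
                    "linear quantile regression",
                    "additive quantile regression",
                    "spatial quantile regression",
                    "structured spatial additive quantile regression")
  structure(list(
    level = level,
    formula = stats::reformulate(terms, response = roles$response),
    likelihood = if (level == 1L) "gaussian" else "al",
    theta = if (level == 1L) NA_real_ else theta,
    description = descriptions[level]), class = "staqr_model_spec")
}

#' @export
print.staqr_model_spec <- function(x, ...) {
  cat(sprintf("Model %d: %s\n  %s\n", x$level, x$description,
              deparse(x$formula)))
  invisible(x)
}

#' Fit the model ladder
#'
#' Fits each requested ladder level with [staqr()] on one dataset.
#'
#' @param data child-level data.frame.
#' @param graph [adjacency_graph()] for the spatial levels.
#' @param roles covariate roles, see [build_model()].
#' @param theta quantile level for the AL models.
#' @param levels which ladder levels to fit (default all five).
#' @param ... MCMC settings passed to [staqr()] (`iters`, `burnin`,
#'   `thin`, `seed`, `priors`).
#' @return named list of `staqr` fits (`model1`, `model2`, ...).
#' @export
fit_ladder <- function(data, graph, roles, theta = 0.37, levels = 1:5, ...) {
  fits <- list()
  for (lv in levels) {
    spec <- build_model(lv, theta, roles)
    fits[[paste0("model", lv)]] <-
      staqr(spec$formula, data, theta = theta, likelihood = spec$likelihood,
            graph = graph, ...)
  }
  fits
}

#' Compare fitted models by DIC
#'
#' Tabulates DIC, the effective number of parameters pD, and the deviance
#' at the posterior mean D for each fit, and flags the smallest-DIC model
#' as selected.  All fits must be on the same dataset.
#'
#' @param fits named list of at least two [staqr()] fits of the same
#'   response vector.
#' @return data.frame of class `staqr_comparison` with one row per model
#'   (columns `model`, `DIC`, `pD`, `D`) and attribute `selected` naming
#'   the argmin-DIC model.
#' @export
compare_models <- function(fits) {
  if (length(fits) < 2L) stop("need at least two fitted models to compare")
  if (!all(vapply(fits, inherits, TRUE, "staqr"))) {
    stop("'fits' must be a list of staqr fits")
  }
  cks <- vapply(fits, function(f) f$data_checksum, numeric(3))
  if (any(apply(cks, 1, function(r) max(abs(r - r[1]))) > 1e-8)) {
    stop("models were fitted on different datasets")
  }
  tab <- data.frame(
    model = names(fits),
    DIC = vapply(fits, function(f) unname(f$dic["DIC"]), 0),
    pD = vapply(fits, function(f) unname(f$dic["pD"]), 0),
    D = vapply(fits, function(f) unname(f$dic["D_at_mean"]), 0),
    row.names = NULL)
  attr(tab, "selected") <- tab$model[which.min(tab$DIC)]
  class(tab) <- c("staqr_comparison", "data.frame")
  tab
}

#' @export
print.staqr_comparison <- function(x, ...) {
  cat("Model comparison (deviance information criterion):\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  cat("Selected (smallest DIC):", attr(x, "selected"), "\n")
  invisible(x)
}
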