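#' Fixed effects across quantile levels
#'
#' Assembles the summary table of categorical fixed effects across a set
#' of per-quantile fits: posterior mean and sd plus per-theta posterior
#' summaries, in the reference-category layout of the fitted design.  A
#' positive effect raises hemoglobin concentration, i.e. lowers anemia
#' risk.  All fits must share the same fixed-effect structure (identical
#' design columns, hence identical reference coding).
#'
#' @param fits a named list of [staqr()] fits, one per quantile level, or
#'   a single fit.
#' @param prob credible level for the significance flag (default 0.95).
#' @return data.frame of class `staqr_effects`: one row per fixed-effect
#'   contrast, with columns `mean_<theta>`, `sd_<theta>`, `lower_<theta>`,
#'   `upper_<theta>` and `sig_<theta>` per fit.
#' @export
effects_table <- function(fits, prob = 0.95) {
  if (inherits(fits, "staqr")) fits <- list(fits)
  if (!all(vapply(fits, inherits, TRUE, "staqr"))) {
    stop("'fits' must be staqr fits")
  }
  cols <- lapply(fits, function(f) colnames(f$X))
  if (length(unique(vapply(cols, paste, "", collapse = "|"))) != 1L) {
    stop("fits have different fixed-effect structure / reference coding")
  }
  a <- (1 - prob) / 2
  out <- data.frame(term = cols[[1L]])
  for (k in seq_along(fits)) {
    f <- fits[[k]]
    tag <- if (f$likelihood == "al") format(f$theta) else "mean"
    beta <- f$draws$beta
    out[[paste0("mean_", tag)]] <- colMeans(beta)
    out[[paste0("sd_", tag)]] <- apply(beta, 2, stats::sd)
    lo <- apply(beta, 2, stats::quantile, a)
    hi <- apply(beta, 2, stats::quantile, 1 - a)
    out[[paste0("lower_", tag)]] <- lo
    out[[paste0("upper_", tag)]] <- hi
    out[[paste0("sig_", tag)]] <- lo > 0 | hi < 0
  }
  class(out) <- c("staqr_effects", "data.frame")
  out
}

#' Posterior smooth-effect curves
#'
#' Extracts the posterior mean of a fitted smooth term on its covariate
#' grid (the sorted unique observed values) with pointwise credible
#' bands.  Curves are centred (each draw sums to zero over the grid).
#'
#' @param fit a fitted [staqr()] model.
#' @param term name of a smooth (`s()`) term in the fit.
#' @param prob pointwise credible level (default 0.95).
#' @return data.frame with columns `grid`, `mean`, `lower`, `upper`.
#' @export
smooth_curves <- function(fit, term, prob = 0.95) {
  stopifnot(inherits(fit, "staqr"))
  b <- fit$blocks[[term]]
  if (is.null(b) || b$kind != "rw2") {
    stop("'", term, "' is not a smooth term of this fit")
  }
  a <- (1 - prob) / 2
  draws <- fit$draws$f[[term]]
  data.frame(grid = b$grid,
             mean = colMeans(draws),
             lower = apply(draws, 2, stats::quantile, a),
             upper = apply(draws, 2, stats::quantile, 1 - a))
}

#' District spatial-effect table
#'
#' Posterior summaries of the intrinsic CAR spatial effect: per-district
#' posterior mean, sd and credible interval, a two-class risk flag
#' (positive posterior mean = higher hemoglobin = lower anemia risk;
#' negative = higher risk), and whether the credible interval excludes
#' zero.  Effects satisfy the sum-to-zero constraint, and every region of
#' the fitted graph is present exactly once.  The table is
#' choropleth-ready: join it to region geometry by the `district` column.
#'
#' @param fit a fitted [staqr()] model containing an `mrf()` term.
#' @param prob credible level (default 0.95).
#' @return data.frame of class `staqr_spatial` with columns `district`,
#'   `mean`, `sd`, `lower`, `upper`, `risk`
#'   (`"lower-risk"`/`"higher-risk"`), `significant`.
#' @export
spatial_table <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "staqr"))
  kinds <- vapply(fit$blocks, `[[`, "", "kind")
  sp <- names(kinds)[kinds == "icar"]
  if (length(sp) == 0L) stop("fit has no spatial (mrf) term")
  out <- spatial_or_group_table(fit, sp[1L], prob)
  names(out)[1L] <- "district"
  class(out) <- c("staqr_spatial", "data.frame")
  out
}

spatial_or_group_table <- function(fit, term, prob = 0.95) {
  b <- fit$blocks[[term]]
  a <- (1 - prob) / 2
  draws <- fit$draws$f[[term]]
  lo <- apply(draws, 2, stats::quantile, a)
  hi <- apply(draws, 2, stats::quantile, 1 - a)
  mn <- colMeans(draws)
  data.frame(region = as.character(b$grid), mean = mn,
             sd = apply(draws, 2, stats::sd), lower = lo, upper = hi,
             risk = ifelse(mn > 0, "lower-risk", "higher-risk"),
             significant = lo > 0 | hi < 0, row.names = NULL)
}

#' Write the report surfaces of a set of fits to CSV
#'
#' Writes the cross-quantile fixed-effects table, one smooth-curve CSV per
#' smooth term of the first fit, and the district spatial-effect table
#' when present.  Deterministic given the fits.
#'
#' @param fits named list of [staqr()] fits (one per theta) or a single
#'   fit.
#' @param out_dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_report <- function(fits, out_dir) {
  if (inherits(fits, "staqr")) fits <- list(fits)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(out_dir, "fixed_effects.csv")
  utils::write.csv(effects_table(fits), p, row.names = FALSE)
  paths <- c(paths, p)
  f1 <- fits[[1L]]
  kinds <- vapply(f1$blocks, `[[`, "", "kind")
  for (nm in names(kinds)[kinds == "rw2"]) {
    p <- file.path(out_dir, paste0("smooth_", nm, ".csv"))
    utils::write.csv(smooth_curves(f1, nm), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (any(kinds == "icar")) {
    p <- file.path(out_dir, "spatial_effects.csv")
    utils::write.csv(spatial_table(f1), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
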