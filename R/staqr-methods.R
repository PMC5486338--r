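#' @export
print.staqr <- function(x, ...) {
  if (x$likelihood == "al") {
    cat(sprintf("Structured additive quantile regression (theta = %g)\n",
                x$theta))
  } else {
    cat("Gaussian mean regression (Gibbs fit)\n")
  }
  cat("Formula:", deparse(x$formula), "\n")
  cat(sprintf("n = %d, %d stored draws (%d iters, burn-in %d, thin %d)\n",
              x$n, x$ndraw, x$mcmc$iters, x$mcmc$burnin, x$mcmc$thin))
  if (length(x$blocks)) {
    kinds <- vapply(x$blocks, `[[`, "", "kind")
    cat("Structured terms:",
        paste(sprintf("%s(%s)", kinds, names(x$blocks)), collapse = ", "),
        "\n")
  }
  cat(sprintf("DIC = %.2f (pD = %.2f, Dbar = %.2f)\n",
              x$dic["DIC"], x$dic["pD"], x$dic["Dbar"]))
  invisible(x)
}

#' @export
coef.staqr <- function(object, ...) {
  colMeans(object$draws$beta)
}

#' @export
fitted.staqr <- function(object, ...) {
  posterior_eta(object)
}

#' @export
residuals.staqr <- function(object, ...) {
  object$y - posterior_eta(object)
}

#' Summarise a fitted structured additive quantile model
#'
#' @param object a fitted [staqr()] model.
#' @param prob credible level of the reported intervals (default 0.95).
#' @param ... unused.
#' @return a list of class `summary.staqr` with fixed-effect posterior
#'   summaries, block variance summaries, the scale and DIC components.
#' @export
summary.staqr <- function(object, prob = 0.95, ...) {
  a <- (1 - prob) / 2
  qs <- c(a, 1 - a)
  beta <- object$draws$beta
  fixed <- data.frame(
    mean = colMeans(beta),
    sd = apply(beta, 2, stats::sd),
    lower = apply(beta, 2, stats::quantile, qs[1]),
    upper = apply(beta, 2, stats::quantile, qs[2]))
  fixed$significant <- fixed$lower > 0 | fixed$upper < 0
  vars <- NULL
  if (length(object$blocks)) {
    tau2 <- object$draws$tau2
    vars <- data.frame(
      term = colnames(tau2),
      kind = vapply(object$blocks, `[[`, "", "kind"),
      mean = colMeans(tau2),
      median = apply(tau2, 2, stats::median))
  }
  structure(list(call = object$call, likelihood = object$likelihood,
                 theta = object$theta, fixed = fixed, variances = vars,
                 sigma = mean(object$draws$sigma), dic = object$dic,
                 prob = prob, n = object$n),
            class = "summary.staqr")
}

#' @export
print.summary.staqr <- function(x, ...) {
  if (x$likelihood == "al") {
    cat(sprintf("Structured additive quantile regression, theta = %g, n = %d\n",
                x$theta, x$n))
  } else {
    cat(sprintf("Gaussian mean regression, n = %d\n", x$n))
  }
  cat(sprintf("\nFixed effects (posterior mean, sd, %g%% interval):\n",
              100 * x$prob))
  print(round(x$fixed[, 1:4], 4))
  if (!is.null(x$variances)) {
    cat("\nStructured-term variances (tau^2):\n")
    print(x$variances, row.names = FALSE)
  }
  cat(sprintf("\nScale: %.4f\nDIC = %.2f, pD = %.2f, D_at_mean = %.2f\n",
              x$sigma, x$dic["DIC"], x$dic["pD"], x$dic["D_at_mean"]))
  invisible(x)
}

#' Predict conditional quantiles (or means) for new data
#'
#' Evaluates the posterior-mean predictor on new observations.  Smooth
#' terms are linearly interpolated between fitted grid values; covariate
#' values outside the fitted grid range, or district labels not present in
#' the fitted graph, are errors.
#'
#' @param object a fitted [staqr()] model.
#' @param newdata optional data.frame; defaults to the fitting data rows.
#' @param ... unused.
#' @return numeric vector of predicted conditional theta-quantiles (AL
#'   likelihood) or means (Gaussian).
#' @export
predict.staqr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(posterior_eta(object))
  spec <- parse_staqr_formula(object$formula)
  fixed_formula <- if (length(spec$fixed)) stats::reformulate(spec$fixed) else ~1
  X <- stats::model.matrix(fixed_formula, newdata,
                           xlev = fixed_xlevels(object, newdata, spec))
  X <- X[, colnames(object$X), drop = FALSE]
  eta <- drop(X %*% colMeans(object$draws$beta))
  for (j in seq_along(object$blocks)) {
    b <- object$blocks[[j]]
    fbar <- colMeans(object$draws$f[[j]])
    xnew <- newdata[[b$name]]
    if (b$kind == "rw2") {
      g <- b$grid
      if (any(xnew < min(g) | xnew > max(g))) {
        stop("'", b$name, "' outside the fitted grid range")
      }
      eta <- eta + stats::approx(g, fbar, xout = xnew)$y
    } else {
      idx <- match(as.character(xnew), b$grid)
      if (anyNA(idx)) stop("unseen level(s) of '", b$name, "'")
      eta <- eta + fbar[idx]
    }
  }
  unname(eta)
}

fixed_xlevels <- function(object, newdata, spec) {
  lv <- list()
  for (v in spec$fixed) {
    if (v %in% names(newdata) && !is.numeric(newdata[[v]])) {
      lv[[v]] <- levels(as.factor(newdata[[v]]))
    }
  }
  lv
}

#' Simulate from the posterior predictive distribution
#'
#' For each requested replicate a stored posterior draw (beta, all blocks,
#' scale) is selected and responses are generated from the corresponding
#' likelihood: asymmetric Laplace around the drawn predictor, or Gaussian
#' for the mean model.
#'
#' @param object a fitted [staqr()] model.
#' @param nsim number of simulated response vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns, one simulated response per
#'   column, as [stats::simulate()] conventions.
#' @export
simulate.staqr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  picks <- sample.int(object$ndraw, nsim, replace = TRUE)
  out <- matrix(NA_real_, n, nsim)
  for (k in seq_len(nsim)) {
    d <- picks[k]
    eta <- drop(object$X %*% object$draws$beta[d, ])
    for (j in seq_along(object$blocks)) {
      eta <- eta + object$draws$f[[j]][d, ][object$blocks[[j]]$index]
    }
    sig <- object$draws$sigma[d]
    out[, k] <- if (object$likelihood == "al") {
      eta + ral(n, 0, sig, object$theta)
    } else {
      stats::rnorm(n, eta, sqrt(sig))
    }
  }
  as.data.frame(stats::setNames(as.data.frame(out),
                                paste0("sim_", seq_len(nsim))))
}

#' Plot fitted smooth and spatial effects
#'
#' One panel per smooth term showing the posterior-mean curve with
#' pointwise 95% credible bands, plus (when present) a caterpillar panel
#' of district spatial effects ordered by posterior mean.
#'
#' @param x a fitted [staqr()] model.
#' @param which optional character vector of term names to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.staqr <- function(x, which = NULL, ...) {
  terms <- names(x$blocks)
  if (!is.null(which)) terms <- intersect(terms, which)
  if (length(terms) == 0L) {
    stop("no structured terms to plot")
  }
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(terms)))
  on.exit(graphics::par(old))
  for (nm in terms) {
    b <- x$blocks[[nm]]
    if (b$kind == "rw2") {
      cv <- smooth_curves(x, nm)
      graphics::plot(cv$grid, cv$mean, type = "l",
                     ylim = range(cv$lower, cv$upper),
                     xlab = nm, ylab = "effect (g/dL)", ...)
      graphics::lines(cv$grid, cv$lower, lty = 2)
      graphics::lines(cv$grid, cv$upper, lty = 2)
      graphics::abline(h = 0, col = "grey")
    } else {
      st <- spatial_or_group_table(x, nm)
      ord <- order(st$mean)
      graphics::plot(seq_along(ord), st$mean[ord], pch = 16,
                     ylim = range(st$lower, st$upper),
                     xlab = paste(nm, "(ordered)"), ylab = "effect (g/dL)",
                     ...)
      graphics::segments(seq_along(ord), st$lower[ord],
                         seq_along(ord), st$upper[ord])
      graphics::abline(h = 0, col = "grey")
    }
  }
  invisible(x)
}
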