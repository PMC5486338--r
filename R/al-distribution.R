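#' The asymmetric Laplace distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the asymmetric Laplace (AL) distribution with location `mu`, scale
#' `sigma` and asymmetry `theta`, parameterised so that
#' \deqn{f(y) = \frac{\theta(1-\theta)}{\sigma}
#'   \exp\{-\rho_\theta((y-\mu)/\sigma)\},}
#' where \eqn{\rho_\theta} is the check (pinball) loss.  Under this
#' parameterisation the \eqn{\theta}-quantile of the distribution is exactly
#' `mu`, which is what makes the AL density the working likelihood of
#' Bayesian quantile regression: maximising it in `mu` is equivalent to
#' minimising the check loss.
#'
#' @param x,q vector of quantiles.
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param mu location (the conditional \eqn{\theta}-quantile).
#' @param sigma scale, must be positive.
#' @param theta asymmetry in (0, 1).
#' @param log,log.p logical; if `TRUE`, probabilities/densities are returned
#'   on the log scale.
#'
#' @return `dal` gives the density, `pal` the distribution function, `qal`
#'   the quantile function and `ral` generates random deviates.
#'
#' @examples
#' dal(0, mu = 0, sigma = 1, theta = 0.5)        # theta(1-theta)/sigma = 1/4
#' pal(0, theta = 0.37)                          # P(Y <= mu) = theta
#' qal(0.37, theta = 0.37)                       # = mu
#' @export
dal <- function(x, mu = 0, sigma = 1, theta = 0.5, log = FALSE) {
  check_theta(theta)
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  u <- (x - mu) / sigma
  ld <- base::log(theta * (1 - theta) / sigma) - check_loss(u, theta)
  if (log) ld else exp(ld)
}

#' @rdname dal
#' @export
pal <- function(q, mu = 0, sigma = 1, theta = 0.5, log.p = FALSE) {
  check_theta(theta)
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  u <- (q - mu) / sigma
  p <- ifelse(u < 0,
              theta * exp((1 - theta) * u),
              1 - (1 - theta) * exp(-theta * u))
  if (log.p) base::log(p) else p
}

#' @rdname dal
#' @export
qal <- function(p, mu = 0, sigma = 1, theta = 0.5) {
  check_theta(theta)
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  if (any(p < 0 | p > 1)) stop("'p' must be in [0, 1]")
  ifelse(p < theta,
         mu + sigma / (1 - theta) * base::log(p / theta),
         mu - sigma / theta * base::log((1 - p) / (1 - theta)))
}

#' @rdname dal
#' @export
ral <- function(n, mu = 0, sigma = 1, theta = 0.5) {
  qal(stats::runif(n), mu = mu, sigma = sigma, theta = theta)
}

#' Log-density of the asymmetric Laplace working likelihood
#'
#' Thin wrapper around [dal()] matching the deviance convention used by
#' [compute_dic()]: the AL deviance of a fit is
#' \eqn{-2 \sum_i} `al_logpdf(y[i], eta[i], sigma, theta)`.
#'
#' @param y observation(s).
#' @param mu location (linear predictor).
#' @param sigma scale.
#' @param theta asymmetry level in (0, 1).
#' @return numeric vector of log densities.
#' @export
al_logpdf <- function(y, mu, sigma, theta) {
  dal(y, mu = mu, sigma = sigma, theta = theta, log = TRUE)
}

#' Scale-mixture constants of the asymmetric Laplace
#'
#' The AL distribution admits the normal-exponential mixture representation
#' \eqn{y = \mu + \xi z + \sqrt{\omega^2 \sigma z}\,\epsilon} with
#' \eqn{z \sim \mathrm{Exp}(\mathrm{mean}\ \sigma)} and
#' \eqn{\epsilon \sim N(0,1)}, where \eqn{\xi = (1-2\theta)/\{\theta(1-\theta)\}}
#' and \eqn{\omega^2 = 2/\{\theta(1-\theta)\}}.  These constants drive the
#' Gibbs sampler's closed-form conditionals.
#'
#' @param theta asymmetry level in (0, 1).
#' @return list with components `xi` and `omega2`.
#' @examples
#' al_mixture_constants(0.5)  # xi = 0, omega2 = 8
#' @export
al_mixture_constants <- function(theta) {
  check_theta(theta)
  list(xi = (1 - 2 * theta) / (theta * (1 - theta)),
       omega2 = 2 / (theta * (1 - theta)))
}

check_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta <= 0 || theta >= 1) {
    stop("'theta' must be a single number strictly between 0 and 1")
  }
  invisible(theta)
}
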