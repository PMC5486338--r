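#' Check (pinball) loss
#'
#' The quantile regression loss
#' \eqn{\rho_\theta(u) = u\theta} for \eqn{u \ge 0} and
#' \eqn{u(\theta - 1)} for \eqn{u < 0}.  Minimising its sum over residuals
#' defines the conditional \eqn{\theta}-quantile fit.
#'
#' @param u numeric vector of residuals.
#' @param theta quantile level in (0, 1).
#' @return non-negative numeric vector, zero only at `u = 0`.
#' @examples
#' check_loss(1, 0.37)   # 0.37
#' check_loss(-1, 0.37)  # 0.63
#' @export
check_loss <- function(u, theta) {
  check_theta(theta)
  u * (theta - (u < 0))
}

#' Total check loss of a fit
#'
#' @param y observed responses.
#' @param eta fitted conditional quantiles, same length as `y`.
#' @param theta quantile level in (0, 1).
#' @return the sum of [check_loss()] over residuals `y - eta`.
#' @export
total_loss <- function(y, eta, theta) {
  if (length(y) != length(eta)) stop("'y' and 'eta' must have equal length")
  sum(check_loss(y - eta, theta))
}

#' Frequentist linear quantile regression
#'
#' Minimises the total check loss \eqn{\sum_i \rho_\theta(y_i - x_i'\beta)}
#' for a full-rank design matrix.  A smoothed iteratively reweighted
#' least-squares pass provides a warm start; the solution is then polished to
#' an exact vertex of the underlying linear programme: a basis of `p`
#' interpolated observations is selected and simplex-type pivots are applied
#' until the subgradient optimality condition
#' \eqn{-\theta \le (B^{-\top} \sum_{i \notin h} \psi_i x_i)_j \le 1-\theta}
#' holds for every basis direction.  At a vertex the fit interpolates `p`
#' data points exactly, so e.g. the intercept-only fit returns an order
#' statistic of `y` (the empirical type-1 \eqn{\theta}-quantile when
#' \eqn{n\theta} is not an integer).
#'
#' This solver is the deterministic oracle against which the Gibbs sampler
#' in [staqr()] is validated.
#'
#' @param X design matrix (n x p), full column rank, n > p.
#' @param y response vector.
#' @param theta quantile level in (0, 1).
#' @param max_pivots maximum number of exact pivot steps after the IRLS
#'   warm start.
#' @return numeric coefficient vector of length `p` (named after the columns
#'   of `X`), with attributes `loss` (the attained total check loss),
#'   `basis` (row indices of the interpolated observations) and `optimal`
#'   (logical: whether the vertex optimality certificate was verified; a
#'   `FALSE` value indicates a degenerate/non-unique solution was flagged).
#' @examples
#' set.seed(1)
#' y <- rnorm(101)
#' b <- fit_linear_qr(matrix(1, 101, 1), y, theta = 0.37)
#' all.equal(unname(b), unname(quantile(y, 0.37, type = 1)))
#' @export
fit_linear_qr <- function(X, y, theta, max_pivots = 500L) {
  check_theta(theta)
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("length of 'y' must match nrow(X)")
  if (n <= p) stop("need more observations than columns (n > p)")
  if (qr(X)$rank < p) stop("design matrix is rank deficient")

  beta <- irls_qr(X, y, theta)
  res <- polish_qr_vertex(X, y, theta, beta, max_pivots = max_pivots)
  beta <- drop(res$beta)
  names(beta) <- colnames(X)
  attr(beta, "loss") <- total_loss(y, drop(X %*% res$beta), theta)
  attr(beta, "basis") <- res$basis
  attr(beta, "optimal") <- res$optimal
  beta
}

# Smoothed-check-loss IRLS (Majorise-Minimise on |r|/2 + (theta-1/2) r),
# with the smoothing parameter driven towards zero.
irls_qr <- function(X, y, theta, tol = 1e-8, max_iter = 200L) {
  beta <- qr.solve(X, y)
  c1 <- (theta - 0.5)
  eps <- 1e-3
  for (it in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    w <- 1 / (4 * pmax(abs(r), eps))
    Xw <- X * w
    beta_new <- tryCatch(
      solve(crossprod(Xw, X), crossprod(Xw, y) + (c1 / 2) * colSums(X)),
      error = function(e) beta)
    delta <- max(abs(beta_new - beta))
    beta <- drop(beta_new)
    if (delta < tol && eps <= 1e-10) break
    if (delta < sqrt(eps)) eps <- max(eps / 10, 1e-10)
  }
  beta
}

# Exact vertex polishing: pick the p observations with the smallest absolute
# residuals as candidate basis, then pivot until the directional-derivative
# optimality condition holds.
polish_qr_vertex <- function(X, y, theta, beta, max_pivots = 500L,
                             tol = 1e-9) {
  n <- nrow(X)
  p <- ncol(X)
  r <- y - drop(X %*% beta)
  h <- order(abs(r))[seq_len(p)]
  B <- X[h, , drop = FALSE]
  if (abs(det(B)) < 1e-12 * max(abs(B), 1)) {
    # fall back: greedily build a non-singular basis from small residuals
    ord <- order(abs(r))
    h <- integer(0)
    for (i in ord) {
      cand <- c(h, i)
      if (qr(X[cand, , drop = FALSE])$rank == length(cand)) h <- cand
      if (length(h) == p) break
    }
    B <- X[h, , drop = FALSE]
  }
  beta <- solve(B, y[h])

  for (pivot in seq_len(max_pivots)) {
    r <- y - drop(X %*% beta)
    r[h] <- 0  # basis residuals are exactly zero
    out <- setdiff(seq_len(n), h)
    psi <- theta - (r[out] < 0)
    v <- drop(crossprod(X[out, , drop = FALSE], psi))
    g <- drop(solve(t(B), v))
    lo <- -theta - tol
    hi <- (1 - theta) + tol
    if (all(g >= lo & g <= hi)) {
      degen <- any(abs(g - (-theta)) < tol | abs(g - (1 - theta)) < tol) ||
        any(abs(r[out]) < tol)
      return(list(beta = beta, basis = sort(h), optimal = TRUE,
                  degenerate = degen))
    }
    j <- which.max(pmax(g - (1 - theta), -theta - g))
    dirsign <- if (g[j] > 1 - theta) 1 else -1
    ej <- numeric(p); ej[j] <- 1
    delta <- dirsign * solve(B, ej)
    xd <- drop(X %*% delta)
    # move along beta + t*delta, t >= 0; loss is convex piecewise linear in t
    slope0 <- -sum((theta - (r[out] < 0)) * xd[out]) + check_loss(-xd[h[j]], theta)
    cand <- out[abs(xd[out]) > 1e-12]
    tvals <- r[cand] / xd[cand]
    keep <- tvals > 1e-14
    cand <- cand[keep]; tvals <- tvals[keep]
    if (length(cand) == 0L) {
      return(list(beta = beta, basis = sort(h), optimal = FALSE,
                  degenerate = TRUE))
    }
    ordt <- order(tvals)
    slope <- slope0
    enter <- cand[ordt[1]]
    for (k in ordt) {
      slope <- slope + abs(xd[cand[k]])
      enter <- cand[k]
      if (slope >= -tol) break
    }
    h[j] <- enter
    B <- X[h, , drop = FALSE]
    if (abs(det(B)) < 1e-14) {
      return(list(beta = beta, basis = sort(h), optimal = FALSE,
                  degenerate = TRUE))
    }
    beta <- solve(B, y[h])
  }
  list(beta = beta, basis = sort(h), optimal = FALSE, degenerate = TRUE)
}
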