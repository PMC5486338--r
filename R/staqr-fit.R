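#' @useDynLib staqr, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Parse a structured additive model formula.  Fixed effects are ordinary
# terms; s(x) declares an RW2 smooth of a continuous covariate; mrf(x)
# declares an intrinsic CAR spatial effect over the adjacency graph;
# re(x) declares an exchangeable (iid) random effect.
parse_staqr_formula <- function(formula) {
  tf <- stats::terms(formula, specials = c("s", "mrf", "re"))
  labels <- attr(tf, "term.labels")
  if (attr(tf, "response") != 1L) stop("formula needs a response")
  response <- deparse(attr(tf, "variables")[[2L]])
  inner_var <- function(lbl) {
    v <- all.vars(str2lang(lbl))
    if (length(v) != 1L) stop("term '", lbl, "' must name a single covariate")
    v
  }
  smooth <- vapply(grep("^s\\(", labels, value = TRUE), inner_var, "")
  spatial <- vapply(grep("^mrf\\(", labels, value = TRUE), inner_var, "")
  iid <- vapply(grep("^re\\(", labels, value = TRUE), inner_var, "")
  fixed <- labels[!grepl("^(s|mrf|re)\\(", labels)]
  if (length(spatial) > 1L) stop("at most one mrf() spatial term is supported")
  list(response = response, fixed = fixed, smooth = unname(smooth),
       spatial = if (length(spatial)) unname(spatial) else NULL,
       iid = if (length(iid)) unname(iid) else NULL)
}

#' Build the design structure of a structured additive predictor
#'
#' Expands a model formula into the fixed-effect design matrix
#' (treatment/dummy coding, first factor level as reference) plus one
#' incidence-indexed penalty block per `s()` smooth (second-order random
#' walk on the covariate's sorted unique values), `mrf()` spatial term
#' (intrinsic CAR over the supplied adjacency graph) and `re()` iid term.
#'
#' @param formula model formula, e.g.
#'   `hb ~ sex + fever + s(child_age) + mrf(district)`.
#' @param data data.frame of child records.
#' @param graph an [adjacency_graph()]; required when the formula contains
#'   an `mrf()` term.  Every district occurring in `data` must be a node of
#'   the graph.
#' @return list with `y` (response vector), `X` (n x p fixed design with
#'   intercept first), and `blocks`: a list of structures each holding
#'   `name`, `kind`, `index` (1-based map of rows to grid points/regions),
#'   `penalty` (a [penalty_block]) and `grid` (values or labels).
#' @export
build_predictor <- function(formula, data, graph = NULL) {
  spec <- parse_staqr_formula(formula)
  if (!spec$response %in% names(data)) {
    stop("response '", spec$response, "' not found in data")
  }
  y <- data[[spec$response]]
  fixed_formula <- if (length(spec$fixed)) {
    stats::reformulate(spec$fixed)
  } else ~1
  X <- stats::model.matrix(fixed_formula, data)
  if (nrow(X) != nrow(data)) stop("missing values in fixed-effect covariates")

  blocks <- list()
  for (v in spec$smooth) {
    x <- data[[v]]
    if (is.null(x)) stop("smooth covariate '", v, "' not found in data")
    if (!is.numeric(x)) stop("smooth covariate '", v, "' must be numeric")
    grid <- sort(unique(x))
    if (length(grid) < 3L) stop("smooth covariate '", v,
                                "' needs at least 3 distinct values")
    idx <- match(x, grid)
    blocks[[length(blocks) + 1L]] <-
      list(name = v, kind = "rw2", index = idx,
           penalty = rw2_precision(grid), grid = grid)
  }
  if (!is.null(spec$spatial)) {
    if (!inherits(graph, "adjacency_graph")) {
      stop("an mrf() term requires an adjacency graph")
    }
    d <- as.character(data[[spec$spatial]])
    idx <- match(d, graph$labels)
    if (anyNA(idx)) {
      stop("unseen district label(s): ",
           paste(unique(d[is.na(idx)]), collapse = ", "))
    }
    blocks[[length(blocks) + 1L]] <-
      list(name = spec$spatial, kind = "icar", index = idx,
           penalty = icar_precision(graph), grid = graph$labels)
  }
  if (!is.null(spec$iid)) {
    for (v in spec$iid) {
      lv <- sort(unique(as.character(data[[v]])))
      blocks[[length(blocks) + 1L]] <-
        list(name = v, kind = "iid", index = match(as.character(data[[v]]), lv),
             penalty = iid_precision(lv), grid = lv)
    }
  }
  names(blocks) <- vapply(blocks, `[[`, "", "name")
  list(y = y, X = X, blocks = blocks, spec = spec)
}

#' Default priors of the Gibbs sampler
#'
#' Diffuse normal priors N(0, 1/`beta_prec`) on fixed effects, inverse
#' gamma IG(`tau_a`, `tau_b`) on every smoothing/spatial variance, and
#' IG(`sig_a`, `sig_b`) on the asymmetric Laplace scale (or the Gaussian
#' error variance).
#'
#' @param beta_prec prior precision of fixed effects (default `1e-6`,
#'   i.e. variance `1e6`).
#' @param tau_a,tau_b inverse-gamma hyperparameters of the structured-block
#'   variances (default IG(1, 0.005), the common structured-additive
#'   choice).
#' @param sig_a,sig_b inverse-gamma hyperparameters of the likelihood scale
#'   (default IG(0.001, 0.001)).
#' @return named list of prior settings.
#' @export
staqr_priors <- function(beta_prec = 1e-6, tau_a = 1, tau_b = 0.005,
                         sig_a = 0.001, sig_b = 0.001) {
  list(beta_prec = beta_prec, tau_a = tau_a, tau_b = tau_b,
       sig_a = sig_a, sig_b = sig_b)
}

#' Bayesian structured additive quantile regression
#'
#' Fits the additive conditional quantile model
#' \deqn{Q_{y_i}(\theta \mid x_i, u_i) = x_i'\beta_\theta +
#'   \sum_k f_{\theta k}(u_{ki}) + f_\theta(\mathrm{district}_i)}
#' by Gibbs sampling under the asymmetric Laplace working likelihood,
#' using its normal-exponential scale mixture for closed-form full
#' conditionals.  Smooth terms `s(x)` carry second-order random-walk
#' priors on the sorted unique covariate values; the spatial term
#' `mrf(district)` carries an intrinsic CAR (Besag) prior over the
#' adjacency graph; `re(g)` adds an exchangeable random effect.  Smooth,
#' spatial and iid blocks are re-centred to sum to zero at every iteration
#' with the removed mean absorbed into the intercept.  With
#' `likelihood = "gaussian"` the same skeleton fits the mean-regression
#' model with conjugate updates (no `theta`).
#'
#' @param formula model formula; see [build_predictor()].
#' @param data data.frame of child records.
#' @param theta quantile level in (0, 1); ignored (and absent from the
#'   result) for the Gaussian likelihood.
#' @param likelihood `"al"` (asymmetric Laplace, quantile regression) or
#'   `"gaussian"` (mean regression).
#' @param graph [adjacency_graph()] for the `mrf()` term.
#' @param iters,burnin,thin MCMC settings (defaults 12000 / 2000 / 5,
#'   giving 2000 stored draws).
#' @param seed integer seed making the whole chain reproducible.
#' @param priors see [staqr_priors()].
#' @return an object of class `staqr`; a list with the data/design, the
#'   posterior draws of every block (`draws$beta`, `draws$f`, `draws$tau2`,
#'   `draws$sigma`, per-draw `draws$deviance`), posterior mean predictor
#'   `etabar`, DIC components (`dic`), and MCMC metadata (`mcmc`).
#'   Supported methods: `print`, `summary`, `coef`, `fitted`, `residuals`,
#'   `predict`, `plot`, `simulate`.
#' @examples
#' sim <- generate_dataset(sim_config(n_children = 400, seed = 1))
#' fit <- staqr(hb ~ sex + fever, data = sim$data, theta = 0.5,
#'              iters = 600, burnin = 200, thin = 2, seed = 1)
#' coef(fit)
#' @export
staqr <- function(formula, data, theta = 0.37,
                  likelihood = c("al", "gaussian"), graph = NULL,
                  iters = 12000, burnin = 2000, thin = 5, seed = NULL,
                  priors = staqr_priors()) {
  likelihood <- match.arg(likelihood)
  if (likelihood == "al") check_theta(theta) else theta <- NA_real_
  if (iters <= burnin) stop("'iters' must exceed 'burnin'")
  if (thin < 1L) stop("'thin' must be >= 1")
  design <- build_predictor(formula, data, graph)
  y <- design$y
  if (!is.numeric(y)) stop("response must be numeric")
  if (anyNA(y)) stop("missing values in the response")
  if (!is.null(seed)) set.seed(seed)

  res <- gibbs_staqr(
    y, design$X,
    lapply(design$blocks, function(b) as.integer(b$index - 1L)),
    lapply(design$blocks, function(b) b$penalty$K),
    vapply(design$blocks, function(b) as.integer(b$penalty$rank),
           integer(1)),
    if (is.na(theta)) 0.5 else theta,
    likelihood == "gaussian",
    as.integer(iters), as.integer(burnin), as.integer(thin), priors)

  colnames(res$beta) <- colnames(design$X)
  names(res$f) <- names(design$blocks)
  if (length(design$blocks)) {
    colnames(res$tau2) <- names(design$blocks)
    for (j in seq_along(res$f)) {
      colnames(res$f[[j]]) <- as.character(design$blocks[[j]]$grid)
    }
  }

  fit <- structure(list(
    call = match.call(), formula = formula, likelihood = likelihood,
    theta = theta, y = y, X = design$X, blocks = design$blocks,
    graph = graph, draws = res[c("beta", "f", "tau2", "sigma", "deviance")],
    etabar = drop(res$etabar), n = length(y), ndraw = res$ndraw,
    mcmc = list(iters = iters, burnin = burnin, thin = thin, seed = seed),
    data_checksum = dataset_checksum(y)), class = "staqr")
  fit$dic <- compute_dic(fit)
  fit
}

dataset_checksum <- function(y) {
  c(n = length(y), sum = sum(y), ss = sum(y^2))
}

#' Deviance information criterion of a fitted model
#'
#' Computes \eqn{\bar D} (posterior mean deviance), the deviance at the
#' posterior means of the predictor and scale, the effective number of
#' parameters \eqn{p_D = \bar D - D(\hat\eta, \hat\sigma)}, and
#' \eqn{DIC = \bar D + p_D}.  The deviance is \eqn{-2\sum_i \log f(y_i)}
#' under the model's likelihood (asymmetric Laplace or Gaussian), so DIC
#' values are computed identically across the model ladder.
#'
#' @param fit a fitted [staqr()] model.
#' @param y optional response vector to evaluate on (defaults to the
#'   fitting data).
#' @return named numeric vector `c(Dbar, D_at_mean, pD, DIC)`.
#' @export
compute_dic <- function(fit, y = NULL) {
  stopifnot(inherits(fit, "staqr"))
  if (fit$ndraw < 50L) stop("need at least 50 post-burn-in draws for DIC")
  if (is.null(y)) y <- fit$y
  etabar <- posterior_eta(fit)
  sigbar <- mean(fit$draws$sigma)
  Dbar <- mean(fit$draws$deviance)
  Dhat <- if (fit$likelihood == "al") {
    -2 * sum(al_logpdf(y, etabar, sigbar, fit$theta))
  } else {
    -2 * sum(stats::dnorm(y, etabar, sqrt(sigbar), log = TRUE))
  }
  pD <- Dbar - Dhat
  c(Dbar = Dbar, D_at_mean = Dhat, pD = pD, DIC = Dbar + pD)
}

# posterior-mean linear predictor reconstructed from the stored draws
posterior_eta <- function(fit) {
  eta <- drop(fit$X %*% colMeans(fit$draws$beta))
  for (j in seq_along(fit$blocks)) {
    fbar <- colMeans(fit$draws$f[[j]])
    eta <- eta + fbar[fit$blocks[[j]]$index]
  }
  unname(eta)
}

#' DIC from printed deviance components
#'
#' The arithmetic identity `DIC = D + 2 * pD` linking a reported deviance
#' at the posterior mean `D` and effective parameter count `pD` to the
#' DIC; used when checking reported model-comparison tables for internal
#' consistency.
#'
#' @param D deviance at the posterior mean (or `Dbar - pD`).
#' @param pD effective number of parameters.
#' @return the DIC value(s).
#' @examples
#' dic_identity(10542.2, 43.82)  # 10629.84
#' @export
dic_identity <- function(D, pD) {
  D + 2 * pD
}
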