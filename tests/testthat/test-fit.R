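test_that("the design expands dummy coding and incidence maps correctly", {
  sim <- generate_dataset(sim_config(n_children = 300, seed = 1))
  d <- sim$data
  des <- build_predictor(hb ~ sex, d)
  expect_equal(colnames(des$X), c("(Intercept)", "sexmale"))  # female = ref
  expect_length(des$blocks, 0)

  des2 <- build_predictor(hb ~ sex + s(child_age) + mrf(district), d,
                          graph = sim$graph)
  expect_equal(names(des2$blocks), c("child_age", "district"))
  b <- des2$blocks$child_age
  expect_equal(b$grid, sort(unique(d$child_age)))
  # incidence: every row maps to exactly one grid point, and back
  expect_equal(b$grid[b$index], d$child_age)
  expect_equal(des2$blocks$district$penalty$kind, "icar")

  # unseen district label is an error
  d2 <- d
  levels(d2$district) <- c(levels(d2$district)[-1], "Atlantis")
  expect_error(build_predictor(hb ~ mrf(district), d2, graph = sim$graph),
               "unseen district")
  expect_error(build_predictor(hb ~ mrf(district), d), "adjacency graph")
})

test_that("an intercept-only median fit recovers the sample median", {
  set.seed(14)
  d <- data.frame(hb = rnorm(2000, 3, 1))
  fit <- staqr(hb ~ 1, d, theta = 0.5, iters = 2500, burnin = 500,
               thin = 2, seed = 1)
  expect_lt(abs(median(fit$draws$beta[, 1]) - median(d$hb)), 0.08)
})

test_that("posterior intercepts are calibrated at their quantile level", {
  set.seed(15)
  d <- data.frame(hb = rnorm(5000, 11, 1.4))
  for (th in c(0.21, 0.37)) {
    fit <- staqr(hb ~ 1, d, theta = th, iters = 2500, burnin = 500,
                 thin = 2, seed = 2)
    below <- mean(d$hb < mean(fit$draws$beta[, 1]))
    expect_lt(abs(below - th), 0.02)
  }
})

test_that("chains are reproducible from the seed", {
  sim <- generate_dataset(sim_config(n_children = 400, seed = 3))
  args <- list(hb ~ sex + fever + s(child_age), sim$data, theta = 0.37,
               iters = 800, burnin = 200, thin = 2, seed = 99)
  f1 <- do.call(staqr, args)
  f2 <- do.call(staqr, args)
  expect_identical(f1$draws, f2$draws)
  f3 <- do.call(staqr, modifyList(args, list(seed = 100)))
  expect_false(identical(f1$draws$beta, f3$draws$beta))
})

test_that("stored smooth and spatial draws satisfy the sum-to-zero
          constraint and variances stay positive", {
  sim <- generate_dataset(sim_config(n_children = 800, seed = 4))
  fit <- staqr(hb ~ sex + s(child_age) + mrf(district), sim$data,
               theta = 0.37, graph = sim$graph, iters = 1200, burnin = 400,
               thin = 2, seed = 5)
  for (nm in names(fit$draws$f)) {
    expect_lt(max(abs(rowMeans(fit$draws$f[[nm]]))), 1e-8)
  }
  expect_true(all(fit$draws$tau2 > 0))
  expect_true(all(fit$draws$sigma > 0))
  expect_gt(fit$dic["pD"], 0)
})

test_that("fixed-effects-only posterior medians track the exact LP fit", {
  sim <- generate_dataset(sim_config(n_children = 1500, seed = 6))
  fit <- staqr(hb ~ sex + fever + wealth, sim$data, theta = 0.37,
               iters = 3000, burnin = 1000, thin = 2, seed = 7)
  lp <- fit_linear_qr(fit$X, sim$data$hb, 0.37)
  gibbs <- apply(fit$draws$beta, 2, median)
  expect_lt(max(abs(gibbs - lp)), 0.1)
})

test_that("the Gaussian likelihood gives a conjugate mean-model fit", {
  set.seed(16)
  n <- 1500
  x <- rnorm(n)
  d <- data.frame(hb = 2 + 0.8 * x + rnorm(n, 0, 1.2), x = x)
  fit <- staqr(hb ~ x, d, likelihood = "gaussian", iters = 2000,
               burnin = 500, thin = 2, seed = 8)
  ls <- lm(hb ~ x, d)
  expect_lt(max(abs(coef(fit) - coef(ls))), 0.05)
  expect_lt(abs(mean(fit$draws$sigma) - sigma(ls)^2), 0.1)
  expect_true(is.na(fit$theta))
})

test_that("DIC components obey their defining identities", {
  sim <- generate_dataset(sim_config(n_children = 600, seed = 9))
  fit <- staqr(hb ~ sex + fever, sim$data, theta = 0.37, iters = 1500,
               burnin = 500, thin = 2, seed = 10)
  dic <- compute_dic(fit)
  expect_equal(unname(dic["pD"]), unname(dic["Dbar"] - dic["D_at_mean"]))
  expect_equal(unname(dic["DIC"]), unname(dic["Dbar"] + dic["pD"]))
  expect_equal(unname(dic["DIC"]),
               unname(dic["D_at_mean"] + 2 * dic["pD"]))
  expect_equal(unname(dic), unname(fit$dic))

  # a degenerate chain with identical draws has pD = 0 and DIC = Dbar
  deg <- fit
  pick <- function(m) m[rep(1L, nrow(m)), , drop = FALSE]
  deg$draws$beta <- pick(fit$draws$beta)
  deg$draws$sigma <- rep(fit$draws$sigma[1], fit$ndraw)
  eta1 <- drop(fit$X %*% fit$draws$beta[1, ])
  dev1 <- -2 * sum(al_logpdf(fit$y, eta1, fit$draws$sigma[1], 0.37))
  deg$draws$deviance <- rep(dev1, fit$ndraw)
  dic_deg <- compute_dic(deg)
  expect_equal(unname(dic_deg["pD"]), 0, tolerance = 1e-8)
  expect_equal(unname(dic_deg["DIC"]), unname(dic_deg["Dbar"]))

  # too few draws is an error
  short <- fit
  short$ndraw <- 10L
  expect_error(compute_dic(short), "at least 50")
})

test_that("printed deviance components recombine into the DIC", {
  expect_equal(dic_identity(0, 0), 0)
  expect_equal(dic_identity(10660.2, 23.74), 10707.68)
  expect_equal(dic_identity(10931, 32.98), 10996.96)
})

test_that("fit methods are coherent with the stored draws", {
  sim <- generate_dataset(sim_config(n_children = 500, seed = 11))
  fit <- staqr(hb ~ sex + s(child_age), sim$data, theta = 0.37,
               iters = 1200, burnin = 400, thin = 2, seed = 12)
  expect_equal(unname(coef(fit)), unname(colMeans(fit$draws$beta)))
  expect_equal(fitted(fit) + residuals(fit), sim$data$hb)
  expect_equal(predict(fit), fitted(fit))
  # newdata prediction matches manual assembly on observed grid values
  nd <- sim$data[3:7, ]
  expect_equal(predict(fit, nd), fitted(fit)[3:7])
  nd_bad <- nd
  nd_bad$child_age <- 200
  expect_error(predict(fit, nd_bad), "outside the fitted grid")
  # simulate returns plausible posterior-predictive draws
  ysim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(ysim), c(500L, 2L))
  expect_lt(abs(mean(ysim[[1]]) - mean(sim$data$hb)), 1)
  s <- summary(fit)
  expect_true(all(c("mean", "sd", "lower", "upper") %in% names(s$fixed)))
  expect_output(print(fit), "quantile regression")
})

test_that("invalid sampler settings are rejected", {
  d <- data.frame(hb = rnorm(30))
  expect_error(staqr(hb ~ 1, d, iters = 100, burnin = 200), "exceed")
  expect_error(staqr(hb ~ 1, d, theta = 1.5), "between 0 and 1")
})
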